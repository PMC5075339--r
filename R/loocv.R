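#' Assemble a DDI family from its files
#'
#' Reads the two labeled alignments and the per-pair ground-truth contact
#' matrices written by [write_family()] and pairs rows by their shared
#' `<pair>_a` / `<pair>_b` naming.
#'
#' @param dir Directory holding `<family>_A.sto`, `<family>_B.sto` and
#'   `<family>_<pair>_contacts.tsv`.
#' @param family_id Family identifier (file prefix).
#' @return A `ddi_family` list usable by [loocv_family()].
#' @export
read_family <- function(dir, family_id) {
  aln_a <- read_labeled_alignment(file.path(dir, sprintf("%s_A.sto", family_id)),
                                  family_id = family_id, domain_role = "A")
  aln_b <- read_labeled_alignment(file.path(dir, sprintf("%s_B.sto", family_id)),
                                  family_id = family_id, domain_role = "B")
  cm_files <- list.files(dir, sprintf("^%s_.+_contacts\\.tsv$", family_id),
                         full.names = TRUE)
  if (length(cm_files) == 0L) stop_format("no contact matrices found in %s", dir)
  contacts <- map(cm_files, read_contact_matrix)
  names(contacts) <- map_chr(contacts, "pair_id")
  pair_ids <- sort(names(contacts))
  contacts <- contacts[pair_ids]
  pairs <- tibble(pair_id = pair_ids,
                  seq_a = paste0(pair_ids, "_a"),
                  seq_b = paste0(pair_ids, "_b"))
  if (!all(pairs$seq_a %in% aln_a$seq_ids) ||
      !all(pairs$seq_b %in% aln_b$seq_ids)) {
    stop_format("alignment rows do not cover all contact-matrix pairs")
  }
  structure(list(family_id = family_id, aln_a = aln_a, aln_b = aln_b,
                 contacts = contacts, pairs = pairs),
            class = "ddi_family")
}

# ground-truth site labels of one pair, from its ground-truth contact matrix
truth_labels_from_cm <- function(cm, domain_role, occupied) {
  margin <- if (domain_role == "A") rowSums(cm$cells) else colSums(cm$cells)
  ifelse(margin > 0, "interacting", "non_interacting")[occupied]
}

#' Cross-validated evaluation of one DDI family
#'
#' Runs the full pipeline under leave-one-out (default) or k-fold
#' cross-validation over the family's sequence pairs. For each held-out
#' pair: the two ipHMMs are rebuilt without it (one alignment row fewer per
#' domain); the contact SVM is trained on the remaining pairs'
#' residue-pair examples; the per-domain logistic site models are trained
#' on the remaining pairs' residues (positives oversampled to balance),
#' using each training pair's own reserved out-of-fold predictions as
#' features; and all requested methods are evaluated on the held-out pair.
#' No held-out information enters any model applied to it.
#'
#' Ground-truth site labels are derived from the ground-truth contact
#' matrices (a residue is an interaction site iff its matrix row/column
#' contains a contact); the alignment's label track is used only to train
#' the ipHMMs.
#'
#' @param family A `ddi_family` or `synthetic_family` (fields `family_id`,
#'   `aln_a`, `aln_b`, `contacts`, `pairs`).
#' @param aaindex An [aaindex_table()] (default the 17-property table).
#' @param methods Subset of `"iphmm"`, `"cm_iphmm"`, `"cm_only"`,
#'   `"ground_truth_cm"`.
#' @param pseudocount ipHMM smoothing count.
#' @param window AAindex window width.
#' @param gamma,cost RBF-SVM parameters (`gamma = NULL` means 1/n-features).
#' @param C Logistic inverse penalty.
#' @param threshold Site-call threshold on probabilities.
#' @param cv `"loocv"` or `"tenfold"`.
#' @param n_folds Fold count when `cv = "tenfold"` (default 10; must not
#'   exceed the number of pairs).
#' @param site_feature ipHMM feature fed to the integrator: continuous
#'   posterior `"p_int"` (default) or the `"binary"` call.
#' @param cm_feature Contact-matrix feature source: `"binary"` (default) or
#'   `"score"`.
#' @param seed Integer seed driving oversampling (and fold assignment for
#'   k-fold).
#' @return Tibble with one row per (method, evaluated residue):
#'   `family_id`, `pair_id`, `domain_role`, `seq_id`, `match_index`,
#'   `method`, `label_true`, `label_pred`, `score`.
#' @export
loocv_family <- function(family,
                         aaindex = default_aaindex(),
                         methods = c("iphmm", "cm_iphmm", "cm_only",
                                     "ground_truth_cm"),
                         pseudocount = 1, window = 11L, gamma = NULL,
                         cost = 1, C = 1, threshold = 0.5,
                         cv = c("loocv", "tenfold"), n_folds = 10L,
                         site_feature = c("p_int", "binary"),
                         cm_feature = c("binary", "score"),
                         seed = 1L) {
  cv <- match.arg(cv)
  site_feature <- match.arg(site_feature)
  cm_feature <- match.arg(cm_feature)
  methods <- match.arg(methods, several.ok = TRUE)
  pairs <- family$pairs
  n_pairs <- nrow(pairs)
  if (n_pairs < 2L) {
    warn(sprintf("family %s has fewer than 2 pairs; skipped",
                 family$family_id))
    return(tibble())
  }
  fold_of <- if (cv == "loocv") {
    seq_len(n_pairs)
  } else {
    if (n_folds > n_pairs) {
      stop_param("%d folds exceed the %d pairs of family %s",
                 n_folds, n_pairs, family$family_id)
    }
    withr::with_seed(as.integer(seed),
                     sample(rep_len(seq_len(n_folds), n_pairs)))
  }
  folds <- sort(unique(fold_of))
  need_cm <- any(methods %in% c("cm_iphmm", "cm_only"))

  maps_a <- setNames(map(pairs$seq_a, ~match_residue_map(family$aln_a, .x)),
                     pairs$pair_id)
  maps_b <- setNames(map(pairs$seq_b, ~match_residue_map(family$aln_b, .x)),
                     pairs$pair_id)
  seqs_a <- setNames(map_chr(pairs$seq_a, ~ungapped_sequence(family$aln_a, .x)),
                     pairs$pair_id)
  seqs_b <- setNames(map_chr(pairs$seq_b, ~ungapped_sequence(family$aln_b, .x)),
                     pairs$pair_id)

  # phase 1: per fold, rebuild ipHMMs, decode, train the contact SVM on the
  # training pairs, and reserve the held-out pairs' predictions
  reserved <- list()
  for (f in folds) {
    test_ids <- pairs$pair_id[fold_of == f]
    train_ids <- pairs$pair_id[fold_of != f]
    hmm_a <- build_iphmm(
      drop_alignment_rows(family$aln_a, pairs$seq_a[fold_of == f]),
      pseudocount)
    hmm_b <- build_iphmm(
      drop_alignment_rows(family$aln_b, pairs$seq_b[fold_of == f]),
      pseudocount)
    pad <- aaindex_training_means(aaindex, c(seqs_a[train_ids],
                                             seqs_b[train_ids]))
    dec_a <- map(seqs_a, ~forward_backward(hmm_a, .x))
    dec_b <- map(seqs_b, ~forward_backward(hmm_b, .x))
    fis_a <- map(dec_a, ~fisher_scores(hmm_a, .x))
    fis_b <- map(dec_b, ~fisher_scores(hmm_b, .x))

    cm_model <- NULL
    if (need_cm) {
      xs <- list(); ys <- list()
      for (q in train_ids) {
        fr <- pair_feature_rows(fis_a[[q]], fis_b[[q]], maps_a[[q]],
                                maps_b[[q]], seqs_a[q], seqs_b[q],
                                aaindex, window = window, pad = pad)
        if (nrow(fr$cells) == 0L) next
        xs[[q]] <- fr$x
        ys[[q]] <- family$contacts[[q]]$cells[fr$cells]
      }
      cm_model <- train_contact_svm(do.call(rbind, xs), unlist(ys),
                                    gamma = gamma, cost = cost)
    }

    for (p in test_ids) {
      occ_a <- !is.na(maps_a[[p]]); occ_b <- !is.na(maps_b[[p]])
      sites_a <- predict_sites(dec_a[[p]], occupied = occ_a,
                               threshold = threshold)
      sites_b <- predict_sites(dec_b[[p]], occupied = occ_b,
                               threshold = threshold)
      cm_pred <- if (need_cm) {
        predict_contact_matrix(cm_model, fis_a[[p]], fis_b[[p]],
                               maps_a[[p]], maps_b[[p]],
                               seqs_a[p], seqs_b[p], aaindex,
                               window = window, pad = pad,
                               family_id = family$family_id, pair_id = p)
      }
      reserved[[p]] <- list(sites_a = sites_a, sites_b = sites_b,
                            occ_a = occ_a, occ_b = occ_b,
                            cm_pred = cm_pred)
    }
  }

  site_score <- function(sites) {
    if (site_feature == "p_int") sites$p_int
    else as.numeric(sites$call == "interacting")
  }
  feature_cm <- function(res, variant, pid) {
    if (variant == "ground_truth_cm") family$contacts[[pid]]
    else if (cm_feature == "binary") res$cm_pred$binary
    else res$cm_pred$score
  }

  # phase 2: integrated site models per fold, trained on the training
  # pairs' reserved out-of-fold features, evaluated on the held-out pairs
  out <- list()
  seed_k <- 0L
  for (f in folds) {
    test_ids <- pairs$pair_id[fold_of == f]
    train_ids <- pairs$pair_id[fold_of != f]
    for (variant in intersect(methods, c("cm_iphmm", "cm_only",
                                         "ground_truth_cm"))) {
      feat_variant <- if (variant == "cm_only") "cm_only" else "cm_iphmm"
      for (role in c("A", "B")) {
        train_rows <- bind_rows(map(train_ids, function(q) {
          res <- reserved[[q]]
          occ <- if (role == "A") res$occ_a else res$occ_b
          sites <- if (role == "A") res$sites_a else res$sites_b
          ft <- build_site_features(feature_cm(res, variant, q),
                                    site_score(sites),
                                    domain_role = role,
                                    variant = feat_variant, occupied = occ)
          ft$label <- truth_labels_from_cm(family$contacts[[q]], role,
                                           occ) == "interacting"
          ft
        }))
        seed_k <- seed_k + 1L
        balanced <- oversample_positives(train_rows,
                                         seed = as.integer(seed) + seed_k)
        model <- train_site_model(balanced, domain_role = role,
                                  variant = variant, C = C)
        for (p in test_ids) {
          res <- reserved[[p]]
          occ <- if (role == "A") res$occ_a else res$occ_b
          sites <- if (role == "A") res$sites_a else res$sites_b
          ft <- build_site_features(feature_cm(res, variant, p),
                                    site_score(sites),
                                    domain_role = role,
                                    variant = feat_variant, occupied = occ)
          pr <- predict_sites_integrated(model, ft)
          out[[length(out) + 1L]] <- tibble(
            family_id = family$family_id, pair_id = p, domain_role = role,
            seq_id = if (role == "A") pairs$seq_a[pairs$pair_id == p]
            else pairs$seq_b[pairs$pair_id == p],
            match_index = pr$match_index, method = variant,
            label_true = truth_labels_from_cm(family$contacts[[p]], role, occ),
            label_pred = pr$call, score = pr$probability)
        }
      }
    }
    if ("iphmm" %in% methods) {
      for (p in test_ids) {
        res <- reserved[[p]]
        for (role in c("A", "B")) {
          occ <- if (role == "A") res$occ_a else res$occ_b
          sites <- if (role == "A") res$sites_a else res$sites_b
          keep <- sites$match_index %in% which(occ)
          out[[length(out) + 1L]] <- tibble(
            family_id = family$family_id, pair_id = p, domain_role = role,
            seq_id = if (role == "A") pairs$seq_a[pairs$pair_id == p]
            else pairs$seq_b[pairs$pair_id == p],
            match_index = sites$match_index[keep], method = "iphmm",
            label_true = truth_labels_from_cm(family$contacts[[p]], role, occ),
            label_pred = sites$call[keep], score = sites$p_int[keep])
        }
      }
    }
  }
  bind_rows(out)
}

#' Per-sequence metrics from a prediction table
#'
#' @param predictions Tibble as returned by [loocv_family()].
#' @return Tibble with one row per (method, sequence) carrying confusion
#'   counts and [compute_metrics()] columns.
#' @export
evaluate_predictions <- function(predictions) {
  predictions |>
    group_by(.data$method, .data$family_id, .data$pair_id,
             .data$domain_role, .data$seq_id) |>
    summarise(confusion_counts(.data$label_true, .data$label_pred),
              .groups = "drop") |>
    dplyr::rowwise() |>
    mutate(compute_metrics(.data$tp, .data$tn, .data$fp, .data$fn)[, -(1:4)]) |>
    ungroup()
}

#' Evaluate a benchmark of families end to end
#'
#' Runs [loocv_family()] on every family, aggregates per-sequence metrics
#' ([aggregate_report()]) and computes paired t-tests on per-sequence MCC
#' between the integrated model and its ablations.
#'
#' @param families List of families ([benchmark_suite()] output or
#'   [read_family()] objects).
#' @param ... Passed to [loocv_family()].
#' @param seed Integer seed; family i runs with `seed + i`.
#' @return A `benchmark_result`: `predictions`, `per_sequence`, `report`
#'   (a `metrics_report`) and `tests` (paired-t table).
#' @export
evaluate_benchmark <- function(families, ..., seed = 1L) {
  predictions <- bind_rows(map(seq_along(families), function(i) {
    loocv_family(families[[i]], ..., seed = as.integer(seed) + i)
  }))
  per_sequence <- evaluate_predictions(predictions)
  report <- aggregate_report(per_sequence)
  wide <- per_sequence |>
    select("method", "family_id", "pair_id", "domain_role", "mcc") |>
    tidyr::pivot_wider(names_from = "method", values_from = "mcc")
  test_pairs <- list(c("cm_iphmm", "iphmm"), c("cm_iphmm", "cm_only"),
                     c("ground_truth_cm", "cm_iphmm"))
  tests <- bind_rows(map(test_pairs, function(tp) {
    if (!all(tp %in% names(wide))) return(NULL)
    paired_t_test(wide[[tp[1]]], wide[[tp[2]]]) |>
      mutate(method_a = tp[1], method_b = tp[2], .before = 1)
  }))
  structure(list(predictions = predictions, per_sequence = per_sequence,
                 report = report, tests = tests),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$report$overall)
  cat("paired t-tests on per-sequence MCC:\n")
  print(x$tests)
  invisible(x)
}
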