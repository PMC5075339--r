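# FNV-1a hash of the deparsed run configuration; stamped into output file
# names so every artifact records the configuration + seed that produced it
#' @keywords internal
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Simulate synthetic DDI families to disk
#'
#' @param out_dir Output directory.
#' @param n_families Number of families.
#' @param spec A [family_spec()] used as the base parameters.
#' @param seed Integer seed.
#' @return Character vector of family ids, invisibly.
#' @export
run_simulate <- function(out_dir, n_families = 10L, spec = family_spec(),
                         seed = 1L) {
  fams <- if (n_families == 1L) {
    list(sample_family(family_spec_with_seed(spec, seed), "fam01"))
  } else {
    benchmark_suite(n_families, base_spec = spec, seed = seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (fam in fams) write_family(fam, out_dir)
  message(sprintf("wrote %d families to %s (seed %d)",
                  length(fams), out_dir, seed))
  invisible(map_chr(fams, "family_id"))
}

#' @keywords internal
family_spec_with_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  do.call(family_spec, unclass(spec))
}

#' Build and serialize an ipHMM from an alignment file
#'
#' @param alignment_path Labeled-alignment file.
#' @param model_path Output JSON model path.
#' @param dialect Alignment dialect (see [read_labeled_alignment()]).
#' @param pseudocount Smoothing count.
#' @return `model_path`, invisibly.
#' @export
run_build_hmm <- function(alignment_path, model_path,
                          dialect = "stockholm_markup", pseudocount = 1) {
  aln <- read_labeled_alignment(alignment_path, dialect = dialect)
  model <- build_iphmm(aln, pseudocount = pseudocount)
  write_iphmm(model, model_path)
  message(sprintf("built ipHMM with %d match positions -> %s",
                  model$n_match, model_path))
  invisible(model_path)
}

#' Contact-matrix prediction for one held-out pair
#'
#' One fold of the contact stage: rebuilds both ipHMMs without the target
#' pair, trains the contact SVM on the remaining pairs, and predicts the
#' target pair's contact matrix.
#'
#' @param family A `ddi_family` / `synthetic_family`.
#' @param pair_id The held-out pair.
#' @inheritParams loocv_family
#' @return List with [contact_matrix()] elements `binary` and `score`.
#' @export
predict_pair_contacts <- function(family, pair_id,
                                  aaindex = default_aaindex(),
                                  pseudocount = 1, window = 11L,
                                  gamma = NULL, cost = 1) {
  pairs <- family$pairs
  if (!pair_id %in% pairs$pair_id) {
    stop_param("unknown pair '%s' in family %s", pair_id, family$family_id)
  }
  hold <- pairs$pair_id == pair_id
  hmm_a <- build_iphmm(drop_alignment_rows(family$aln_a, pairs$seq_a[hold]),
                       pseudocount)
  hmm_b <- build_iphmm(drop_alignment_rows(family$aln_b, pairs$seq_b[hold]),
                       pseudocount)
  seqs_a <- setNames(map_chr(pairs$seq_a, ~ungapped_sequence(family$aln_a, .x)),
                     pairs$pair_id)
  seqs_b <- setNames(map_chr(pairs$seq_b, ~ungapped_sequence(family$aln_b, .x)),
                     pairs$pair_id)
  maps_a <- setNames(map(pairs$seq_a, ~match_residue_map(family$aln_a, .x)),
                     pairs$pair_id)
  maps_b <- setNames(map(pairs$seq_b, ~match_residue_map(family$aln_b, .x)),
                     pairs$pair_id)
  train_ids <- pairs$pair_id[!hold]
  pad <- aaindex_training_means(aaindex, c(seqs_a[train_ids], seqs_b[train_ids]))
  fis <- function(hmm, s) fisher_scores(hmm, forward_backward(hmm, s))
  xs <- list(); ys <- list()
  fis_a <- map(seqs_a, ~fis(hmm_a, .x))
  fis_b <- map(seqs_b, ~fis(hmm_b, .x))
  for (q in train_ids) {
    fr <- pair_feature_rows(fis_a[[q]], fis_b[[q]], maps_a[[q]], maps_b[[q]],
                            seqs_a[q], seqs_b[q], aaindex,
                            window = window, pad = pad)
    if (nrow(fr$cells) == 0L) next
    xs[[q]] <- fr$x
    ys[[q]] <- family$contacts[[q]]$cells[fr$cells]
  }
  cm_model <- train_contact_svm(do.call(rbind, xs), unlist(ys),
                                gamma = gamma, cost = cost)
  predict_contact_matrix(cm_model, fis_a[[pair_id]], fis_b[[pair_id]],
                         maps_a[[pair_id]], maps_b[[pair_id]],
                         seqs_a[pair_id], seqs_b[pair_id], aaindex,
                         window = window, pad = pad,
                         family_id = family$family_id, pair_id = pair_id)
}

#' Site and contact predictions for one pair of one family
#'
#' Writes the held-out pair's predicted contact matrices (binary and score)
#' and its per-residue site predictions for the requested methods.
#'
#' @param dir Directory with the family's files (see [read_family()]).
#' @param family_id Family identifier.
#' @param pair_id Held-out pair.
#' @param out_dir Output directory.
#' @param ... Passed to [loocv_family()].
#' @param seed Integer seed.
#' @return Paths of the written files, invisibly.
#' @export
run_predict <- function(dir, family_id, pair_id, out_dir = dir, ...,
                        seed = 1L) {
  family <- read_family(dir, family_id)
  cfg <- c(list(family_id = family_id, pair_id = pair_id, seed = seed),
           list(...))
  tag <- sprintf("%s_%s_cfg%s_seed%d", family_id, pair_id,
                 config_hash(cfg), seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cms <- predict_pair_contacts(family, pair_id)
  f_bin <- file.path(out_dir, sprintf("%s_predicted_binary.tsv", tag))
  f_sc <- file.path(out_dir, sprintf("%s_predicted_score.tsv", tag))
  write_contact_matrix(cms$binary, f_bin)
  write_contact_matrix(cms$score, f_sc)
  preds <- loocv_family(family, ..., seed = seed) |>
    filter(.data$pair_id == !!pair_id)
  f_pred <- file.path(out_dir, sprintf("%s_sites.tsv", tag))
  write_predictions(preds, f_pred)
  message(sprintf("wrote %s, %s, %s", f_bin, f_sc, f_pred))
  invisible(c(f_bin, f_sc, f_pred))
}

#' Cross-validated evaluation over families on disk
#'
#' Reads every family in `dir`, runs the cross-validated pipeline, and
#' writes a JSON report (per-sequence, per-family, overall metric blocks
#' plus the paired-test table), a human-readable TSV summary, and the full
#' prediction table.
#'
#' @param dir Directory with family files.
#' @param out_dir Output directory.
#' @param ... Passed to [loocv_family()] (methods, cv protocol, stage
#'   parameters).
#' @param seed Integer seed.
#' @return Paths of the written files, invisibly.
#' @export
run_evaluate <- function(dir, out_dir = dir, ..., seed = 1L) {
  ids <- sub("_A\\.sto$", "", basename(list.files(dir, "_A\\.sto$")))
  if (length(ids) == 0L) stop_format("no families found in %s", dir)
  families <- map(ids, ~read_family(dir, .x))
  res <- evaluate_benchmark(families, ..., seed = seed)
  cfg <- c(list(families = ids, seed = seed), list(...))
  tag <- sprintf("evaluation_cfg%s_seed%d", config_hash(cfg), seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_json <- file.path(out_dir, paste0(tag, ".json"))
  jsonlite::write_json(
    list(config = cfg[names(cfg) != "families"],
         overall = res$report$overall, per_family = res$report$per_family,
         per_sequence = res$per_sequence, paired_tests = res$tests),
    f_json, digits = NA, auto_unbox = TRUE)
  f_tsv <- file.path(out_dir, paste0(tag, "_summary.tsv"))
  utils::write.table(res$report$overall, f_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_pred <- file.path(out_dir, paste0(tag, "_predictions.tsv"))
  write_predictions(res$predictions, f_pred)
  message(sprintf("wrote %s, %s, %s", f_json, f_tsv, f_pred))
  invisible(c(f_json, f_tsv, f_pred))
}
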