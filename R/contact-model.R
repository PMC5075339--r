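#' Windowed amino-acid property features for one residue
#'
#' Flattens the property values of a sliding window centred on the target
#' residue (window order -5..+5 for the default width 11, property order as
#' in the table) into one vector of length `window * n_properties`
#' (11 x 17 = 187 by default). Window slots falling outside the sequence are
#' padded with `pad` (one value per property; by default the per-property
#' mean over the 20 amino acids, in the pipeline the per-property mean over
#' the training residues).
#'
#' @param seq Amino-acid string.
#' @param aaindex An [aaindex_table()].
#' @param pos 1-based residue position.
#' @param window Odd window width (default 11).
#' @param pad Named numeric vector of per-property padding values, or `NULL`
#'   for the table means.
#' @return Numeric vector, offset-major (all properties of offset -5, then
#'   -4, ...).
#' @export
residue_window_features <- function(seq, aaindex, pos, window = 11L,
                                    pad = NULL) {
  stopifnot(inherits(aaindex, "aaindex_table"))
  if (window %% 2L != 1L || window < 1L) {
    stop_param("window must be a positive odd integer")
  }
  n <- nchar(seq)
  if (pos < 1L || pos > n) stop_param("pos %d outside sequence of length %d", pos, n)
  if (is.null(pad)) pad <- rowMeans(aaindex$values)
  if (length(pad) != n_properties(aaindex)) {
    stop_param("pad must hold one value per property")
  }
  cc <- chars(seq)
  half <- (window - 1L) %/% 2L
  offsets <- (-half):half
  out <- numeric(0)
  for (o in offsets) {
    p <- pos + o
    out <- c(out, if (p < 1L || p > n) as.numeric(pad)
             else as.numeric(aaindex$values[, cc[p]]))
  }
  out
}

#' Per-property means over training-set residues
#'
#' The padding values used for window slots beyond the sequence ends:
#' each property's mean over every residue of the supplied sequences.
#'
#' @param aaindex An [aaindex_table()].
#' @param seqs Character vector of (ungapped) training sequences.
#' @return Named numeric vector, one mean per property.
#' @export
aaindex_training_means <- function(aaindex, seqs) {
  cc <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
  cc <- cc[cc %in% AA_ALPHABET]
  if (length(cc) == 0L) stop_param("no residues in training sequences")
  rowMeans(aaindex$values[, cc, drop = FALSE])
}

#' Residue-pair feature vector for the contact classifier
#'
#' Concatenates the two residues' feature blocks in A-then-B order, each
#' block being the 20 Fisher scores followed by the windowed property
#' features: total length (20 + 11 x 17) x 2 = 414 at the defaults.
#'
#' @param fisher_a,fisher_b 20-vectors of Fisher scores.
#' @param window_a,window_b Windowed property vectors
#'   ([residue_window_features()]).
#' @return Numeric vector.
#' @export
build_pair_vector <- function(fisher_a, window_a, fisher_b, window_b) {
  if (length(fisher_a) != 20L || length(fisher_b) != 20L) {
    stop_param("Fisher blocks must have length 20")
  }
  if (length(window_a) != length(window_b)) {
    stop_param("window blocks must have equal length")
  }
  c(as.numeric(fisher_a), as.numeric(window_a),
    as.numeric(fisher_b), as.numeric(window_b))
}

#' Fit / apply a per-feature min-max normalizer
#'
#' Scales every feature to `[0,1]` by the training minima and maxima.
#' Constant features map to 0; values outside the training range are
#' clamped to `[0,1]`.
#'
#' @param train Numeric matrix of training feature vectors (rows =
#'   examples).
#' @return A `minmax_normalizer` (fit) or a scaled matrix (apply).
#' @export
fit_normalizer <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop_param("empty training set")
  structure(list(min = apply(train, 2, min), max = apply(train, 2, max)),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `minmax_normalizer`.
#' @param x Matrix (or single vector) of feature vectors to scale.
#' @export
apply_normalizer <- function(normalizer, x) {
  stopifnot(inherits(normalizer, "minmax_normalizer"))
  one <- is.null(dim(x))
  x <- rbind(x)
  if (ncol(x) != length(normalizer$min)) {
    stop_param("feature dimension %d does not match normalizer (%d)",
               ncol(x), length(normalizer$min))
  }
  rng <- normalizer$max - normalizer$min
  out <- sweep(x, 2, normalizer$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (one) out[1, ] else out
}

#' Train the RBF-kernel contact classifier
#'
#' Support vector machine with kernel `K(x, y) = exp(-gamma ||x - y||^2)` on
#' min-max-normalised residue-pair vectors. Defaults follow the usual
#' library convention: `gamma = 1/n_features` and `C = 1`.
#'
#' @param x Matrix of residue-pair feature vectors.
#' @param y Binary contact labels (0/1).
#' @param gamma RBF width (default `1/ncol(x)`).
#' @param cost Misclassification penalty C (default 1).
#' @return A `contact_model` holding the SVM, kernel parameters and the
#'   fitted normalizer.
#' @export
train_contact_svm <- function(x, y, gamma = NULL, cost = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop_param("contact training set must contain both classes")
  }
  gamma <- gamma %||% (1 / ncol(x))
  if (gamma <= 0 || cost <= 0) stop_param("gamma and cost must be positive")
  normalizer <- fit_normalizer(x)
  xs <- apply_normalizer(normalizer, x)
  fit <- e1071::svm(xs, factor(y, levels = c(0L, 1L)),
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  structure(list(svm = fit, gamma = gamma, cost = cost,
                 normalizer = normalizer, n_features = ncol(x)),
            class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("<contact_model> RBF-SVM on %d features, gamma = %.4g, C = %g, %d SVs\n",
              x$n_features, x$gamma, x$cost, x$svm$tot.nSV))
  invisible(x)
}

#' Decision values of the contact classifier
#'
#' Signed decision values oriented so that positive means contact.
#'
#' @param model A `contact_model`.
#' @param x Matrix of raw (unnormalised) pair feature vectors.
#' @return Numeric vector of decision values.
#' @export
contact_decision_values <- function(model, x) {
  stopifnot(inherits(model, "contact_model"))
  xs <- apply_normalizer(model$normalizer, as.matrix(x))
  pr <- predict(model$svm, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the value toward the first class label seen in training
  if (colnames(dv)[1] == "0/1") -as.numeric(dv) else as.numeric(dv)
}

#' Predict the contact matrix for one sequence pair
#'
#' Builds the residue-pair feature vector for every (match column of A,
#' match column of B) cell where both sequences align a residue, scores it
#' with the contact SVM, and returns both the signed-score matrix and its
#' binarisation (positive decision value = contact). Cells where either
#' sequence deletes its match column are 0 in the binary matrix and carry
#' the minimum score in the score matrix.
#'
#' @param model A [train_contact_svm()] model.
#' @param fisher_a,fisher_b [fisher_scores()] profiles of the two sequences.
#' @param map_a,map_b [match_residue_map()] vectors (residue position per
#'   match column, `NA` for deleted columns).
#' @param seq_a,seq_b Ungapped sequences.
#' @param aaindex An [aaindex_table()].
#' @param window Window width for the property features.
#' @param pad Per-property padding values (training means).
#' @param family_id,pair_id Identifiers for the returned matrices.
#' @return List with elements `binary` and `score`, both [contact_matrix()].
#' @export
predict_contact_matrix <- function(model, fisher_a, fisher_b, map_a, map_b,
                                   seq_a, seq_b, aaindex, window = 11L,
                                   pad = NULL, family_id = "", pair_id = "") {
  stopifnot(inherits(model, "contact_model"))
  La <- length(map_a); Lb <- length(map_b)
  feats <- pair_feature_rows(fisher_a, fisher_b, map_a, map_b, seq_a, seq_b,
                             aaindex, window = window, pad = pad)
  if (nrow(feats$x) > 0L && ncol(feats$x) != model$n_features) {
    stop_validation("pair feature dimension %d does not match model (%d)",
                    ncol(feats$x), model$n_features)
  }
  score <- matrix(0, La, Lb)
  present <- matrix(FALSE, La, Lb)
  if (nrow(feats$x) > 0L) {
    dv <- contact_decision_values(model, feats$x)
    for (k in seq_len(nrow(feats$cells))) {
      score[feats$cells[k, 1L], feats$cells[k, 2L]] <- dv[k]
      present[feats$cells[k, 1L], feats$cells[k, 2L]] <- TRUE
    }
  }
  binary <- ifelse(present & score > 0, 1, 0)
  floor_val <- if (any(present)) min(score[present]) else 0
  score[!present] <- min(floor_val, 0)
  list(binary = contact_matrix(binary, "predicted_binary", family_id, pair_id),
       score = contact_matrix(score, "predicted_score", family_id, pair_id))
}

# feature rows for all occupied (row, col) cells of one pair
# returns list(x = matrix, cells = matrix of (a_index, b_index), label vector
# optional)
#' @keywords internal
pair_feature_rows <- function(fisher_a, fisher_b, map_a, map_b, seq_a, seq_b,
                              aaindex, window = 11L, pad = NULL) {
  if (is.null(pad)) pad <- rowMeans(aaindex$values)
  win_a <- lapply(seq_len(nchar(seq_a)), function(p)
    residue_window_features(seq_a, aaindex, p, window = window, pad = pad))
  win_b <- lapply(seq_len(nchar(seq_b)), function(p)
    residue_window_features(seq_b, aaindex, p, window = window, pad = pad))
  occ_a <- which(!is.na(map_a)); occ_b <- which(!is.na(map_b))
  cells <- as.matrix(expand.grid(a = occ_a, b = occ_b))
  if (nrow(cells) == 0L) {
    return(list(x = matrix(0, 0, 0), cells = cells))
  }
  x <- t(apply(cells, 1, function(cell) {
    ra <- map_a[cell[1L]]; rb <- map_b[cell[2L]]
    build_pair_vector(fisher_a[ra, ], win_a[[ra]], fisher_b[rb, ], win_b[[rb]])
  }))
  list(x = x, cells = cells)
}
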