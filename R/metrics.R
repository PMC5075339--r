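#' Confusion counts from true/predicted site labels
#'
#' @param label_true,label_pred Character vectors over the evaluated
#'   residues, values `"interacting"` / `"non_interacting"`.
#' @return Tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(label_true, label_pred) {
  stopifnot(length(label_true) == length(label_pred))
  pos_t <- label_true == "interacting"
  pos_p <- label_pred == "interacting"
  tibble(tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
         fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p))
}

#' Binary-classification metrics from confusion counts
#'
#' Computes, from TP/TN/FP/FN:
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/(TP+TN+FP+FN),
#' F1 = 2 * precision * recall / (precision + recall), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is reported as `NA` (an undefined
#' ratio is never silently 0).
#'
#' @param tp,tn,fp,fn Non-negative integer counts, or a single data frame
#'   with those columns passed as `tp`.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `precision`, `recall`, `f1`, `mcc`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    cc <- tp
    tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  stopifnot(length(tp) == 1L)
  if (any(c(tp, tn, fp, fn) < 0)) stop_param("counts must be non-negative")
  total <- tp + tn + fp + fn
  if (total == 0) stop_param("all-zero confusion counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- ratio(tp, tp + fn)
  precision <- ratio(tp, tp + fp)
  accuracy <- (tp + tn) / total
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  tibble(tp = tp, tn = tn, fp = fp, fn = fn, accuracy = accuracy,
         precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Paired t-test between two per-unit metric vectors
#'
#' Classical two-sided paired t-test on the differences `a - b`, paired by
#' unit (sequence or family). Zero-variance differences are reported as a
#' degenerate result (`t = Inf`/`-Inf`/`0`, `degenerate = TRUE`) rather than
#' an error.
#'
#' @param a,b Equal-length numeric vectors (>= 2 pairs), e.g. per-sequence
#'   MCC of two methods.
#' @return One-row tibble with `mean_diff`, `t`, `df`, `p_value`,
#'   `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_param("a and b must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop_param("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(tibble(mean_diff = m,
                  t = if (m == 0) 0 else sign(m) * Inf,
                  df = length(d) - 1L,
                  p_value = if (m == 0) 1 else 0,
                  degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(mean_diff = mean(d), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         degenerate = FALSE)
}

#' Aggregate per-sequence metrics into per-family and overall means
#'
#' Macro-averages the per-sequence metrics: the overall value of each
#' metric is its unweighted mean over all sequences of all families, with
#' undefined (`NA`) entries excluded and their count reported.
#'
#' @param per_sequence Tibble with columns `family_id`, `method`, `seq_id`
#'   (or any per-unit key) and the metric columns `accuracy`, `precision`,
#'   `recall`, `f1`, `mcc`.
#' @return A `metrics_report`: list of tibbles `per_sequence`, `per_family`,
#'   `overall` (the latter two with `n_excluded_<metric>` counts).
#' @export
aggregate_report <- function(per_sequence) {
  metrics <- c("accuracy", "precision", "recall", "f1", "mcc")
  stopifnot(all(c("family_id", "method", metrics) %in% names(per_sequence)))
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  per_family <- per_sequence |>
    group_by(.data$method, .data$family_id) |>
    summarise(n_sequences = n(),
              across(all_of(metrics), mean_na),
              .groups = "drop")
  overall <- per_sequence |>
    group_by(.data$method) |>
    summarise(n_sequences = n(),
              n_excluded = sum(is.na(.data$mcc) | is.na(.data$precision) |
                                 is.na(.data$recall) | is.na(.data$f1)),
              across(all_of(metrics), mean_na),
              .groups = "drop")
  structure(list(per_sequence = as_tibble(per_sequence),
                 per_family = per_family, overall = overall),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  %d sequences, %d families, methods: %s\n",
              length(unique(paste(x$per_sequence$family_id,
                                  x$per_sequence$seq_id))),
              length(unique(x$per_sequence$family_id)),
              paste(unique(x$per_sequence$method), collapse = ", ")))
  print(x$overall)
  invisible(x)
}

#' Summary table of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The overall tibble (one row per method).
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$overall
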