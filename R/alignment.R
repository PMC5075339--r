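#' Labeled multiple sequence alignment of one domain family
#'
#' The training input of the interaction-profile HMM: a gapped alignment of
#' the family members in which a subset of columns is designated as match
#' (consensus) columns, and every residue sitting in a match column carries a
#' per-residue interaction label (`"i"` interacting, `"n"` non-interacting).
#' Residues in non-match (insert) columns and gap cells are unlabeled (`"."`).
#'
#' @param family_id Family identifier string.
#' @param domain_role `"A"` or `"B"` — which side of the domain-domain
#'   interaction this alignment describes.
#' @param seq_ids Character vector of sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal width, letters
#'   from the 20-letter amino-acid alphabet plus `-`).
#' @param match_columns Strictly increasing integer vector of 1-based
#'   alignment columns designated as match states.
#' @param labels Character matrix (`length(seqs)` rows by alignment-width
#'   columns) with `"i"`/`"n"` exactly at (row, match column) cells where the
#'   row has a residue, `"."` everywhere else.
#'
#' @return A `labeled_alignment` object.
#' @export
labeled_alignment <- function(family_id, domain_role, seq_ids, seqs,
                              match_columns, labels) {
  domain_role <- match.arg(domain_role, c("A", "B"))
  if (length(seqs) == 0L) stop_format("alignment has no sequences")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- seq_ids[which(widths != widths[1])[1]]
    stop_format("ragged alignment: row '%s' has width %d, expected %d",
                bad, nchar(seqs[match(bad, seq_ids)]), widths[1])
  }
  width <- widths[1]
  for (k in seq_along(seqs)) {
    check_residues(seqs[k], what = sprintf("row '%s'", seq_ids[k]),
                   allow_gap = TRUE)
  }
  match_columns <- as.integer(match_columns)
  if (length(match_columns) == 0L) {
    stop_format("alignment has zero match columns")
  }
  if (any(diff(match_columns) <= 0) || match_columns[1] < 1L ||
      match_columns[length(match_columns)] > width) {
    stop_format("match_columns must be strictly increasing within 1..%d",
                width)
  }
  labels <- as.matrix(labels)
  if (!all(dim(labels) == c(length(seqs), width))) {
    stop_format("label matrix must be %d x %d (rows x alignment width)",
                length(seqs), width)
  }
  seq_mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  is_match <- seq_len(width) %in% match_columns
  for (k in seq_along(seqs)) {
    resid <- seq_mat[k, ] != "-"
    need_label <- resid & is_match
    if (any(!labels[k, need_label] %in% c("i", "n"))) {
      stop_format("row '%s': match-column residues must be labeled 'i' or 'n'",
                  seq_ids[k])
    }
    if (any(labels[k, !need_label] != ".")) {
      stop_format("row '%s': labels outside match-column residues must be '.'",
                  seq_ids[k])
    }
  }
  structure(
    list(family_id = as.character(family_id), domain_role = domain_role,
         seq_ids = as.character(seq_ids), seqs = unname(seqs),
         match_columns = match_columns, labels = unname(labels),
         width = width),
    class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf(
    "<labeled_alignment> family %s, domain %s: %d sequences, width %d, %d match columns\n",
    x$family_id, x$domain_role, length(x$seq_ids), x$width,
    length(x$match_columns)))
  invisible(x)
}

#' Number of match columns of a labeled alignment
#' @param aln A `labeled_alignment`.
#' @return Integer.
#' @export
n_match_columns <- function(aln) length(aln$match_columns)

#' Map match columns to ungapped residue positions for one row
#'
#' For each match column, the 1-based position of the row's residue in its
#' ungapped sequence, or `NA` where the row has a gap (the column is deleted
#' by that sequence).
#'
#' @param aln A `labeled_alignment`.
#' @param seq_id Row identifier.
#' @return Integer vector of length `n_match_columns(aln)`.
#' @export
match_residue_map <- function(aln, seq_id) {
  k <- match(seq_id, aln$seq_ids)
  if (is.na(k)) stop_param("unknown seq_id '%s'", seq_id)
  cc <- chars(aln$seqs[k])
  resid_no <- cumsum(cc != "-")
  out <- ifelse(cc[aln$match_columns] == "-", NA_integer_,
                resid_no[aln$match_columns])
  as.integer(out)
}

#' Ungapped sequence of one alignment row
#' @param aln A `labeled_alignment`.
#' @param seq_id Row identifier.
#' @return Character scalar (no gaps).
#' @export
ungapped_sequence <- function(aln, seq_id) {
  k <- match(seq_id, aln$seq_ids)
  if (is.na(k)) stop_param("unknown seq_id '%s'", seq_id)
  gsub("-", "", aln$seqs[k], fixed = TRUE)
}

#' Per-row interaction labels on match columns
#'
#' @param aln A `labeled_alignment`.
#' @return A tibble with columns `seq_id`, `match_index` (1-based index into
#'   the match-column list), `column` (alignment column), `label`
#'   (`"interacting"`, `"non_interacting"` or `"gap"`).
#' @export
site_labels <- function(aln) {
  lab <- aln$labels[, aln$match_columns, drop = FALSE]
  tibble(
    seq_id = rep(aln$seq_ids, times = length(aln$match_columns)),
    match_index = rep(seq_along(aln$match_columns), each = length(aln$seq_ids)),
    column = rep(aln$match_columns, each = length(aln$seq_ids)),
    label = dplyr::case_match(as.vector(lab),
                              "i" ~ "interacting",
                              "n" ~ "non_interacting",
                              "." ~ "gap")) |>
    arrange(.data$seq_id, .data$match_index)
}

#' Drop rows from a labeled alignment
#'
#' Removes the given rows (used by the leave-one-out harness) and prunes
#' alignment columns that become all-gap, keeping match-column designations
#' of the surviving columns.
#'
#' @param aln A `labeled_alignment`.
#' @param seq_ids Identifiers of rows to remove.
#' @return A `labeled_alignment` without those rows.
#' @export
drop_alignment_rows <- function(aln, seq_ids) {
  keep <- !(aln$seq_ids %in% seq_ids)
  if (!any(keep)) stop_param("cannot drop all rows of an alignment")
  seq_mat <- do.call(rbind, strsplit(aln$seqs[keep], "", fixed = TRUE))
  lab <- aln$labels[keep, , drop = FALSE]
  is_match <- seq_len(aln$width) %in% aln$match_columns
  # prune all-gap insert columns; match columns are structural and stay
  col_keep <- is_match | colSums(seq_mat != "-") > 0
  seq_mat <- seq_mat[, col_keep, drop = FALSE]
  lab <- lab[, col_keep, drop = FALSE]
  new_match <- which(is_match[col_keep])
  labeled_alignment(aln$family_id, aln$domain_role,
                    aln$seq_ids[keep],
                    apply(seq_mat, 1, paste, collapse = ""),
                    new_match, lab)
}

#' @importFrom rlang .data
NULL
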