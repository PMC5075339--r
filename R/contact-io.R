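#' Residue-residue contact matrix between two interacting domains
#'
#' A matrix over the match-state coordinates of domain A (rows) by domain B
#' (columns) for one interacting sequence pair. Using model coordinates
#' rather than raw sequence positions keeps the dimension constant across
#' family members; residues in insert states have no row/column. `1` marks a
#' residue-residue contact across the interface.
#'
#' @param cells Numeric matrix. Binary (`0`/`1`) for `ground_truth` and
#'   `predicted_binary`, finite reals for `predicted_score`.
#' @param kind `"ground_truth"`, `"predicted_binary"` or `"predicted_score"`.
#' @param family_id,pair_id Identifiers.
#' @param max_total Validation bound on `nrow + ncol` (default 150, the
#'   summed-domain-length cap of the intended family size class).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(cells, kind = c("ground_truth", "predicted_binary",
                                           "predicted_score"),
                           family_id = "", pair_id = "", max_total = 150L) {
  kind <- match.arg(kind)
  cells <- as.matrix(cells)
  if (nrow(cells) < 1L || ncol(cells) < 1L) {
    stop_validation("contact matrix must have positive dimensions")
  }
  if (nrow(cells) + ncol(cells) > max_total) {
    stop_validation("summed domain length %d exceeds the %d-residue bound",
                    nrow(cells) + ncol(cells), max_total)
  }
  if (any(!is.finite(cells))) stop_format("contact matrix has non-finite cells")
  if (kind != "predicted_score" && !all(cells %in% c(0, 1))) {
    stop_format("kind '%s' requires binary cells; found value %s",
                kind, format(cells[!cells %in% c(0, 1)][1]))
  }
  structure(list(family_id = as.character(family_id),
                 pair_id = as.character(pair_id),
                 kind = kind, cells = unname(cells)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s/%s [%s] %d x %d, %d contacts\n",
              x$family_id, x$pair_id, x$kind,
              nrow(x$cells), ncol(x$cells),
              if (x$kind == "predicted_score") NA_integer_
              else sum(x$cells == 1)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$cells)

#' Read / write a contact matrix
#'
#' TSV with a `#kind=` comment line, optional `#family=`/`#pair=` lines, a
#' header row of 1-based domain-B match indices, and a first column of
#' 1-based domain-A match indices. `read_contact_matrix(write_contact_matrix(x))`
#' is the identity.
#'
#' @param path File path.
#' @param max_total Validation bound on summed dimensions.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, max_total = 150L) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = "") {
    hit <- grep(sprintf("^#%s=", key), meta, value = TRUE)
    if (length(hit) == 0L) default else sub(sprintf("^#%s=", key), "", hit[1])
  }
  kind <- get_meta("kind")
  if (!kind %in% c("ground_truth", "predicted_binary", "predicted_score")) {
    stop_format("%s: missing or invalid '#kind=' header line", path)
  }
  body <- lines[!grepl("^#", lines) & lines != ""]
  if (length(body) < 2L) stop_format("%s: no matrix body", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  n_cols <- length(header) - 1L
  cells <- matrix(NA_real_, nrow = length(rows), ncol = n_cols)
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != n_cols + 1L) {
      stop_format("%s: row %d has %d fields, expected %d", path, r,
                  length(rows[[r]]), n_cols + 1L)
    }
    v <- suppressWarnings(as.numeric(rows[[r]][-1]))
    if (any(is.na(v))) stop_format("%s: non-numeric cell in row %d", path, r)
    cells[r, ] <- v
  }
  contact_matrix(cells, kind = kind, family_id = get_meta("family"),
                 pair_id = get_meta("pair"), max_total = max_total)
}

#' @rdname read_contact_matrix
#' @param cm A [contact_matrix()].
#' @export
write_contact_matrix <- function(cm, path) {
  fmt <- function(v) sprintf("%.17g", v)
  header <- paste(c("", as.character(seq_len(ncol(cm$cells)))), collapse = "\t")
  body <- map_chr(seq_len(nrow(cm$cells)), function(r) {
    paste(c(as.character(r), fmt(cm$cells[r, ])), collapse = "\t")
  })
  writeLines(c(sprintf("#kind=%s", cm$kind),
               sprintf("#family=%s", cm$family_id),
               sprintf("#pair=%s", cm$pair_id),
               header, body), path)
  invisible(path)
}

#' Write / read a site-prediction report
#'
#' Long-format TSV with one row per evaluated match-column residue and
#' method: `family_id`, `pair_id`, `domain_role`, `seq_id`, `match_index`,
#' `method`, `label_true`, `label_pred`, `score`.
#'
#' @param predictions Tibble as produced by [loocv_family()].
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}
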