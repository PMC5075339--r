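#' The default set of amino-acid property scales
#'
#' Accessions of the 17 AAindex physicochemical property scales used by the
#' contact-matrix feature stage, in their canonical order.
#'
#' @return Character vector of 17 AAindex accessions.
#' @export
default_aaindex_accessions <- function() {
  c("ANDN920101", "ARGP820101", "BEGF750101", "BUNA790103", "BHAR880101",
    "BURA740102", "GEOR030101", "CHOP780204", "CHOP780215", "JOND920102",
    "KHAG800101", "FAUJ880104", "PALJ810107", "RACS820114", "WERD780103",
    "YUTK870102", "CHAM830102")
}

# row order of the two value rows of an AAindex1 "I" block
AAINDEX1_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
AAINDEX1_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct an amino-acid property table
#'
#' @param values Numeric matrix, one row per property (rownames = accessions),
#'   20 columns named by the one-letter amino-acid alphabet.
#' @return An `aaindex_table` object.
#' @export
aaindex_table <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 20L || is.null(colnames(values)) ||
      !setequal(colnames(values), AA_ALPHABET)) {
    stop_format("property table needs 20 columns named by amino-acid letters")
  }
  values <- values[, AA_ALPHABET, drop = FALSE]
  if (any(!is.finite(values))) {
    bad <- rownames(values)[which(rowSums(!is.finite(values)) > 0)[1]]
    stop_format("property '%s' has non-finite values", bad)
  }
  structure(list(accessions = rownames(values), values = values),
            class = "aaindex_table")
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat(sprintf("<aaindex_table> %d properties: %s%s\n",
              length(x$accessions),
              paste(utils::head(x$accessions, 4), collapse = ", "),
              if (length(x$accessions) > 4) ", ..." else ""))
  invisible(x)
}

#' Number of properties in a table
#' @param aaindex An `aaindex_table`.
#' @return Integer.
#' @export
n_properties <- function(aaindex) length(aaindex$accessions)

#' Default amino-acid property table
#'
#' Builds the 17-property table from the AAindex database release bundled
#' with the seqinr package.
#'
#' @param accessions Accessions to include (default
#'   [default_aaindex_accessions()]).
#' @return An [aaindex_table()].
#' @export
default_aaindex <- function(accessions = default_aaindex_accessions()) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  db <- env$aaindex
  have <- map_chr(db, "H")
  miss <- setdiff(accessions, have)
  if (length(miss) > 0L) {
    stop_format("accessions missing from the AAindex database: %s",
                paste(miss, collapse = ", "))
  }
  vals <- do.call(rbind, map(accessions, function(a) {
    v <- db[[match(a, have)]]$I
    setNames(as.numeric(v), AA_THREE_TO_ONE[names(v)])[AA_ALPHABET]
  }))
  rownames(vals) <- accessions
  aaindex_table(vals)
}

#' Read amino-acid property scales from an AAindex1 flat file
#'
#' Parses the standard AAindex1 format: records introduced by
#' `H <accession>`, with the 20 values in the `I` block's two rows of ten
#' (row 1: A R N D C Q E G H I; row 2: L K M F P S T W Y V). `NA` entries
#' are rejected.
#'
#' @param path File path.
#' @param accessions Accessions to extract, in the order the returned table
#'   should have.
#' @return An [aaindex_table()].
#' @export
read_aaindex <- function(path, accessions = default_aaindex_accessions()) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  h_at <- grep("^H ", lines)
  found <- sub("^H\\s+", "", lines[h_at])
  miss <- setdiff(accessions, found)
  if (length(miss) > 0L) {
    stop_format("accessions missing from %s: %s", path,
                paste(miss, collapse = ", "))
  }
  vals <- do.call(rbind, map(accessions, function(a) {
    start <- h_at[match(a, found)]
    i_at <- start + grep("^I ", lines[start:length(lines)])[1] - 1L
    if (is.na(i_at)) stop_format("record %s has no 'I' block", a)
    parse_row <- function(ln) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) != 10L) {
        stop_format("record %s: malformed value row '%s'", a, ln)
      }
      if (any(toupper(toks) == "NA")) {
        stop_format("record %s contains NA values", a)
      }
      v <- suppressWarnings(as.numeric(toks))
      if (any(is.na(v))) stop_format("record %s: non-numeric value row", a)
      v
    }
    setNames(c(parse_row(lines[i_at + 1L]), parse_row(lines[i_at + 2L])),
             c(AAINDEX1_ROW1, AAINDEX1_ROW2))[AA_ALPHABET]
  }))
  rownames(vals) <- accessions
  aaindex_table(vals)
}

#' Write an amino-acid property table in AAindex1 format
#'
#' @param aaindex An [aaindex_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(aaindex, path) {
  fmt_row <- function(v) paste(sprintf("%.17g", v), collapse = "  ")
  lines <- unlist(map(aaindex$accessions, function(a) {
    v <- aaindex$values[a, ]
    c(sprintf("H %s", a),
      "D synthetic property scale",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      fmt_row(v[AAINDEX1_ROW1]),
      fmt_row(v[AAINDEX1_ROW2]),
      "//")
  }))
  writeLines(lines, path)
  invisible(path)
}
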