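#' Read a labeled domain-family alignment
#'
#' Two dialects are supported. `stockholm_markup` is Stockholm 1.0 with a
#' `#=GC RF` line marking match columns (`x` = match, `.` = insert) and one
#' `#=GR <seq> PPI` line per sequence carrying the per-residue interaction
#' labels (`i` interacting, `n` non-interacting, `.` gap/insert).
#' `annotated_fasta` is FASTA in which every sequence record is immediately
#' followed by a `>#labels` record of the same width, and the first record is
#' `>#match` holding the `x`/`.` reference line.
#'
#' Files use 1-based column conventions; all returned indices are 1-based.
#'
#' @param path File path.
#' @param dialect `"stockholm_markup"` or `"annotated_fasta"`.
#' @param family_id Family identifier to record (default: file base name).
#' @param domain_role `"A"` or `"B"`.
#' @return A [labeled_alignment()].
#' @export
read_labeled_alignment <- function(path,
                                   dialect = c("stockholm_markup",
                                               "annotated_fasta"),
                                   family_id = NULL,
                                   domain_role = "A") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  family_id <- family_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(dialect,
                   stockholm_markup = parse_stockholm_markup(lines, path),
                   annotated_fasta = parse_annotated_fasta(lines, path))
  build_alignment_from_parse(parsed, family_id, domain_role)
}

parse_stockholm_markup <- function(lines, path) {
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1])) {
    stop_format("%s: missing '# STOCKHOLM 1.0' header", path)
  }
  seqs <- character(); ids <- character(); labels <- list(); rf <- NULL
  for (ln in lines[-1]) {
    if (ln == "" || ln == "//") next
    if (grepl("^#=GC\\s+RF\\s+", ln)) {
      rf <- sub("^#=GC\\s+RF\\s+", "", ln)
    } else if (grepl("^#=GR\\s+\\S+\\s+PPI\\s+", ln)) {
      m <- regmatches(ln, regexec("^#=GR\\s+(\\S+)\\s+PPI\\s+(\\S+)$", ln))[[1]]
      labels[[m[2]]] <- m[3]
    } else if (grepl("^#", ln)) {
      next
    } else {
      m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1]]
      if (length(m) != 3L) stop_format("%s: unparseable line '%s'", path, ln)
      ids <- c(ids, m[2]); seqs <- c(seqs, m[3])
    }
  }
  if (is.null(rf)) stop_format("%s: missing '#=GC RF' match-column line", path)
  miss <- setdiff(ids, names(labels))
  if (length(miss) > 0L) {
    stop_format("%s: missing '#=GR %s PPI' label line", path, miss[1])
  }
  list(ids = ids, seqs = seqs, rf = rf, labels = labels[ids])
}

parse_annotated_fasta <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) < 3L) stop_format("%s: need '>#match' plus sequence/label record pairs", path)
  rec_txt <- function(i) {
    to <- if (i == length(hdr)) length(lines) else hdr[i + 1] - 1L
    paste(lines[(hdr[i] + 1L):to], collapse = "")
  }
  names <- sub("^>", "", lines[hdr])
  if (names[1] != "#match") stop_format("%s: first record must be '>#match'", path)
  rf <- rec_txt(1)
  rest <- seq(2L, length(hdr))
  if (length(rest) %% 2L != 0L) {
    stop_format("%s: every sequence must be followed by a '>#labels' record", path)
  }
  ids <- character(); seqs <- character(); labels <- list()
  for (k in seq(2L, length(hdr), by = 2L)) {
    if (names[k + 1L] != "#labels") {
      stop_format("%s: record '%s' not followed by '>#labels'", path, names[k])
    }
    ids <- c(ids, names[k]); seqs <- c(seqs, rec_txt(k))
    labels[[names[k]]] <- rec_txt(k + 1L)
  }
  list(ids = ids, seqs = seqs, rf = rf, labels = labels[ids])
}

build_alignment_from_parse <- function(parsed, family_id, domain_role) {
  ids <- parsed$ids; seqs <- parsed$seqs
  if (length(ids) == 0L) stop_format("alignment has no sequences")
  width <- nchar(seqs[1])
  bad <- which(nchar(seqs) != width)
  if (length(bad) > 0L) {
    stop_format("ragged alignment: row '%s' has width %d, expected %d",
                ids[bad[1]], nchar(seqs[bad[1]]), width)
  }
  if (nchar(parsed$rf) != width) {
    stop_format("reference (match-column) line length %d != alignment width %d",
                nchar(parsed$rf), width)
  }
  rf <- chars(parsed$rf)
  if (!all(rf %in% c("x", "."))) {
    stop_format("reference line may contain only 'x' and '.'")
  }
  match_columns <- which(rf == "x")
  lab_mat <- matrix(".", nrow = length(ids), ncol = width)
  for (k in seq_along(ids)) {
    lab <- parsed$labels[[ids[k]]]
    if (nchar(lab) != width) {
      stop_format("label line for row '%s' has length %d != alignment width %d",
                  ids[k], nchar(lab), width)
    }
    lc <- chars(lab)
    if (!all(lc %in% c("i", "n", "."))) {
      stop_format("label line for row '%s' may contain only 'i', 'n', '.'",
                  ids[k])
    }
    lab_mat[k, ] <- lc
  }
  labeled_alignment(family_id, domain_role, ids, seqs, match_columns, lab_mat)
}

#' Write a labeled alignment
#'
#' Inverse of [read_labeled_alignment()]; both dialects round-trip.
#'
#' @param aln A [labeled_alignment()].
#' @param path Output file path.
#' @param dialect `"stockholm_markup"` or `"annotated_fasta"`.
#' @return `path`, invisibly.
#' @export
write_labeled_alignment <- function(aln, path,
                                    dialect = c("stockholm_markup",
                                                "annotated_fasta")) {
  dialect <- match.arg(dialect)
  rf <- rep(".", aln$width)
  rf[aln$match_columns] <- "x"
  rf <- paste(rf, collapse = "")
  labs <- apply(aln$labels, 1, paste, collapse = "")
  lines <- if (dialect == "stockholm_markup") {
    w <- max(nchar(aln$seq_ids)) + 12L
    c("# STOCKHOLM 1.0",
      sprintf("#=GF ID %s_%s", aln$family_id, aln$domain_role),
      unlist(map(seq_along(aln$seq_ids), function(k) {
        c(sprintf("%-*s%s", w, aln$seq_ids[k], aln$seqs[k]),
          sprintf("%-*s%s", w, sprintf("#=GR %s PPI", aln$seq_ids[k]), labs[k]))
      })),
      sprintf("%-*s%s", w, "#=GC RF", rf),
      "//")
  } else {
    c(">#match", rf,
      unlist(map(seq_along(aln$seq_ids), function(k) {
        c(paste0(">", aln$seq_ids[k]), aln$seqs[k], ">#labels", labs[k])
      })))
  }
  writeLines(lines, path)
  invisible(path)
}
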