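#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise
#'   ungroup left_join across all_of n
#' @importFrom purrr map map_dbl map_chr map2 imap pmap keep
#' @importFrom stats plogis predict rgamma runif rbinom setNames t.test
NULL

# Single-letter amino-acid alphabet, alphabetical by letter.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Three-letter -> one-letter map (seqinr's aaindex names values by
# three-letter code).
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' @keywords internal
check_residues <- function(seq, what = "sequence", allow_gap = FALSE) {
  cc <- chars(seq)
  ok <- cc %in% AA_ALPHABET | (allow_gap & cc %in% c("-", "."))
  if (!all(ok)) {
    pos <- which(!ok)[1]
    abort(sprintf("invalid residue letter '%s' at position %d in %s",
                  cc[pos], pos, what),
          class = "cmiphmm_format_error")
  }
  invisible(cc)
}

#' @keywords internal
stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cmiphmm_format_error")
}

#' @keywords internal
stop_param <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cmiphmm_parameter_error")
}

#' @keywords internal
stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cmiphmm_validation_error")
}
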