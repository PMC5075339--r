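#' Build an interaction-profile HMM from a labeled alignment
#'
#' An ipHMM is a profile HMM in which every match position j carries two
#' match flavours — an interacting match state `M_i(j)` and a non-interacting
#' match state `M_ni(j)` — alongside the usual insert `I(j)` and delete
#' `D(j)` states. Connectivity follows the profile-HMM (HMMER-style)
#' restrictions: `Begin -> {M*, D, I}`, `M* -> {M*, I, D, End}`,
#' `I -> {I, M*, D}`, `D -> {D, M*, End}`, with `M*` ranging over both match
#' flavours of the next position and `I(L)` additionally allowed to reach
#' `End`.
#'
#' Parameters are maximum-likelihood counts from the alignment, smoothed by
#' adding `pseudocount` to every amino acid of every emitting state and to
#' every allowed transition arc, so all probabilities are strictly positive:
#' an amino acid never observed in a state still receives one (pseudo)count.
#' The match flavour of each residue's state is taken from its interaction
#' label; each row's gap structure implies its insert/delete path. A row
#' configuration that would imply the disallowed `D -> I` arc contributes
#' its emission counts but no count for that arc.
#'
#' @param aln A [labeled_alignment()].
#' @param pseudocount Positive smoothing count (default 1, add-one).
#' @return An `iphmm` object with elements `n_match`, `emissions`
#'   (`match_i`, `match_ni` as `L x 20`; `insert` as `(L+1) x 20`, slot j in
#'   row j+1) and `transitions` (`begin`; `match_i`, `match_ni`, `delete` as
#'   `L x 5`; `insert` as `(L+1) x 5`; arc order `m_ni, m_i, ins, del, end`).
#' @export
build_iphmm <- function(aln, pseudocount = 1) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop_param("pseudocount must be a single positive number")
  }
  L <- length(aln$match_columns)
  if (L == 0L) stop_format("alignment has zero match columns")
  arc <- c("m_ni", "m_i", "ins", "del", "end")

  em_i <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  em_ni <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  em_ins <- matrix(0, L + 1L, 20, dimnames = list(NULL, AA_ALPHABET))
  t_begin <- setNames(numeric(5), arc)
  t_mi <- matrix(0, L, 5, dimnames = list(NULL, arc))
  t_mni <- matrix(0, L, 5, dimnames = list(NULL, arc))
  t_ins <- matrix(0, L + 1L, 5, dimnames = list(NULL, arc))
  t_del <- matrix(0, L, 5, dimnames = list(NULL, arc))

  is_match <- seq_len(aln$width) %in% aln$match_columns
  match_no <- cumsum(is_match)          # match index at/before each column

  for (k in seq_along(aln$seq_ids)) {
    cc <- chars(aln$seqs[k])
    lab <- aln$labels[k, ]
    # implied state path: list of (type, j) in column order
    types <- character(0); js <- integer(0)
    for (col in seq_len(aln$width)) {
      if (is_match[col]) {
        j <- match_no[col]
        if (cc[col] == "-") {
          types <- c(types, "del"); js <- c(js, j)
        } else {
          flav <- if (lab[col] == "i") "m_i" else "m_ni"
          em <- if (flav == "m_i") "em_i" else "em_ni"
          if (flav == "m_i") em_i[j, cc[col]] <- em_i[j, cc[col]] + 1
          else em_ni[j, cc[col]] <- em_ni[j, cc[col]] + 1
          types <- c(types, flav); js <- c(js, j)
        }
      } else if (cc[col] != "-") {
        slot <- match_no[col]             # insert slot after match column slot
        em_ins[slot + 1L, cc[col]] <- em_ins[slot + 1L, cc[col]] + 1
        types <- c(types, "ins"); js <- c(js, slot)
      }
    }
    # transition counts along Begin -> path -> End
    full_t <- c("begin", types, "end")
    full_j <- c(0L, js, L)
    for (s in seq_len(length(full_t) - 1L)) {
      from <- full_t[s]; to <- full_t[s + 1L]
      fj <- full_j[s]
      to_arc <- switch(to, m_ni = "m_ni", m_i = "m_i", ins = "ins",
                       del = "del", end = "end")
      if (from == "begin") {
        t_begin[to_arc] <- t_begin[to_arc] + 1
      } else if (from == "m_i") {
        t_mi[fj, to_arc] <- t_mi[fj, to_arc] + 1
      } else if (from == "m_ni") {
        t_mni[fj, to_arc] <- t_mni[fj, to_arc] + 1
      } else if (from == "ins") {
        t_ins[fj + 1L, to_arc] <- t_ins[fj + 1L, to_arc] + 1
      } else if (from == "del") {
        if (to_arc == "ins") next       # D -> I arc not in the architecture
        t_del[fj, to_arc] <- t_del[fj, to_arc] + 1
      }
    }
  }

  norm_rows <- function(m) m / rowSums(m)
  em_i <- norm_rows(em_i + pseudocount)
  em_ni <- norm_rows(em_ni + pseudocount)
  em_ins <- norm_rows(em_ins + pseudocount)

  allowed <- iphmm_allowed_arcs(L)
  smooth <- function(counts, mask) {
    counts <- counts + pseudocount * mask
    counts[!mask] <- 0
    counts / rowSums(counts)
  }
  t_begin <- {
    v <- t_begin + pseudocount * allowed$begin
    v[!allowed$begin] <- 0
    v / sum(v)
  }
  t_mi <- smooth(t_mi, allowed$match)
  t_mni <- smooth(t_mni, allowed$match)
  t_ins <- smooth(t_ins, allowed$insert)
  t_del <- smooth(t_del, allowed$delete)

  structure(
    list(n_match = L, pseudocount = pseudocount, alphabet = AA_ALPHABET,
         emissions = list(match_i = em_i, match_ni = em_ni, insert = em_ins),
         transitions = list(begin = t_begin, match_i = t_mi, match_ni = t_mni,
                            insert = t_ins, delete = t_del)),
    class = "iphmm")
}

# logical masks of allowed outgoing arcs, arc order m_ni, m_i, ins, del, end
iphmm_allowed_arcs <- function(L) {
  arc <- c("m_ni", "m_i", "ins", "del", "end")
  last_m <- setNames(c(FALSE, FALSE, TRUE, FALSE, TRUE), arc)
  mid_m <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE), arc)
  match <- matrix(rep(mid_m, each = L), L, 5, dimnames = list(NULL, arc))
  if (L >= 1L) match[L, ] <- last_m
  insert <- matrix(rep(mid_m, each = L + 1L), L + 1L, 5,
                   dimnames = list(NULL, arc))
  insert[L + 1L, ] <- last_m
  mid_d <- setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE), arc)
  delete <- matrix(rep(mid_d, each = L), L, 5, dimnames = list(NULL, arc))
  delete[L, ] <- setNames(c(FALSE, FALSE, FALSE, FALSE, TRUE), arc)
  begin <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE), arc)
  list(begin = begin, match = match, insert = insert, delete = delete)
}

#' @export
print.iphmm <- function(x, ...) {
  cat(sprintf("<iphmm> %d match positions (split M_i/M_ni), pseudocount %g\n",
              x$n_match, x$pseudocount))
  invisible(x)
}

#' Validate the stochasticity of an ipHMM
#'
#' Checks that every emission vector and every outgoing transition
#' distribution sums to 1 (within `tol`) and that all probabilities on
#' allowed arcs are strictly positive.
#'
#' @param model An `iphmm`.
#' @param tol Tolerance on the sums (default 1e-9).
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_iphmm <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "iphmm"))
  for (nm in names(model$emissions)) {
    s <- rowSums(model$emissions[[nm]])
    if (any(abs(s - 1) > tol)) stop_validation("emission rows of %s do not sum to 1", nm)
    if (any(model$emissions[[nm]] <= 0)) stop_validation("non-positive emission in %s", nm)
  }
  allowed <- iphmm_allowed_arcs(model$n_match)
  tr <- model$transitions
  chk <- function(m, mask, nm) {
    m <- rbind(m)
    if (any(abs(rowSums(m) - 1) > tol)) stop_validation("transition rows of %s do not sum to 1", nm)
    if (any(m[mask] <= 0)) stop_validation("zero probability on allowed arc in %s", nm)
    if (any(m[!mask] != 0)) stop_validation("probability mass on disallowed arc in %s", nm)
  }
  chk(tr$begin, rbind(allowed$begin), "begin")
  chk(tr$match_i, allowed$match, "match_i")
  chk(tr$match_ni, allowed$match, "match_ni")
  chk(tr$insert, allowed$insert, "insert")
  chk(tr$delete, allowed$delete, "delete")
  invisible(TRUE)
}

#' Serialize / deserialize an ipHMM as JSON
#'
#' @param model An `iphmm`.
#' @param path File path.
#' @return `path` (write) or an `iphmm` (read).
#' @export
write_iphmm <- function(model, path) {
  stopifnot(inherits(model, "iphmm"))
  obj <- list(format = "cmiphmm-iphmm", version = 1L,
              n_match = model$n_match, pseudocount = model$pseudocount,
              alphabet = paste(model$alphabet, collapse = ""),
              emissions = map(model$emissions, unclass),
              transitions = map(model$transitions, unclass))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_iphmm
#' @export
read_iphmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cmiphmm-iphmm")) {
    stop_format("%s is not an ipHMM model file", path)
  }
  arc <- c("m_ni", "m_i", "ins", "del", "end")
  fix_em <- function(m) {
    m <- matrix(as.numeric(m), ncol = 20)
    colnames(m) <- AA_ALPHABET
    m
  }
  fix_tr <- function(m) {
    m <- matrix(as.numeric(m), ncol = 5)
    colnames(m) <- arc
    m
  }
  model <- structure(
    list(n_match = as.integer(obj$n_match),
         pseudocount = as.numeric(obj$pseudocount),
         alphabet = AA_ALPHABET,
         emissions = list(match_i = fix_em(obj$emissions$match_i),
                          match_ni = fix_em(obj$emissions$match_ni),
                          insert = fix_em(obj$emissions$insert)),
         transitions = list(begin = setNames(as.numeric(obj$transitions$begin), arc),
                            match_i = fix_tr(obj$transitions$match_i),
                            match_ni = fix_tr(obj$transitions$match_ni),
                            insert = fix_tr(obj$transitions$insert),
                            delete = fix_tr(obj$transitions$delete))),
    class = "iphmm")
  validate_iphmm(model)
  model
}
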