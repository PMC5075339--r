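#' Decode a sequence against an ipHMM by forward-backward
#'
#' Computes the forward log-likelihood of the (ungapped) sequence and the
#' posterior probability of every emitting state at every residue position
#' by the forward-backward algorithm in log space.
#'
#' @param model An [build_iphmm()] model.
#' @param seq Amino-acid string (no gaps).
#' @param seq_id Identifier recorded in the decoding.
#' @return An `iphmm_decoding`: `log_likelihood`; posterior matrices
#'   `gamma_match_i`, `gamma_match_ni` (`L x n`), `gamma_insert`
#'   (`(L+1) x n`, slot j in row j+1); per-match-column posterior masses and
#'   `site_probability` `p_int(j)` = mass on `M_i(j)` normalised over the
#'   two match flavours of position j.
#' @export
forward_backward <- function(model, seq, seq_id = "seq") {
  stopifnot(inherits(model, "iphmm"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop_param("seq must be a single non-empty string")
  }
  cc <- check_residues(seq, what = sprintf("sequence '%s'", seq_id))
  x <- match(cc, AA_ALPHABET)
  n <- length(x)
  L <- model$n_match
  NEG <- -Inf

  lem_i <- log(model$emissions$match_i)
  lem_ni <- log(model$emissions$match_ni)
  lem_ins <- log(model$emissions$insert)
  tb <- log(model$transitions$begin)
  tmi <- log(model$transitions$match_i)
  tmni <- log(model$transitions$match_ni)
  tins <- log(model$transitions$insert)
  tdel <- log(model$transitions$delete)

  lse2 <- function(v) {
    m <- max(v)
    if (!is.finite(m)) return(NEG)
    m + log(sum(exp(v - m)))
  }

  # forward; column ci = i + 1 residues consumed
  fMi <- matrix(NEG, L, n + 1L); fMni <- matrix(NEG, L, n + 1L)
  fI <- matrix(NEG, L + 1L, n + 1L); fD <- matrix(NEG, L, n + 1L)
  fB <- c(0, rep(NEG, n))

  for (i in 0:n) {
    ci <- i + 1L
    if (i >= 1L) {
      pi <- ci - 1L
      for (j in seq_len(L)) {
        src_ni <- if (j == 1L) c(fB[pi] + tb["m_ni"], fI[1L, pi] + tins[1L, "m_ni"])
        else c(fMni[j - 1L, pi] + tmni[j - 1L, "m_ni"],
               fMi[j - 1L, pi] + tmi[j - 1L, "m_ni"],
               fD[j - 1L, pi] + tdel[j - 1L, "m_ni"],
               fI[j, pi] + tins[j, "m_ni"])
        src_i <- if (j == 1L) c(fB[pi] + tb["m_i"], fI[1L, pi] + tins[1L, "m_i"])
        else c(fMni[j - 1L, pi] + tmni[j - 1L, "m_i"],
               fMi[j - 1L, pi] + tmi[j - 1L, "m_i"],
               fD[j - 1L, pi] + tdel[j - 1L, "m_i"],
               fI[j, pi] + tins[j, "m_i"])
        fMni[j, ci] <- lem_ni[j, x[i]] + lse2(src_ni)
        fMi[j, ci] <- lem_i[j, x[i]] + lse2(src_i)
      }
      for (j in 0:L) {
        r <- j + 1L
        src <- c(fI[r, pi] + tins[r, "ins"],
                 if (j == 0L) fB[pi] + tb["ins"]
                 else c(fMni[j, pi] + tmni[j, "ins"],
                        fMi[j, pi] + tmi[j, "ins"]))
        fI[r, ci] <- lem_ins[r, x[i]] + lse2(src)
      }
    }
    for (j in seq_len(L)) {
      src <- if (j == 1L) c(fB[ci] + tb["del"], fI[1L, ci] + tins[1L, "del"])
      else c(fMni[j - 1L, ci] + tmni[j - 1L, "del"],
             fMi[j - 1L, ci] + tmi[j - 1L, "del"],
             fD[j - 1L, ci] + tdel[j - 1L, "del"],
             fI[j, ci] + tins[j, "del"])
      fD[j, ci] <- lse2(src)
    }
  }
  en <- n + 1L
  logP <- lse2(c(fMni[L, en] + tmni[L, "end"], fMi[L, en] + tmi[L, "end"],
                 fD[L, en] + tdel[L, "end"], fI[L + 1L, en] + tins[L + 1L, "end"]))
  if (!is.finite(logP)) {
    stop_validation("sequence '%s' has zero likelihood under the model", seq_id)
  }

  # backward
  bMi <- matrix(NEG, L, n + 1L); bMni <- matrix(NEG, L, n + 1L)
  bI <- matrix(NEG, L + 1L, n + 1L); bD <- matrix(NEG, L, n + 1L)
  for (i in n:0) {
    ci <- i + 1L
    has_next <- i < n
    xi1 <- if (has_next) x[i + 1L] else NA_integer_
    for (j in L:1) {
      v <- c(if (j == L && i == n) tdel[L, "end"] else NEG,
             if (j < L) c(bD[j + 1L, ci] + tdel[j, "del"],
                          if (has_next) c(
                            bMni[j + 1L, ci + 1L] + lem_ni[j + 1L, xi1] + tdel[j, "m_ni"],
                            bMi[j + 1L, ci + 1L] + lem_i[j + 1L, xi1] + tdel[j, "m_i"])))
      bD[j, ci] <- lse2(v)
    }
    for (j in 0:L) {
      r <- j + 1L
      v <- c(if (j == L && i == n) tins[r, "end"] else NEG,
             if (has_next) bI[r, ci + 1L] + lem_ins[r, xi1] + tins[r, "ins"],
             if (j < L) c(bD[j + 1L, ci] + tins[r, "del"],
                          if (has_next) c(
                            bMni[j + 1L, ci + 1L] + lem_ni[j + 1L, xi1] + tins[r, "m_ni"],
                            bMi[j + 1L, ci + 1L] + lem_i[j + 1L, xi1] + tins[r, "m_i"])))
      bI[r, ci] <- lse2(v)
    }
    for (j in seq_len(L)) {
      mk <- function(tm) {
        v <- c(if (j == L && i == n) tm[j, "end"] else NEG,
               if (has_next) bI[j + 1L, ci + 1L] + lem_ins[j + 1L, xi1] + tm[j, "ins"],
               if (j < L) c(bD[j + 1L, ci] + tm[j, "del"],
                            if (has_next) c(
                              bMni[j + 1L, ci + 1L] + lem_ni[j + 1L, xi1] + tm[j, "m_ni"],
                              bMi[j + 1L, ci + 1L] + lem_i[j + 1L, xi1] + tm[j, "m_i"])))
        lse2(v)
      }
      bMni[j, ci] <- mk(tmni)
      bMi[j, ci] <- mk(tmi)
    }
  }

  cols <- 2:(n + 1L)
  gMi <- exp(fMi[, cols, drop = FALSE] + bMi[, cols, drop = FALSE] - logP)
  gMni <- exp(fMni[, cols, drop = FALSE] + bMni[, cols, drop = FALSE] - logP)
  gIns <- exp(fI[, cols, drop = FALSE] + bI[, cols, drop = FALSE] - logP)

  mass_i <- rowSums(gMi)
  mass_ni <- rowSums(gMni)
  denom <- mass_i + mass_ni
  p_int <- ifelse(denom > 0, mass_i / denom, NA_real_)

  structure(
    list(seq_id = seq_id, seq = seq, log_likelihood = logP,
         gamma_match_i = gMi, gamma_match_ni = gMni, gamma_insert = gIns,
         match_mass_i = mass_i, match_mass_ni = mass_ni,
         match_mass = denom, site_probability = p_int),
    class = "iphmm_decoding")
}

#' @export
print.iphmm_decoding <- function(x, ...) {
  cat(sprintf("<iphmm_decoding> '%s': %d residues, logL = %.4f\n",
              x$seq_id, nchar(x$seq), x$log_likelihood))
  invisible(x)
}

#' Posterior interaction-site calls from a decoding
#'
#' A match column is called interacting when its posterior interaction
#' probability `p_int` exceeds `threshold`; a tie goes to the majority
#' (non-interacting) class. Columns the sequence deletes are called
#' non-interacting with `p_int = 0`.
#'
#' @param dec An [forward_backward()] decoding.
#' @param occupied Optional logical vector over match columns (`TRUE` where
#'   the sequence has an aligned residue). When `NULL`, a column counts as
#'   occupied when its posterior match mass exceeds 0.5.
#' @param threshold Decision threshold on `p_int` (default 0.5).
#' @return Tibble with `match_index`, `p_int`, `call`
#'   (`"interacting"`/`"non_interacting"`), `occupied`.
#' @export
predict_sites <- function(dec, occupied = NULL, threshold = 0.5) {
  stopifnot(inherits(dec, "iphmm_decoding"))
  L <- length(dec$site_probability)
  if (is.null(occupied)) occupied <- dec$match_mass > 0.5
  if (length(occupied) != L) {
    stop_param("occupied must have one entry per match column")
  }
  p <- ifelse(occupied, dec$site_probability, 0)
  p[is.na(p)] <- 0
  tibble(match_index = seq_len(L),
         p_int = p,
         call = ifelse(occupied & p > threshold,
                       "interacting", "non_interacting"),
         occupied = occupied)
}

#' Fisher scores of a decoded sequence
#'
#' The gradient of the sequence log-likelihood with respect to the
#' (sum-constrained) emission parameters of the match states, restricted to
#' one residue's term: residue i is assigned the match column `j*` carrying
#' its largest posterior match mass, and
#' `F_i(a) = sum over flavours m of gamma(i, m(j*)) * (1[x_i = a] - e_m(j*)(a))`.
#' Each 20-vector sums to zero (the constrained-gradient identity). A
#' residue with (numerically) zero posterior match mass gets an all-zero
#' vector and is flagged in the `pure_insert` attribute.
#'
#' @param model The `iphmm` used for decoding.
#' @param dec The [forward_backward()] decoding of `seq` under `model`.
#' @return `n x 20` matrix (class `fisher_profile`) with attribute
#'   `pure_insert` (logical per residue) and `match_column` (the `j*`
#'   assignment per residue).
#' @export
fisher_scores <- function(model, dec) {
  stopifnot(inherits(model, "iphmm"), inherits(dec, "iphmm_decoding"))
  x <- match(chars(dec$seq), AA_ALPHABET)
  n <- length(x)
  F <- matrix(0, n, 20, dimnames = list(NULL, AA_ALPHABET))
  pure_insert <- logical(n)
  jstar <- integer(n)
  for (i in seq_len(n)) {
    mass <- dec$gamma_match_i[, i] + dec$gamma_match_ni[, i]
    if (max(mass) < 1e-12) {
      pure_insert[i] <- TRUE
      jstar[i] <- NA_integer_
      next
    }
    j <- which.max(mass)
    jstar[i] <- j
    onehot <- as.numeric(seq_len(20) == x[i])
    F[i, ] <- dec$gamma_match_i[j, i] * (onehot - model$emissions$match_i[j, ]) +
      dec$gamma_match_ni[j, i] * (onehot - model$emissions$match_ni[j, ])
  }
  structure(F, class = c("fisher_profile", class(F)),
            pure_insert = pure_insert, match_column = jstar,
            seq_id = dec$seq_id)
}
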