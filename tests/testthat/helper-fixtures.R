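# shared fixtures, built in code

# 2 x 4 toy alignment: match columns 1, 2, 4 (alignment column 3 is an
# insert column)
toy_alignment <- function() {
  labeled_alignment(
    family_id = "toy", domain_role = "A",
    seq_ids = c("s1", "s2"),
    seqs = c("AC-D", "ACED"),
    match_columns = c(1L, 2L, 4L),
    labels = rbind(c("i", "i", ".", "n"),
                   c("i", "n", ".", "n")))
}

# hand-built single-position model: Begin -> M_i(1) = Begin -> M_ni(1) = 0.5,
# uniform emissions, M* -> End = 1
toy_one_state_model <- function() {
  arc <- c("m_ni", "m_i", "ins", "del", "end")
  em <- matrix(1 / 20, 1, 20, dimnames = list(NULL, AA20))
  em_ins <- matrix(1 / 20, 2, 20, dimnames = list(NULL, AA20))
  t_m <- matrix(0, 1, 5, dimnames = list(NULL, arc))
  t_m[1, "end"] <- 1
  t_ins <- matrix(0, 2, 5, dimnames = list(NULL, arc))
  t_ins[, "end"] <- 1
  t_del <- matrix(0, 1, 5, dimnames = list(NULL, arc))
  t_del[1, "end"] <- 1
  structure(
    list(n_match = 1L, pseudocount = 0, alphabet = AA20,
         emissions = list(match_i = em, match_ni = em, insert = em_ins),
         transitions = list(
           begin = stats::setNames(c(0.5, 0.5, 0, 0, 0), arc),
           match_i = t_m, match_ni = t_m, insert = t_ins, delete = t_del)),
    class = "iphmm")
}

# fabricated decoding with full posterior mass on chosen match states; used
# to unit-test the Fisher-score formula in isolation
manual_decoding <- function(seq, gamma_i, gamma_ni, L) {
  n <- nchar(seq)
  gi <- matrix(0, L, n); gni <- matrix(0, L, n)
  for (i in seq_len(n)) {
    gi[, i] <- gamma_i[[i]]
    gni[, i] <- gamma_ni[[i]]
  }
  structure(
    list(seq_id = "manual", seq = seq, log_likelihood = 0,
         gamma_match_i = gi, gamma_match_ni = gni,
         gamma_insert = matrix(0, L + 1, n),
         match_mass_i = rowSums(gi), match_mass_ni = rowSums(gni),
         match_mass = rowSums(gi) + rowSums(gni),
         site_probability = rowSums(gi) / pmax(rowSums(gi) + rowSums(gni),
                                               .Machine$double.eps)),
    class = "iphmm_decoding")
}

# single-property table with distinctive values, for window-feature tests
tiny_aaindex <- function(n_props = 1L) {
  vals <- matrix(seq_len(20 * n_props), nrow = n_props, byrow = TRUE,
                 dimnames = list(sprintf("TEST%06d", seq_len(n_props)), AA20))
  aaindex_table(vals)
}

# small sharp family without label noise (clean regime, fast pipeline runs)
clean_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_family(
        family_spec(n_pairs = 10, frac_interface = 0.5, contact_density = 1,
                    label_noise = 0, indel_rate = 0.05, seed = 404), "clean")
    }
    cache
  }
})

# default-regime benchmark suite shared by the acceptance checks
bench_cache <- new.env(parent = emptyenv())
get_benchmark_suite <- function() {
  if (is.null(bench_cache$suite)) {
    bench_cache$suite <- benchmark_suite(10L, seed = 1L)
  }
  bench_cache$suite
}
get_benchmark_decodings <- function() {
  if (is.null(bench_cache$decodings)) {
    bench_cache$decodings <- purrr::map(get_benchmark_suite(), function(fam) {
      hmm_a <- build_iphmm(fam$aln_a)
      hmm_b <- build_iphmm(fam$aln_b)
      decs <- c(
        purrr::map(fam$pairs$seq_a,
                   ~forward_backward(hmm_a, ungapped_sequence(fam$aln_a, .x), .x)),
        purrr::map(fam$pairs$seq_b,
                   ~forward_backward(hmm_b, ungapped_sequence(fam$aln_b, .x), .x)))
      list(hmm_a = hmm_a, hmm_b = hmm_b, decodings = decs)
    })
  }
  bench_cache$decodings
}
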