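test_that("match emissions follow add-one counting over labeled residues", {
  # column of interacting residues {A, A, C, C}: e(A) = (2+1)/(4+20)
  aln <- labeled_alignment(
    "f", "A", paste0("s", 1:4), c("A", "A", "C", "C"),
    match_columns = 1L,
    labels = matrix("i", 4, 1))
  m <- build_iphmm(aln, pseudocount = 1)
  expect_equal(unname(m$emissions$match_i[1, "A"]), 3 / 24)
  expect_equal(unname(m$emissions$match_i[1, "C"]), 3 / 24)
  # an amino acid absent from the column still gets one pseudo-observation
  expect_equal(unname(m$emissions$match_i[1, "K"]), 1 / 24)
  expect_true(all(m$emissions$match_i > 0))
  # the non-interacting flavour saw no residues: uniform from pseudocounts
  expect_equal(unname(m$emissions$match_ni[1, ]), rep(1 / 20, 20),
               ignore_attr = TRUE)
})

test_that("pseudocount -> 0 limit recovers empirical column frequencies", {
  aln <- labeled_alignment(
    "f", "A", paste0("s", 1:4), c("AC", "AC", "AC", "AC"),
    match_columns = 1:2,
    labels = matrix(c("i", "i", "i", "i", "n", "n", "n", "n"), 4, 2))
  m <- build_iphmm(aln, pseudocount = 1e-9)
  expect_equal(unname(m$emissions$match_i[1, "A"]), 1, tolerance = 1e-7)
  expect_equal(unname(m$emissions$match_ni[2, "C"]), 1, tolerance = 1e-7)
})

test_that("degenerate build inputs raise parameter errors", {
  aln <- toy_alignment()
  expect_error(build_iphmm(aln, pseudocount = 0),
               class = "cmiphmm_parameter_error")
  expect_error(build_iphmm(aln, pseudocount = -1),
               class = "cmiphmm_parameter_error")
  expect_error(
    labeled_alignment("f", "A", "s1", "AC", integer(0),
                      matrix(".", 1, 2)),
    class = "cmiphmm_format_error")
})

test_that("built models are properly stochastic and serialize losslessly", {
  withr::with_seed(21, {
    for (k in 1:5) {
      m <- random_small_model()
      expect_true(validate_iphmm(m))
    }
  })
  fam <- clean_family()
  m <- build_iphmm(fam$aln_a)
  expect_true(validate_iphmm(m))
  path <- withr::local_tempfile(fileext = ".json")
  write_iphmm(m, path)
  back <- read_iphmm(path)
  expect_equal(back$emissions, m$emissions)
  expect_equal(back$transitions, m$transitions)
  expect_equal(back$n_match, m$n_match)
})

test_that("two-path sum: L = 1 model with uniform emissions gives P(seq) = 0.05", {
  m <- toy_one_state_model()
  dec <- forward_backward(m, "A")
  expect_equal(exp(dec$log_likelihood), 0.05)
  # posterior over the two match flavours sums to one
  expect_equal(dec$gamma_match_i[1, 1] + dec$gamma_match_ni[1, 1], 1)
  expect_equal(dec$site_probability[1], 0.5)
})

test_that("forward equals the exhaustive path-sum oracle on random small models", {
  withr::with_seed(31, {
    for (k in 1:40) {
      m <- random_small_model()
      s <- random_sequence()
      lo <- unname(enumerate_likelihood(m, s))
      lf <- forward_backward(m, s)$log_likelihood
      expect_equal(lf, lo, tolerance = 1e-10)
    }
  })
})

test_that("posteriors normalize per residue and decoding is deterministic", {
  fam <- clean_family()
  hmm <- build_iphmm(fam$aln_a)
  s <- ungapped_sequence(fam$aln_a, "p01_a")
  dec <- forward_backward(hmm, s, "p01_a")
  sums <- colSums(dec$gamma_match_i) + colSums(dec$gamma_match_ni) +
    colSums(dec$gamma_insert)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(dec$site_probability >= 0 & dec$site_probability <= 1,
                  na.rm = TRUE))
  dec2 <- forward_backward(hmm, s, "p01_a")
  expect_identical(dec$log_likelihood, dec2$log_likelihood)
  expect_identical(dec$gamma_match_i, dec2$gamma_match_i)
  expect_error(forward_backward(hmm, "ACZ"), "position 3",
               class = "cmiphmm_format_error")
})
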