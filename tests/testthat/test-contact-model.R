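test_that("window features have 11 x 17 layout with boundary padding", {
  tab <- default_aaindex()
  seq3 <- "ACD"
  v <- residue_window_features(seq3, tab, pos = 2)
  expect_length(v, 187L)
  # |seq| = 3, pos = 2: 8 of the 11 slots fall outside the sequence
  pad <- rowMeans(tab$values)
  slots <- matrix(v, nrow = 17)
  padded <- apply(slots, 2, function(s) isTRUE(all.equal(s, unname(pad))))
  expect_equal(sum(padded), 8L)
  # pos = 1 on a long sequence: exactly the 5 left slots are padded
  long <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  v1 <- matrix(residue_window_features(long, tab, pos = 1), nrow = 17)
  padded1 <- apply(v1, 2, function(s) isTRUE(all.equal(s, unname(pad))))
  expect_equal(which(padded1), 1:5)
})

test_that("degenerate windows and bad parameters are handled", {
  tab1 <- tiny_aaindex(1L)
  v <- residue_window_features("ACD", tab1, pos = 2, window = 1L)
  expect_length(v, 1L)
  expect_equal(v, unname(tab1$values[1, "C"]))
  expect_error(residue_window_features("ACD", tab1, pos = 2, window = 4L),
               class = "cmiphmm_parameter_error")
  expect_error(residue_window_features("ACD", tab1, pos = 9),
               class = "cmiphmm_parameter_error")
})

test_that("pair vectors concatenate A-then-B blocks to length 414", {
  fa <- rnorm(20); fb <- rnorm(20)
  wa <- rnorm(187); wb <- rnorm(187)
  v <- build_pair_vector(fa, wa, fb, wb)
  expect_length(v, 414L)
  expect_equal(v[1:20], fa)
  expect_equal(v[21:207], wa)
  expect_equal(v[208:227], fb)
  # zero inputs give the zero vector
  expect_equal(build_pair_vector(numeric(20), numeric(187),
                                 numeric(20), numeric(187)),
               numeric(414))
  # A-first ordering is asymmetric by design
  expect_false(isTRUE(all.equal(v, build_pair_vector(fb, wb, fa, wa))))
})

test_that("min-max normalizer scales, clamps and zeroes constant features", {
  train <- cbind(c(2, 6, 4), c(5, 5, 5))
  nm <- fit_normalizer(train)
  expect_equal(unname(apply_normalizer(nm, c(4, 5))), c(0.5, 0))
  expect_equal(unname(apply_normalizer(nm, c(8, 5))), c(1, 0))   # clamped
  expect_equal(unname(apply_normalizer(nm, c(0, 9))), c(0, 0))
  xs <- apply_normalizer(nm, train)
  expect_true(all(xs >= 0 & xs <= 1))
  expect_error(fit_normalizer(matrix(0, 0, 3)),
               class = "cmiphmm_parameter_error")
})

test_that("the RBF-SVM separates a constructed margin and flags degenerate input", {
  withr::with_seed(5, {
    x <- rbind(matrix(runif(200, 0.75, 1), 10),
               matrix(runif(200, 0, 0.25), 10))
    y <- rep(c(1, 0), each = 10)
  })
  m <- train_contact_svm(x, y, gamma = 0.05, cost = 10)
  dv <- contact_decision_values(m, x)
  expect_equal(as.numeric(dv > 0), y)          # training accuracy 1.0
  # hard-margin limit: large C keeps the separable set error-free
  m2 <- train_contact_svm(x, y, gamma = 0.05, cost = 1e4)
  expect_equal(as.numeric(contact_decision_values(m2, x) > 0), y)
  # identical points with conflicting labels cannot all be fit
  xc <- rbind(x, x[1:4, ]); yc <- c(y, 1 - y[1:4])
  m3 <- train_contact_svm(xc, yc, gamma = 0.05, cost = 10)
  dup <- contact_decision_values(m3, xc[c(1:4, 21:24), ]) > 0
  lab <- c(y[1:4], 1 - y[1:4])
  expect_lte(mean(dup == lab), 0.5)
  expect_error(train_contact_svm(x, rep(1, 20)),
               class = "cmiphmm_parameter_error")
})

test_that("predicted contact matrices have model-coordinate shape with zeroed deletions", {
  fam <- clean_family()
  cms <- predict_pair_contacts(fam, "p02")
  expect_equal(dim(cms$binary), c(fam$spec$len_a, fam$spec$len_b))
  expect_equal(dim(cms$score), dim(cms$binary))
  # binary = positive score, everywhere
  expect_equal(cms$binary$cells == 1, cms$score$cells > 0)
  # deleted match columns give all-zero rows / columns
  map_a <- match_residue_map(fam$aln_a, "p02_a")
  if (any(is.na(map_a))) {
    expect_true(all(cms$binary$cells[is.na(map_a), ] == 0))
  }
  # in the clean sharp regime the prediction recovers most true contacts
  truth <- fam$contacts[["p02"]]$cells
  tp <- sum(truth == 1 & cms$binary$cells == 1)
  expect_gt(tp / sum(truth), 0.5)                      # recall
  expect_gt(tp / max(sum(cms$binary$cells), 1), 0.5)   # precision
})
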