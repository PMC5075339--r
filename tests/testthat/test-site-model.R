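test_that("site feature vectors are contact rows/columns plus the ipHMM slot", {
  cm <- contact_matrix(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 0), 3, 4),
                       "ground_truth")
  p_int <- c(0.7, 0.2, 0.9)
  ft <- build_site_features(cm, p_int, "A", "cm_iphmm")
  expect_equal(attr(ft, "n_features"), 5L)
  expect_equal(ft$features[[1]], c(cm$cells[1, ], 0.7))
  # cm_only drops the trailing ipHMM slot
  ft0 <- build_site_features(cm, p_int, "A", "cm_only")
  expect_equal(attr(ft0, "n_features"), 4L)
  expect_equal(ft0$features[[1]], ft$features[[1]][1:4])
  # domain B residues take columns
  ftb <- build_site_features(cm, c(0.1, 0.2, 0.3, 0.4), "B", "cm_iphmm")
  expect_equal(ftb$features[[2]], c(cm$cells[, 2], 0.2))
  # deleted columns are skipped
  ftocc <- build_site_features(cm, p_int, "A", "cm_iphmm",
                               occupied = c(TRUE, FALSE, TRUE))
  expect_equal(ftocc$match_index, c(1L, 3L))
  expect_error(build_site_features(cm, c(0.5, 0.5), "A", "cm_iphmm"),
               class = "cmiphmm_validation_error")
})

test_that("ground-truth features are consistent with the labels they encode", {
  fam <- clean_family()
  cm <- fam$contacts[["p01"]]
  tl <- fam$truth$labels
  tl <- tl[tl$pair_id == "p01" & tl$domain_role == "A", ]
  occ <- !tl$deleted
  ft <- build_site_features(cm, rep(0.5, nrow(cm$cells)), "A", "cm_only",
                            occupied = occ)
  has_contact <- purrr::map_lgl(ft$features, ~any(.x == 1))
  expect_equal(has_contact, tl$interacting[occ])
})

test_that("oversampling balances classes deterministically", {
  data <- tibble::tibble(features = as.list(1:12),
                         label = c(rep(1, 3), rep(0, 9)))
  bal <- oversample_positives(data, seed = 5)
  expect_equal(sum(bal$label == 1), 9L)
  expect_equal(sum(bal$label == 0), 9L)
  # negatives untouched: the original nine negatives each appear once
  expect_setequal(unlist(bal$features[bal$label == 0]), 4:12)
  # already balanced input keeps its counts
  eq <- tibble::tibble(features = as.list(1:6), label = rep(c(0, 1), 3))
  expect_equal(table(oversample_positives(eq, 1)$label), table(eq$label))
  # determinism
  expect_identical(oversample_positives(data, seed = 11),
                   oversample_positives(data, seed = 11))
  expect_error(oversample_positives(tibble::tibble(features = list(1),
                                                   label = 1)),
               "negative", class = "cmiphmm_parameter_error")
  expect_error(oversample_positives(tibble::tibble(features = list(1),
                                                   label = 0)),
               "positive", class = "cmiphmm_parameter_error")
})

test_that("the logistic response follows Pr(Y=1|X) = 1/(1+exp(-(b0 + b'x)))", {
  model <- structure(
    list(intercept = 0, coefficients = c(1, 0, 0), domain_role = "A",
         variant = "cm_iphmm", C = 1, n_features = 3L, n_train = 0L,
         converged = TRUE),
    class = "logistic_site_model")
  ft <- tibble::tibble(match_index = 1:3,
                       features = list(c(2, 0, 0), c(0, 5, 1), c(-2, 0, 0)))
  pr <- predict_sites_integrated(model, ft)
  expect_equal(pr$probability[1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(pr$call[1], "interacting")
  # all-zero coefficients: probability one half everywhere, tie -> majority
  model$coefficients <- c(0, 0, 0)
  pr0 <- predict_sites_integrated(model, ft)
  expect_equal(pr0$probability, rep(0.5, 3))
  expect_equal(unique(pr0$call), "non_interacting")
  # intercept -> -Inf saturates to non-interacting
  model$intercept <- -1e6
  expect_equal(unique(predict_sites_integrated(model, ft)$call),
               "non_interacting")
  expect_error(predict_sites_integrated(model,
                                        tibble::tibble(match_index = 1,
                                                       features = list(1:5))),
               class = "cmiphmm_validation_error")
})

test_that("fitting recovers the sign of an informative final feature", {
  withr::with_seed(9, {
    n <- 120
    last <- runif(n)
    x <- cbind(runif(n), runif(n), last)
    data <- tibble::tibble(
      features = purrr::map(seq_len(n), ~x[.x, ]),
      label = as.integer(last > 0.5))
  })
  bal <- oversample_positives(data, seed = 2)
  fit <- train_site_model(bal, "A", "cm_iphmm")
  expect_s3_class(fit, "logistic_site_model")
  expect_gt(fit$coefficients[3], 0)
  expect_true(all(is.finite(fit$coefficients)))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "partner_01", "partner_02",
                          "iphmm_score"))
  expect_equal(td$estimate[-1], fit$coefficients)
  expect_equal(glance(fit)$variant, "cm_iphmm")
  expect_error(train_site_model(bal[bal$label == 1, ], "A", "cm_iphmm"),
               class = "cmiphmm_parameter_error")
})

test_that("ground-truth contact features give a near-separable site fit", {
  fam <- clean_family()
  rows <- purrr::map(fam$pairs$pair_id, function(pid) {
    cm <- fam$contacts[[pid]]
    tl <- fam$truth$labels
    tl <- tl[tl$pair_id == pid & tl$domain_role == "A", ]
    occ <- !tl$deleted
    ft <- build_site_features(cm, rep(0.5, nrow(cm$cells)), "A", "cm_iphmm",
                              occupied = occ)
    ft$label <- tl$interacting[occ]
    ft
  })
  data <- dplyr::bind_rows(rows)
  fit <- train_site_model(oversample_positives(data, 3), "A",
                          "ground_truth_cm")
  pr <- predict_sites_integrated(fit, data)
  cc <- confusion_counts(ifelse(data$label, "interacting", "non_interacting"),
                         pr$call)
  expect_gte(compute_metrics(cc)$mcc, 0.95)
})
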