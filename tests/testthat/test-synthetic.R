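test_that("family generation is deterministic and respects the spec", {
  spec <- family_spec(len_a = 20, len_b = 30, n_pairs = 14, seed = 7)
  f1 <- sample_family(spec, "famD")
  f2 <- sample_family(spec, "famD")
  expect_identical(f1$aln_a$seqs, f2$aln_a$seqs)
  expect_identical(f1$truth$pattern, f2$truth$pattern)
  expect_identical(purrr::map(f1$contacts, "cells"),
                   purrr::map(f2$contacts, "cells"))
  # frac_interface 0.2 on a 20-column domain: exactly 4 interface columns
  f3 <- sample_family(family_spec(len_a = 20, len_b = 30,
                                  frac_interface = 0.2, seed = 1))
  expect_length(f3$truth$iface_a, 4L)
  expect_length(f3$truth$iface_b, 6L)
})

test_that("contact matrices live inside the interface block and match labels", {
  fam <- sample_family(family_spec(seed = 13), "famC")
  for (pid in fam$pairs$pair_id) {
    cells <- fam$contacts[[pid]]$cells
    ones <- which(cells == 1, arr.ind = TRUE)
    expect_true(all(ones[, 1] %in% fam$truth$iface_a))
    expect_true(all(ones[, 2] %in% fam$truth$iface_b))
    # a residue's ground-truth label is exactly "has a contact in its row"
    tl <- fam$truth$labels
    tla <- tl[tl$pair_id == pid & tl$domain_role == "A", ]
    expect_equal(tla$interacting[order(tla$match_index)], rowSums(cells) > 0)
  }
  # every interface column participates in the family topology
  expect_true(all(rowSums(fam$truth$pattern)[fam$truth$iface_a] >= 1))
  expect_true(all(colSums(fam$truth$pattern)[fam$truth$iface_b] >= 1))
})

test_that("invalid family specifications are rejected", {
  expect_error(family_spec(len_a = 80, len_b = 80),
               class = "cmiphmm_parameter_error")
  expect_error(family_spec(frac_interface = 0),
               class = "cmiphmm_parameter_error")
  expect_error(family_spec(label_noise = 1.2),
               class = "cmiphmm_parameter_error")
  expect_error(sample_family(family_spec(len_a = 8, len_b = 30,
                                         frac_interface = 0.02)),
               "zero interface", class = "cmiphmm_parameter_error")
})

test_that("benchmark suites are reproducible and respect the length bound", {
  suite <- benchmark_suite(4L, seed = 2)
  suite2 <- benchmark_suite(4L, seed = 2)
  expect_length(suite, 4L)
  expect_identical(purrr::map(suite, ~.x$aln_a$seqs),
                   purrr::map(suite2, ~.x$aln_a$seqs))
  for (fam in suite) {
    expect_lt(fam$spec$len_a + fam$spec$len_b, 150L)
    expect_gte(fam$spec$n_pairs, 10L)
    # label universe per sequence = its non-deleted match columns
    sid <- fam$pairs$seq_a[1]
    occ <- !is.na(match_residue_map(fam$aln_a, sid))
    lab <- fam$aln_a$labels[1, fam$aln_a$match_columns]
    expect_equal(lab != ".", occ)
  }
  expect_error(benchmark_suite(1L), class = "cmiphmm_parameter_error")
})

test_that("alignment labels are the ground truth up to the label-noise rate", {
  spec <- family_spec(n_pairs = 40, label_noise = 0.2, indel_rate = 0,
                      seed = 19)
  fam <- sample_family(spec, "famN")
  tl <- fam$truth$labels
  tla <- tl[tl$domain_role == "A", ]
  tla <- tla[order(tla$pair_id, tla$match_index), ]
  emitted <- fam$aln_a$labels[, fam$aln_a$match_columns]
  emitted <- as.vector(t(emitted)) == "i"
  flips <- mean(emitted != tla$interacting)
  expect_gt(flips, 0.1)
  expect_lt(flips, 0.3)
})

test_that("suppressing emission sharpness removes the ipHMM signal but not the contact channel", {
  run <- function(sharp) {
    fam <- sample_family(family_spec(n_pairs = 12, contact_density = 0.35,
                                     pair_dropout = 0.5, label_noise = 0.1,
                                     emission_sharpness = sharp, seed = 11),
                         "famI")
    pred <- loocv_family(fam, methods = c("iphmm", "ground_truth_cm"),
                         seed = 1)
    rep <- aggregate_report(evaluate_predictions(pred))$overall
    setNames(rep$mcc, rep$method)
  }
  sharp <- run(6)
  flat <- run(0)
  expect_lt(flat[["iphmm"]], sharp[["iphmm"]] - 0.1)
  expect_gt(sharp[["ground_truth_cm"]], 0.9)
  expect_gt(flat[["ground_truth_cm"]], 0.9)
})
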