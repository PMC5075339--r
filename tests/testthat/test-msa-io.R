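test_that("stockholm dialect parses the toy alignment with match columns and labels", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "s1              AC-D",
    "#=GR s1 PPI     ii.n",
    "s2              ACED",
    "#=GR s2 PPI     in.n",
    "#=GC RF         xx.x",
    "//"), path)
  aln <- read_labeled_alignment(path, "stockholm_markup", family_id = "toy")
  expect_s3_class(aln, "labeled_alignment")
  expect_equal(aln$match_columns, c(1L, 2L, 4L))
  labs <- site_labels(aln)
  expect_equal(labs$label[labs$seq_id == "s1" & labs$column == 1], "interacting")
  expect_equal(labs$label[labs$seq_id == "s2" & labs$column == 4],
               "non_interacting")
  # s1 has a gap in the insert column only; all match cells carry labels
  expect_false(any(labs$label == "gap"))
})

test_that("malformed alignments raise typed format errors naming the problem", {
  write_toy <- function(lab1 = "ii.n", seqs = c("AC-D", "ACED"),
                        rf = "xx.x") {
    path <- withr::local_tempfile(fileext = ".sto", .local_envir = parent.frame())
    writeLines(c(
      "# STOCKHOLM 1.0",
      paste("s1      ", seqs[1]),
      paste("#=GR s1 PPI", lab1),
      paste("s2      ", seqs[2]),
      "#=GR s2 PPI in.n",
      paste("#=GC RF ", rf),
      "//"), path)
    path
  }
  # label line of wrong length
  expect_error(read_labeled_alignment(write_toy(lab1 = "ii.nn")),
               class = "cmiphmm_format_error")
  # ragged alignment names the offending row (the one departing from the
  # width established by the first row)
  expect_error(read_labeled_alignment(write_toy(seqs = c("AC-DG", "ACED"))),
               "row 's[12]'", class = "cmiphmm_format_error")
  # unknown residue letter reports letter and position
  expect_error(read_labeled_alignment(write_toy(seqs = c("AZ-D", "ACED"))),
               "'Z' at position 2", class = "cmiphmm_format_error")
  # missing label line
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 AC-D", "#=GC RF xx.x", "//"), path)
  expect_error(read_labeled_alignment(path), class = "cmiphmm_format_error")
})

test_that("labeled alignments round-trip through both dialects", {
  aln <- toy_alignment()
  for (dialect in c("stockholm_markup", "annotated_fasta")) {
    path <- withr::local_tempfile()
    write_labeled_alignment(aln, path, dialect)
    back <- read_labeled_alignment(path, dialect, family_id = "toy")
    expect_equal(back$seqs, aln$seqs)
    expect_equal(back$match_columns, aln$match_columns)
    expect_equal(back$labels, aln$labels)
  }
  # property: random valid instances round-trip exactly
  withr::with_seed(7, {
    for (k in 1:10) {
      aln <- random_small_alignment(L = sample(2:5, 1), nseq = sample(2:5, 1),
                                    extra_cols = sample(0:2, 1))
      path <- withr::local_tempfile()
      dialect <- sample(c("stockholm_markup", "annotated_fasta"), 1)
      write_labeled_alignment(aln, path, dialect)
      back <- read_labeled_alignment(path, dialect, family_id = aln$family_id)
      expect_equal(back$seqs, aln$seqs)
      expect_equal(back$match_columns, aln$match_columns)
      expect_equal(back$labels, aln$labels)
    }
  })
})

test_that("AAindex1 parsing extracts requested accessions in order and rejects NA", {
  tab <- withr::with_seed(3, {
    aaindex_table(matrix(round(runif(60, -2, 5), 3), nrow = 3,
                         dimnames = list(c("AAAA000001", "BBBB000002",
                                           "CCCC000003"), AA20)))
  })
  path <- withr::local_tempfile(fileext = ".txt")
  write_aaindex(tab, path)
  back <- read_aaindex(path, accessions = c("CCCC000003", "AAAA000001"))
  expect_equal(back$accessions, c("CCCC000003", "AAAA000001"))
  expect_equal(back$values["AAAA000001", ], tab$values["AAAA000001", ])
  expect_equal(back$values["CCCC000003", ], tab$values["CCCC000003", ])
  # missing accession named in the error
  expect_error(read_aaindex(path, accessions = c("AAAA000001", "MISSING999")),
               "MISSING999", class = "cmiphmm_format_error")
  # NA entry rejected
  lines <- readLines(path)
  lines[4] <- sub("^\\s*\\S+", "      NA", lines[4])
  writeLines(lines, path)
  expect_error(read_aaindex(path, accessions = "AAAA000001"),
               class = "cmiphmm_format_error")
})

test_that("the default physicochemical property set has 17 scales with finite values", {
  expect_length(default_aaindex_accessions(), 17L)
  tab <- default_aaindex()
  expect_equal(tab$accessions, default_aaindex_accessions())
  expect_equal(dim(tab$values), c(17L, 20L))
  expect_true(all(is.finite(tab$values)))
  # spot value: alpha-CH chemical shift of alanine
  expect_equal(unname(tab$values["ANDN920101", "A"]), 4.35)
})

test_that("contact matrices round-trip and enforce kind and size constraints", {
  cm <- contact_matrix(matrix(0, 2, 3), "ground_truth", "fam", "p01")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, path)
  back <- read_contact_matrix(path)
  expect_equal(back$cells, cm$cells)
  expect_equal(back$kind, "ground_truth")
  expect_equal(back$pair_id, "p01")

  # real-valued score matrices round-trip exactly
  sc <- contact_matrix(matrix(rnorm(12), 3, 4), "predicted_score")
  write_contact_matrix(sc, path)
  expect_equal(read_contact_matrix(path)$cells, sc$cells)

  # binary kinds refuse non-binary cells
  expect_error(contact_matrix(matrix(c(0, 2, 1, 0), 2, 2), "ground_truth"),
               class = "cmiphmm_format_error")
  m <- matrix(c(0, 2, 1, 0), 2, 2)
  write_contact_matrix(contact_matrix(m, "predicted_score"), path)
  lines <- readLines(path)
  lines[1] <- "#kind=ground_truth"
  writeLines(lines, path)
  expect_error(read_contact_matrix(path), class = "cmiphmm_format_error")

  # the summed-domain-length bound rejects an 80 x 80 matrix
  expect_error(contact_matrix(matrix(0, 80, 80), "ground_truth"),
               class = "cmiphmm_validation_error")
})

test_that("prediction reports round-trip through TSV", {
  preds <- tibble::tibble(
    family_id = "fam", pair_id = "p01", domain_role = c("A", "B"),
    seq_id = c("p01_a", "p01_b"), match_index = c(3L, 7L),
    method = "cm_iphmm", label_true = c("interacting", "non_interacting"),
    label_pred = c("interacting", "interacting"), score = c(0.9, 0.62))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  expect_equal(as.data.frame(read_predictions(path)), as.data.frame(preds))
})
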