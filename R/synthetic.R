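#' Specification of a synthetic DDI family
#'
#' Parameters of the generator that emulates the structure of real
#' domain-domain interaction (DDI) families: two conserved domain
#' alignments with a minority of interacting (interface) columns, one
#' shared bipartite interface topology per family, and a binary
#' residue-residue contact matrix per sequence pair consistent with the
#' per-residue labels.
#'
#' @param n_pairs Number of member sequence pairs (default 14, inside the
#'   10-20 range typical of curated DDI families).
#' @param len_a,len_b Match-column counts of the two domains
#'   (`len_a + len_b < 150`).
#' @param frac_interface Fraction of columns per domain that belong to the
#'   interface; the interface column count is `round(frac * len)`.
#' @param emission_sharpness Concentration `kappa >= 0` separating the
#'   interacting emission from the background: the interacting distribution
#'   is `(1-w) b + w d` with `w = 1 - exp(-kappa)`, so `kappa = 0` makes
#'   interface residues indistinguishable from background.
#' @param contact_density Probability that an (interface A, interface B)
#'   column pair is an edge of the family's shared contact topology.
#' @param indel_rate Per-column probability of a deletion, and per-slot
#'   probability of an insertion, in each emitted sequence.
#' @param label_noise Probability that a residue's emitted training label is
#'   flipped relative to the ground truth.
#' @param pair_dropout Per-pair probability that a topology edge is absent
#'   from that pair's contact matrix (per-pair interface variation).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_pairs = 14L, len_a = 12L, len_b = 15L,
                        frac_interface = 0.45, emission_sharpness = 6,
                        contact_density = 0.9, indel_rate = 0.02,
                        label_noise = 0.3, pair_dropout = 0.15,
                        seed = 1L) {
  spec <- list(n_pairs = as.integer(n_pairs), len_a = as.integer(len_a),
               len_b = as.integer(len_b), frac_interface = frac_interface,
               emission_sharpness = emission_sharpness,
               contact_density = contact_density, indel_rate = indel_rate,
               label_noise = label_noise, pair_dropout = pair_dropout,
               seed = as.integer(seed))
  if (spec$n_pairs < 1L) stop_param("n_pairs must be >= 1")
  if (spec$len_a < 2L || spec$len_b < 2L) stop_param("domain lengths must be >= 2")
  if (spec$len_a + spec$len_b >= 150L) {
    stop_param("len_a + len_b must be < 150 (got %d)", spec$len_a + spec$len_b)
  }
  if (frac_interface <= 0 || frac_interface >= 1) {
    stop_param("frac_interface must be in (0, 1)")
  }
  for (nm in c("contact_density", "indel_rate", "label_noise", "pair_dropout")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) stop_param("%s must be in [0, 1]", nm)
  }
  if (emission_sharpness < 0) stop_param("emission_sharpness must be >= 0")
  structure(spec, class = "family_spec")
}

# support-2 conserved column distribution: consensus mass in [0.96, 0.99]
draw_column_dist <- function(avoid = integer(0)) {
  cons <- sample(setdiff(seq_len(20), avoid), 1L)
  alt <- sample(setdiff(seq_len(20), cons), 1L)
  g <- runif(1, 0.96, 0.99)
  p <- numeric(20)
  p[cons] <- g
  p[alt] <- 1 - g
  p
}

#' Generate one synthetic DDI family
#'
#' Draws per-column emission distributions (interface columns get a
#' sharpness-shifted interacting distribution), a shared bipartite contact
#' topology over the interface columns in which every interface column has
#' at least one edge, and `n_pairs` member sequence pairs. Each pair's
#' ground-truth contact matrix is the topology with per-pair edge dropout;
#' a residue's ground-truth label is "interacting" iff its matrix row or
#' column contains a contact, and emitted training labels add
#' `label_noise` flips. Deleted residues (rate `indel_rate`) lose their
#' contacts; insertions are drawn from a flat background. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [family_spec()].
#' @param family_id Family identifier.
#' @return A `synthetic_family`: labeled alignments `aln_a`, `aln_b`,
#'   ground-truth `contacts` (one [contact_matrix()] per pair), `pairs`
#'   tibble, and `truth` (interface columns, topology, generating emission
#'   distributions, per-residue ground-truth labels).
#' @export
sample_family <- function(spec, family_id = "fam01") {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, sample_family_impl(spec, family_id))
}

sample_family_impl <- function(spec, family_id) {
  k_a <- round(spec$frac_interface * spec$len_a)
  k_b <- round(spec$frac_interface * spec$len_b)
  if (k_a == 0L || k_b == 0L) {
    stop_param("frac_interface %.3f leaves a domain with zero interface columns",
               spec$frac_interface)
  }
  iface_a <- sort(sample(spec$len_a, k_a))
  iface_b <- sort(sample(spec$len_b, k_b))

  w <- 1 - exp(-spec$emission_sharpness)
  draw_domain <- function(len, iface) {
    bg <- t(vapply(seq_len(len), function(j) draw_column_dist(), numeric(20)))
    int <- bg
    for (j in iface) {
      d <- draw_column_dist(avoid = which.max(bg[j, ]))
      int[j, ] <- (1 - w) * bg[j, ] + w * d
    }
    colnames(bg) <- AA_ALPHABET; colnames(int) <- AA_ALPHABET
    list(bg = bg, int = int)
  }
  em_a <- draw_domain(spec$len_a, iface_a)
  em_b <- draw_domain(spec$len_b, iface_b)

  # shared interface topology; every interface column keeps >= 1 edge
  pattern <- matrix(0L, spec$len_a, spec$len_b)
  pattern[iface_a, iface_b] <-
    matrix(rbinom(k_a * k_b, 1L, spec$contact_density), k_a, k_b)
  for (j in iface_a[rowSums(pattern[iface_a, iface_b, drop = FALSE]) == 0]) {
    pattern[j, sample(iface_b, 1L)] <- 1L
  }
  for (j in iface_b[colSums(pattern[iface_a, iface_b, drop = FALSE]) == 0]) {
    pattern[sample(iface_a, 1L), j] <- 1L
  }

  pair_ids <- sprintf("p%02d", seq_len(spec$n_pairs))
  insert_dist <- rep(1 / 20, 20)

  emit_domain <- function(len, em, labels, deleted) {
    # residues at non-deleted match columns + inserts per slot 0..len
    resid <- character(len)
    for (j in seq_len(len)) {
      if (deleted[j]) { resid[j] <- "-"; next }
      p <- if (labels[j]) em$int[j, ] else em$bg[j, ]
      resid[j] <- AA_ALPHABET[sample.int(20L, 1L, prob = p)]
    }
    inserts <- vector("list", len + 1L)
    for (s in 0:len) {
      # no insert directly after a deleted match column (keeps the implied
      # state path inside the profile architecture)
      if (s >= 1L && deleted[s]) { inserts[[s + 1L]] <- character(0); next }
      n_ins <- rbinom(1L, 1L, spec$indel_rate)
      inserts[[s + 1L]] <- if (n_ins > 0) {
        AA_ALPHABET[sample.int(20L, n_ins, replace = TRUE, prob = insert_dist)]
      } else character(0)
    }
    list(resid = resid, inserts = inserts)
  }

  contacts <- list()
  rows_a <- list(); rows_b <- list()
  truth_rows <- list()
  for (p in seq_along(pair_ids)) {
    keep <- matrix(rbinom(length(pattern), 1L, 1 - spec$pair_dropout),
                   nrow(pattern), ncol(pattern))
    m <- pattern * keep
    del_a <- runif(spec$len_a) < spec$indel_rate
    del_b <- runif(spec$len_b) < spec$indel_rate
    m[del_a, ] <- 0L
    m[, del_b] <- 0L
    lab_a <- rowSums(m) > 0
    lab_b <- colSums(m) > 0
    rows_a[[p]] <- emit_domain(spec$len_a, em_a, lab_a, del_a)
    rows_b[[p]] <- emit_domain(spec$len_b, em_b, lab_b, del_b)
    contacts[[pair_ids[p]]] <- contact_matrix(m, "ground_truth",
                                              family_id, pair_ids[p])
    truth_rows[[p]] <- bind_rows(
      tibble(pair_id = pair_ids[p], domain_role = "A",
             match_index = seq_len(spec$len_a),
             interacting = lab_a, deleted = del_a),
      tibble(pair_id = pair_ids[p], domain_role = "B",
             match_index = seq_len(spec$len_b),
             interacting = lab_b, deleted = del_b))
  }
  truth_labels <- bind_rows(truth_rows)

  noisy <- function(lab, deleted) {
    flip <- runif(length(lab)) < spec$label_noise
    out <- ifelse(xor(lab, flip), "i", "n")
    out[deleted] <- "."
    out
  }

  assemble <- function(rows, len, role, seq_ids) {
    slot_w <- vapply(0:len, function(s) {
      max(vapply(rows, function(r) length(r$inserts[[s + 1L]]), integer(1)))
    }, integer(1))
    width <- len + sum(slot_w)
    is_match <- logical(width)
    col <- 0L
    match_cols <- integer(len)
    # column layout: slot 0 inserts, match 1, slot 1 inserts, match 2, ...
    layout <- list()
    for (s in 0:len) {
      if (slot_w[s + 1L] > 0) col <- col + slot_w[s + 1L]
      if (s < len) { match_cols[s + 1L] <- col + 1L; col <- col + 1L }
    }
    seq_mat <- matrix("-", length(rows), width)
    lab_mat <- matrix(".", length(rows), width)
    for (k in seq_along(rows)) {
      r <- rows[[k]]
      col <- 0L
      for (s in 0:len) {
        ins <- r$inserts[[s + 1L]]
        if (slot_w[s + 1L] > 0) {
          if (length(ins) > 0) seq_mat[k, col + seq_along(ins)] <- ins
          col <- col + slot_w[s + 1L]
        }
        if (s < len) {
          col <- col + 1L
          seq_mat[k, col] <- r$resid[s + 1L]
        }
      }
    }
    for (k in seq_along(rows)) {
      del <- rows[[k]]$resid == "-"
      tl <- truth_labels |>
        filter(.data$pair_id == pair_ids[k], .data$domain_role == role)
      lab_mat[k, match_cols] <- noisy(tl$interacting, del)
    }
    labeled_alignment(family_id, role, seq_ids,
                      apply(seq_mat, 1, paste, collapse = ""),
                      match_cols, lab_mat)
  }

  seq_a <- paste0(pair_ids, "_a")
  seq_b <- paste0(pair_ids, "_b")
  aln_a <- assemble(rows_a, spec$len_a, "A", seq_a)
  aln_b <- assemble(rows_b, spec$len_b, "B", seq_b)

  structure(
    list(family_id = family_id, spec = spec,
         aln_a = aln_a, aln_b = aln_b, contacts = contacts,
         pairs = tibble(pair_id = pair_ids, seq_a = seq_a, seq_b = seq_b),
         truth = list(iface_a = iface_a, iface_b = iface_b,
                      pattern = pattern,
                      emissions_a = em_a, emissions_b = em_b,
                      labels = truth_labels)),
    class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "<synthetic_family> %s: %d pairs, domains %d + %d match columns, %d topology contacts\n",
    x$family_id, nrow(x$pairs), x$spec$len_a, x$spec$len_b,
    sum(x$truth$pattern)))
  invisible(x)
}

#' Generate a benchmark suite of synthetic families
#'
#' Draws `n_families` families with parameters jittered around `base_spec`
#' (lengths, member counts, interface fraction, sharpness), on a fixed seed
#' stream, in the regime where the shared contact topology is informative.
#'
#' @param n_families Number of families (>= 2).
#' @param base_spec A [family_spec()] supplying the central parameter
#'   values.
#' @param seed Integer seed for the whole suite.
#' @return List of `synthetic_family` objects.
#' @export
benchmark_suite <- function(n_families = 10L, base_spec = family_spec(),
                            seed = 1L) {
  if (n_families < 2L) stop_param("n_families must be >= 2")
  specs <- withr::with_seed(as.integer(seed), {
    map(seq_len(n_families), function(f) {
      family_spec(
        n_pairs = sample(10:14, 1L),
        len_a = base_spec$len_a + sample(-2:3, 1L),
        len_b = base_spec$len_b + sample(-2:3, 1L),
        frac_interface = min(0.6, max(0.15,
          base_spec$frac_interface + runif(1, -0.05, 0.05))),
        emission_sharpness = base_spec$emission_sharpness * runif(1, 0.7, 1.3),
        contact_density = base_spec$contact_density,
        indel_rate = base_spec$indel_rate,
        label_noise = base_spec$label_noise,
        pair_dropout = base_spec$pair_dropout,
        seed = sample.int(.Machine$integer.max - 1L, 1L))
    })
  })
  map(seq_len(n_families),
      function(f) sample_family(specs[[f]], sprintf("fam%02d", f)))
}

#' Write a synthetic family's files
#'
#' Writes both labeled alignments (Stockholm dialect) and every pair's
#' ground-truth contact matrix into a directory, in the package's on-disk
#' formats.
#'
#' @param family A `synthetic_family`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "synthetic_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_alignment(family$aln_a,
                          file.path(dir, sprintf("%s_A.sto", family$family_id)))
  write_labeled_alignment(family$aln_b,
                          file.path(dir, sprintf("%s_B.sto", family$family_id)))
  for (pid in names(family$contacts)) {
    write_contact_matrix(family$contacts[[pid]],
                         file.path(dir, sprintf("%s_%s_contacts.tsv",
                                                family$family_id, pid)))
  }
  invisible(dir)
}
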