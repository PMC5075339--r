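# Independent likelihood oracle: exhaustive sum over every state path of the
# profile architecture, by depth-first enumeration. Kept deliberately free of
# any dynamic programming so it cross-checks forward_backward() from first
# principles. Only feasible for tiny models (L <= 4, |seq| <= 6).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

enumerate_likelihood <- function(model, seq) {
  x <- match(strsplit(seq, "")[[1]], AA20)
  n <- length(x)
  em <- model$emissions
  tr <- model$transitions
  total <- 0
  succ <- function(type, j) {
    row <- switch(type,
                  begin = tr$begin,
                  m_i = tr$match_i[j, ], m_ni = tr$match_ni[j, ],
                  ins = tr$insert[j + 1, ], del = tr$delete[j, ])
    out <- list()
    add <- function(t2, j2, p) {
      if (p > 0) out[[length(out) + 1]] <<- list(t = t2, j = j2, p = p)
    }
    add("m_ni", j + 1, row[["m_ni"]])
    add("m_i", j + 1, row[["m_i"]])
    add("ins", j, row[["ins"]])
    add("del", j + 1, row[["del"]])
    add("end", j, row[["end"]])
    out
  }
  rec <- function(type, j, i, prob) {
    if (type == "end") {
      if (i == n) total <<- total + prob
      return(invisible())
    }
    for (s in succ(type, j)) {
      if (s$t %in% c("m_i", "m_ni", "ins")) {
        if (i >= n) next
        e <- switch(s$t,
                    m_i = em$match_i[s$j, x[i + 1]],
                    m_ni = em$match_ni[s$j, x[i + 1]],
                    ins = em$insert[s$j + 1, x[i + 1]])
        rec(s$t, s$j, i + 1, prob * s$p * e)
      } else {
        rec(s$t, s$j, i, prob * s$p)
      }
    }
  }
  rec("begin", 0, 0, 1)
  unname(log(total))
}

# random small labeled alignment (valid by construction), for random models
random_small_alignment <- function(L = sample(1:4, 1), nseq = sample(2:4, 1),
                                   extra_cols = sample(0:1, 1)) {
  repeat {
    width <- L + extra_cols
    mc <- sort(sample(width, L))
    seqs <- vapply(seq_len(nseq), function(k) {
      paste(ifelse(runif(width) < 0.85, sample(AA20, width, TRUE), "-"),
            collapse = "")
    }, character(1))
    if (any(vapply(strsplit(seqs, ""), function(cc) all(cc == "-"),
                   logical(1)))) next
    lab <- matrix(".", nseq, width)
    for (k in seq_len(nseq)) {
      cc <- strsplit(seqs[k], "")[[1]]
      for (c0 in mc) if (cc[c0] != "-") lab[k, c0] <- sample(c("i", "n"), 1)
    }
    aln <- tryCatch(
      labeled_alignment("f", "A", paste0("s", seq_len(nseq)), seqs, mc, lab),
      error = function(e) NULL)
    if (!is.null(aln)) return(aln)
  }
}

random_small_model <- function(...) {
  build_iphmm(random_small_alignment(...), pseudocount = runif(1, 0.3, 2))
}

random_sequence <- function(n = sample(1:6, 1)) {
  paste(sample(AA20, n, TRUE), collapse = "")
}
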