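#' Per-residue site feature vectors from a contact matrix
#'
#' For each occupied match column of the chosen domain, concatenates the
#' residue's contact-matrix row (domain A) or column (domain B) with the
#' residue's ipHMM site score as the final component. The `cm_only` variant
#' omits the trailing ipHMM slot; the `ground_truth_cm` variant is built by
#' passing the ground-truth matrix as `cm`.
#'
#' @param cm A [contact_matrix()] (predicted or ground truth).
#' @param p_int Numeric vector of ipHMM site probabilities, one per match
#'   column of the chosen domain.
#' @param domain_role `"A"` (rows) or `"B"` (columns).
#' @param variant `"cm_iphmm"` (row/column + ipHMM score) or `"cm_only"`
#'   (row/column only).
#' @param occupied Logical vector over the domain's match columns; `FALSE`
#'   rows are skipped (deleted columns have no residue to classify).
#' @return Tibble with `match_index` and a list-column `features`; attribute
#'   `n_features` records the common vector length
#'   (partner match count + 1, or partner match count for `cm_only`).
#' @export
build_site_features <- function(cm, p_int, domain_role = c("A", "B"),
                                variant = c("cm_iphmm", "cm_only"),
                                occupied = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  domain_role <- match.arg(domain_role)
  variant <- match.arg(variant)
  own_n <- if (domain_role == "A") nrow(cm$cells) else ncol(cm$cells)
  partner_n <- if (domain_role == "A") ncol(cm$cells) else nrow(cm$cells)
  if (length(p_int) != own_n) {
    stop_validation("p_int has length %d but domain %s has %d match columns",
                    length(p_int), domain_role, own_n)
  }
  occupied <- occupied %||% rep(TRUE, own_n)
  if (length(occupied) != own_n) {
    stop_validation("occupied must have one entry per match column")
  }
  idx <- which(occupied)
  feats <- map(idx, function(j) {
    row <- if (domain_role == "A") as.numeric(cm$cells[j, ])
    else as.numeric(cm$cells[, j])
    if (variant == "cm_iphmm") c(row, p_int[j]) else row
  })
  out <- tibble(match_index = idx, features = feats)
  attr(out, "n_features") <- partner_n + as.integer(variant == "cm_iphmm")
  out
}

#' Balance classes by oversampling the positives
#'
#' Randomly resamples the positive (interacting) examples with replacement
#' until both classes have the same count, leaves the negatives untouched,
#' and shuffles the result. Deterministic given `seed`.
#'
#' @param data Tibble with at least a logical/0-1 `label` column.
#' @param seed Integer seed.
#' @return The balanced, shuffled tibble.
#' @export
oversample_positives <- function(data, seed = 1L) {
  lab <- as.integer(data$label)
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L) stop_param("no positive (interacting) examples")
  if (n_neg == 0L) stop_param("no negative (non-interacting) examples")
  out <- withr::with_seed(as.integer(seed), {
    pos_idx <- which(lab == 1L)
    extra <- if (n_neg > n_pos) sample(pos_idx, n_neg - n_pos, replace = TRUE)
    else integer(0)
    balanced <- data[c(seq_len(nrow(data)), extra), ]
    balanced[sample(nrow(balanced)), ]
  })
  out
}

#' Train the L2-penalised logistic site classifier
#'
#' Fits `Pr(Y = 1 | X) = 1 / (1 + exp(-(b0 + b' X)))` by ridge-penalised
#' maximum likelihood. The penalty follows the `C` convention of the usual
#' machine-learning libraries (total squared-coefficient penalty with weight
#' `1/C` against the summed log-loss), mapped onto glmnet's per-observation
#' scale as `lambda = 1 / (n C)`.
#'
#' @param data Tibble with list-column `features` and 0/1 `label` (already
#'   balanced via [oversample_positives()]).
#' @param domain_role `"A"` or `"B"`.
#' @param variant `"cm_iphmm"`, `"cm_only"` or `"ground_truth_cm"`.
#' @param C Inverse penalty strength (default 1).
#' @return A `logistic_site_model` with `intercept`, `coefficients`,
#'   `domain_role`, `variant`, `C`, `converged`.
#' @export
train_site_model <- function(data, domain_role = c("A", "B"),
                             variant = c("cm_iphmm", "cm_only",
                                         "ground_truth_cm"),
                             C = 1) {
  domain_role <- match.arg(domain_role)
  variant <- match.arg(variant)
  if (C <= 0) stop_param("C must be positive")
  x <- do.call(rbind, data$features)
  y <- as.integer(data$label)
  if (length(unique(y)) < 2L) stop_param("training set must contain both classes")
  k <- ncol(x)
  padded <- FALSE
  if (k == 1L) {                       # glmnet needs >= 2 columns
    x <- cbind(x, 0)
    padded <- TRUE
  }
  lambda <- 1 / (nrow(x) * C)
  if (all(apply(x, 2, function(v) diff(range(v))) == 0)) {
    # degenerate design (every feature constant): intercept-only fit
    beta <- numeric(k)
    return(structure(
      list(intercept = stats::qlogis(mean(y)), coefficients = beta,
           domain_role = domain_role, variant = variant, C = C,
           n_features = k, n_train = nrow(data), converged = TRUE),
      class = "logistic_site_model"))
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  conv <- fit$npasses < 1e6
  if (!conv) {
    warn("logistic site model did not converge; using best iterate")
  }
  beta <- as.numeric(fit$beta)
  if (padded) beta <- beta[1L]
  structure(
    list(intercept = as.numeric(fit$a0), coefficients = beta,
         domain_role = domain_role, variant = variant, C = C,
         n_features = k, n_train = nrow(data), converged = conv),
    class = "logistic_site_model")
}

#' @export
print.logistic_site_model <- function(x, ...) {
  cat(sprintf(
    "<logistic_site_model> domain %s, variant %s: %d features, C = %g%s\n",
    x$domain_role, x$variant, x$n_features, x$C,
    if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Predict interaction sites with a logistic site model
#'
#' Applies the fitted logistic model to per-residue feature vectors; a
#' residue is called interacting when its probability exceeds 0.5 (a tie
#' goes to the majority, non-interacting, class).
#'
#' @param model A [train_site_model()] fit.
#' @param features Tibble as from [build_site_features()] (list-column
#'   `features`).
#' @return Tibble with `match_index`, `probability`, `call`.
#' @export
predict_sites_integrated <- function(model, features) {
  stopifnot(inherits(model, "logistic_site_model"))
  x <- do.call(rbind, features$features)
  if (ncol(x) != model$n_features) {
    stop_validation("feature length %d does not match model (%d)",
                    ncol(x), model$n_features)
  }
  eta <- model$intercept + as.numeric(x %*% model$coefficients)
  p <- plogis(eta)
  tibble(match_index = features$match_index,
         probability = p,
         call = ifelse(p > 0.5, "interacting", "non_interacting"))
}

#' Tidy a logistic site model
#'
#' One row per model term. The final non-intercept term of a `cm_iphmm`
#' model is the ipHMM site-score slot, whose (typically large positive)
#' weight is the documented diagnostic of how much the integrated model
#' leans on the ipHMM call.
#'
#' @param x A `logistic_site_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @method tidy logistic_site_model
#' @export
tidy.logistic_site_model <- function(x, ...) {
  terms <- c("(Intercept)",
             if (x$variant == "cm_iphmm") {
               c(sprintf("partner_%02d", seq_len(x$n_features - 1L)),
                 "iphmm_score")
             } else {
               sprintf("partner_%02d", seq_len(x$n_features))
             })
  tibble(term = terms, estimate = c(x$intercept, x$coefficients))
}

#' Glance at a logistic site model
#'
#' @param x A `logistic_site_model`.
#' @param ... Unused.
#' @return One-row tibble with fit metadata.
#' @method glance logistic_site_model
#' @export
glance.logistic_site_model <- function(x, ...) {
  tibble(domain_role = x$domain_role, variant = x$variant,
         n_features = x$n_features, n_train = x$n_train, C = x$C,
         converged = x$converged)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
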