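# The quadratic similarity model and its Gaussian likelihood.
# Standardized similarity of an isoform pair with shared-term count tau
# is modelled as  S ~ N(beta2 tau^2 + beta1 tau + beta0, 1); the noise
# sd is fixed at 1, so maximizing the log-likelihood is the same as
# minimizing the sum of squared residuals, and the M-step is ordinary
# least squares on the design [1, tau, tau^2].

#' Construct a quadratic similarity model
#'
#' @param beta0,beta1,beta2 finite real coefficients.
#' @param noise_sd fixed residual standard deviation; always 1 in this
#'   model (the value is validated, not estimated).
#' @return object of class `quadratic_model`.
#' @export
quadratic_model <- function(beta0, beta1, beta2, noise_sd = 1) {
  beta <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2)
  if (!all(is.finite(beta))) {
    .stop_typed("isoformGO_model_error", "non-finite model coefficient")
  }
  if (!identical(noise_sd, 1) && noise_sd != 1) {
    .stop_typed("isoformGO_model_error", "noise_sd is fixed at 1")
  }
  structure(list(beta = beta, noise_sd = 1), class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("quadratic_model: mu(tau) = %.6g tau^2 + %.6g tau + %.6g  (sd = 1)\n",
              x$beta[["beta2"]], x$beta[["beta1"]], x$beta[["beta0"]]))
  invisible(x)
}

#' Predicted similarity for a shared-term count
#'
#' @param tau non-negative integer vector of shared-term counts.
#' @param model a [quadratic_model()].
#' @return numeric vector `beta2 tau^2 + beta1 tau + beta0`.
#' @export
predict_similarity <- function(tau, model) {
  stopifnot(inherits(model, "quadratic_model"), all(tau >= 0))
  b <- model$beta
  b[["beta2"]] * tau^2 + b[["beta1"]] * tau + b[["beta0"]]
}

.std_scores <- function(pairs) {
  if (is.data.frame(pairs)) pairs$std else as.numeric(pairs)
}

#' Sum of squared residuals of the quadratic fit
#'
#' @param pairs a `pair_score_table` (its `std` column is used) or a
#'   numeric vector of standardized scores.
#' @param taus integer vector of shared-term counts, aligned 1:1 with
#'   the pairs.
#' @param model a [quadratic_model()].
#' @return non-negative scalar.
#' @export
ssr <- function(pairs, taus, model) {
  s <- .std_scores(pairs)
  stopifnot(length(s) == length(taus))
  sum((predict_similarity(taus, model) - s)^2)
}

#' Gaussian log-likelihood of a set of scored pairs
#'
#' With unit noise sd the total log-likelihood is
#' `-ssr/2 - n log(2 pi)/2`.
#'
#' @inheritParams ssr
#' @return list with `total` (the log-likelihood) and `n_terms` (the
#'   pair count entering the sum).
#' @export
log_likelihood <- function(pairs, taus, model) {
  s <- .std_scores(pairs)
  n <- length(s)
  if (n == 0L) return(list(total = 0, n_terms = 0L))
  list(total = -ssr(pairs, taus, model) / 2 - n * log(2 * pi) / 2,
       n_terms = n)
}

#' Fit the quadratic coefficients by ordinary least squares (M-step)
#'
#' Solves `min_beta sum (beta2 tau^2 + beta1 tau + beta0 - S)^2` on the
#' design `[1, tau, tau^2]`. Requires at least three pairs with three
#' distinct tau values; a rank-deficient design raises a typed error
#' (callers should keep the previous coefficients in that case).
#'
#' @inheritParams ssr
#' @return a [quadratic_model()].
#' @export
fit_quadratic <- function(pairs, taus) {
  s <- .std_scores(pairs)
  stopifnot(length(s) == length(taus))
  if (length(s) < 3L || length(unique(taus)) < 3L) {
    .stop_typed("isoformGO_rank_deficient",
                "quadratic fit needs >= 3 pairs with >= 3 distinct shared-term counts (got %d pairs, %d distinct); keep the previous coefficients instead",
                length(s), length(unique(taus)))
  }
  X <- cbind(1, taus, taus^2)
  fit <- stats::lm.fit(X, s)
  if (fit$rank < 3L) {
    .stop_typed("isoformGO_rank_deficient",
                "rank-deficient quadratic design; keep the previous coefficients instead")
  }
  b <- unname(fit$coefficients)
  quadratic_model(b[[1L]], b[[2L]], b[[3L]])
}

#' Initial coefficients from a random isoform subset (EM initialization)
#'
#' Samples a random subset of isoforms, scores its eligible pairs, and
#' fits the quadratic model to the shared-term counts of the seed
#' assignment. A rank-deficient subset (fewer than three distinct
#' counts) is resampled with the next seed, up to `max_tries` times;
#' each resample is reported via `message()`.
#'
#' @param assignment an [assignment_matrix()] holding the seed bits.
#' @param scorer a score provider (see [make_table_scorer()] /
#'   [make_sequence_scorer()]).
#' @param tg [gene_annotation_map()] used for pair eligibility.
#' @param subset_size number of isoforms to sample; default
#'   `min(p, max(30, ceiling(p / 200)))`, i.e. one mini-batch-sized
#'   subset with a floor that keeps small corpora identifiable.
#' @param seed integer seed for the subset draw.
#' @param max_tries resampling budget for degenerate subsets.
#' @details When every resampled subset is rank-deficient — typical of
#'   very sparse seed assignments, whose shared-term counts may take
#'   fewer than three distinct values anywhere — the initializer falls
#'   back to a linear fit on the last subset (quadratic coefficient 0)
#'   when two counts are distinguishable, and otherwise to
#'   `beta0 = mean(S)`, `beta1 = sd(S)`, `beta2 = 0`: a positive slope
#'   of one score standard deviation per shared term, encoding the
#'   model's monotonicity assumption so the first E-step has a
#'   gradient to follow. Later M-steps refit the full quadratic once
#'   the search has diversified the counts.
#' @return a [quadratic_model()].
#' @export
initialize_beta <- function(assignment, scorer, tg, subset_size = NULL,
                            seed = 1L, max_tries = 25L) {
  p <- length(assignment$isoforms)
  subset_size <- subset_size %||% min(p, max(30L, ceiling(p / 200)))
  subset_size <- min(p, subset_size)
  last <- NULL
  for (try in seq_len(max_tries)) {
    s <- seed + try - 1L
    set.seed(s)
    subset <- sample(assignment$isoforms, subset_size)
    pairs <- eligible_pairs(subset, assignment$gene_of, tg)
    tab <- tryCatch(scorer(subset, pairs), isoformGO_alignment_error = function(e) NULL)
    if (is.null(tab) || nrow(tab) < 3L) {
      message(sprintf("initialize_beta: subset for seed %d too sparse; resampling", s))
      next
    }
    taus <- pair_taus(assignment, tab)
    last <- list(tab = tab, taus = taus)
    mod <- tryCatch(fit_quadratic(tab, taus),
                    isoformGO_rank_deficient = function(e) NULL)
    if (!is.null(mod)) return(mod)
    message(sprintf("initialize_beta: rank-deficient subset for seed %d; resampling", s))
  }
  if (is.null(last)) {
    .stop_typed("isoformGO_rank_deficient",
                "initialize_beta found no scorable subset in %d attempts",
                max_tries)
  }
  message("initialize_beta: falling back to a reduced-degree initial fit")
  s <- .std_scores(last$tab)
  taus <- last$taus
  if (length(unique(taus)) >= 2L) {
    co <- unname(stats::lm.fit(cbind(1, taus), s)$coefficients)
    if (abs(co[[2L]]) > .Machine$double.eps) {
      return(quadratic_model(co[[1L]], co[[2L]], 0))
    }
  }
  quadratic_model(mean(s), stats::sd(s), 0)
}

#' Shared-term counts for a list of scored pairs
#'
#' @param assignment an [assignment_matrix()].
#' @param pairs data.frame with columns `a`, `b`.
#' @return integer vector of tau values aligned with the rows of
#'   `pairs`.
#' @export
pair_taus <- function(assignment, pairs) {
  if (!nrow(pairs)) return(integer())
  b <- assignment$bits
  storage.mode(b) <- "integer"
  i <- match(pairs$a, assignment$isoforms)
  j <- match(pairs$b, assignment$isoforms)
  unname(rowSums(b[i, , drop = FALSE] * b[j, , drop = FALSE]))
}

#' Kolmogorov-Smirnov diagnostic for the unit-variance residual model
#'
#' One-sample KS test of the fitted residuals against N(0, 1). Reported
#' as a diagnostic only; it never gates the EM run.
#'
#' @inheritParams ssr
#' @param alpha significance level used for the returned verdict.
#' @return list with `statistic`, `p_value` and logical `consistent`
#'   (`p_value > alpha`).
#' @export
residual_normality_check <- function(pairs, taus, model, alpha = 0.01) {
  res <- .std_scores(pairs) - predict_similarity(taus, model)
  kt <- suppressWarnings(stats::ks.test(res, "pnorm", 0, 1))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       consistent = kt$p.value > alpha)
}
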