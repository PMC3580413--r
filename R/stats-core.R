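# Core likelihood machinery: logistic maximum likelihood with an optional
# offset, likelihood-ratio tests, Wald intervals, the two-component chi-square
# combination rule, and multiplicity adjustment over a restricted family.

#' Bernoulli log-likelihood at a linear predictor
#'
#' Numerically stable via `plogis(log.p = TRUE)`.
#' @noRd
bernoulli_loglik <- function(y, eta) {
  sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Newton-Raphson (iteratively reweighted least squares) with step-halving.
#' Supports a fixed offset on the log-odds scale, which is how the case-only
#' interaction model anchors its intercept at the design randomization
#' fraction: `logit P(Z = 1 | G) = log(q / (1 - q)) + b0 + b2 G`.
#'
#' Convergence is declared when the maximum absolute score falls below
#' `score_tol` or the relative log-likelihood change falls below `ll_tol`;
#' fits reaching `max_iter` or with any coefficient beyond `coef_cap` in
#' absolute value (a separation signature) are returned with
#' `converged = FALSE` rather than silently trusted — downstream consumers
#' report `NA` for such fits.
#'
#' @param x Numeric design matrix including an explicit intercept column.
#'   Must be full column rank and free of missing values.
#' @param y Binary response vector (0/1) with both classes present.
#' @param offset Optional numeric vector of fixed log-odds offsets, one per
#'   observation.
#' @param max_iter,score_tol,ll_tol,coef_cap Optimizer controls.
#' @return An object of class `logistic_fit`: list with `coefficients`
#'   (named), `covariance` (inverse observed information), `log_likelihood`,
#'   `converged`, `n_iter`, and `n`.
#' @examples
#' x <- cbind(intercept = 1, g = c(1, 1, 1, 1, 0, 0, 0, 0))
#' y <- c(1, 1, 0, 1, 0, 0, 1, 0)
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(x, y, offset = NULL, max_iter = 100L,
                         score_tol = 1e-8, ll_tol = 1e-10, coef_cap = 15) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("missing values in design or response")
  if (nrow(x) != length(y)) stop("row count of x must equal length of y")
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  if (all(y == y[1])) stop("degenerate response")
  if (qr(x)$rank < ncol(x)) stop("collinear design")
  if (is.null(offset)) offset <- numeric(length(y))
  offset <- as.numeric(offset)
  if (length(offset) != length(y) || any(!is.finite(offset)))
    stop("offset must be finite and match the response length")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  beta <- numeric(ncol(x))
  eta <- offset + drop(x %*% beta)
  ll <- bernoulli_loglik(y, eta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(x, y - mu))
    info <- crossprod(x, x * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break  # information singular: separation territory
    # step-halving keeps the likelihood monotone
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      eta_new <- offset + drop(x %*% beta_new)
      ll_new <- bernoulli_loglik(y, eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { ll_new <- ll; beta_new <- beta; eta_new <- eta; break }
    }
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    mu <- stats::plogis(eta)
    score <- drop(crossprod(x, y - mu))
    if (max(abs(score)) < score_tol || rel_change < ll_tol) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > coef_cap)) converged <- FALSE
  info <- crossprod(x, x * (stats::plogis(eta) * (1 - stats::plogis(eta))))
  covariance <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x))
  })
  names(beta) <- colnames(x)
  dimnames(covariance) <- list(colnames(x), colnames(x))
  structure(list(coefficients = beta, covariance = covariance,
                 log_likelihood = ll, converged = converged,
                 n_iter = iter, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", x$n, "observations,",
      length(x$coefficients), "coefficients\n")
  se <- sqrt(diag(x$covariance))
  print(cbind(estimate = x$coefficients, se = se))
  cat("log-likelihood:", format(x$log_likelihood),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced `logistic_fit` objects, `reduced` nested in `full`.
#' @param df Degrees of freedom (number of constrained parameters).
#' @return Object of class `lrt_result`: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, df) {
  stopifnot(inherits(full, "logistic_fit"), inherits(reduced, "logistic_fit"),
            df >= 1)
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (stat < -1e-6) stop("non-nested fits")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Wald confidence interval
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(lower, upper)`. Callers working on the odds-ratio
#'   scale exponentiate.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  if (!is.numeric(se) || any(se <= 0)) stop("se must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = estimate - z * se, upper = estimate + z * se)
}

#' Combine two independent 1-df p-values into a 2-df chi-square p-value
#'
#' Each p-value is converted back to its chi-square(1) statistic, the two
#' statistics are summed (legitimate because the two trial components enrol
#' non-overlapping women), and the sum is referred to a chi-square(2)
#' distribution. When the raw statistics are available callers may sum those
#' directly; the two routes agree by construction.
#'
#' @param p_e_alone,p_eplusp Component p-values in (0, 1].
#' @return Combined p-value (vectorized over inputs).
#' @examples
#' combine_component_pvalues(0.10080, 0.00020)  # 0.00026
#' @export
combine_component_pvalues <- function(p_e_alone, p_eplusp) {
  p <- cbind(p_e_alone, p_eplusp)
  if (any(!is.finite(p)) || any(p > 1)) stop("p-values must lie in (0, 1]")
  if (any(p <= 0)) stop("degenerate p-value")
  q1 <- stats::qchisq(p[, 1], df = 1, lower.tail = FALSE)
  q2 <- stats::qchisq(p[, 2], df = 1, lower.tail = FALSE)
  unname(stats::pchisq(q1 + q2, df = 2, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment over a possibly larger family
#'
#' Computes the step-up adjusted value at rank i as
#' `min over j >= i of p(j) * m / j` in sorted order, capped at 1. The family
#' size `m` may exceed the number of supplied p-values: the use case is a
#' restricted multiple-testing family of which only the smallest members are
#' in hand (the remaining members are known to be no smaller than the largest
#' supplied p-value). In that case the minimum runs over supplied ranks only,
#' so adjusted values whose running minimum is realized at a supplied rank
#' are exact, while values at the largest supplied ranks are upper bounds;
#' the returned object carries a `note` saying so.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @param m Family size, at least `length(pvalues)`.
#' @return Object of class `adjusted_pvalues`: `raw`, `adjusted` (in input
#'   order), `m`, `method`, and `note` when `m > length(pvalues)`.
#' @export
bh_adjust <- function(pvalues, m = length(pvalues)) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (m < n) stop("family size m must be at least length(pvalues)")
  o <- order(p)                       # stable: ties keep input order
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(n)))))
  adjusted <- numeric(n)
  adjusted[o] <- adj_sorted
  note <- if (m > n) {
    paste0(m - n, " unsupplied family members assumed >= max supplied p; ",
           "adjusted values at the largest supplied ranks are upper bounds")
  } else NULL
  structure(list(raw = p, adjusted = adjusted, m = as.integer(m),
                 method = "BH", note = note),
            class = "adjusted_pvalues")
}

#' Bonferroni adjustment
#'
#' @inheritParams bh_adjust
#' @return Object of class `adjusted_pvalues` with `adjusted = pmin(p * m, 1)`.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < 1) stop("family size m must be >= 1")
  structure(list(raw = p, adjusted = pmin(p * m, 1), m = as.integer(m),
                 method = "Bonferroni", note = NULL),
            class = "adjusted_pvalues")
}

#' @export
print.adjusted_pvalues <- function(x, ...) {
  cat(x$method, "adjustment, family size m =", x$m, "\n")
  print(data.frame(raw = x$raw, adjusted = x$adjusted))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# drop columns that are linearly dependent (QR with pivoting); returns the
# reduced matrix with an attribute naming what was dropped
drop_aliased <- function(x) {
  qx <- qr(x)
  if (qx$rank == ncol(x)) return(x)
  keep <- qx$pivot[seq_len(qx$rank)]
  dropped <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
  out <- x[, sort(keep), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
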