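# Incremental discrimination: AUC of logistic risk scores, with pair-level
# bootstrap confidence intervals and a bootstrap test for an AUC increase
# between nested risk models.

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Probability that a random case outscores a random control; ties count
#' one half. Computed from midranks, which is exactly the all-pairs
#' concordance count.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 case indicators.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                     # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Specify a case-control risk model
#'
#' @param covariates Covariate column names (factors expanded to dummies).
#' @param snps rsids whose genotype columns enter the model.
#' @param snp_coding `"indicator"` (separate terms for one and two minor
#'   alleles, the convention for descriptive risk models) or `"additive"`.
#' @param interactions If `TRUE`, each SNP term is also crossed with the
#'   hormone-trial assignment indicator (`z_ht0`).
#' @return A `risk_model_spec` list.
#' @export
risk_model_spec <- function(covariates, snps = character(),
                            snp_coding = c("indicator", "additive"),
                            interactions = FALSE) {
  snp_coding <- match.arg(snp_coding)
  if (interactions && !length(snps))
    stop("interactions require SNP main effects")
  structure(list(covariates = covariates, snps = snps,
                 snp_coding = snp_coding, interactions = interactions),
            class = "risk_model_spec")
}

# design matrix for a risk model on a case-control table
risk_design <- function(cc, spec) {
  x <- covariate_design(cc, spec$covariates)
  for (rs in spec$snps) {
    if (!rs %in% names(cc)) stop("genotype column not found: ", rs)
    g <- as.numeric(cc[[rs]])
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (spec$snp_coding == "additive") {
      m <- cbind(g); colnames(m) <- rs
    } else {
      m <- cbind(as.numeric(g == 1), as.numeric(g == 2))
      colnames(m) <- paste0(rs, c("_1", "_2"))
    }
    x <- cbind(x, m)
    if (spec$interactions) {
      zint <- m * cc$z_ht0
      colnames(zint) <- paste0(colnames(m), ":z_ht")
      x <- cbind(x, zint)
    }
  }
  xr <- drop_aliased(x)
  if (!is.null(attr(xr, "dropped")))
    message("dropping aliased risk-model column(s): ",
            paste(attr(xr, "dropped"), collapse = ", "))
  xr
}

#' Fit a risk model and estimate its apparent AUC
#'
#' Fits the logistic risk model, scores every subject with its fitted
#' probability, and reports the in-sample (apparent) AUC with a percentile
#' bootstrap interval resampling matched pairs as the unit.
#'
#' @param cc Case-control table from [build_cc_data()] (needs `case`,
#'   `pair_id` and the model columns).
#' @param spec A `risk_model_spec`.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Object of class `auc_result`: `auc`, `ci`, `n_boot`, `seed`,
#'   `scores`, `fit`.
#' @export
fit_and_score <- function(cc, spec, n_boot = 1000, seed = 1L) {
  x <- risk_design(cc, spec)
  y <- as.numeric(cc$case)
  fit <- fit_logistic(x, y)
  if (!fit$converged)
    stop("risk-model fit did not converge (separation?); columns: ",
         paste(colnames(x), collapse = ", "))
  scores <- stats::plogis(drop(x %*% fit$coefficients))
  est <- auc(scores, y)
  set.seed(as.integer(seed))
  pair_rows <- split(seq_len(nrow(cc)), cc$pair_id)
  boots <- vapply(seq_len(n_boot), function(b) {
    take <- sample(length(pair_rows), replace = TRUE)
    idx <- unlist(pair_rows[take], use.names = FALSE)
    bx <- x[idx, , drop = FALSE]; by <- y[idx]
    bfit <- tryCatch(fit_logistic(drop_aliased(bx), by),
                     error = function(e) NULL)
    if (is.null(bfit) || !bfit$converged) return(NA_real_)
    bxr <- bx[, names(bfit$coefficients), drop = FALSE]
    auc(stats::plogis(drop(bxr %*% bfit$coefficients)), by)
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  ci <- c(min(ci[1], est), max(ci[2], est))   # CI always contains the estimate
  structure(list(auc = est, ci = ci, n_boot = n_boot,
                 n_dropped = sum(is.na(boots)), seed = as.integer(seed),
                 scores = scores, fit = fit),
            class = "auc_result")
}

#' Bootstrap comparison of two nested risk models' AUCs
#'
#' Resamples matched pairs with replacement, refits both models per
#' replicate and records the AUC difference. The confidence interval is
#' percentile; the two-sided p-value refers the observed difference to a
#' normal approximation with the bootstrap standard deviation.
#'
#' @param cc Case-control table.
#' @param spec_base,spec_extended Nested `risk_model_spec`s (base columns a
#'   subset of the extended design's).
#' @param n_boot Bootstrap replicates (a warning is logged below 100).
#' @param seed Integer seed.
#' @return Object of class `auc_comparison`: `delta`, `ci`, `p_value`,
#'   `auc_base`, `auc_extended`, `n_boot`, `n_dropped`, `seed`.
#' @export
bootstrap_auc_comparison <- function(cc, spec_base, spec_extended,
                                     n_boot = 1000, seed = 1L) {
  if (n_boot < 100) warning("n_boot < 100: bootstrap p-value is unstable")
  xb <- risk_design(cc, spec_base)
  xe <- risk_design(cc, spec_extended)
  if (!all(colnames(xb) %in% colnames(xe)))
    stop("spec_base must be nested in spec_extended")
  y <- as.numeric(cc$case)
  score_auc <- function(x, yy) {
    fit <- fit_logistic(drop_aliased(x), yy)
    if (!fit$converged) return(NA_real_)
    xr <- x[, names(fit$coefficients), drop = FALSE]
    auc(stats::plogis(drop(xr %*% fit$coefficients)), yy)
  }
  auc_b <- score_auc(xb, y); auc_e <- score_auc(xe, y)
  if (is.na(auc_b) || is.na(auc_e)) stop("full-data risk fit did not converge")
  delta <- auc_e - auc_b
  set.seed(as.integer(seed))
  pair_rows <- split(seq_len(nrow(cc)), cc$pair_id)
  deltas <- vapply(seq_len(n_boot), function(b) {
    take <- sample(length(pair_rows), replace = TRUE)
    idx <- unlist(pair_rows[take], use.names = FALSE)
    db <- tryCatch(score_auc(xb[idx, , drop = FALSE], y[idx]),
                   error = function(e) NA_real_)
    de <- tryCatch(score_auc(xe[idx, , drop = FALSE], y[idx]),
                   error = function(e) NA_real_)
    de - db
  }, numeric(1))
  n_dropped <- sum(is.na(deltas))
  deltas_ok <- deltas[!is.na(deltas)]
  ci <- stats::quantile(deltas_ok, c(0.025, 0.975), names = FALSE)
  sdd <- stats::sd(deltas_ok)
  p <- if (!is.finite(sdd) || sdd == 0) 1
       else 2 * stats::pnorm(-abs(delta) / sdd)
  structure(list(delta = delta, ci = ci, p_value = min(p, 1),
                 auc_base = auc_b, auc_extended = auc_e,
                 n_boot = n_boot, n_dropped = n_dropped,
                 seed = as.integer(seed)),
            class = "auc_comparison")
}
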