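# Follow-up analyses for flagged SNPs: genotype-stratified intervention odds
# ratios with the NA convention for empty cells, 1-df/2-df interaction
# likelihood-ratio tests, stroke-subtype subsetting, and joint two-SNP
# case-only models.

#' Intervention odds ratios stratified by minor-allele count
#'
#' At each genotype level g in 0/1/2, with `a` treated and `b` placebo cases
#' carrying g minor alleles, the intervention odds ratio is
#' `(a/b) / (q/(1-q))` — the case-only estimator of the treatment-versus-
#' placebo stroke odds ratio within that genotype stratum. The Wald interval
#' uses `SE = sqrt(1/a + 1/b)` on the log scale. Cells with `a = 0` or
#' `b = 0` report `NA` for the OR and CI (no continuity correction).
#'
#' @param z 0/1 randomization assignment of cases in one trial.
#' @param g Minor-allele counts aligned to `z` (NAs dropped).
#' @param q Active-arm randomization fraction.
#' @param level Confidence level.
#' @return data.frame with one row per genotype level: `genotype_level`,
#'   `n_treated`, `n_placebo`, `or_`, `ci_lower`, `ci_upper`.
#' @export
genotype_stratified_or <- function(z, g, q, level = 0.95) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ok <- !is.na(g) & !is.na(z)
  z <- z[ok]; g <- g[ok]
  rows <- lapply(0:2, function(lev) {
    a <- sum(z == 1 & g == lev)
    b <- sum(z == 0 & g == lev)
    if (a == 0 || b == 0) {
      return(data.frame(genotype_level = lev, n_treated = a, n_placebo = b,
                        or_ = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_))
    }
    or_ <- (a / b) / (q / (1 - q))
    se <- sqrt(1 / a + 1 / b)
    ci <- exp(wald_ci(log(or_), se, level))
    data.frame(genotype_level = lev, n_treated = a, n_placebo = b,
               or_ = or_, ci_lower = ci[[1]], ci_upper = ci[[2]])
  })
  do.call(rbind, rows)
}

#' 1-df and 2-df case-only interaction tests
#'
#' The 1-df test models genotype as a linear minor-allele-count term
#' ("monotone" interaction); the 2-df test uses separate indicators for one
#' and for two minor alleles. When a genotype level is absent among the
#' analyzed cases its indicator is dropped and the nominal 2-df test
#' collapses to the available degrees of freedom — with no G=2 cases the two
#' p-values coincide by construction.
#'
#' @param z,g,q As in [genotype_stratified_or()].
#' @return list: `p_1df`, `p_2df`, `df_2df`, `beta2_hat`.
#' @export
interaction_trend_tests <- function(z, g, q) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ok <- !is.na(g) & !is.na(z)
  z <- as.numeric(z[ok]); g <- as.numeric(g[ok])
  out <- list(p_1df = NA_real_, p_2df = NA_real_, df_2df = NA_integer_,
              beta2_hat = NA_real_)
  if (length(g) == 0 || stats::var(g) == 0 || all(z == z[1])) return(out)
  offset <- rep(log(q / (1 - q)), length(z))
  red <- fit_logistic(cbind("(Intercept)" = rep(1, length(z))), z,
                      offset = offset)
  add <- tryCatch(fit_logistic(cbind("(Intercept)" = 1, G = g), z,
                               offset = offset), error = function(e) NULL)
  if (!is.null(add) && add$converged) {
    out$p_1df <- likelihood_ratio_test(add, red, 1)$p_value
    out$beta2_hat <- add$coefficients[["G"]]
  }
  # indicator model: a non-reference level whose cases sit on a single arm
  # has no finite cell odds ratio (the analogue of an empty cell), so its
  # cases are excluded and the nominal 2-df test collapses to the
  # remaining degrees of freedom
  usable <- vapply(1:2, function(lev) {
    any(g == lev & z == 1) && any(g == lev & z == 0)
  }, logical(1))
  keep <- g == 0 | (g == 1 & usable[1]) | (g == 2 & usable[2])
  zs <- z[keep]; gs <- g[keep]
  labs <- paste0("G", (1:2)[usable & c(any(g == 1), any(g == 2))])
  if (length(labs) > 0 && length(unique(zs)) == 2) {
    ind <- cbind("(Intercept)" = rep(1, length(zs)))
    for (lev in (1:2)[usable & c(any(g == 1), any(g == 2))])
      ind <- cbind(ind, as.numeric(gs == lev))
    colnames(ind) <- c("(Intercept)", labs)
    ind <- drop_aliased(ind)            # e.g. only levels 1 and 2 observed
    df2 <- ncol(ind) - 1L
    offs <- rep(log(q / (1 - q)), length(zs))
    red_s <- fit_logistic(ind[, 1, drop = FALSE], zs, offset = offs)
    full <- tryCatch(fit_logistic(ind, zs, offset = offs),
                     error = function(e) NULL)
    if (df2 > 0 && !is.null(full) && full$converged) {
      out$p_2df <- likelihood_ratio_test(full, red_s, df2)$p_value
      out$df_2df <- as.integer(df2)
    }
  }
  out
}

#' Restrict a case table to a stroke subtype
#'
#' `"all"` keeps every case (including the "other" subcategory); a named
#' subtype filters exactly.
#'
#' @param cases data.frame with a `subtype` column.
#' @param subtype `"all"`, `"ischemic"` or `"hemorrhagic"`.
#' @return The filtered data.frame.
#' @export
subtype_subset <- function(cases, subtype = c("all", "ischemic",
                                              "hemorrhagic")) {
  subtype <- match.arg(subtype)
  if (subtype == "all") cases
  else cases[cases$subtype == subtype, , drop = FALSE]
}

#' Joint case-only model for two SNPs in one trial
#'
#' A single offset-logistic regression of treatment assignment on both SNPs'
#' genotype terms (one linear term each under additive coding; indicators
#' for one and two minor alleles each under indicator coding). Each SNP's
#' likelihood-ratio test drops only that SNP's term(s), so it measures the
#' SNP's interaction adjusted for its partner.
#'
#' @param z 0/1 assignment of the cases.
#' @param g1,g2 Aligned minor-allele-count vectors.
#' @param q Randomization fraction.
#' @param coding `"additive"` (1 df per SNP) or `"indicator"` (up to 2 df).
#' @return list with per-SNP `lrt_result`s (`snp1`, `snp2`) and the joint
#'   fit's coefficients.
#' @export
joint_two_snp_test <- function(z, g1, g2, q, coding = c("additive",
                                                        "indicator")) {
  coding <- match.arg(coding)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ok <- !is.na(g1) & !is.na(g2) & !is.na(z)
  z <- as.numeric(z[ok]); g1 <- as.numeric(g1[ok]); g2 <- as.numeric(g2[ok])
  if (stats::var(g1) == 0 || stats::var(g2) == 0) stop("monomorphic")
  if (abs(stats::cor(g1, g2)) > 1 - 1e-12) stop("collinear SNPs")
  offset <- rep(log(q / (1 - q)), length(z))
  terms_for <- function(g, tag) {
    if (coding == "additive") {
      m <- cbind(g); colnames(m) <- tag
    } else {
      m <- NULL; labs <- character(0)
      for (lev in 1:2) if (any(g == lev) && any(g != lev)) {
        m <- cbind(m, as.numeric(g == lev))
        labs <- c(labs, paste0(tag, "_", lev))
      }
      colnames(m) <- labs
    }
    m
  }
  t1 <- terms_for(g1, "snp1"); t2 <- terms_for(g2, "snp2")
  x_full <- cbind("(Intercept)" = 1, t1, t2)
  if (qr(x_full)$rank < ncol(x_full)) stop("collinear SNPs")
  full <- fit_logistic(x_full, z, offset = offset)
  drop_fit <- function(drop_cols) {
    keep <- setdiff(colnames(x_full), drop_cols)
    fit_logistic(x_full[, keep, drop = FALSE], z, offset = offset)
  }
  r1 <- drop_fit(colnames(t1))
  r2 <- drop_fit(colnames(t2))
  list(snp1 = likelihood_ratio_test(full, r1, ncol(t1)),
       snp2 = likelihood_ratio_test(full, r2, ncol(t2)),
       coefficients = full$coefficients)
}

#' Full follow-up block for one SNP in one trial
#'
#' Mirrors the descriptive follow-up layout: for each requested subtype
#' scope, the case count, intervention OR and CI at 0/1/2 minor alleles,
#' and the 2-df and 1-df interaction p-values.
#'
#' @param cases data.frame of one trial's cases with `z` (assignment) and
#'   `subtype` columns.
#' @param g Minor-allele counts aligned to `cases`.
#' @param q Randomization fraction.
#' @param scopes Subtype scopes to report.
#' @param level CI level.
#' @return data.frame, one row per scope, wide OR/CI columns plus `p_2df`,
#'   `p_1df`.
#' @export
followup_block <- function(cases, g, q,
                           scopes = c("all", "ischemic", "hemorrhagic"),
                           level = 0.95) {
  rows <- lapply(scopes, function(sc) {
    keep <- if (sc == "all") rep(TRUE, nrow(cases))
            else cases$subtype == sc
    zz <- cases$z[keep]; gg <- g[keep]
    ors <- genotype_stratified_or(zz, gg, q, level)
    tt <- tryCatch(interaction_trend_tests(zz, gg, q),
                   error = function(e) list(p_1df = NA_real_,
                                            p_2df = NA_real_))
    data.frame(scope = sc, n_cases = sum(keep),
               or_0 = ors$or_[1], ci_0_lower = ors$ci_lower[1],
               ci_0_upper = ors$ci_upper[1],
               or_1 = ors$or_[2], ci_1_lower = ors$ci_lower[2],
               ci_1_upper = ors$ci_upper[2],
               or_2 = ors$or_[3], ci_2_lower = ors$ci_lower[3],
               ci_2_upper = ors$ci_upper[3],
               p_2df = tt$p_2df, p_1df = tt$p_1df,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
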