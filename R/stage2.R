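# Stage 2: case-only interaction testing among stage-1 survivors.
#
# Randomization makes treatment assignment independent of genotype in the
# source population, so among cases of one trial the dependence of the
# active/placebo split on minor-allele count measures SNP-by-treatment
# interaction. The working model is
#   logit P(Z = 1 | G) = log(q / (1 - q)) + b0 + b2 G,
# with q the design fraction randomized to active treatment; b2 is the
# interaction log-odds ratio per minor allele.

#' Case-only interaction test for one trial component
#'
#' Fits the offset-logistic case-only model by maximum likelihood and tests
#' `b2 = 0` with a 1-df likelihood-ratio test. Complete-case on genotype.
#' `q` is a design constant; it is never estimated from the cases (doing so
#' would bias `b0` and destroy the offset's anchoring).
#'
#' @param z 0/1 randomization assignment of the cases in one trial.
#' @param g Minor-allele counts aligned to `z` (NAs dropped).
#' @param q Active-arm randomization fraction, in (0, 1).
#' @param trial,rsid Labels carried through to the result.
#' @return Object of class `component_test`: `trial`, `rsid`, `beta2_hat`,
#'   `se`, `lrt_statistic`, `p_value`, `n_cases_used`, `converged`.
#' @export
case_only_component_test <- function(z, g, q, trial = NA_character_,
                                     rsid = NA_character_) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  ok <- !is.na(g) & !is.na(z)
  z <- as.numeric(z[ok]); g <- as.numeric(g[ok])
  if (length(g) == 0 || stats::var(g) == 0) stop("monomorphic")
  out <- list(trial = trial, rsid = rsid, beta2_hat = NA_real_,
              se = NA_real_, lrt_statistic = NA_real_, p_value = NA_real_,
              n_cases_used = length(z), converged = FALSE)
  class(out) <- "component_test"
  if (all(z == z[1])) return(out)       # all-treated/all-placebo: separation
  offset <- rep(log(q / (1 - q)), length(z))
  x_full <- cbind("(Intercept)" = 1, G = g)
  x_red <- x_full[, 1, drop = FALSE]
  full <- tryCatch(fit_logistic(x_full, z, offset = offset),
                   error = function(e) NULL)
  red <- tryCatch(fit_logistic(x_red, z, offset = offset),
                  error = function(e) NULL)
  if (is.null(full) || is.null(red) || !full$converged || !red$converged)
    return(out)
  lrt <- likelihood_ratio_test(full, red, 1)
  out$beta2_hat <- full$coefficients[["G"]]
  out$se <- sqrt(full$covariance["G", "G"])
  out$lrt_statistic <- lrt$statistic
  out$p_value <- lrt$p_value
  out$converged <- TRUE
  out
}

#' Combine the two trial-component interaction tests
#'
#' The two 1-df likelihood-ratio statistics are summed into a chi-square
#' statistic with two degrees of freedom; the two components are independent
#' because the trials enrol non-overlapping women. When one component is
#' unavailable (separation / monomorphic among those cases) the result
#' degrades to the surviving component's 1-df p-value and is flagged
#' `partial`.
#'
#' @param res_e,res_ep `component_test` results for the same SNP from the
#'   E-alone and E+P components.
#' @return Object of class `combined_test`: `rsid`, `chi2_2df`,
#'   `p_combined`, `df_used`, `partial`, plus the component results.
#' @export
combined_ht_test <- function(res_e, res_ep) {
  stopifnot(inherits(res_e, "component_test"),
            inherits(res_ep, "component_test"))
  if (!identical(res_e$rsid, res_ep$rsid)) stop("mismatched rsid")
  s <- c(res_e$lrt_statistic, res_ep$lrt_statistic)
  ok <- !is.na(s)
  out <- list(rsid = res_e$rsid, chi2_2df = NA_real_, p_combined = NA_real_,
              df_used = 0L, partial = FALSE,
              p_e_alone = res_e$p_value, p_eplusp = res_ep$p_value,
              component_e = res_e, component_ep = res_ep)
  if (all(ok)) {
    out$chi2_2df <- sum(s)
    out$p_combined <- stats::pchisq(sum(s), 2, lower.tail = FALSE)
    out$df_used <- 2L
  } else if (any(ok)) {
    out$chi2_2df <- s[ok]
    out$p_combined <- stats::pchisq(s[ok], 1, lower.tail = FALSE)
    out$df_used <- 1L
    out$partial <- TRUE
  }
  class(out) <- "combined_test"
  out
}

#' Run stage 2 over the stage-1 pass list
#'
#' For every SNP that passed the first-stage screen, runs both per-trial
#' case-only tests and the 2-df combination, then controls multiplicity over
#' the *restricted* family — `m` equals the stage-1 pass count, never the
#' full panel size (the screening and interaction statistics are
#' asymptotically independent, which is what licenses the restriction).
#'
#' @param stage1 `stage1_result` table (only rows with `passes = TRUE` are
#'   tested).
#' @param subjects,outcomes,genotypes Cohort tables; cases are taken from
#'   the two hormone-therapy trials.
#' @param q_by_trial Named list with `E-alone` and `E+P` randomization
#'   fractions.
#' @param fdr_threshold FDR flagging threshold.
#' @return data.frame of class `stage2_result`, ranked by combined p-value:
#'   rank, rsid, SNP metadata, marginal OR/p from stage 1, `chi2_2df`,
#'   `p_combined`, `fdr`, `bonferroni`, per-component p-values, `flagged`.
#' @export
run_stage2 <- function(stage1, subjects, outcomes, genotypes, q_by_trial,
                       fdr_threshold = 0.05) {
  pass <- stage1[stage1$passes %in% TRUE, , drop = FALSE]
  if (nrow(pass) == 0) {
    warning("empty stage-1 pass list; no interaction tests run")
    return(structure(data.frame(), class = c("stage2_result", "data.frame")))
  }
  stroke <- outcomes$stroke[match(subjects$subject_id, outcomes$subject_id)]
  res <- lapply(seq_len(nrow(pass)), function(i) {
    rs <- pass$rsid[i]
    comp <- lapply(c("E-alone", "E+P"), function(tr) {
      sel <- stroke & subjects$ht_trial == tr
      ids <- subjects$subject_id[sel]
      g <- genotypes$values[match(ids, genotypes$subject_ids), rs]
      if (isTRUE(pass$flipped[i])) g <- 2 - g
      z <- subjects$z_ht[sel]
      tryCatch(case_only_component_test(z, g, q_by_trial[[tr]],
                                        trial = tr, rsid = rs),
               error = function(e) {
                 structure(list(trial = tr, rsid = rs, beta2_hat = NA_real_,
                                se = NA_real_, lrt_statistic = NA_real_,
                                p_value = NA_real_, n_cases_used = sum(sel),
                                converged = FALSE),
                           class = "component_test")
               })
    })
    comb <- combined_ht_test(comp[[1]], comp[[2]])
    meta <- genotypes$snps[match(rs, genotypes$snps$rsid), , drop = FALSE]
    data.frame(rsid = rs,
               chromosome = if (nrow(meta)) meta$chromosome else NA,
               position = if (nrow(meta)) meta$position else NA,
               alleles = if (nrow(meta))
                 paste0(meta$ref_allele, "/", meta$alt_allele) else NA,
               maf = {
                 f <- mean(genotypes$values[, rs], na.rm = TRUE) / 2
                 min(f, 1 - f)
               },
               marginal_or = pass$or_[i], marginal_p = pass$p_value[i],
               chi2_2df = comb$chi2_2df, p_combined = comb$p_combined,
               df_used = comb$df_used, partial = comb$partial,
               p_e_alone = comb$p_e_alone, p_eplusp = comb$p_eplusp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  m <- nrow(pass)
  has_p <- !is.na(res$p_combined)
  res$fdr <- NA_real_
  res$bonferroni <- NA_real_
  if (any(has_p)) {
    res$fdr[has_p] <- bh_adjust(res$p_combined[has_p], m = m)$adjusted
    res$bonferroni[has_p] <-
      bonferroni_adjust(res$p_combined[has_p], m = m)$adjusted
  }
  res <- res[order(res$p_combined, method = "radix", na.last = TRUE), ]
  res$rank <- seq_len(nrow(res))
  res$flagged <- !is.na(res$fdr) & res$fdr < fdr_threshold
  res <- res[, c("rank", setdiff(names(res), "rank"))]
  rownames(res) <- NULL
  attr(res, "m") <- m
  attr(res, "fdr_threshold") <- fdr_threshold
  class(res) <- c("stage2_result", "data.frame")
  res
}
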