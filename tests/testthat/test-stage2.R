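# Case-only component tests, the 2-df combination, and the stage-2 scan
# with restricted-family FDR.

mk_component <- function(p, rsid = "rs1", trial = "E-alone") {
  structure(list(trial = trial, rsid = rsid,
                 beta2_hat = NA_real_, se = NA_real_,
                 lrt_statistic = qchisq(p, 1, lower.tail = FALSE),
                 p_value = p, n_cases_used = 100L, converged = TRUE),
            class = "component_test")
}

mk_na_component <- function(rsid = "rs1", trial = "E-alone") {
  structure(list(trial = trial, rsid = rsid, beta2_hat = NA_real_,
                 se = NA_real_, lrt_statistic = NA_real_,
                 p_value = NA_real_, n_cases_used = 0L, converged = FALSE),
            class = "component_test")
}

test_that("case_only_component_test matches closed forms and the grid oracle", {
  # balanced treated/placebo at every genotype: no dependence of Z on G
  z <- rep(c(1, 0), times = 30)
  g <- rep(c(0, 0, 1, 1, 2, 2), each = 10)
  res <- case_only_component_test(z, g, q = 0.5)
  expect_equal(res$lrt_statistic, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-8)

  # counts (treated, placebo): (30,10) at G=0, (10,30) at G=1
  z2 <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  g2 <- rep(c(0, 1), each = 40)
  res2 <- case_only_component_test(z2, g2, q = 0.5)
  x <- cbind(1, g2)
  off <- rep(log(0.5 / 0.5), 80)
  o_full <- oracle_logistic_grid(x, z2, offset = off)
  expect_equal(res2$beta2_hat, o_full$coefficients[2], tolerance = 1e-3)
  # the G=0 stratum is 3:1 treated so beta0 > 0, G=1 is 1:3 so beta2 < 0
  expect_lt(res2$beta2_hat, 0)
  # statistic equals twice the log-likelihood gap from the oracle
  ll0 <- function(b0) {
    eta <- off + b0
    sum(ifelse(z2 == 1, plogis(eta, log.p = TRUE),
               plogis(-eta, log.p = TRUE)))
  }
  o_red <- optimize(ll0, c(-5, 5), maximum = TRUE)$objective
  expect_equal(res2$lrt_statistic, 2 * (o_full$log_likelihood - o_red),
               tolerance = 1e-4)

  expect_error(case_only_component_test(z, rep(0, 60), q = 0.5),
               "monomorphic")
  expect_error(case_only_component_test(z, g, q = 0), "q must lie")
})

test_that("the case-only fit agrees with glm's offset logistic route", {
  set.seed(44)
  g <- rbinom(300, 2, 0.3)
  z <- rbinom(300, 1, plogis(log(0.4 / 0.6) + 0.5 * g))
  res <- case_only_component_test(z, g, q = 0.4)
  ref <- glm(z ~ g, family = binomial, offset = rep(log(0.4 / 0.6), 300))
  expect_equal(res$beta2_hat, unname(coef(ref)[2]), tolerance = 1e-6)
  ref0 <- glm(z ~ 1, family = binomial, offset = rep(log(0.4 / 0.6), 300))
  expect_equal(res$lrt_statistic,
               unname(ref0$deviance - ref$deviance), tolerance = 1e-6)
})

test_that("combined_ht_test reproduces printed two-component p-values", {
  # (E-alone p, E+P p) -> combined 2-df p
  cases <- list(c(0.01939, 0.00610, 0.00151),
                c(0.02295, 0.32839, 0.04671))
  for (cs in cases) {
    comb <- combined_ht_test(mk_component(cs[1], trial = "E-alone"),
                             mk_component(cs[2], trial = "E+P"))
    expect_equal(comb$p_combined, cs[3], tolerance = 0.01)
    expect_equal(comb$df_used, 2L)
    expect_false(comb$partial)
  }
  zero <- combined_ht_test(mk_component(1), mk_component(1, trial = "E+P"))
  expect_equal(zero$p_combined, 1)
  expect_error(combined_ht_test(mk_component(0.5, rsid = "a"),
                                mk_component(0.5, rsid = "b")),
               "mismatched rsid")
})

test_that("one unavailable component degrades to a flagged 1-df test", {
  comb <- combined_ht_test(mk_na_component(), mk_component(0.02,
                                                           trial = "E+P"))
  expect_true(comb$partial)
  expect_equal(comb$df_used, 1L)
  expect_equal(comb$p_combined, 0.02, tolerance = 1e-10)
  both_na <- combined_ht_test(mk_na_component(),
                              mk_na_component(trial = "E+P"))
  expect_true(is.na(both_na$p_combined))
})

test_that("run_stage2 ranks, restricts the family and flags by FDR", {
  fx <- make_fixture("f13a1_like", seed = 1, dir = tempfile())
  cc <- build_cc_data(fx$data$subjects, fx$data$outcomes, fx$data$matched,
                      fx$data$genotypes)
  s1 <- marginal_scan(cc, fx$data$genotypes, threshold = 1)
  s2 <- run_stage2(s1, fx$data$subjects, fx$data$outcomes,
                   fx$data$genotypes,
                   q_by_trial = list("E-alone" = 0.5, "E+P" = 0.5))
  expect_equal(attr(s2, "m"), sum(s1$passes))
  expect_equal(s2$rank, seq_len(nrow(s2)))
  expect_true(all(diff(s2$p_combined) >= 0, na.rm = TRUE))
  expect_true(all(s2$fdr >= s2$p_combined, na.rm = TRUE))
  # the planted interaction SNP pair leads the ranking at this seed
  expect_true(s2$rsid[1] %in% c("rs_f13_1", "rs_f13_2"))
  # MAF column reports minor-allele frequency
  expect_true(all(s2$maf > 0 & s2$maf <= 0.5))

  # single-SNP family: fdr equals the combined p
  one <- s1[s1$rsid == "rs_f13_1", ]
  one$passes <- TRUE
  s2_one <- run_stage2(one, fx$data$subjects, fx$data$outcomes,
                       fx$data$genotypes,
                       q_by_trial = list("E-alone" = 0.5, "E+P" = 0.5))
  expect_equal(s2_one$fdr, s2_one$p_combined)

  none <- s1; none$passes <- FALSE
  expect_warning(empty <- run_stage2(none, fx$data$subjects,
                                     fx$data$outcomes, fx$data$genotypes,
                                     q_by_trial = list("E-alone" = 0.5,
                                                       "E+P" = 0.5)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("combined p-values are uniform under the interaction null", {
  # treatment main effect and SNP main effect present, zero interaction;
  # 600 replicates (scaled from the stated 2000) of a single SNP
  set.seed(17)
  pvals <- replicate(600, {
    de <- sim_trial(2500, maf = 0.3, q = 0.5, baseline = qlogis(0.12),
                    b_trt = log(1.4), b_g = log(1.2), b_int = 0,
                    seed = sample.int(1e6, 1))
    dp <- sim_trial(3500, maf = 0.3, q = 0.5, baseline = qlogis(0.12),
                    b_trt = log(1.4), b_g = log(1.2), b_int = 0,
                    seed = sample.int(1e6, 1))
    re <- case_only_component_test(de$z[de$y], de$g[de$y], q = 0.5)
    rp <- case_only_component_test(dp$z[dp$y], dp$g[dp$y], q = 0.5)
    combined_ht_test(structure(re, rsid = NULL),
                     structure(rp, rsid = NULL))$p_combined
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
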