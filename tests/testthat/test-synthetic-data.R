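# Cohort generator: genotypes (HWE, drift, LD), trial assignment, outcomes,
# matched control selection and on-disk fixtures.

simple_panel <- function() {
  snp_panel(rsid = c("rsA", "rsB", "rsC"),
            chromosome = c("1", "1", "2"),
            position = c(100L, 200L, 300L),
            ref_allele = c("G", "G", "C"), alt_allele = c("A", "A", "T"),
            base_maf = c(0.09, 0.09, 0.3),
            ld_partner = c(NA, "rsA", NA),
            target_r2 = c(NA, 1, NA))
}

test_that("generate_genotypes matches the target allele frequency without drift", {
  panel <- snp_panel("rs1", "1", 100L, "G", "A", base_maf = 0.09)
  gm <- generate_genotypes(20000, panel, rep(1L, 20000), seed = 5)
  expect_true(all(gm$values %in% 0:2))
  expect_lt(abs(mean(gm$values[, "rs1"]) / 2 - 0.09), 0.005)
})

test_that("LD partners realize their target correlation", {
  gm <- generate_genotypes(5000, simple_panel(), rep(1L, 5000), seed = 9)
  # target_r2 = 1: the partner is a deterministic copy
  expect_equal(abs(cor(gm$values[, "rsA"], gm$values[, "rsB"])), 1)
  panel98 <- snp_panel(rsid = c("rsA", "rsB"), chromosome = "1",
                       position = c(100L, 200L), ref_allele = "G",
                       alt_allele = "A", base_maf = 0.2,
                       ld_partner = c(NA, "rsA"), target_r2 = c(NA, 0.98))
  gm98 <- generate_genotypes(20000, panel98, rep(1L, 20000), seed = 3)
  r2 <- cor(gm98$values[, "rsA"], gm98$values[, "rsB"])^2
  expect_gt(r2, 0.95)
})

test_that("genotype generation is deterministic and validates its panel", {
  panel <- simple_panel()
  g1 <- generate_genotypes(500, panel, rep(1:2, 250), seed = 77)
  g2 <- generate_genotypes(500, panel, rep(1:2, 250), seed = 77)
  expect_identical(g1$values, g2$values)
  bad <- panel; bad$rsid <- c("x", "x", "y")
  expect_error(generate_genotypes(10, bad, rep(1L, 10), seed = 1),
               "duplicate rsid")
})

test_that("allele-frequency drift separates subpopulations", {
  panel <- snp_panel(sprintf("rs%02d", 1:30), "1", seq_len(30) * 100L,
                     "G", "A", base_maf = 0.3, fst = 0.1)
  labs <- rep(1:2, each = 1000)
  gm <- generate_genotypes(2000, panel, labs, seed = 12)
  freq_diff <- abs(colMeans(gm$values[labs == 1, ]) -
                   colMeans(gm$values[labs == 2, ])) / 2
  expect_gt(mean(freq_diff), 0.02)    # drift present on average
})

test_that("assign_cohort_and_trials honours the design fractions", {
  des <- trial_design(os_fraction = 0)
  sub <- assign_cohort_and_trials(25000, des, seed = 4)
  ht <- sub$ht_trial != "none"
  expect_gt(sum(ht), 8000)
  expect_lt(abs(mean(sub$z_ht[ht]) - 0.5), 0.015)
  # hysterectomy routes the trials
  expect_true(all(sub$hysterectomy[sub$ht_trial == "E-alone"]))
  expect_true(all(!sub$hysterectomy[sub$ht_trial == "E+P"]))
  # every trial subject is in HT or DM
  expect_true(all(sub$in_ht | sub$in_dm))

  no_hyst <- assign_cohort_and_trials(
    2000, trial_design(hysterectomy_prev = 0), seed = 4)
  expect_equal(sum(no_hyst$ht_trial == "E-alone"), 0)

  all_os <- assign_cohort_and_trials(
    2000, trial_design(os_fraction = 1), seed = 4)
  expect_true(all(is.na(all_os$z_ht)))
  expect_true(all(is.na(all_os$z_dm)))
  expect_true(all(is.na(all_os$z_cad)))
  expect_true(all(!all_os$in_ht & !all_os$in_dm & !all_os$in_cad))
})

test_that("simulate_outcomes hits the baseline rate and is deterministic", {
  n <- 50000
  sub <- assign_cohort_and_trials(n, trial_design(), seed = 2)
  gm <- generate_genotypes(n, simple_panel(), sub$subpopulation, seed = 2)
  eff <- effect_config(baseline_logodds = qlogis(0.05))
  out <- simulate_outcomes(sub, gm, eff, seed = 8)
  expect_lt(abs(mean(out$stroke) - 0.05), 0.004)
  out2 <- simulate_outcomes(sub, gm, eff, seed = 8)
  expect_identical(out, out2)
  expect_true(all((out$subtype == "none") == !out$stroke))
  bad <- effect_config(qlogis(0.05),
                       snp_marginal_logodds = list(nosuch = 0.5))
  expect_error(simulate_outcomes(sub, gm, bad, seed = 1), "unknown rsid")
})

test_that("full-cohort refits recover the planted interaction effect", {
  # consistency of the generating model: the 95% Wald interval for the
  # interaction covers truth; 25 replicates (scaled from the stated 100,
  # pass bound >= 21 keeps the same nominal coverage check)
  truth <- -0.8
  covered <- 0L
  for (s in 1:25) {
    d <- sim_trial(8000, maf = 0.3, q = 0.5, baseline = qlogis(0.07),
                   b_trt = log(1.4), b_g = log(1.2), b_int = truth,
                   seed = 100 + s)
    x <- cbind("(Intercept)" = 1, z = d$z, g = d$g, gz = d$g * d$z)
    f <- fit_logistic(x, as.numeric(d$y))
    ci <- wald_ci(f$coefficients[["gz"]], sqrt(f$covariance["gz", "gz"]))
    if (ci[1] <= truth && truth <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 21)
})

test_that("matched control selection satisfies its postconditions", {
  n <- 4000
  des <- trial_design()
  sub <- assign_cohort_and_trials(n, des, seed = 31)
  gm <- generate_genotypes(n, simple_panel(), sub$subpopulation, seed = 31)
  out <- simulate_outcomes(sub, gm,
                           effect_config(qlogis(0.10)), seed = 31)
  ms <- select_matched_controls(sub, out, seed = 31)
  pairs <- ms$pairs
  expect_gt(nrow(pairs), 0)
  # controls unique, partition preserved
  expect_false(anyDuplicated(pairs$control_id) > 0)
  expect_equal(nrow(pairs) + length(ms$dropped_cases), sum(out$stroke))
  # exact factor agreement + age caliper
  ci <- match(pairs$case_id, sub$subject_id)
  ki <- match(pairs$control_id, sub$subject_id)
  for (f in ms$matching_factors)
    expect_identical(sub[[f]][ci], sub[[f]][ki])
  expect_true(all(abs(sub$age[ci] - sub$age[ki]) <= ms$age_caliper))
  # controls really are non-cases
  expect_true(all(!out$stroke[match(pairs$control_id, out$subject_id)]))
  # per-component pair counts mirror matched-case counts (structural)
  for (comp in c("in_ht", "in_dm", "in_cad"))
    expect_equal(sum(sub[[comp]][ci]), sum(sub[[comp]][ki]))
})

test_that("a case with an empty risk set is dropped, not fatal", {
  sub <- data.frame(subject_id = c("a", "b", "c"),
                    ethnicity = c("unique", "x", "x"),
                    cohort = "CT", age = c(60, 61, 62),
                    stringsAsFactors = FALSE)
  out <- data.frame(subject_id = c("a", "b", "c"),
                    stroke = c(TRUE, TRUE, FALSE))
  ms <- select_matched_controls(sub, out,
                                matching_factors = c("ethnicity", "cohort"),
                                age_caliper = 5, seed = 1)
  expect_true("a" %in% ms$dropped_cases)
  expect_equal(ms$pairs$case_id, "b")
})

test_that("fixtures round-trip and the planted scenario is as configured", {
  dir1 <- tempfile(); dir2 <- tempfile()
  fx1 <- make_fixture("tiny", seed = 19, dir = dir1)
  fx2 <- make_fixture("tiny", seed = 19, dir = dir2)
  expect_lte(nrow(fx1$data$subjects), 200)
  expect_lte(ncol(fx1$data$genotypes$values), 20)
  # byte-identical under identical preset + seed
  for (f in c("phenotypes.tsv", "genotypes.tsv", "manifest.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # round-trip through the readers
  phen <- read_phenotypes(fx1$paths$phenotypes)
  gm <- read_genotypes(fx1$paths$genotypes)
  expect_identical(phen$subject_id, fx1$data$subjects$subject_id)
  expect_identical(unname(gm$values),
                   unname(fx1$data$genotypes$values))

  # planted-scenario manifest audit
  fx3 <- make_fixture("f13a1_like", seed = 2, dir = tempfile())
  man <- jsonlite::fromJSON(fx3$paths$manifest)
  pair <- man$snps[!is.na(man$snps$ld_partner) &
                     man$snps$rsid == "rs_f13_2", ]
  expect_gt(pair$target_r2, 0.98)
  expect_equal(pair$base_maf, 0.09)
  expect_lt(man$effects$interaction_logodds$rs_f13_1$`E+P`, 0)
  v <- fx3$data$genotypes$values
  expect_gt(cor(v[, "rs_f13_1"], v[, "rs_f13_2"])^2, 0.95)
})
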