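# Synthetic cohort generator: SNP panels with population structure and LD,
# trial/cohort assignment, logistic outcome simulation, and one-to-one
# matched control selection. The generator exists so the whole two-stage
# interaction analysis can be exercised end-to-end without individual-level
# trial data.

TRIALS <- c("E-alone", "E+P", "DM", "CaD")

#' Describe a SNP panel for simulation
#'
#' One row per SNP. `fst` controls Balding-Nichols allele-frequency drift
#' across subpopulations (0 = identical frequency everywhere). A SNP may name
#' an `ld_partner` appearing *earlier* in the panel; its genotypes are then
#' generated on shared haplotypes so the realized r-squared approaches
#' `target_r2`.
#'
#' @param rsid,chromosome,position,ref_allele,alt_allele SNP metadata
#'   (positions 1-based).
#' @param base_maf Ancestral minor-allele frequency in (0, 0.5].
#' @param fst Wright's fixation index in \[0, 1).
#' @param ld_partner Optional rsid of the anchor SNP this one is in LD with.
#' @param target_r2 Target squared correlation with the anchor, in (0, 1].
#' @return data.frame of class `snp_panel`.
#' @export
snp_panel <- function(rsid, chromosome, position, ref_allele, alt_allele,
                      base_maf, fst = 0, ld_partner = NA_character_,
                      target_r2 = NA_real_) {
  panel <- data.frame(rsid = as.character(rsid),
                      chromosome = as.character(chromosome),
                      position = as.integer(position),
                      ref_allele = as.character(ref_allele),
                      alt_allele = as.character(alt_allele),
                      base_maf = as.numeric(base_maf),
                      fst = as.numeric(fst),
                      ld_partner = as.character(ld_partner),
                      target_r2 = as.numeric(target_r2),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel$rsid)) stop("duplicate rsid")
  if (any(panel$position <= 0)) stop("positions must be positive")
  if (any(panel$base_maf <= 0 | panel$base_maf > 0.5))
    stop("base_maf must lie in (0, 0.5]")
  if (any(panel$fst < 0 | panel$fst >= 1)) stop("fst must lie in [0, 1)")
  has_ld <- !is.na(panel$ld_partner)
  if (any(has_ld)) {
    if (!all(panel$ld_partner[has_ld] %in% panel$rsid))
      stop("ld_partner must name a SNP in the panel")
    anchor_pos <- match(panel$ld_partner[has_ld], panel$rsid)
    if (any(anchor_pos >= which(has_ld)))
      stop("ld_partner must appear earlier in the panel than its dependent")
    if (any(is.na(panel$target_r2[has_ld]) |
            panel$target_r2[has_ld] <= 0 | panel$target_r2[has_ld] > 1))
      stop("target_r2 must lie in (0, 1] for LD pairs")
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Generate a subjects-by-SNPs minor-allele-count matrix
#'
#' Within each subpopulation a SNP's allele frequency is drawn once from the
#' Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F) distribution (frequency equals
#' `base_maf` exactly when `fst = 0`); genotypes are then binomial(2, freq),
#' i.e. Hardy-Weinberg within subpopulation. LD partners copy each anchor
#' haplotype allele with probability `sqrt(target_r2)` and redraw it from the
#' partner's own frequency otherwise, so the allele-level (and hence
#' genotype-level) correlation approaches `sqrt(target_r2)`; `target_r2 = 1`
#' duplicates the anchor exactly.
#'
#' @param n_subjects Number of subjects.
#' @param snps `snp_panel` data.frame.
#' @param subpopulations Integer subpopulation label per subject.
#' @param seed Integer seed (generation is deterministic given it).
#' @param missing_rate Per-genotype missingness probability.
#' @return Object of class `genotype_matrix`: list with `values`
#'   (matrix of 0/1/2/NA, rownames = subject ids, colnames = rsids),
#'   `snps`, `subject_ids`.
#' @export
generate_genotypes <- function(n_subjects, snps, subpopulations,
                               seed, missing_rate = 0) {
  stopifnot(inherits(snps, "data.frame"))
  if (anyDuplicated(snps$rsid)) stop("duplicate rsid")
  if (length(subpopulations) != n_subjects)
    stop("subpopulations must have one label per subject")
  set.seed(as.integer(seed))
  pops <- sort(unique(subpopulations))
  g <- matrix(NA_integer_, n_subjects, nrow(snps))
  haps <- vector("list", nrow(snps))      # kept only for LD anchors
  needed_as_anchor <- snps$rsid %in% snps$ld_partner
  for (j in seq_len(nrow(snps))) {
    p0 <- snps$base_maf[j]
    fst <- snps$fst[j]
    freq <- vapply(pops, function(k) {
      if (fst == 0) p0
      else stats::rbeta(1, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
    }, numeric(1))
    names(freq) <- as.character(pops)
    fi <- freq[as.character(subpopulations)]
    if (is.na(snps$ld_partner[j])) {
      h1 <- stats::rbinom(n_subjects, 1, fi)
      h2 <- stats::rbinom(n_subjects, 1, fi)
    } else {
      a <- match(snps$ld_partner[j], snps$rsid)
      if (is.null(haps[[a]]))
        stop("ld_partner must appear earlier in the panel")
      copy_prob <- sqrt(snps$target_r2[j])
      fresh1 <- stats::rbinom(n_subjects, 1, fi)
      fresh2 <- stats::rbinom(n_subjects, 1, fi)
      take1 <- stats::runif(n_subjects) < copy_prob
      take2 <- stats::runif(n_subjects) < copy_prob
      h1 <- ifelse(take1, haps[[a]][[1]], fresh1)
      h2 <- ifelse(take2, haps[[a]][[2]], fresh2)
    }
    if (needed_as_anchor[j]) haps[[j]] <- list(h1, h2)
    gj <- h1 + h2
    if (missing_rate > 0)
      gj[stats::runif(n_subjects) < missing_rate] <- NA_integer_
    g[, j] <- gj
  }
  subject_ids <- sprintf("S%05d", seq_len(n_subjects))
  dimnames(g) <- list(subject_ids, snps$rsid)
  structure(list(values = g, snps = as.data.frame(snps),
                 subject_ids = subject_ids),
            class = "genotype_matrix")
}

#' Default design of the simulated study
#'
#' Fractions loosely follow a large postmenopausal cohort with an
#' observational arm and a partial-factorial clinical trial containing two
#' non-overlapping hormone-therapy trials (E-alone for post-hysterectomy
#' women, E+P otherwise), a dietary-modification component and a
#' calcium/vitamin-D component. Randomization fractions `q_by_trial` are
#' design constants, never estimated from the data.
#'
#' @param os_fraction Fraction of subjects in the observational cohort.
#' @param subpop_probs Mixing proportions of the genetic subpopulations.
#' @param hysterectomy_prev Prevalence of hysterectomy (routes HT members to
#'   the E-alone trial).
#' @param ht_rate,dm_rate,cad_rate Component participation rates among trial
#'   subjects; subjects in neither HT nor DM are assigned to DM (every trial
#'   subject is in at least one primary component).
#' @param q_by_trial Named list of active-arm randomization fractions.
#' @param ... Covariate distribution overrides (see defaults in the source).
#' @return A validated `trial_design` list.
#' @export
trial_design <- function(os_fraction = 0.25,
                         subpop_probs = c(0.8, 0.2),
                         hysterectomy_prev = 0.40,
                         ht_rate = 0.40, dm_rate = 0.72, cad_rate = 0.53,
                         q_by_trial = list("E-alone" = 0.5, "E+P" = 0.5,
                                           "DM" = 0.4, "CaD" = 0.5),
                         ...) {
  design <- list(os_fraction = os_fraction, subpop_probs = subpop_probs,
                 hysterectomy_prev = hysterectomy_prev,
                 ht_rate = ht_rate, dm_rate = dm_rate, cad_rate = cad_rate,
                 q_by_trial = q_by_trial,
                 age_range = c(50, 79),
                 ethnicity_probs = c(white = 0.81, black = 0.10,
                                     hispanic = 0.06, other = 0.03),
                 smoking_probs = c(never = 0.5, former = 0.4, current = 0.1),
                 diabetes_prev = 0.06, hypertension_prev = 0.35,
                 aspirin_prev = 0.20, statin_prev = 0.10,
                 prevalent_stroke_prev = 0.015,
                 pf_mean = 80, pf_sd = 15, followup_years = 8)
  dots <- list(...)
  design[names(dots)] <- dots
  probs <- c(design$os_fraction, design$hysterectomy_prev, design$ht_rate,
             design$dm_rate, design$cad_rate, unlist(design$q_by_trial))
  if (any(probs < 0 | probs > 1)) stop("design fractions must be in [0, 1]")
  if (any(unlist(design$q_by_trial) %in% c(0, 1)))
    stop("q must lie strictly inside (0, 1)")
  if (abs(sum(design$subpop_probs) - 1) > 1e-8)
    stop("subpop_probs must sum to 1")
  class(design) <- "trial_design"
  design
}

#' Simulate cohort membership, trial randomizations and baseline covariates
#'
#' Trial subjects are randomized into the hormone-therapy component (routed
#' to E-alone or E+P by hysterectomy status), the dietary-modification
#' component, and the calcium/vitamin-D component; observational-cohort
#' subjects carry no randomization indicators.
#'
#' @param n_subjects Number of subjects.
#' @param design A `trial_design` list.
#' @param seed Integer seed.
#' @return data.frame, one row per subject, with covariates, component
#'   memberships (`in_ht`, `in_dm`, `in_cad`), `ht_trial`, and randomization
#'   indicators `z_ht`, `z_dm`, `z_cad` (NA where not a member).
#' @export
assign_cohort_and_trials <- function(n_subjects, design = trial_design(),
                                     seed) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(as.integer(seed))
  d <- design
  subject_id <- sprintf("S%05d", seq_len(n_subjects))
  subpopulation <- sample.int(length(d$subpop_probs), n_subjects,
                              replace = TRUE, prob = d$subpop_probs)
  cohort <- ifelse(stats::runif(n_subjects) < d$os_fraction, "OS", "CT")
  age <- round(stats::runif(n_subjects, d$age_range[1], d$age_range[2]), 1)
  ethnicity <- sample(names(d$ethnicity_probs), n_subjects, replace = TRUE,
                      prob = d$ethnicity_probs)
  hysterectomy <- stats::runif(n_subjects) < d$hysterectomy_prev
  prevalent_stroke <- stats::runif(n_subjects) < d$prevalent_stroke_prev
  smoking <- sample(names(d$smoking_probs), n_subjects, replace = TRUE,
                    prob = d$smoking_probs)
  diabetes <- stats::runif(n_subjects) < d$diabetes_prev
  hypertension <- stats::runif(n_subjects) < d$hypertension_prev
  aspirin <- stats::runif(n_subjects) < d$aspirin_prev
  statin <- stats::runif(n_subjects) < d$statin_prev
  physical_functioning <- pmin(100, pmax(
    0, round(stats::rnorm(n_subjects, d$pf_mean, d$pf_sd), 1)))

  ct <- cohort == "CT"
  in_ht <- ct & stats::runif(n_subjects) < d$ht_rate
  in_dm <- ct & stats::runif(n_subjects) < d$dm_rate
  in_dm[ct & !in_ht] <- TRUE            # every trial subject: HT or DM
  in_cad <- ct & stats::runif(n_subjects) < d$cad_rate
  ht_trial <- rep("none", n_subjects)
  ht_trial[in_ht & hysterectomy] <- "E-alone"
  ht_trial[in_ht & !hysterectomy] <- "E+P"

  z_ht <- rep(NA_integer_, n_subjects)
  qe <- d$q_by_trial[["E-alone"]]; qp <- d$q_by_trial[["E+P"]]
  z_ht[ht_trial == "E-alone"] <-
    stats::rbinom(sum(ht_trial == "E-alone"), 1, qe)
  z_ht[ht_trial == "E+P"] <- stats::rbinom(sum(ht_trial == "E+P"), 1, qp)
  z_dm <- rep(NA_integer_, n_subjects)
  z_dm[in_dm] <- stats::rbinom(sum(in_dm), 1, d$q_by_trial[["DM"]])
  z_cad <- rep(NA_integer_, n_subjects)
  z_cad[in_cad] <- stats::rbinom(sum(in_cad), 1, d$q_by_trial[["CaD"]])

  data.frame(subject_id, subpopulation, cohort, age, ethnicity,
             hysterectomy, prevalent_stroke, smoking, diabetes, hypertension,
             aspirin, statin, physical_functioning,
             in_ht, in_dm, in_cad, ht_trial, z_ht, z_dm, z_cad,
             stringsAsFactors = FALSE)
}

#' Configure the outcome-generating model
#'
#' The stroke indicator is Bernoulli with log-odds
#' `baseline + covariate terms + SNP main effects + trial main effects * Z +
#' interaction effects * G * Z`; stroke subtype is multinomial among cases.
#'
#' @param baseline_logodds Intercept on the log-odds scale.
#' @param covariate_logodds Named list: log-odds per unit of a numeric or
#'   logical subject column.
#' @param snp_marginal_logodds Named list keyed by rsid: log-odds per minor
#'   allele.
#' @param trial_main_logodds Named list keyed by trial
#'   (`E-alone`, `E+P`, `DM`, `CaD`): active-arm main effect.
#' @param interaction_logodds Nested named list `rsid -> trial -> log-odds`:
#'   SNP-by-treatment interaction per minor allele.
#' @param subtype_probs Probabilities over ischemic/hemorrhagic/other,
#'   summing to 1.
#' @return An `effect_config` list.
#' @export
effect_config <- function(baseline_logodds,
                          covariate_logodds = list(),
                          snp_marginal_logodds = list(),
                          trial_main_logodds = list(),
                          interaction_logodds = list(),
                          subtype_probs = c(ischemic = 0.66,
                                            hemorrhagic = 0.17,
                                            other = 0.17)) {
  if (abs(sum(subtype_probs) - 1) > 1e-8) stop("subtype_probs must sum to 1")
  if (!all(names(trial_main_logodds) %in% TRIALS))
    stop("unknown trial in trial_main_logodds")
  for (rs in names(interaction_logodds))
    if (!all(names(interaction_logodds[[rs]]) %in% TRIALS))
      stop("unknown trial in interaction_logodds")
  structure(list(baseline_logodds = baseline_logodds,
                 covariate_logodds = covariate_logodds,
                 snp_marginal_logodds = snp_marginal_logodds,
                 trial_main_logodds = trial_main_logodds,
                 interaction_logodds = interaction_logodds,
                 subtype_probs = subtype_probs),
            class = "effect_config")
}

# randomization indicator for a subject relative to a named trial (0 when
# not a member, so effect terms vanish for non-members)
trial_z <- function(subjects, trial) {
  z <- switch(trial,
              "E-alone" = ifelse(subjects$ht_trial == "E-alone",
                                 subjects$z_ht, NA),
              "E+P" = ifelse(subjects$ht_trial == "E+P", subjects$z_ht, NA),
              "DM" = subjects$z_dm,
              "CaD" = subjects$z_cad,
              stop("unknown trial: ", trial))
  ifelse(is.na(z), 0, z)
}

#' Simulate stroke outcomes under a logistic model
#'
#' @param subjects Output of [assign_cohort_and_trials()].
#' @param genotypes `genotype_matrix` aligned to the same subjects.
#' @param effects An `effect_config`.
#' @param seed Integer seed.
#' @return data.frame: `subject_id`, `stroke` (logical), `subtype`
#'   (`ischemic`/`hemorrhagic`/`other`/`none`), `event_year` (NA for
#'   non-cases).
#' @export
simulate_outcomes <- function(subjects, genotypes, effects, seed) {
  stopifnot(inherits(effects, "effect_config"))
  set.seed(as.integer(seed))
  n <- nrow(subjects)
  lp <- rep(effects$baseline_logodds, n)
  for (nm in names(effects$covariate_logodds)) {
    if (!nm %in% names(subjects)) stop("unknown covariate: ", nm)
    lp <- lp + effects$covariate_logodds[[nm]] * as.numeric(subjects[[nm]])
  }
  gmat <- genotypes$values
  snp_effects <- unique(c(names(effects$snp_marginal_logodds),
                          names(effects$interaction_logodds)))
  if (!all(snp_effects %in% colnames(gmat)))
    stop("unknown rsid in effect configuration")
  for (rs in names(effects$snp_marginal_logodds)) {
    g <- gmat[, rs]
    g[is.na(g)] <- mean(g, na.rm = TRUE)   # missing -> mean dosage
    lp <- lp + effects$snp_marginal_logodds[[rs]] * g
  }
  for (tr in names(effects$trial_main_logodds))
    lp <- lp + effects$trial_main_logodds[[tr]] * trial_z(subjects, tr)
  for (rs in names(effects$interaction_logodds)) {
    g <- gmat[, rs]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    for (tr in names(effects$interaction_logodds[[rs]]))
      lp <- lp + effects$interaction_logodds[[rs]][[tr]] * g *
        trial_z(subjects, tr)
  }
  stroke <- stats::runif(n) < stats::plogis(lp)
  subtype <- rep("none", n)
  n_cases <- sum(stroke)
  if (n_cases > 0)
    subtype[stroke] <- sample(names(effects$subtype_probs), n_cases,
                              replace = TRUE, prob = effects$subtype_probs)
  event_year <- rep(NA_real_, n)
  event_year[stroke] <- round(stats::runif(n_cases, 0, 8), 2)
  data.frame(subject_id = subjects$subject_id, stroke = stroke,
             subtype = subtype, event_year = event_year,
             stringsAsFactors = FALSE)
}

#' Select one-to-one matched controls
#'
#' Greedy nearest-age matching within exact strata of the categorical
#' matching factors; cases are processed in a seeded random order and each
#' control is used at most once. Cases with an empty risk set are reported in
#' `dropped_cases`, never an error.
#'
#' @param subjects,outcomes Aligned subject and outcome tables.
#' @param matching_factors Character vector of categorical subject columns
#'   requiring exact agreement.
#' @param age_caliper Maximum |age difference| in years.
#' @param seed Integer seed (ordering of cases).
#' @return Object of class `matched_set`: `pairs` (data.frame with
#'   `case_id`, `control_id`, `stratum_key`, `age_diff`) and `dropped_cases`.
#' @export
select_matched_controls <- function(subjects, outcomes,
                                    matching_factors = c(
                                      "ethnicity", "cohort", "in_ht",
                                      "in_dm", "in_cad", "hysterectomy",
                                      "prevalent_stroke"),
                                    age_caliper = 2, seed = 1L) {
  if (!all(matching_factors %in% names(subjects)))
    stop("matching factors must be subject columns: missing ",
         paste(setdiff(matching_factors, names(subjects)), collapse = ", "))
  set.seed(as.integer(seed))
  stroke <- outcomes$stroke[match(subjects$subject_id, outcomes$subject_id)]
  key <- do.call(paste, c(subjects[matching_factors], sep = "|"))
  case_idx <- which(stroke)
  pool_idx <- which(!stroke)
  pool_by_key <- split(pool_idx, key[pool_idx])
  used <- logical(nrow(subjects))
  order_cases <- sample(case_idx)
  res_case <- character(0); res_ctrl <- character(0)
  res_key <- character(0); res_diff <- numeric(0)
  dropped <- character(0)
  for (ci in order_cases) {
    cand <- pool_by_key[[key[ci]]]
    cand <- cand[!used[cand]]
    if (length(cand)) {
      diffs <- abs(subjects$age[cand] - subjects$age[ci])
      cand <- cand[diffs <= age_caliper]
      diffs <- diffs[diffs <= age_caliper]
    }
    if (!length(cand)) {
      dropped <- c(dropped, subjects$subject_id[ci])
      next
    }
    pick <- cand[which.min(diffs)]      # ties: first in subject order
    used[pick] <- TRUE
    res_case <- c(res_case, subjects$subject_id[ci])
    res_ctrl <- c(res_ctrl, subjects$subject_id[pick])
    res_key <- c(res_key, key[ci])
    res_diff <- c(res_diff, min(diffs))
  }
  structure(list(
    pairs = data.frame(case_id = res_case, control_id = res_ctrl,
                       stratum_key = res_key, age_diff = res_diff,
                       stringsAsFactors = FALSE),
    dropped_cases = dropped,
    matching_factors = matching_factors, age_caliper = age_caliper),
    class = "matched_set")
}

# ---------------------------------------------------------------------------
# Fixture presets

fixture_presets <- function() {
  base_panel <- function(extra = NULL) {
    core <- snp_panel(
      rsid = c("rs_f13_1", "rs_f13_2", "rs_pk_1", "rs_pk_2",
               "rs_null_1", "rs_null_2", "rs_null_3", "rs_null_4"),
      chromosome = c("6", "6", "1", "1", "4", "9", "16", "2"),
      position = c(6231297L, 6233241L, 55299911L, 55297430L,
                   88654846L, 116000000L, 54084923L, 12000000L),
      ref_allele = c("A", "G", "G", "G", "A", "T", "C", "C"),
      alt_allele = c("G", "A", "A", "A", "G", "G", "T", "G"),
      base_maf = c(0.09, 0.09, 0.34, 0.34, 0.17, 0.36, 0.39, 0.25),
      fst = 0.02,
      ld_partner = c(NA, "rs_f13_1", NA, "rs_pk_1", NA, NA, NA, NA),
      target_r2 = c(NA, 0.985, NA, 0.985, NA, NA, NA, NA))
    core
  }
  confounders <- list(diabetes = log(1.6), hypertension = log(1.6),
                      aspirin = log(1.2), prevalent_stroke = log(2.5))
  list(
    tiny = list(
      n = 200,
      design = trial_design(os_fraction = 0.2),
      panel = base_panel(),
      effects = effect_config(
        baseline_logodds = stats::qlogis(0.20),
        covariate_logodds = confounders,
        trial_main_logodds = list("E-alone" = log(1.4), "E+P" = log(1.4)))),
    null = list(
      n = 8000,
      design = trial_design(os_fraction = 0.2, ht_rate = 0.5),
      panel = base_panel(),
      effects = effect_config(
        baseline_logodds = stats::qlogis(0.08),
        covariate_logodds = confounders,
        snp_marginal_logodds = list(rs_null_1 = log(1.2)),
        trial_main_logodds = list("E-alone" = log(1.4), "E+P" = log(1.4)))),
    f13a1_like = list(
      n = 12000,
      design = trial_design(os_fraction = 0.15, ht_rate = 0.6),
      panel = base_panel(),
      effects = effect_config(
        baseline_logodds = stats::qlogis(0.08),
        covariate_logodds = confounders,
        snp_marginal_logodds = list(rs_f13_1 = log(1.4)),
        trial_main_logodds = list("E-alone" = log(1.4), "E+P" = log(1.5)),
        interaction_logodds = list(
          rs_f13_1 = list("E+P" = -0.8, "E-alone" = -0.3)))),
    pcsk9_like = list(
      n = 12000,
      design = trial_design(os_fraction = 0.15, ht_rate = 0.6),
      panel = base_panel(),
      effects = effect_config(
        baseline_logodds = stats::qlogis(0.08),
        covariate_logodds = confounders,
        snp_marginal_logodds = list(rs_pk_1 = log(0.91)),
        trial_main_logodds = list("E-alone" = log(1.4), "E+P" = log(1.4)),
        interaction_logodds = list(
          rs_pk_1 = list("E-alone" = -0.35, "E+P" = 0.37)))))
}

#' Generate a complete synthetic dataset and write it to disk
#'
#' Presets: `"tiny"` (a fast smoke-test cohort), `"null"` (treatment and SNP
#' main effects, zero interactions — the calibration world for type-I-error
#' checks), `"f13a1_like"` (a high-LD low-MAF SNP pair whose minor allele
#' attenuates the E+P stroke-risk elevation) and `"pcsk9_like"` (a common
#' high-LD pair with opposite-sign interactions in the two hormone trials).
#'
#' @param profile Preset name.
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (phenotypes/genotypes/manifest) and
#'   `data` (the in-memory subjects, outcomes, genotypes, matched set).
#' @export
make_fixture <- function(profile = c("tiny", "null", "f13a1_like",
                                     "pcsk9_like"),
                         seed, dir = tempfile("fixture")) {
  profile <- match.arg(profile)
  preset <- fixture_presets()[[profile]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(preset$n, preset$panel, preset$design,
                         preset$effects, seed)
  phen <- merge(sim$subjects, sim$outcomes, by = "subject_id", sort = FALSE)
  phen_path <- file.path(dir, "phenotypes.tsv")
  geno_path <- file.path(dir, "genotypes.tsv")
  man_path <- file.path(dir, "manifest.json")
  utils::write.table(phen, phen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gdf <- data.frame(subject_id = sim$genotypes$subject_ids,
                    sim$genotypes$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(profile = profile, seed = as.integer(seed),
                   n_subjects = preset$n,
                   q_by_trial = preset$design$q_by_trial,
                   snps = preset$panel,
                   effects = unclass(preset$effects),
                   n_cases = sum(sim$outcomes$stroke),
                   n_pairs = nrow(sim$matched$pairs))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "rows"),
             man_path)
  invisible(list(paths = list(phenotypes = phen_path, genotypes = geno_path,
                              manifest = man_path),
                 data = sim, preset = preset))
}

#' Simulate a full cohort in memory
#'
#' Convenience wrapper chaining [assign_cohort_and_trials()],
#' [generate_genotypes()], [simulate_outcomes()] and
#' [select_matched_controls()] with per-step seeds derived from a master
#' seed.
#'
#' @param n_subjects,panel,design,effects,seed See the component functions.
#' @param missing_rate Genotype missingness rate.
#' @return list with `subjects`, `genotypes`, `outcomes`, `matched`.
#' @export
simulate_cohort <- function(n_subjects, panel, design, effects, seed,
                            missing_rate = 0) {
  seeds <- derive_seeds(seed, 4)
  subjects <- assign_cohort_and_trials(n_subjects, design, seeds[1])
  genotypes <- generate_genotypes(n_subjects, panel,
                                  subjects$subpopulation, seeds[2],
                                  missing_rate = missing_rate)
  outcomes <- simulate_outcomes(subjects, genotypes, effects, seeds[3])
  matched <- select_matched_controls(subjects, outcomes, seed = seeds[4])
  list(subjects = subjects, genotypes = genotypes, outcomes = outcomes,
       matched = matched)
}

#' Derive per-stage seeds from a master seed
#'
#' Linear-congruential chain (multiplier 48271 modulo 2^31 - 1), so each
#' pipeline stage is independently reproducible from the master seed alone.
#'
#' @param master Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`, each in \[1, 2^31 - 2\].
#' @export
derive_seeds <- function(master, n) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% (m - 1)) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% m
    out[i] <- as.integer(s)
  }
  out
}
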