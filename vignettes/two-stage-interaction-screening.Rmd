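---
title: "Two-stage screening for SNP-by-treatment interactions in randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage screening for SNP-by-treatment interactions in randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescreen)
```

## The problem and the design

Genome-wide association signals explain only a small part of familial
aggregation of stroke, and genotype-by-environment interaction is one of the
places the remainder may hide. Observational exposure measurement makes
interaction estimation fragile; a randomized trial removes that fragility
because the exposure — assignment to active treatment — is known exactly and
is independent of genotype by randomization. `gxescreen` implements a
two-stage screening analysis for exactly this setting: a cohort of
postmenopausal women containing an observational arm and a clinical-trial
arm whose hormone-therapy (HT) component consists of two non-overlapping
randomized trials — estrogen alone (E-alone) for women with prior
hysterectomy, estrogen plus progestin (E+P) for the rest — with stroke as
the outcome and a matched case-control sample as the analysis set.

## The two-stage procedure

**Stage 1 — marginal screen.** For each SNP, a standard logistic regression
of case (1) versus control (0) status on the minor-allele count $G$
(additive coding) plus confounders (smoking, physical functioning score,
treated diabetes, hypertension, aspirin use, statin use), the matching
variables, the trial randomization assignments, and the top genotype
principal components for population-stratification control. SNPs with
two-sided $p < 0.05$ (Wald by default; LRT by flag) pass to stage 2.

**Stage 2 — case-only interaction test.** Among the *cases* of one trial
component, randomization implies that treatment assignment $Z$ would be
independent of $G$ were there no interaction, so dependence of $Z$ on $G$
among cases measures interaction directly. The working model is

$$\operatorname{logit} P(Z = 1 \mid G)
  = \log\!\frac{q}{1-q} + \beta_0 + \beta_2 G,$$

where $q$ is the design fraction randomized to active treatment. $q$ is a
known constant and enters as a fixed offset; estimating it from the cases
would absorb part of the treatment main effect into $\beta_0$ and bias the
test. $\beta_2$ is the interaction log-odds ratio per minor allele. Each
trial component contributes a 1-df likelihood-ratio statistic for
$\beta_2 = 0$; because E-alone and E+P enrol disjoint women the two
statistics are independent, and their sum is referred to a $\chi^2_2$
distribution (`combined_ht_test()`, `combine_component_pvalues()`).

**Multiplicity.** The stage-1 and stage-2 statistics are asymptotically
independent, so the false-discovery-rate adjustment runs over the stage-1
survivors only — `m` equals the pass-list size, never the full panel.
`bh_adjust()` accepts `m` larger than the number of supplied p-values for
the situation where only the smallest members of the family are in hand;
adjusted values whose running minimum is realized at a supplied rank are
exact, and values at the largest supplied ranks are conservative upper
bounds (the output carries a note).

**Follow-up.** For flagged SNPs the package reports intervention odds
ratios stratified by genotype: with $a$ treated and $b$ placebo cases at
genotype level $g$, the case-only estimator is
$\widehat{OR}(g) = (a/b)\,/\,(q/(1-q))$ with Wald interval from
$SE = \sqrt{1/a + 1/b}$ on the log scale. Empty cells ($a = 0$ or $b = 0$)
are reported as `NA` with no continuity correction. Interaction is
re-tested with 1-df (linear in $G$) and 2-df (indicators for $G=1$ and
$G=2$) LRTs, overall and within stroke subtypes; when the $G = 2$ cell is
empty among the analyzed cases the 2-df test collapses onto the remaining
indicator and the two p-values coincide by construction. The same policy
extends to a level whose cases all sit on one arm: its cell odds ratio is
infinite, so its indicator cannot be estimated, its cases are excluded
from the indicator fit and the test collapses to the remaining degrees of
freedom (the `df_2df` field records what was used). A joint
case-only model for two SNPs (`joint_two_snp_test()`) tests each SNP's
interaction adjusted for the other's.

**Discrimination.** `fit_and_score()` and `bootstrap_auc_comparison()`
measure the incremental ability of SNP main-effect and interaction terms to
separate cases from controls via the Mann-Whitney AUC, with the matched
pair as the bootstrap resampling unit (preserving the 1:1 design), a
percentile interval, and a two-sided p-value from a normal approximation on
the bootstrap distribution of the AUC difference. The reported AUC is
apparent (in-sample); because flagged SNPs are selected on the same data,
the increment is optimistic, and winner's-curse inflation of flagged effect
sizes is likewise documented rather than corrected.

## What the synthetic generator emulates

No individual-level data accompany the motivating study, so the package
ships a generator whose stated world mirrors the design:

* **Cohort structure** (`assign_cohort_and_trials()`): an observational
  fraction; trial subjects randomized into HT (routed to E-alone/E+P by
  hysterectomy status), dietary-modification and calcium/vitamin-D
  components in a partial factorial; every trial subject is in HT or DM.
  Default component rates (HT 0.40, DM 0.72, CaD 0.53, OS fraction,
  hysterectomy prevalence 0.40) echo the published enrolment counts;
  covariate distributions (age uniform 50–79, ethnicity 81% white, binary
  risk-factor prevalences) are configurable defaults, not claims about the
  original cohort. Randomization fractions default to $q = 0.5$ for both
  HT trials (1:1 randomization), 0.4 for DM, 0.5 for CaD; the source never
  prints its $q$ values, so they are mandatory configuration, never
  inferred from data.
* **Genotypes** (`generate_genotypes()`): within each subpopulation a SNP's
  frequency is drawn once from the Balding–Nichols
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ distribution and genotypes are
  binomial(2, freq) — Hardy–Weinberg within subpopulation, drift $F$
  between. High-LD pairs are generated on shared haplotypes: each partner
  haplotype allele copies its anchor with probability $\sqrt{r^2_{target}}$
  and is redrawn from the partner's own frequency otherwise, so the
  realized genotype $r^2$ approaches the target ($r^2 = 1$ duplicates the
  anchor exactly).
* **Outcomes** (`simulate_outcomes()`): Bernoulli stroke with logistic
  log-odds combining baseline, covariate, SNP main, trial main and
  SNP-by-trial interaction terms; subtype (ischemic 0.66 / hemorrhagic
  0.17 / other 0.17, near the published case mix) multinomial among cases.
* **Matching** (`select_matched_controls()`): greedy nearest-age matching
  within exact strata of ethnicity, cohort, component memberships,
  hysterectomy and prevalent stroke, age caliper 2 years, cases in seeded
  random order, controls used once, unmatched cases logged — never fatal.
  The original design also matched on years since enrolment; with no
  censoring in the generator every non-case is at risk at every event
  time, so that factor cannot constrain selection here and is omitted from
  the default list.

What a green test does **not** establish: the generator has no realistic
human LD map, no time-to-event structure, no genotyping error, and its
covariates are independent of genotype; tests against it validate the
machinery and the statistical calibration of the tests, not any biological
claim.

## Numerical choices

* Logistic maximum likelihood is Newton–Raphson/IRLS with step-halving,
  convergence at max |score| < 1e-8 or relative log-likelihood change
  < 1e-10, 100 iterations maximum. Any |coefficient| > 15 or
  non-convergence flags the fit (separation) and downstream consumers
  report `NA` rather than a spurious p-value — the origin of the
  `NA (NA, NA)` convention in follow-up tables.
* Chi-square tails and quantiles use R's `pchisq()`/`qchisq()` (the
  regularized incomplete gamma function); re-implementing them would
  duplicate base R.
* Genotype PCA imputes missing genotypes to the per-SNP mean, drops
  monomorphic columns with a message, scales to unit variance and takes
  SVD scores; the component sign convention fixes the first nonzero
  loading positive. The pipeline computes PCs on an LD-pruned panel
  (pairwise $r^2 \le 0.2$) and caps $k$ at a quarter of the pruned panel
  size: with a desk-scale panel, components computed from all SNPs span
  the tested genotypes and would void the scan — a situation the
  motivating 2,763-SNP panel never faces.
* The minor allele is defined in the analyzed sample; a SNP arriving
  major-allele-coded is flipped (logged) so $\beta_2$ is always per minor
  allele.
* Stage-1 p-values default to Wald (the conventional scan statistic; one
  fit per SNP instead of two); the LRT is one flag away. The case-only
  models contain only $G$ — covariates are deliberately absent, matching
  the stated second-stage model.
* Master seeds spawn per-stage seeds through a multiplicative
  linear-congruential chain (`derive_seeds()`), so each stage is
  independently reproducible and reruns are byte-identical.

## Known limitations

* The case-only slope estimates the *risk-ratio* interaction; it
  coincides with the generating odds-ratio interaction only for rare
  outcomes. At a baseline risk of 8% a planted $\beta_2 = -0.8$ is
  recovered as about $-0.73$; at 1.5% as $-0.81$. Calibration tests
  therefore use rare-outcome worlds; with common outcomes the test keeps
  its size under the null but the estimate is attenuated.
* The screen is insensitive to interactions at SNPs without marginal
  association — a property of the two-stage design, not a defect.
* Apparent AUC on a matched case-control sample is a distorted estimate of
  the population AUC (matching removes between-factor discrimination), and
  the flagged-SNP increment is optimistic; both caveats are inherited from
  the design.
* Conditional logistic regression, genomic-control inflation factors,
  winner's-curse correction and survival outcomes are out of scope.

## A worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(preset = "f13a1_like", seed = 1,
                       out_dir = "f13a1_run")
res <- run_pipeline(cfg)
res$stage2[, c("rank", "rsid", "maf", "marginal_or", "p_combined",
               "fdr", "flagged")]
```

The planted low-MAF pair (minor allele attenuating the E+P stroke-risk
elevation, $r^2 > 0.98$ within the pair) passes the marginal screen, leads
the stage-2 ranking and is flagged at FDR < 0.05 in most seeds; the
follow-up table shows intervention odds ratios falling with minor-allele
count and the AUC comparison a small positive increment. The `f13a1_like`
preset plants a marginal OR of 1.4 — larger than the motivating scale —
so that a ~1,300-pair cohort retains screen power; at the published effect
size (OR 1.19) the screen's power is modest even at full scale, which is
precisely the two-stage design's stated trade-off.
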