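# Pipeline orchestration: simulate (or read) -> stage 1 -> stage 2 ->
# follow-up -> discrimination, with TSV outputs, a manifest and
# deterministic per-stage seeds derived from one master seed.

#' Assemble and validate a pipeline configuration
#'
#' @param preset Simulation preset name (see [make_fixture()]), or `NULL`
#'   when reading files.
#' @param phenotype_path,genotype_path Input files when not simulating.
#' @param covariates Stage-1 adjustment covariates
#'   (default [default_stage1_covariates()]).
#' @param k_pcs Number of genotype principal components (default 10; capped
#'   at the available rank at run time).
#' @param stage1_threshold Marginal screen p-value threshold.
#' @param fdr_threshold Stage-2 FDR flagging threshold.
#' @param q_by_trial Named list of randomization fractions (mandatory when
#'   reading files; filled from the preset when simulating).
#' @param subtype_scopes Follow-up subtype scopes.
#' @param n_boot Bootstrap replicates for the AUC comparison.
#' @param seed Master seed (mandatory).
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(preset = NULL, phenotype_path = NULL,
                            genotype_path = NULL,
                            covariates = default_stage1_covariates(),
                            k_pcs = 10, stage1_threshold = 0.05,
                            fdr_threshold = 0.05, q_by_trial = NULL,
                            subtype_scopes = c("all", "ischemic",
                                               "hemorrhagic"),
                            n_boot = 200, seed, out_dir) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(preset) && (is.null(phenotype_path) || is.null(genotype_path)))
    stop("either a preset or phenotype + genotype paths must be given")
  if (stage1_threshold <= 0 || stage1_threshold > 1 ||
      fdr_threshold <= 0 || fdr_threshold > 1)
    stop("thresholds must lie in (0, 1]")
  if (is.null(preset) && is.null(q_by_trial))
    stop("q_by_trial is mandatory when reading files (q is a design ",
         "constant, never inferred from the data)")
  structure(list(preset = preset, phenotype_path = phenotype_path,
                 genotype_path = genotype_path, covariates = covariates,
                 k_pcs = k_pcs, stage1_threshold = stage1_threshold,
                 fdr_threshold = fdr_threshold, q_by_trial = q_by_trial,
                 subtype_scopes = subtype_scopes, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

log_stage <- function(log, stage, ...) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(line)
  c(log, line)
}

#' Run the full two-stage interaction analysis pipeline
#'
#' Executes, in order: data simulation (or reading), genotype PCA, the
#' stage-1 marginal screen on the matched case-control sample, the stage-2
#' case-only 2-df interaction scan with restricted-family FDR, descriptive
#' follow-up for every FDR-flagged SNP (falling back to the top-ranked SNP
#' when none is flagged), and the AUC comparison of the covariate-only risk
#' model against the model adding flagged-SNP main effects and
#' hormone-trial interaction terms. All tables are written as TSV together
#' with a JSON manifest recording the configuration, seeds and per-stage
#' counts. Re-running the same configuration is byte-identical.
#'
#' @param config A `pipeline_config`.
#' @param stages Subset of stages to run (earlier stages a later one needs
#'   are always run in memory; `"simulate"` covers reading files too).
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "stage1", "stage2",
                                    "followup", "auc")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 3)
  log <- character(0)
  paths <- list()
  counts <- list()

  # --- data ---------------------------------------------------------------
  if (!is.null(config$preset)) {
    fx <- make_fixture(config$preset, seed = seeds[1],
                       dir = file.path(config$out_dir, "data"))
    subjects <- fx$data$subjects
    outcomes <- fx$data$outcomes
    genotypes <- fx$data$genotypes
    matched <- fx$data$matched
    q_by_trial <- config$q_by_trial
    if (is.null(q_by_trial)) q_by_trial <- fx$preset$design$q_by_trial
    paths$data <- fx$paths
    log <- log_stage(log, "simulate", "preset=", config$preset,
                     " subjects=", nrow(subjects),
                     " cases=", sum(outcomes$stroke),
                     " pairs=", nrow(matched$pairs),
                     " dropped_cases=", length(matched$dropped_cases))
  } else {
    phen <- read_phenotypes(config$phenotype_path)
    genotypes <- read_genotypes(config$genotype_path)
    subjects <- phen[setdiff(names(phen), c("stroke", "subtype",
                                            "event_year"))]
    outcomes <- phen[intersect(names(phen),
                               c("subject_id", "stroke", "subtype",
                                 "event_year"))]
    matched <- select_matched_controls(subjects, outcomes,
                                       seed = seeds[1])
    q_by_trial <- config$q_by_trial
    log <- log_stage(log, "read", "subjects=", nrow(subjects),
                     " cases=", sum(outcomes$stroke),
                     " pairs=", nrow(matched$pairs))
  }
  counts$n_subjects <- nrow(subjects)
  counts$n_snps <- ncol(genotypes$values)
  counts$n_cases <- sum(outcomes$stroke)
  counts$n_pairs <- nrow(matched$pairs)
  result <- list(subjects = subjects, outcomes = outcomes,
                 genotypes = genotypes, matched = matched)
  if (identical(stages, "simulate")) {
    writeLines(log, file.path(config$out_dir, "pipeline.log"))
    return(invisible(result))
  }

  cc <- build_cc_data(subjects, outcomes, matched, genotypes)

  # --- stage 1 ------------------------------------------------------------
  # PCs summarize ancestry, not the tested SNPs themselves: compute them on
  # an LD-pruned panel, and with a small panel cap k at a quarter of the
  # pruned size so the components cannot absorb the tested genotype
  pruned <- prune_by_ld(genotypes)
  k <- min(config$k_pcs, floor(ncol(pruned$values) / 4))
  pcs <- compute_genotype_pcs(pruned, k = k)
  stage1 <- marginal_scan(cc, genotypes,
                          covariates = intersect(config$covariates,
                                                 names(cc)),
                          pcs = pcs, threshold = config$stage1_threshold)
  paths$stage1 <- write_tsv(stage1, file.path(config$out_dir, "stage1.tsv"))
  counts$n_pass_stage1 <- sum(stage1$passes)
  log <- log_stage(log, "stage1", "snps=", nrow(stage1),
                   " passing=", sum(stage1$passes), " k_pcs=", k)
  result$stage1 <- stage1

  # --- stage 2 ------------------------------------------------------------
  stage2 <- NULL
  if (any(c("stage2", "followup", "auc") %in% stages) &&
      sum(stage1$passes) > 0) {
    stage2 <- run_stage2(stage1, subjects, outcomes, genotypes,
                         q_by_trial = q_by_trial,
                         fdr_threshold = config$fdr_threshold)
    paths$stage2 <- write_tsv(stage2[setdiff(names(stage2),
                                             c("df_used", "partial"))],
                              file.path(config$out_dir, "stage2.tsv"))
    counts$m_stage2 <- attr(stage2, "m")
    counts$n_flagged <- sum(stage2$flagged)
    log <- log_stage(log, "stage2", "m=", attr(stage2, "m"),
                     " flagged=", sum(stage2$flagged))
    result$stage2 <- stage2
  }

  # --- follow-up ----------------------------------------------------------
  if ("followup" %in% stages && !is.null(stage2) && nrow(stage2) > 0) {
    snps_fu <- stage2$rsid[stage2$flagged]
    if (!length(snps_fu)) snps_fu <- stage2$rsid[1]
    stroke <- outcomes$stroke[match(subjects$subject_id,
                                    outcomes$subject_id)]
    blocks <- list()
    for (rs in snps_fu) {
      flipped <- isTRUE(stage1$flipped[stage1$rsid == rs])
      for (tr in c("E-alone", "E+P")) {
        sel <- stroke & subjects$ht_trial == tr
        ids <- subjects$subject_id[sel]
        g <- genotypes$values[match(ids, genotypes$subject_ids), rs]
        if (flipped) g <- 2 - g
        cases <- data.frame(z = subjects$z_ht[sel],
                            subtype = outcomes$subtype[
                              match(ids, outcomes$subject_id)])
        blk <- followup_block(cases, g, q_by_trial[[tr]],
                              scopes = config$subtype_scopes)
        blk <- cbind(rsid = rs, trial = tr, blk)
        blocks[[paste(rs, tr)]] <- blk
      }
    }
    followup <- do.call(rbind, blocks)
    rownames(followup) <- NULL
    paths$followup <- write_tsv(followup,
                                file.path(config$out_dir, "followup.tsv"))
    log <- log_stage(log, "followup", "snps=", length(snps_fu))
    result$followup <- followup
  }

  # --- discrimination -----------------------------------------------------
  if ("auc" %in% stages && !is.null(stage2) && nrow(stage2) > 0) {
    snps_auc <- stage2$rsid[stage2$flagged]
    if (!length(snps_auc)) snps_auc <- stage2$rsid[1]
    # one SNP per LD region: high-LD twins carry the same signal and make
    # the risk design near-singular, so keep the top-ranked SNP per group
    if (length(snps_auc) > 1) {
      keep <- snps_auc[1]
      for (rs in snps_auc[-1]) {
        g <- genotypes$values[, rs]
        g[is.na(g)] <- mean(g, na.rm = TRUE)
        r2 <- vapply(keep, function(ks) {
          gk <- genotypes$values[, ks]
          gk[is.na(gk)] <- mean(gk, na.rm = TRUE)
          stats::cor(g, gk)^2
        }, numeric(1))
        if (all(r2 <= 0.2)) keep <- c(keep, rs)
      }
      snps_auc <- keep
    }
    base_cov <- intersect(config$covariates, names(cc))
    spec_base <- risk_model_spec(base_cov)
    spec_ext <- risk_model_spec(base_cov, snps = snps_auc,
                                snp_coding = "indicator",
                                interactions = TRUE)
    cmp <- tryCatch(
      bootstrap_auc_comparison(cc, spec_base, spec_ext,
                               n_boot = config$n_boot, seed = seeds[2]),
      error = function(e) e)
    if (inherits(cmp, "error")) {
      # separation on a small cohort is a data property, not a pipeline
      # defect: record and continue
      counts$auc_error <- conditionMessage(cmp)
      log <- log_stage(log, "auc", "failed: ", conditionMessage(cmp))
      cmp <- NULL
    }
  } else cmp <- NULL
  if (!is.null(cmp)) {
    auc_tab <- data.frame(
      model = c("base", "extended"),
      auc = c(cmp$auc_base, cmp$auc_extended),
      delta = c(NA, cmp$delta),
      ci_lower = c(NA, cmp$ci[1]), ci_upper = c(NA, cmp$ci[2]),
      p_value = c(NA, cmp$p_value),
      n_boot = cmp$n_boot, seed = cmp$seed)
    paths$auc <- write_tsv(auc_tab, file.path(config$out_dir, "auc.tsv"))
    log <- log_stage(log, "auc", "base=", round(cmp$auc_base, 4),
                     " extended=", round(cmp$auc_extended, 4),
                     " delta=", round(cmp$delta, 4),
                     " p=", signif(cmp$p_value, 3))
    result$auc <- cmp
  }

  manifest <- list(package_version = "gxescreen 0.1.0",
                   config = unclass(config), seeds = seeds,
                   counts = counts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(config$out_dir, "manifest.json"))
  writeLines(log, file.path(config$out_dir, "pipeline.log"))
  result$paths <- paths
  result$counts <- counts
  invisible(result)
}
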