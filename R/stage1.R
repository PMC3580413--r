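# Stage 1: per-SNP marginal association screen on the matched case-control
# sample, adjusted for covariates and genotype principal components.

#' Principal components of the genotype matrix
#'
#' Missing genotypes are imputed to the per-SNP mean, columns are centered
#' and scaled to unit variance (monomorphic columns dropped with a message),
#' and subject scores are taken from the singular-value decomposition —
#' equivalent to eigen-decomposition of the SNP correlation matrix. Sign
#' convention: the first nonzero loading of each component is positive.
#'
#' @param genotypes A `genotype_matrix`.
#' @param k Number of components (0 allowed).
#' @return Object of class `pc_scores`: `scores` (subjects x k),
#'   `explained_variance`, `dropped_snps`.
#' @export
compute_genotype_pcs <- function(genotypes, k = 10) {
  x <- genotypes$values
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped), " monomorphic SNP(s) from PCA: ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (k == 0 || ncol(x) == 0) {
    return(structure(list(scores = matrix(numeric(0), nrow(x), 0),
                          explained_variance = numeric(0),
                          dropped_snps = dropped),
                     class = "pc_scores"))
  }
  xs <- scale(x)
  sv <- svd(xs)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) stop("k exceeds the rank of the genotype matrix (", rank, ")")
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(x)
  structure(list(scores = scores,
                 explained_variance = sv$d[seq_len(k)]^2 / (nrow(x) - 1),
                 dropped_snps = dropped),
            class = "pc_scores")
}

#' Greedy LD pruning of a genotype matrix
#'
#' Keeps SNPs in panel order, dropping any SNP whose squared correlation
#' with an already-kept SNP exceeds `r2_threshold`. Principal components
#' meant to capture ancestry are computed on the pruned panel so that
#' high-LD pairs do not masquerade as structure axes.
#'
#' @param genotypes A `genotype_matrix`.
#' @param r2_threshold Pairwise squared-correlation ceiling (default 0.2).
#' @return A `genotype_matrix` restricted to the pruned SNP set.
#' @export
prune_by_ld <- function(genotypes, r2_threshold = 0.2) {
  x <- genotypes$values
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  keep <- integer(0)
  for (j in seq_len(ncol(x))) {
    if (stats::sd(x[, j]) == 0) next
    r2 <- if (length(keep))
      stats::cor(x[, j], x[, keep, drop = FALSE])^2 else 0
    if (all(r2 <= r2_threshold)) keep <- c(keep, j)
  }
  structure(list(values = genotypes$values[, keep, drop = FALSE],
                 snps = genotypes$snps[
                   genotypes$snps$rsid %in% colnames(genotypes$values)[keep],
                   , drop = FALSE],
                 subject_ids = genotypes$subject_ids),
            class = "genotype_matrix")
}

# assemble intercept + covariate dummy design from a phenotype table,
# dropping aliased columns with a message
covariate_design <- function(phenotypes, covariates) {
  missing_cov <- setdiff(covariates, names(phenotypes))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  if (!length(covariates))
    return(matrix(1, nrow(phenotypes), 1,
                  dimnames = list(NULL, "(Intercept)")))
  dat <- phenotypes[covariates]
  for (nm in names(dat))
    if (is.character(dat[[nm]])) dat[[nm]] <- factor(dat[[nm]])
  constant <- vapply(dat, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant covariate column(s): ",
            paste(names(dat)[constant], collapse = ", "))
    dat <- dat[!constant]
    if (!length(dat))
      return(matrix(1, nrow(phenotypes), 1,
                    dimnames = list(NULL, "(Intercept)")))
  }
  x <- stats::model.matrix(stats::reformulate(names(dat)), data = dat)
  xr <- drop_aliased(x)
  if (!is.null(attr(xr, "dropped")))
    message("dropping aliased covariate column(s): ",
            paste(attr(xr, "dropped"), collapse = ", "))
  xr
}

#' First-stage marginal per-SNP association scan
#'
#' For each SNP, fits a logistic regression of case (1) versus control (0)
#' status on the minor-allele count plus confounders, matching variables,
#' randomization assignments and genotype principal components (all supplied
#' through `covariates`/`pcs`). Genotypes are oriented so the modeled allele
#' is the minor allele in the analyzed sample; analysis is complete-case on
#' per-SNP genotype missingness. SNPs with a separated or non-converged fit
#' carry `NA` p-values and never pass.
#'
#' @param phenotypes data.frame with `subject_id`, a 0/1 `case` column and
#'   the covariate columns.
#' @param genotypes `genotype_matrix` covering at least the phenotype
#'   subjects.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param pcs Optional `pc_scores` aligned to the genotype matrix.
#' @param threshold Two-sided p-value threshold for passing to stage 2.
#' @param test `"wald"` (default) or `"lrt"` for the per-SNP p-value.
#' @return data.frame of class `stage1_result`, ranked by p-value: `rsid`,
#'   `beta`, `se`, `or_`, `p_value`, `n_used`, `passes`, `flipped`.
#' @export
marginal_scan <- function(phenotypes, genotypes, covariates = character(),
                          pcs = NULL, threshold = 0.05,
                          test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!"case" %in% names(phenotypes)) stop("phenotypes must have a case column")
  gidx <- match(phenotypes$subject_id, genotypes$subject_ids)
  if (anyNA(gidx)) stop("phenotype subjects missing from genotype matrix")
  gmat <- genotypes$values[gidx, , drop = FALSE]
  base <- covariate_design(phenotypes, covariates)
  if (!is.null(pcs)) {
    stopifnot(inherits(pcs, "pc_scores"))
    if (ncol(pcs$scores)) {
      pidx <- match(phenotypes$subject_id, rownames(pcs$scores))
      if (anyNA(pidx)) stop("phenotype subjects missing from PC scores")
      base <- cbind(base, pcs$scores[pidx, , drop = FALSE])
    }
  }
  y <- as.numeric(phenotypes$case)
  rows <- lapply(colnames(gmat), function(rs) {
    g <- as.numeric(gmat[, rs])
    ok <- !is.na(g)
    g <- g[ok]
    flipped <- FALSE
    if (length(g) && mean(g) / 2 > 0.5) { g <- 2 - g; flipped <- TRUE }
    out <- data.frame(rsid = rs, beta = NA_real_, se = NA_real_,
                      or_ = NA_real_, p_value = NA_real_,
                      n_used = sum(ok), passes = FALSE, flipped = flipped,
                      stringsAsFactors = FALSE)
    if (stats::var(g) == 0 || length(unique(y[ok])) < 2) return(out)
    x <- cbind(base[ok, 1, drop = FALSE], G = g,
               base[ok, -1, drop = FALSE])
    fit <- tryCatch(fit_logistic(x, y[ok]), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(out)
    beta <- fit$coefficients[["G"]]
    se <- sqrt(fit$covariance["G", "G"])
    p <- if (test == "wald") {
      2 * stats::pnorm(-abs(beta / se))
    } else {
      red <- tryCatch(fit_logistic(x[, colnames(x) != "G", drop = FALSE],
                                   y[ok]), error = function(e) NULL)
      if (is.null(red) || !red$converged) NA_real_
      else likelihood_ratio_test(fit, red, 1)$p_value
    }
    out$beta <- beta; out$se <- se; out$or_ <- exp(beta); out$p_value <- p
    out$passes <- isTRUE(p < threshold)
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, method = "radix", na.last = TRUE), ]
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  attr(res, "test") <- test
  class(res) <- c("stage1_result", "data.frame")
  res
}

#' Build the matched case-control analysis table
#'
#' One row per matched subject, combining case status, pair identifier,
#' covariates, randomization assignments coded 0 for non-members, and
#' (optionally) genotype dosage columns.
#'
#' @param subjects,outcomes,matched Cohort tables and a `matched_set`.
#' @param genotypes Optional `genotype_matrix`; its columns are appended.
#' @return data.frame with `subject_id`, `case`, `pair_id`, subject
#'   covariates, `z_ht0`, `z_dm0`, `z_cad0` and genotype columns.
#' @export
build_cc_data <- function(subjects, outcomes, matched, genotypes = NULL) {
  stopifnot(inherits(matched, "matched_set"))
  ids <- c(matched$pairs$case_id, matched$pairs$control_id)
  pair_id <- rep(seq_len(nrow(matched$pairs)), 2)
  case <- rep(c(1, 0), each = nrow(matched$pairs))
  idx <- match(ids, subjects$subject_id)
  cc <- subjects[idx, ]
  cc$case <- case
  cc$pair_id <- pair_id
  oidx <- match(ids, outcomes$subject_id)
  cc$subtype <- outcomes$subtype[oidx]
  cc$z_ht0 <- ifelse(is.na(cc$z_ht), 0, cc$z_ht)
  cc$z_dm0 <- ifelse(is.na(cc$z_dm), 0, cc$z_dm)
  cc$z_cad0 <- ifelse(is.na(cc$z_cad), 0, cc$z_cad)
  if (!is.null(genotypes)) {
    gidx <- match(ids, genotypes$subject_ids)
    if (anyNA(gidx)) stop("matched subjects missing from genotype matrix")
    cc <- cbind(cc, as.data.frame(genotypes$values[gidx, , drop = FALSE]))
  }
  rownames(cc) <- NULL
  cc
}

#' Default stage-1 adjustment covariates
#'
#' Confounders, matching variables and randomization assignments used by the
#' marginal screen when run through the pipeline.
#' @return Character vector of column names.
#' @export
default_stage1_covariates <- function() {
  c("smoking", "physical_functioning", "diabetes", "hypertension",
    "aspirin", "statin",
    "age", "ethnicity", "cohort", "in_ht", "in_dm", "in_cad",
    "hysterectomy", "prevalent_stroke",
    "z_ht0", "z_dm0", "z_cad0")
}
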