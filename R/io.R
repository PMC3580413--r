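# Readers for the tabular phenotype/genotype formats the pipeline accepts,
# plus an optional VCF genotype reader.

#' Read a phenotype/covariate table
#'
#' Tab- or comma-separated, one row per subject. `subject_id` and `stroke`
#' are mandatory; any further columns (covariates, trial memberships,
#' randomization indicators, `subtype`, `event_year`) are carried through.
#'
#' @param path File path.
#' @return data.frame with logical `stroke`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  phen <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("subject_id", "stroke"))
    if (!col %in% names(phen)) stop("missing mandatory column: ", col)
  phen$stroke <- as.logical(phen$stroke)
  phen
}

#' Read a genotype matrix
#'
#' TSV/CSV layout: first column `subject_id`, remaining columns one rsid
#' each, values 0/1/2/NA (minor-allele counts). VCF input (requires the
#' VariantAnnotation package) converts GT fields to ALT-allele counts and
#' re-orients any SNP whose ALT allele is the *major* allele in the sample
#' so stored counts are always of the minor allele (a message flags each
#' flip); unknown or missing genotypes become NA.
#'
#' @param path File path.
#' @param format `"tsv"` (also covers CSV) or `"vcf"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!"subject_id" %in% names(tab))
      stop("missing mandatory column: subject_id")
    ids <- as.character(tab$subject_id)
    vals <- as.matrix(tab[setdiff(names(tab), "subject_id")])
    storage.mode(vals) <- "integer"
    bad <- !is.na(vals) & !(vals %in% 0:2)
    if (any(bad)) stop("genotype values must be 0/1/2/NA")
    rownames(vals) <- ids
    snps <- data.frame(rsid = colnames(vals), stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("VCF input requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    count_alt <- function(s) {
      if (s %in% c(".", "./.", ".|.")) return(NA_integer_)
      alleles <- strsplit(s, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(alleles != "0")
    }
    vals <- t(apply(gt, 1, function(row)
      vapply(as.character(row), count_alt, integer(1))))
    if (ncol(gt) == 1) vals <- t(vals)
    vals <- t(vals)                      # subjects x SNPs
    rownames(vals) <- colnames(gt)
    colnames(vals) <- rownames(gt)
    # orient to the minor allele by sample frequency
    for (j in seq_len(ncol(vals))) {
      f <- mean(vals[, j], na.rm = TRUE) / 2
      if (is.finite(f) && f > 0.5) {
        vals[, j] <- 2L - vals[, j]
        message("ALT is the major allele for ", colnames(vals)[j],
                "; counts flipped to the minor allele")
      }
    }
    snps <- data.frame(rsid = colnames(vals), stringsAsFactors = FALSE)
  }
  structure(list(values = vals, snps = snps, subject_ids = rownames(vals)),
            class = "genotype_matrix")
}

# consistent TSV writer (deterministic byte output)
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
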