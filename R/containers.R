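#' Genotype dosage panel
#'
#' A light container for imputed genotype dosages: a samples x SNPs numeric
#' matrix with values in \[0, 2\] plus a SNP annotation table. Minor allele
#' frequency is computed from the dosages and stored alongside.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns. Row and
#'   column names give sample and SNP IDs.
#' @param snps Data frame with columns `snp`, `chrom`, `pos` (1-based),
#'   one row per dosage column, in column order.
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (matrix), `snps` (tibble with an added `maf` column) and `samples`.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  snps <- tibble::as_tibble(snps)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)))
  if (ncol(dosages) != nrow(snps)) {
    abort("`snps` must have one row per dosage column.")
  }
  if (anyDuplicated(snps$snp)) abort("duplicate SNP IDs are not allowed.")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie in [0, 2].")
  colnames(dosages) <- snps$snp
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  }
  af <- colMeans(dosages, na.rm = TRUE) / 2
  snps$maf <- pmin(af, 1 - af)
  structure(
    list(dosages = dosages, snps = snps, samples = rownames(dosages)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (MAF %.3f-%.3f)\n",
    nrow(x$dosages), ncol(x$dosages), min(x$snps$maf), max(x$snps$maf)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Drop SNPs below a minor-allele-frequency threshold
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Exclusive lower MAF bound (default 0.05).
#' @return A filtered `geno_matrix`.
#' @export
filter_maf <- function(geno, maf_min = 0.05) {
  keep <- geno$snps$maf > maf_min
  genotype_matrix(geno$dosages[, keep, drop = FALSE], geno$snps[keep, 1:3])
}

#' Subset a genotype panel by samples and/or SNPs
#'
#' @param geno A [genotype_matrix()].
#' @param samples,snps Character vectors of IDs to keep (default all).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  samples <- samples %||% geno$samples
  snps <- snps %||% geno$snps$snp
  keep <- geno$snps$snp %in% snps
  genotype_matrix(
    geno$dosages[samples, keep, drop = FALSE],
    geno$snps[keep, c("snp", "chrom", "pos")]
  )
}

#' Molecular phenotype panel
#'
#' Samples x probes matrix of molecular phenotypes (expression probes or
#' CpG methylation) with per-probe genomic anchor positions and a scale tag
#' recording the transformation applied.
#'
#' @param values Numeric matrix, samples in rows, probes in columns.
#' @param probes Data frame with columns `probe`, `chrom`, `pos` (1-based
#'   anchor: TSS for expression probes, CpG coordinate for methylation).
#' @param scale One of `"raw-expression"`, `"log-expression"`,
#'   `"raw-methylation"`, `"logit-methylation"`.
#' @return An object of class `pheno_matrix`.
#' @export
phenotype_matrix <- function(values,
                             probes,
                             scale = c("raw-expression", "log-expression",
                                       "raw-methylation", "logit-methylation")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  probes <- tibble::as_tibble(probes)
  stopifnot(all(c("probe", "chrom", "pos") %in% names(probes)))
  if (ncol(values) != nrow(probes)) {
    abort("`probes` must have one row per value column.")
  }
  colnames(values) <- probes$probe
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  structure(
    list(values = values, probes = probes, scale = scale,
         samples = rownames(values)),
    class = "pheno_matrix"
  )
}

#' @export
print.pheno_matrix <- function(x, ...) {
  cat(sprintf(
    "<pheno_matrix> %d samples x %d probes [%s]\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  invisible(x)
}

#' @export
dim.pheno_matrix <- function(x) dim(x$values)

#' Subset a phenotype panel by samples and/or probes
#'
#' @param pheno A [phenotype_matrix()].
#' @param samples,probes Character vectors of IDs to keep (default all).
#' @return A `pheno_matrix`.
#' @export
subset_pheno <- function(pheno, samples = NULL, probes = NULL) {
  samples <- samples %||% pheno$samples
  probes <- probes %||% pheno$probes$probe
  keep <- pheno$probes$probe %in% probes
  phenotype_matrix(
    pheno$values[samples, keep, drop = FALSE],
    pheno$probes[keep, c("probe", "chrom", "pos")],
    scale = pheno$scale
  )
}
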