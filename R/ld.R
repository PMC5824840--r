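#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two dosage vectors on complete
#' cases (composite LD on imputed dosages, not phased haplotypes).
#'
#' @param a,b Numeric dosage vectors of equal length (>= 3).
#' @return r-squared in \[0, 1\], or `NA` with a warning if either vector
#'   has zero variance.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) abort("dosage vectors must have equal length.")
  cc <- complete.cases(a, b)
  if (sum(cc) < 3) abort("need at least 3 complete observations.")
  a <- a[cc]; b <- b[cc]
  if (var(a) == 0 || var(b) == 0) {
    warn("zero dosage variance; r-squared undefined.")
    return(NA_real_)
  }
  min(cor(a, b)^2, 1)
}

#' LD score of a lead SNP
#'
#' Sum of pairwise r-squared between the lead SNP and every SNP whose
#' position is within `window` bp of it, including the self term (r² = 1),
#' following the LD-score convention. SNPs with undefined r² (zero
#' variance) are excluded from the sum.
#'
#' @param geno A [genotype_matrix()].
#' @param lead_snp SNP ID present in `geno`.
#' @param window Window in bp (default 500000).
#' @return A one-row tibble: `snp`, `window`, `n_snps` (SNPs in window,
#'   self included), `ld_score`.
#' @export
ld_score <- function(geno, lead_snp, window = 5e5) {
  stopifnot(inherits(geno, "geno_matrix"))
  i <- match(lead_snp, geno$snps$snp)
  if (is.na(i)) abort(sprintf("lead SNP '%s' not found.", lead_snp))
  here <- geno$snps$chrom == geno$snps$chrom[i] &
    abs(geno$snps$pos - geno$snps$pos[i]) <= window
  others <- setdiff(which(here), i)
  g0 <- geno$dosages[, i]
  score <- 1
  if (length(others)) {
    r2 <- suppressWarnings(
      vapply(others, function(j) ld_r2(g0, geno$dosages[, j]), numeric(1))
    )
    score <- score + sum(r2, na.rm = TRUE)
  }
  tibble::tibble(snp = lead_snp, window = window,
                 n_snps = length(others) + 1L, ld_score = score)
}

#' Greedy LD pruning by significance
#'
#' Visits SNPs in ascending P-value order and keeps a SNP iff its
#' r-squared with every already-kept SNP is `<= threshold` (strict `>`
#' triggers removal), so of each violating pair the more significant SNP
#' survives. Output is order-stable for a given input.
#'
#' @param snp_stats Tibble with columns `snp` and `p`.
#' @param geno A [genotype_matrix()] containing all listed SNPs.
#' @param threshold r-squared threshold (default 0.3).
#' @return The kept rows of `snp_stats`, in visit (ascending-P) order.
#' @export
ld_prune <- function(snp_stats, geno, threshold = 0.3) {
  stopifnot(all(c("snp", "p") %in% names(snp_stats)))
  ord <- order(snp_stats$p)
  kept <- integer(0)
  for (i in ord) {
    gi <- geno$dosages[, snp_stats$snp[i]]
    ok <- TRUE
    for (j in kept) {
      r2 <- suppressWarnings(ld_r2(gi, geno$dosages[, snp_stats$snp[j]]))
      if (!is.na(r2) && r2 > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  snp_stats[kept, ]
}
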