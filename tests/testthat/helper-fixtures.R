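# shared fixture builders: everything is generated in code at test time

# small genotype panel with independent SNPs
toy_geno <- function(n = 50, m = 5, maf = 0.3, seed = 1, spacing = 1000) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, maf), n, m)
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  genotype_matrix(
    dos,
    tibble::tibble(snp = sprintf("snp%02d", seq_len(m)), chrom = "1",
                   pos = 1e6 + (seq_len(m) - 1) * spacing)
  )
}

toy_pheno <- function(values, pos, scale = "log-expression", chrom = "1") {
  values <- as.matrix(values)
  phenotype_matrix(
    values,
    tibble::tibble(probe = colnames(values) %||%
                     sprintf("pr%02d", seq_len(ncol(values))),
                   chrom = chrom, pos = pos),
    scale = scale
  )
}

# the printed QTL counts used for prior derivation throughout the tests
PRIOR_COUNTS <- list(n_eqtl = 5022, n_meqtl = 29472, n_snps = 8639940)

paper_priors <- function(f = 0.75) {
  derive_priors(PRIOR_COUNTS$n_eqtl, PRIOR_COUNTS$n_meqtl,
                PRIOR_COUNTS$n_snps, f)
}

# summary stats for one simulated region, standardized for ABF input
region_summary_stats <- function(ds, trait = c("expression", "methylation"),
                                 cpg = "cpg_001") {
  trait <- match.arg(trait)
  if (trait == "expression") {
    samp <- c(ds$panels$eqtl)
    g <- subset_geno(ds$genotypes, samples = samp)
    ph <- subset_pheno(ds$expression, samples = samp)
  } else {
    g <- subset_geno(ds$genotypes, samples = ds$panels$meqtl)
    ph <- subset_pheno(ds$methylation, probes = cpg)
  }
  a <- cis_scan(g, ph)
  st <- standardize_effects(a$beta, a$se,
                            g$snps$maf[match(a$snp, g$snps$snp)], a$n)
  st$snp <- a$snp
  st$pos <- a$snp_pos
  st
}
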