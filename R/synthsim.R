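#' Design for a SNP-mediator-outcome trio simulation
#'
#' Describes one simulated trio: a biallelic SNP dosage `g`, a molecular
#' phenotype `x` receiving a linear SNP effect with standard-normal noise,
#' and a downstream phenotype `y` receiving a linear effect of `x` with
#' standard-normal noise. The SNP effect is parameterised by the fraction
#' of mediator variance it explains; the implied raw-scale coefficient is
#' `beta_gx = sqrt(v / ((1 - v) * var(g)))` with `var(g) = 2*maf*(1-maf)`.
#'
#' @param n_samples Number of individuals (default 316, the size of a
#'   typical overlap panel with both expression and methylation data).
#' @param maf Minor allele frequency of the simulated SNP, in (0, 0.5].
#' @param var_explained Fraction of mediator variance explained by the SNP,
#'   in (0, 1); study grids span 0.01-0.75.
#' @param beta_xy Effect of the mediator on the outcome; grids span 0.01-0.75.
#' @param mediator_role `"X_mediates"` (default) or `"Y_mediates"`: which
#'   variable is treated as the mediator, and therefore receives any
#'   measurement error.
#' @param measurement_error_sd Standard deviation of Gaussian measurement
#'   error added to the designated mediator (default 0: error-free).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `trio_design` list.
#' @export
trio_design <- function(n_samples = 316,
                        maf = 0.3,
                        var_explained = 0.1,
                        beta_xy = 0.3,
                        mediator_role = c("X_mediates", "Y_mediates"),
                        measurement_error_sd = 0,
                        seed = NULL) {
  mediator_role <- match.arg(mediator_role)
  if (n_samples < 3) abort("`n_samples` must be at least 3.")
  if (maf <= 0 || maf > 0.5) abort("`maf` must lie in (0, 0.5].")
  if (var_explained <= 0 || var_explained >= 1) {
    abort("`var_explained` must lie strictly in (0, 1).")
  }
  if (measurement_error_sd < 0) abort("`measurement_error_sd` must be >= 0.")
  structure(
    list(n_samples = as.integer(n_samples), maf = maf,
         var_explained = var_explained, beta_xy = beta_xy,
         mediator_role = mediator_role,
         measurement_error_sd = measurement_error_sd, seed = seed),
    class = "trio_design"
  )
}

#' Simulate a SNP-mediator-outcome trio
#'
#' Draws dosages as the sum of two Hardy-Weinberg Bernoulli haplotypes,
#' then `x = beta_gx * g + e` and `y = beta_xy * x + r` with `e`, `r`
#' standard normal. `beta_gx` is set so the population fraction of `var(x)`
#' explained by the SNP equals `var_explained` (the dosage is used on its
#' raw 0-2 scale). Measurement error, if requested, is added to the
#' designated mediator after the causal chain is generated, so it attenuates
#' mediation estimates without altering the true causal effects.
#'
#' @param design A [trio_design()].
#' @return A tibble of class `trio_dataset` with columns `g`, `x`, `y` and
#'   the design stored in attribute `truth`.
#' @export
simulate_trio <- function(design) {
  stopifnot(inherits(design, "trio_design"))
  if (!is.null(design$seed)) set.seed(derive_seed(design$seed, "trio"))
  n <- design$n_samples
  g <- rbinom(n, 1L, design$maf) + rbinom(n, 1L, design$maf)
  v <- design$var_explained
  var_g <- 2 * design$maf * (1 - design$maf)
  beta_gx <- sqrt(v / ((1 - v) * var_g))
  x <- beta_gx * g + rnorm(n)
  y <- design$beta_xy * x + rnorm(n)
  if (design$measurement_error_sd > 0) {
    err <- rnorm(n, sd = design$measurement_error_sd)
    if (design$mediator_role == "X_mediates") x <- x + err else y <- y + err
  }
  out <- tibble::tibble(g = as.numeric(g), x = x, y = y)
  attr(out, "truth") <- design
  attr(out, "beta_gx") <- beta_gx
  class(out) <- c("trio_dataset", class(out))
  out
}

#' Design for a multi-SNP cis region with known causal structure
#'
#' Describes a simulated cis window: `n_snps` dosage SNPs organised into
#' LD blocks, one expression probe, and `n_cpgs` CpG sites, generated under
#' one of five causal models mirroring the co-localization hypotheses:
#' `NULL` (no genetic effect), `PLEIOTROPY` (one SNP affects expression and
#' methylation independently), `SME` (SNP -> methylation -> expression),
#' `SEM` (SNP -> expression -> methylation), and `DISTINCT` (different
#' causal SNPs for the two traits).
#'
#' @param n_snps Number of SNPs in the region.
#' @param block_structure List of `c(size, r)` pairs: block length and the
#'   target within-block dosage correlation (in \[0, 1)); a single block of
#'   `r = 1` duplicates its SNPs. Sizes must sum to `n_snps`.
#' @param maf Target minor allele frequency (scalar or per-SNP vector).
#' @param causal_model One of `"NULL"`, `"PLEIOTROPY"`, `"SME"`, `"SEM"`,
#'   `"DISTINCT"`.
#' @param causal_snp_indices One SNP index (shared models) or two distinct
#'   indices (`DISTINCT`).
#' @param var_g_e,var_g_m Fraction of expression / primary-CpG variance
#'   explained by the causal SNP (where the model includes that edge).
#' @param beta_path Coefficient of the mediating edge (M -> E under SME,
#'   E -> M under SEM).
#' @param n_cpgs Number of CpG sites; the first is the primary CpG.
#' @param cpg_signs Sign (+1/-1) of each CpG's genetic or mediated effect;
#'   default alternates, giving anti-correlated CpG clusters.
#' @param noise_sd_e,noise_sd_m Residual standard deviations.
#' @param n_eqtl,n_meqtl,n_overlap Panel sizes: the eQTL and meQTL panels
#'   are disjoint (a requirement of co-localization on two summary-statistic
#'   sets); `n_overlap` members of the meQTL panel also carry expression and
#'   form the causal-analysis panel. Defaults 992/337/316 mirror a typical
#'   two-platform cohort split.
#' @param snp_spacing_bp Distance between adjacent simulated SNPs (default
#'   1000 bp).
#' @param seed Integer seed or `NULL`.
#' @return A `region_design` list.
#' @export
region_design <- function(n_snps = 50,
                          block_structure = list(c(n_snps, 0.8)),
                          maf = 0.3,
                          causal_model = c("NULL", "PLEIOTROPY", "SME",
                                           "SEM", "DISTINCT"),
                          causal_snp_indices = 1L,
                          var_g_e = 0.1,
                          var_g_m = 0.1,
                          beta_path = 0.5,
                          n_cpgs = 3,
                          cpg_signs = NULL,
                          noise_sd_e = 1,
                          noise_sd_m = 1,
                          n_eqtl = 992,
                          n_meqtl = 337,
                          n_overlap = min(316, n_meqtl),
                          snp_spacing_bp = 1000,
                          seed = NULL) {
  causal_model <- match.arg(causal_model)
  sizes <- vapply(block_structure, function(b) b[1], numeric(1))
  rs <- vapply(block_structure, function(b) b[2], numeric(1))
  if (sum(sizes) != n_snps) {
    abort("block sizes must sum to `n_snps` (configuration error).")
  }
  if (any(rs < 0 | rs > 1)) abort("block correlations must lie in [0, 1].")
  idx <- as.integer(causal_snp_indices)
  if (any(idx < 1 | idx > n_snps)) abort("causal indices must be in 1..n_snps.")
  if (causal_model == "DISTINCT" && length(unique(idx)) != 2L) {
    abort("DISTINCT requires two distinct causal SNP indices.")
  }
  if (n_overlap > n_meqtl) abort("`n_overlap` cannot exceed `n_meqtl`.")
  maf <- rep_len(maf, n_snps)
  if (any(maf <= 0 | maf > 0.5)) abort("`maf` must lie in (0, 0.5].")
  cpg_signs <- cpg_signs %||% rep_len(c(1, -1), n_cpgs)
  if (length(cpg_signs) != n_cpgs) abort("`cpg_signs` must have length n_cpgs.")
  structure(
    list(n_snps = as.integer(n_snps), block_structure = block_structure,
         maf = maf, causal_model = causal_model, causal_snp_indices = idx,
         var_g_e = var_g_e, var_g_m = var_g_m, beta_path = beta_path,
         n_cpgs = as.integer(n_cpgs), cpg_signs = cpg_signs,
         noise_sd_e = noise_sd_e, noise_sd_m = noise_sd_m,
         n_eqtl = as.integer(n_eqtl), n_meqtl = as.integer(n_meqtl),
         n_overlap = as.integer(n_overlap),
         snp_spacing_bp = snp_spacing_bp, seed = seed),
    class = "region_design"
  )
}

# calibrate the latent-Gaussian correlation so that the realized
# allele-indicator correlation matches the requested block correlation;
# an uncalibrated threshold model attenuates r for maf != 0.5
latent_rho_cache <- new.env(parent = emptyenv())

latent_rho <- function(r, maf) {
  if (r <= 0) return(0)
  if (r >= 1) return(1)
  key <- sprintf("%.6f_%.6f", r, maf)
  hit <- latent_rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  t <- qnorm(maf)
  target <- r * maf * (1 - maf) + maf^2
  f <- function(rho) {
    mvtnorm::pmvnorm(upper = c(t, t),
                     corr = matrix(c(1, rho, rho, 1), 2)) - target
  }
  rho <- uniroot(f, c(max(r - 0.2, 0), 0.999999), tol = 1e-8)$root
  latent_rho_cache[[key]] <- rho
  rho
}

#' Simulate block-LD genotype dosages
#'
#' Dosages are sums of two independent haplotypes. Within a block, each
#' haplotype's alleles are derived by thresholding a shared latent Gaussian
#' factor, with the latent correlation calibrated so that realized pairwise
#' allele correlation matches the requested block correlation (hence
#' pairwise dosage r-squared approximates the requested correlation
#' squared). Blocks are mutually independent. SNPs are placed on chromosome
#' "1" at fixed spacing.
#'
#' @param design A [region_design()].
#' @param n_samples Number of individuals (default: the design's total
#'   panel size `n_eqtl + n_meqtl`).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(design, n_samples = NULL) {
  stopifnot(inherits(design, "region_design"))
  n <- n_samples %||% (design$n_eqtl + design$n_meqtl)
  if (!is.null(design$seed)) set.seed(derive_seed(design$seed, "genotypes"))
  sizes <- vapply(design$block_structure, function(b) b[1], numeric(1))
  rs <- vapply(design$block_structure, function(b) b[2], numeric(1))
  dos <- matrix(0, n, design$n_snps)
  col0 <- 0L
  for (b in seq_along(sizes)) {
    m <- as.integer(sizes[b])
    cols <- col0 + seq_len(m)
    maf_b <- design$maf[cols]
    for (hap in 1:2) {
      z0 <- rnorm(n)
      for (j in seq_len(m)) {
        rho <- latent_rho(rs[b], maf_b[j])
        z <- if (rho >= 1) z0 else
          sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(n)
        dos[, cols[j]] <- dos[, cols[j]] + (z < qnorm(maf_b[j]))
      }
    }
    col0 <- col0 + m
  }
  snps <- tibble::tibble(
    snp = sprintf("snp_%04d", seq_len(design$n_snps)),
    chrom = "1",
    pos = 1e6 + (seq_len(design$n_snps) - 1L) * design$snp_spacing_bp
  )
  rownames(dos) <- sprintf("S%04d", seq_len(n))
  genotype_matrix(dos, snps)
}

# raw-dosage-scale coefficient giving population variance explained v
# when the residual SD is `noise_sd`
beta_from_varexp <- function(v, maf, noise_sd = 1) {
  if (v <= 0) return(0)
  var_g <- 2 * maf * (1 - maf)
  sqrt(v * noise_sd^2 / ((1 - v) * var_g))
}

#' Simulate a cis region with expression and methylation phenotypes
#'
#' Generates genotypes for the full cohort, then expression and methylation
#' (on the logit scale) under the design's causal model. The cohort is then
#' split into a disjoint eQTL panel (expression only) and meQTL panel
#' (methylation; its first `n_overlap` members also carry expression),
#' mirroring two non-overlapping profiling panels with a causal-analysis
#' overlap. Methylation is also exposed as back-transformed beta values.
#'
#' @param design A [region_design()].
#' @return A list of class `region_dataset` with elements `genotypes`
#'   (full-cohort [genotype_matrix()]), `expression` and `methylation`
#'   ([phenotype_matrix()] objects restricted to the samples observing each
#'   trait; methylation on the logit scale), `methylation_beta` (matrix of
#'   beta values in (0,1)), `panels` (sample-ID lists `eqtl`, `meqtl`,
#'   `overlap`), and `truth` (the design).
#' @export
simulate_region <- function(design) {
  stopifnot(inherits(design, "region_design"))
  n <- design$n_eqtl + design$n_meqtl
  geno <- simulate_genotypes(design, n_samples = n)
  if (!is.null(design$seed)) set.seed(derive_seed(design$seed, "phenotypes"))

  idx <- design$causal_snp_indices
  g_e <- geno$dosages[, idx[1]]
  g_m <- geno$dosages[, if (design$causal_model == "DISTINCT") idx[2] else idx[1]]
  maf_e <- geno$snps$maf[idx[1]]
  maf_m <- geno$snps$maf[if (design$causal_model == "DISTINCT") idx[2] else idx[1]]
  b_e <- beta_from_varexp(design$var_g_e, maf_e, design$noise_sd_e)
  b_m <- beta_from_varexp(design$var_g_m, maf_m, design$noise_sd_m)
  s <- design$cpg_signs
  k <- design$n_cpgs

  e_noise <- rnorm(n, sd = design$noise_sd_e)
  m_noise <- matrix(rnorm(n * k, sd = design$noise_sd_m), n, k)

  M <- matrix(0, n, k)
  expr <- switch(
    design$causal_model,
    "NULL" = {
      M <- m_noise
      e_noise
    },
    "PLEIOTROPY" = {
      M <- outer(b_m * g_m, s) + m_noise
      b_e * g_e + e_noise
    },
    "SME" = {
      M <- outer(b_m * g_m, s) + m_noise
      design$beta_path * M[, 1] + e_noise
    },
    "SEM" = {
      e <- b_e * g_e + e_noise
      M <- outer(design$beta_path * e, s) + m_noise
      e
    },
    "DISTINCT" = {
      M <- outer(b_m * g_m, s) + m_noise
      b_e * g_e + e_noise
    }
  )

  samples <- geno$samples
  meqtl_ids <- samples[seq_len(design$n_meqtl)]
  eqtl_ids <- samples[design$n_meqtl + seq_len(design$n_eqtl)]
  overlap_ids <- meqtl_ids[seq_len(design$n_overlap)]
  expr_ids <- c(overlap_ids, eqtl_ids)

  causal_pos <- geno$snps$pos[idx[1]]
  span <- max(geno$snps$pos) - min(geno$snps$pos)
  expr_probes <- tibble::tibble(probe = "eprobe_1", chrom = "1",
                                pos = causal_pos + 5000)
  cpg_pos <- round(causal_pos + seq(-span / 4, span / 4, length.out = k))
  cpg_probes <- tibble::tibble(probe = sprintf("cpg_%03d", seq_len(k)),
                               chrom = "1", pos = cpg_pos)

  expr_mat <- matrix(expr, n, 1, dimnames = list(samples, "eprobe_1"))
  colnames(M) <- cpg_probes$probe
  rownames(M) <- samples

  out <- list(
    genotypes = geno,
    expression = phenotype_matrix(expr_mat[expr_ids, , drop = FALSE],
                                  expr_probes, scale = "log-expression"),
    methylation = phenotype_matrix(M[meqtl_ids, , drop = FALSE],
                                   cpg_probes, scale = "logit-methylation"),
    methylation_beta = plogis(M[meqtl_ids, , drop = FALSE]),
    panels = list(eqtl = eqtl_ids, meqtl = meqtl_ids, overlap = overlap_ids),
    truth = design
  )
  class(out) <- "region_dataset"
  out
}

#' @export
print.region_dataset <- function(x, ...) {
  cat(sprintf(
    "<region_dataset> model %s: %d SNPs, %d CpGs; panels e=%d m=%d overlap=%d\n",
    x$truth$causal_model, x$truth$n_snps, x$truth$n_cpgs,
    length(x$panels$eqtl), length(x$panels$meqtl), length(x$panels$overlap)
  ))
  invisible(x)
}
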