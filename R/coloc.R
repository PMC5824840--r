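#' Co-localization priors from observed QTL counts
#'
#' Converts the numbers of independent eSNPs and meSNPs among all tested
#' SNPs into per-SNP prior probabilities. With `P_e` the probability a SNP
#' is a causal eSNP and `P_m` for meSNPs, and `f` the prior probability
#' that a causal eSNP is also a causal meSNP:
#' `p12 = f * P_e`, `p1 = P_e - p12`, `p2 = P_m - p12`.
#'
#' @param n_indep_eqtl,n_indep_meqtl Counts of independent eSNPs / meSNPs.
#' @param n_snps_total Total SNPs tested genome-wide.
#' @param f Prior probability a causal eSNP is a causal meSNP, in (0, 1).
#' @return A one-row tibble of class `coloc_priors`: `f`, `p_e`, `p_m`,
#'   `p1`, `p2`, `p12`.
#' @export
derive_priors <- function(n_indep_eqtl, n_indep_meqtl, n_snps_total, f) {
  if (any(c(n_indep_eqtl, n_indep_meqtl, n_snps_total) <= 0)) {
    abort("counts must be positive.")
  }
  if (f <= 0 || f >= 1) abort("`f` must lie in (0, 1).")
  p_e <- n_indep_eqtl / n_snps_total
  p_m <- n_indep_meqtl / n_snps_total
  p12 <- f * p_e
  p1 <- p_e - p12
  p2 <- p_m - p12
  if (p2 <= 0) {
    abort("`f` too large relative to the meQTL rate: p2 would be non-positive.")
  }
  out <- tibble::tibble(f = f, p_e = p_e, p_m = p_m, p1 = p1, p2 = p2,
                        p12 = p12)
  class(out) <- c("coloc_priors", class(out))
  out
}

#' Log approximate Bayes factor for a single SNP association
#'
#' Wakefield-style ABF comparing a normal effect prior N(0, W²) against
#' the point null, computed from the effect estimate and its standard
#' error: with `V = se²`, `z = beta / se`, `r = W² / (W² + V)`,
#' `log ABF = 0.5 * log(1 - r) + 0.5 * z² * r`.
#'
#' @param beta,se Effect estimates and standard errors (vectorized).
#' @param W Prior effect-size standard deviation on the analysis scale
#'   (default 0.15, the standard choice for standardized quantitative
#'   traits).
#' @return Numeric vector of log ABFs.
#' @export
log_abf <- function(beta, se, W = 0.15) {
  if (any(se <= 0)) abort("standard errors must be positive.")
  if (W < 0) abort("`W` must be non-negative.")
  V <- se^2
  z <- beta / se
  r <- W^2 / (W^2 + V)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Rescale effect and SE to the standardized-phenotype scale
#'
#' For a phenotype not analysed in standard-deviation units, the ABF prior
#' `W` is defined on the standardized scale; the z score is preserved and
#' the SE is replaced by the approximation
#' `SE_std = sqrt(1 / (2 * n * maf * (1 - maf)))`.
#'
#' @param beta,se Raw-scale effect and SE.
#' @param maf Minor allele frequency.
#' @param n Sample size.
#' @return Tibble with columns `beta`, `se` on the standardized scale.
#' @export
standardize_effects <- function(beta, se, maf, n) {
  se_std <- sqrt(1 / (2 * n * maf * (1 - maf)))
  tibble::tibble(beta = (beta / se) * se_std, se = se_std)
}

#' Reconstruct standardized effects from P, MAF and n
#'
#' For external summary statistics carrying only a P-value, MAF, sample
#' size and an effect sign, reconstructs `|z| = qnorm(p / 2, lower = FALSE)`
#' and `SE = sqrt(1 / (2 * n * maf * (1 - maf)))`.
#'
#' @param p Two-sided P-values.
#' @param maf Minor allele frequencies.
#' @param n Sample sizes.
#' @param sign Effect signs (+1/-1, default +1).
#' @return Tibble with columns `beta`, `se`.
#' @export
effects_from_p <- function(p, maf, n, sign = 1) {
  z <- qnorm(p / 2, lower.tail = FALSE)
  se <- sqrt(1 / (2 * n * maf * (1 - maf)))
  tibble::tibble(beta = sign * z * se, se = se)
}

#' Posterior probabilities of the five co-localization hypotheses
#'
#' Enumerates the single-causal-variant configurations over the SNPs
#' shared by the two summary-statistic sets: H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 a
#' common causal variant. With per-SNP log ABFs `L1`, `L2`:
#' `S1 = sum exp(L1)`, `S2 = sum exp(L2)`, `S4 = sum exp(L1 + L2)`,
#' `S3 = S1 * S2 - S4`, and unnormalized hypothesis weights
#' `(1, p1 S1, p2 S2, p1 p2 S3, p12 S4)` normalized to PP0..PP4. All sums
#' run in log space. In a single-SNP region S3 vanishes exactly, so
#' PP3 = 0; small negative S3 from cancellation is clamped to zero with a
#' warning.
#'
#' @param summ1,summ2 Tibbles of per-SNP summary statistics for trait 1
#'   (expression) and trait 2 (methylation): columns `snp`, `beta`, `se`.
#'   Only SNPs present in both are used.
#' @param priors A [derive_priors()] row (or any list with `p1`, `p2`,
#'   `p12`).
#' @param W Prior effect SD passed to [log_abf()]; scalar or length 2 for
#'   the two traits.
#' @return A one-row tibble of class `coloc_posterior`: `n_snps`,
#'   `pp0`..`pp4`, `p1`, `p2`, `p12`, `f`.
#' @export
coloc_posteriors <- function(summ1, summ2, priors, W = 0.15) {
  W <- rep_len(W, 2L)
  shared <- intersect(summ1$snp, summ2$snp)
  if (!length(shared)) abort("no shared SNPs between the two trait sets.")
  s1 <- summ1[match(shared, summ1$snp), ]
  s2 <- summ2[match(shared, summ2$snp), ]
  if (any(s1$se <= 0) || any(s2$se <= 0)) abort("SEs must be positive.")
  l1 <- log_abf(s1$beta, s1$se, W[1])
  l2 <- log_abf(s2$beta, s2$se, W[2])

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls4 <- logsumexp(l1 + l2)
  # S3 = S1*S2 - S4 in log space
  d <- ls1 + ls2
  frac <- -expm1(ls4 - d)          # S3 / (S1*S2)
  if (frac < -1e-9) warn("negative S3 after cancellation; clamped to 0.")
  ls3 <- if (frac <= 0) -Inf else d + log(frac)

  lw <- c(0,
          log(priors$p1) + ls1,
          log(priors$p2) + ls2,
          log(priors$p1) + log(priors$p2) + ls3,
          log(priors$p12) + ls4)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  out <- tibble::tibble(
    n_snps = length(shared),
    pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
    p1 = priors$p1, p2 = priors$p2, p12 = priors$p12,
    f = if (!is.null(priors$f)) priors$f else NA_real_
  )
  class(out) <- c("coloc_posterior", class(out))
  out
}

#' Restrict summary statistics to the co-localization region
#'
#' The tested region is the set of SNPs within `region_bp` of the lead
#' eSNP, excluding SNPs more than `cis_window` bp from the CpG (those were
#' never tested in the methylation scan), intersected across the two sets.
#'
#' @param summ Tibble with columns `snp`, `pos` (and stats columns).
#' @param lead_pos Lead eSNP position.
#' @param cpg_pos CpG coordinate.
#' @param region_bp Half-width around the lead eSNP (default 250000).
#' @param cis_window Methylation cis window (default 500000).
#' @return The filtered tibble.
#' @export
coloc_region <- function(summ, lead_pos, cpg_pos, region_bp = 2.5e5,
                         cis_window = 5e5) {
  summ |>
    dplyr::filter(abs(.data$pos - lead_pos) <= region_bp,
                  abs(.data$pos - cpg_pos) <= cis_window)
}

#' Relative posterior support for a common causal variant
#'
#' Adds `rel_ccv = PP4 / (PP3 + PP4)` to a posterior table, together with
#' an inclusion flag: the ratio is only interpreted when the data are
#' decisive between the two causal-variant hypotheses, i.e. when
#' `PP3 + PP4 > min_total` (default 0.8). The ratio itself is `NA` only
#' when both posteriors vanish.
#'
#' @param pp A `coloc_posterior` tibble (any rows).
#' @param min_total Minimum `PP3 + PP4` for inclusion (default 0.8).
#' @return `pp` with columns `rel_ccv` and `rel_ccv_included`.
#' @export
relative_ccv_support <- function(pp, min_total = 0.8) {
  tot <- pp$pp3 + pp$pp4
  pp$rel_ccv <- ifelse(tot > 0, pp$pp4 / tot, NA_real_)
  pp$rel_ccv_included <- tot > min_total & !is.na(pp$rel_ccv)
  pp
}

#' Internal empirical calibration of the shared-causal prior
#'
#' For each prior fraction `f` in the grid, compares the posterior
#' expectation of co-localization over the tested pairs (the sum of PP4)
#' with the prior expectation (`f * n_pairs`); the calibrated `f` is the
#' grid value minimizing the absolute discrepancy. The count of pairs with
#' PP4 above `ccv_threshold` is reported alongside.
#'
#' @param posteriors Tibble with one row per (pair, f): columns `f`, `pp4`.
#' @param ccv_threshold Designation threshold for "co-localized" pairs
#'   (default 0.8).
#' @return A tibble of class `coloc_calibration` with one row per `f`:
#'   `f`, `n_pairs`, `posterior_expectation`, `prior_expectation`,
#'   `discrepancy`, `n_ccv`, `selected`; the chosen `f` is also in
#'   attribute `"selected_f"`.
#' @export
empirical_calibration <- function(posteriors, ccv_threshold = 0.8) {
  stopifnot(all(c("f", "pp4") %in% names(posteriors)))
  if (dplyr::n_distinct(posteriors$f) < 2) {
    abort("calibration needs at least 2 grid values of `f`.")
  }
  out <- posteriors |>
    dplyr::group_by(f = .data$f) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      posterior_expectation = sum(.data$pp4),
      n_ccv = sum(.data$pp4 > ccv_threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prior_expectation = .data$f * .data$n_pairs,
      discrepancy = .data$posterior_expectation - .data$prior_expectation,
      selected = abs(.data$discrepancy) == min(abs(.data$discrepancy))
    )
  attr(out, "selected_f") <- out$f[which.min(abs(out$discrepancy))]
  class(out) <- c("coloc_calibration", class(out))
  out
}

#' Co-localization over candidate pairs and a prior grid
#'
#' Runs [coloc_posteriors()] for every candidate eProbe-CpG pair and every
#' `f` in the prior grid, restricting each pair to its region via
#' [coloc_region()].
#'
#' @param pairs Candidate pairs from [prune_pairs()] (needs `eprobe`,
#'   `cpg`, `lead_esnp`).
#' @param eqtl_assoc,meqtl_assoc Per-pair association tibbles from
#'   [cis_scan()] (columns `probe`, `snp`, `snp_pos`, `beta`, `se`).
#' @param snp_pos Tibble `snp`, `pos` giving SNP coordinates.
#' @param cpg_anno Tibble `probe`, `pos` giving CpG coordinates.
#' @param priors_grid A [derive_priors()] tibble with one row per `f`.
#' @param W Prior effect SD (scalar or length 2).
#' @param region_bp,cis_window Region definition, see [coloc_region()].
#' @return Tibble: one row per (pair, f) with the pair IDs and all
#'   `coloc_posterior` columns plus `rel_ccv`.
#' @export
coloc_candidates <- function(pairs, eqtl_assoc, meqtl_assoc, snp_pos,
                             cpg_anno, priors_grid, W = 0.15,
                             region_bp = 2.5e5, cis_window = 5e5) {
  rows <- purrr::pmap(
    list(pairs$eprobe, pairs$cpg, pairs$lead_esnp),
    function(ep, cg, lead) {
      s1 <- eqtl_assoc |>
        dplyr::filter(.data$probe == ep) |>
        dplyr::left_join(snp_pos, by = "snp")
      s2 <- meqtl_assoc |>
        dplyr::filter(.data$probe == cg) |>
        dplyr::left_join(snp_pos, by = "snp")
      lead_pos <- snp_pos$pos[match(lead, snp_pos$snp)]
      cpg_pos <- cpg_anno$pos[match(cg, cpg_anno$probe)]
      s1 <- coloc_region(s1, lead_pos, cpg_pos, region_bp, cis_window)
      s2 <- coloc_region(s2, lead_pos, cpg_pos, region_bp, cis_window)
      if (!length(intersect(s1$snp, s2$snp))) return(NULL)
      purrr::map_dfr(seq_len(nrow(priors_grid)), function(k) {
        pp <- coloc_posteriors(s1, s2, priors_grid[k, ], W = W)
        dplyr::bind_cols(tibble::tibble(eprobe = ep, cpg = cg,
                                        lead_esnp = lead), pp)
      })
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- relative_ccv_support(out)
  out
}
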