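#' Partial correlation of expression and methylation given genotype
#'
#' Pearson correlation of the two (already covariate/PC-adjusted)
#' phenotypes before and after residualizing both on the lead SNP
#' dosage(s). If the SNP fully drives the observed correlation, the
#' post-adjustment correlation is expected to vanish; residual correlation
#' indicates a shared mechanism beyond independent SNP effects. Multiple
#' dosage columns may be supplied to adjust jointly for primary and
#' secondary lead SNPs.
#'
#' @param e,m Numeric phenotype vectors (expression, methylation).
#' @param snps Dosage vector, or samples x SNPs matrix for multi-SNP
#'   adjustment.
#' @param covars Optional covariate matrix residualized out of both
#'   phenotypes before any correlation is computed.
#' @return A one-row tibble: `r_before`, `p_before`, `r_after`, `p_after`,
#'   `n`. Degenerate residuals give `NA` with a warning.
#' @export
partial_correlation <- function(e, m, snps, covars = NULL) {
  snps <- as.matrix(snps)
  cc <- complete.cases(e, m, snps, if (is.null(covars)) e else covars)
  if (sum(cc) < 10) abort("need at least 10 complete cases.")
  e <- e[cc]; m <- m[cc]
  snps <- snps[cc, , drop = FALSE]
  if (!is.null(covars)) {
    X <- as.matrix(covars)[cc, , drop = FALSE]
    e <- drop(residualize(e, X))
    m <- drop(residualize(m, X))
  }
  n <- length(e)
  ct0 <- cor.test(e, m)
  er <- drop(residualize(e, snps))
  mr <- drop(residualize(m, snps))
  if (sd(er) < 1e-12 || sd(mr) < 1e-12) {
    warn("zero residual variance after SNP adjustment.")
    return(tibble::tibble(r_before = unname(ct0$estimate),
                          p_before = ct0$p.value,
                          r_after = NA_real_, p_after = NA_real_, n = n))
  }
  ct1 <- cor.test(er, mr)
  tibble::tibble(r_before = unname(ct0$estimate), p_before = ct0$p.value,
                 r_after = unname(ct1$estimate), p_after = ct1$p.value,
                 n = n)
}

#' Sobel mediation test for a SNP-mediator-outcome triple
#'
#' Fits three regressions (each with optional covariates): the total
#' effect `outcome ~ g`; the direct effect and mediator coefficient
#' `outcome ~ g + mediator` (giving `beta_adj` and `beta1`); and the SNP
#' effect on the mediator `mediator ~ g` (giving `beta2`). The indirect
#' effect is `beta1 * beta2`, tested with the Sobel statistic
#' `t = beta1 * beta2 / SE`, `SE = sqrt(beta1² sigma_beta2² + beta2²
#' sigma_beta1²)`, compared to the standard normal. The mediation
#' proportion is `(beta_unadj - beta_adj) / beta_unadj` (undefined when
#' the total effect is zero).
#'
#' @param g Dosage vector.
#' @param outcome,mediator Phenotype vectors.
#' @param covars Optional covariate matrix included in all three fits.
#' @param model Label stored with the result, conventionally `"SME"`
#'   (methylation mediates the SNP effect on expression) or `"SEM"`.
#' @return An object of class `mediation_fit`; see [tidy.mediation_fit()]
#'   and [glance.mediation_fit()].
#' @export
mediation_test <- function(g, outcome, mediator, covars = NULL,
                           model = "SME") {
  cc <- complete.cases(g, outcome, mediator,
                       if (is.null(covars)) g else covars)
  if (sum(cc) < 10) abort("need at least 10 complete cases.")
  g <- g[cc]; outcome <- outcome[cc]; mediator <- mediator[cc]
  if (var(g) == 0) abort("zero dosage variance.")
  X <- if (is.null(covars)) NULL else as.matrix(covars)[cc, , drop = FALSE]
  dm <- function(...) if (is.null(X)) cbind(...) else cbind(..., X)

  f_tot <- lm(outcome ~ dm(g))
  f_adj <- lm(outcome ~ dm(g, mediator))
  f_med <- lm(mediator ~ dm(g))
  s_adj <- summary(f_adj)$coefficients
  s_med <- summary(f_med)$coefficients

  beta_unadj <- coef(f_tot)[[2]]
  beta_adj <- s_adj[2, 1]
  beta1 <- s_adj[3, 1]; se1 <- s_adj[3, 2]
  beta2 <- s_med[2, 1]; se2 <- s_med[2, 2]
  se_sobel <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  t_sobel <- if (se_sobel > 0) beta1 * beta2 / se_sobel else 0
  p_sobel <- max(2 * pnorm(-abs(t_sobel)), 1e-300)
  prop <- if (abs(beta_unadj) > 0) (beta_unadj - beta_adj) / beta_unadj
          else NA_real_

  structure(
    list(model = model, n = length(g),
         beta_unadj = beta_unadj, beta_adj = beta_adj,
         beta1 = beta1, se_beta1 = se1,
         beta2 = beta2, se_beta2 = se2,
         indirect = beta1 * beta2, se_sobel = se_sobel,
         t_sobel = t_sobel, p_sobel = p_sobel,
         prop_mediated = prop),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf(
    "<mediation_fit %s> indirect = %.4g (Sobel t = %.3f, P = %.3g), %%mediation = %.3f\n",
    x$model, x$indirect, x$t_sobel, x$p_sobel, x$prop_mediated
  ))
  invisible(x)
}

#' Tidy a mediation fit
#'
#' @param x A [mediation_test()] result.
#' @param ... Unused.
#' @return A tibble with one row per effect (`total`, `direct`,
#'   `mediator_on_outcome`, `snp_on_mediator`, `indirect`), with standard
#'   errors, statistics and P-values where defined.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("total", "direct", "mediator_on_outcome", "snp_on_mediator",
             "indirect"),
    estimate = c(x$beta_unadj, x$beta_adj, x$beta1, x$beta2, x$indirect),
    std.error = c(NA, NA, x$se_beta1, x$se_beta2, x$se_sobel),
    statistic = c(NA, NA, x$beta1 / x$se_beta1, x$beta2 / x$se_beta2,
                  x$t_sobel),
    p.value = c(NA, NA, 2 * pnorm(-abs(x$beta1 / x$se_beta1)),
                2 * pnorm(-abs(x$beta2 / x$se_beta2)), x$p_sobel)
  )
}

#' Glance at a mediation fit
#'
#' @inheritParams tidy.mediation_fit
#' @return A one-row tibble: `model`, `beta_unadj`, `beta_adj`, `beta1`,
#'   `beta2`, `indirect`, `se_sobel`, `t_sobel`, `p_sobel`,
#'   `prop_mediated`, `n`.
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, beta_unadj = x$beta_unadj, beta_adj = x$beta_adj,
    beta1 = x$beta1, beta2 = x$beta2, indirect = x$indirect,
    se_sobel = x$se_sobel, t_sobel = x$t_sobel, p_sobel = x$p_sobel,
    prop_mediated = x$prop_mediated, n = x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Run both mediation models for one eProbe-CpG pair
#'
#' SME treats methylation as the mediator of the SNP effect on expression;
#' SEM reverses the roles. The correctly specified model is expected to
#' yield the stronger (smaller) Sobel P.
#'
#' @param g Dosage vector of the shared lead SNP.
#' @param e,m Expression and methylation vectors (covariate/PC-adjusted
#'   or supply `covars`).
#' @param covars Optional covariate matrix.
#' @return A two-row tibble (models `"SME"` and `"SEM"`), the
#'   [glance.mediation_fit()] columns.
#' @export
run_both_models <- function(g, e, m, covars = NULL) {
  dplyr::bind_rows(
    glance(mediation_test(g, outcome = e, mediator = m, covars, model = "SME")),
    glance(mediation_test(g, outcome = m, mediator = e, covars, model = "SEM"))
  )
}

#' Per-model FDR over a batch of mediation results
#'
#' Adds a q-value column computed separately within each model (SME, SEM)
#' and an `evidence` flag requiring the q-value below `fdr` and a positive
#' mediation proportion.
#'
#' @param results Row-bound [run_both_models()] output across pairs.
#' @param fdr FDR level (default 0.05).
#' @return `results` with columns `qvalue` and `evidence`.
#' @export
mediation_fdr <- function(results, fdr = 0.05) {
  results |>
    dplyr::group_by(.data$model) |>
    dplyr::mutate(qvalue = fdr_qvalues(.data$p_sobel)) |>
    dplyr::ungroup() |>
    dplyr::mutate(evidence = .data$qvalue < fdr &
                    !is.na(.data$prop_mediated) & .data$prop_mediated > 0)
}

#' Direction-of-effect summary over co-localized pairs
#'
#' For each stratum (all pairs, then pairs with Sobel or partial
#' correlation P below each threshold), reports the fraction of pairs
#' whose SNP effects on expression and methylation have opposite signs,
#' and the fraction with a negative expression-methylation correlation.
#' Effects are assumed oriented to a common allele per pair.
#'
#' @param pairs Tibble with columns `beta_e` (SNP effect on expression),
#'   `beta_m` (SNP effect on methylation), `r_em` (E-M correlation), and
#'   `sobel_p`, `corr_p` used for stratification.
#' @param thresholds P-value thresholds defining nested strata
#'   (default `c(0.05, 0.001)`).
#' @return A tibble: `stratum`, `n`, `frac_opposite`, `frac_negative_corr`.
#' @export
direction_summary <- function(pairs, thresholds = c(0.05, 0.001)) {
  strata <- c(list(all = rep(TRUE, nrow(pairs))),
              setNames(
                lapply(thresholds, function(th)
                  (pairs$sobel_p < th | pairs$corr_p < th) &
                    !is.na(pairs$sobel_p) & !is.na(pairs$corr_p)),
                paste0("p<", thresholds)
              ))
  purrr::imap_dfr(strata, function(keep, nm) {
    d <- pairs[keep, ]
    tibble::tibble(
      stratum = nm,
      n = nrow(d),
      frac_opposite = if (nrow(d)) mean(sign(d$beta_e) != sign(d$beta_m))
                      else NA_real_,
      frac_negative_corr = if (nrow(d)) mean(d$r_em < 0) else NA_real_
    )
  })
}

#' Opposite-direction secondary CpGs near a same-direction pair
#'
#' For a pair whose SNP affects expression and the primary CpG in the same
#' direction, searches the significant meQTL results for additional CpGs
#' within `window` bp of the SNP whose association with the SNP has the
#' opposite sign to the eQTL effect. Reports the primary-secondary CpG
#' distance and, when methylation data are supplied, the correlation
#' between the two CpGs.
#'
#' @param snp SNP ID of the pair's lead eSNP.
#' @param eqtl_beta Sign-carrying eQTL effect of that SNP.
#' @param primary_cpg Primary CpG ID.
#' @param meqtl_signif Significant meQTL pairs (columns `snp`, `probe`,
#'   `beta`, `p`, `distance`); CpG coordinates via `cpg_anno`.
#' @param cpg_anno Tibble `probe`, `pos` of CpG coordinates.
#' @param meth Optional [phenotype_matrix()] of methylation values for
#'   inter-CpG correlations.
#' @param window Search window around the SNP in bp (default 500000, the
#'   meQTL testing window).
#' @return Tibble of hits: `snp`, `secondary_cpg`, `beta_secondary`,
#'   `p_secondary`, `distance_to_primary`, `cor_with_primary` (NA without
#'   `meth`). Empty when no opposite-sign CpG exists.
#' @export
find_opposite_cpgs <- function(snp, eqtl_beta, primary_cpg, meqtl_signif,
                               cpg_anno, meth = NULL, window = 5e5) {
  hits <- meqtl_signif |>
    dplyr::filter(.data$snp == !!snp, .data$probe != primary_cpg,
                  sign(.data$beta) == -sign(eqtl_beta),
                  abs(.data$distance) < window)
  prim_pos <- cpg_anno$pos[match(primary_cpg, cpg_anno$probe)]
  out <- hits |>
    dplyr::left_join(dplyr::select(cpg_anno, probe = "probe", cpg_pos = "pos"),
                     by = "probe") |>
    dplyr::transmute(
      snp = .data$snp, secondary_cpg = .data$probe,
      beta_secondary = .data$beta, p_secondary = .data$p,
      distance_to_primary = .data$cpg_pos - prim_pos
    )
  out$cor_with_primary <- NA_real_
  if (!is.null(meth) && nrow(out)) {
    x0 <- meth$values[, primary_cpg]
    out$cor_with_primary <- vapply(
      out$secondary_cpg,
      function(cg) cor(x0, meth$values[, cg], use = "complete.obs"),
      numeric(1)
    )
  }
  out
}

#' Conditional scan for a secondary association signal
#'
#' Re-runs the probe's cis scan with the primary lead SNP's dosage
#' appended to the covariates; if the best remaining association passes
#' `threshold`, that SNP is returned as the secondary lead. A secondary
#' dosage collinear with the primary is skipped (zero residual variance).
#'
#' @param geno A [genotype_matrix()].
#' @param pheno A [phenotype_matrix()] (the scanned probe(s)).
#' @param probe Probe ID to re-test.
#' @param primary_snp Primary lead SNP ID.
#' @param covars Optional covariate matrix.
#' @param window Cis window (default 500000).
#' @param threshold Nominal significance threshold for declaring a
#'   secondary signal (default 1e-5).
#' @return The secondary lead association row, or an empty tibble when no
#'   SNP passes.
#' @export
conditional_secondary_scan <- function(geno, pheno, probe, primary_snp,
                                       covars = NULL, window = 5e5,
                                       threshold = 1e-5) {
  shared <- intersect(geno$samples, pheno$samples)
  if (!is.null(covars)) shared <- intersect(shared, rownames(covars))
  g0 <- geno$dosages[shared, primary_snp]
  X <- cbind(if (is.null(covars)) NULL
             else as.matrix(covars)[shared, , drop = FALSE],
             primary = g0)
  rownames(X) <- shared
  assoc <- cis_scan(geno, subset_pheno(pheno, probes = probe), X, window)
  assoc <- assoc[assoc$snp != primary_snp, ]
  if (!nrow(assoc)) return(assoc)
  lead <- select_lead(assoc)
  if (lead$p < threshold) lead else assoc[0, ]
}
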