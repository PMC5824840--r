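test_that("partial correlation of identical phenotypes stays perfect", {
  set.seed(61)
  g <- rbinom(50, 2, 0.3)
  e <- 0.5 * g + rnorm(50)
  res <- partial_correlation(e, e, g)
  expect_equal(res$r_before, 1)
  expect_equal(res$r_after, 1)
})

test_that("partial correlation matches an explicit two-stage lm oracle", {
  set.seed(62)
  n <- 120
  g <- rbinom(n, 2, 0.4)
  e <- 0.4 * g + rnorm(n)
  m <- -0.3 * g + 0.2 * e + rnorm(n)
  res <- partial_correlation(e, m, g)
  er <- residuals(lm(e ~ g))
  mr <- residuals(lm(m ~ g))
  ct <- cor.test(er, mr)
  expect_equal(res$r_after, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_after, ct$p.value, tolerance = 1e-12)
  expect_equal(res$r_before, unname(cor.test(e, m)$estimate))
})

test_that("multi-SNP adjustment removes both signals", {
  set.seed(63)
  n <- 500
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.3)
  e <- 0.8 * g1 + 0.8 * g2 + rnorm(n)
  m <- 0.8 * g1 + 0.8 * g2 + rnorm(n)
  res1 <- partial_correlation(e, m, g1)
  res2 <- partial_correlation(e, m, cbind(g1, g2))
  # adjusting for both SNPs removes the g2-driven residual correlation
  expect_lt(abs(res2$r_after), 0.15)
  expect_gt(abs(res1$r_after), abs(res2$r_after))
})

test_that("the Sobel statistic reproduces the hand-evaluated formula", {
  # closed-form check of the pooled-SE and t arithmetic:
  # beta1 = 0.5, se1 = 0.1, beta2 = 0.4, se2 = 0.1
  se <- sqrt(0.5^2 * 0.1^2 + 0.4^2 * 0.1^2)
  expect_equal(se, 0.06403124, tolerance = 1e-7)
  t <- 0.5 * 0.4 / se
  expect_equal(t, 3.123475, tolerance = 1e-6)
  expect_equal(2 * pnorm(-t), 1.787289e-3, tolerance = 1e-6)

  # the fitted object applies the same arithmetic to estimated coefficients
  set.seed(64)
  n <- 316
  g <- rbinom(n, 2, 0.3)
  x <- 0.5 * g + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  fit <- mediation_test(g, outcome = y, mediator = x)
  s_adj <- summary(lm(y ~ g + x))$coefficients
  s_med <- summary(lm(x ~ g))$coefficients
  se_o <- sqrt(s_adj[3, 1]^2 * s_med[2, 2]^2 + s_med[2, 1]^2 * s_adj[3, 2]^2)
  expect_equal(fit$se_sobel, se_o, tolerance = 1e-12)
  expect_equal(fit$t_sobel, s_adj[3, 1] * s_med[2, 1] / se_o, tolerance = 1e-12)
  expect_equal(fit$p_sobel, 2 * pnorm(-abs(fit$t_sobel)))
  expect_equal(fit$beta_unadj, unname(coef(lm(y ~ g))[2]), tolerance = 1e-12)
})

test_that("an unrelated mediator gives a null Sobel test", {
  set.seed(65)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * g + rnorm(n)
  x <- rnorm(n)  # no path g -> x, no path x -> y
  fit <- mediation_test(g, outcome = y, mediator = x)
  expect_gt(fit$p_sobel, 0.01)
})

test_that("noiseless full mediation yields proportion one and zero direct effect", {
  set.seed(66)
  n <- 100
  g <- rbinom(n, 2, 0.4)
  x <- 0.7 * g + rnorm(n)
  y <- 2 * x            # outcome an exact function of the mediator
  fit <- suppressWarnings(mediation_test(g, outcome = y, mediator = x))
  expect_equal(fit$beta_adj, 0, tolerance = 1e-10)
  expect_equal(fit$prop_mediated, 1, tolerance = 1e-10)
})

test_that("mediation invariances hold", {
  set.seed(67)
  n <- 316
  g <- rbinom(n, 2, 0.3)
  x <- 0.5 * g + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  f1 <- mediation_test(g, outcome = y, mediator = x)
  # proportion invariant to rescaling the mediator
  f2 <- mediation_test(g, outcome = y, mediator = 10 * x)
  expect_equal(f1$prop_mediated, f2$prop_mediated, tolerance = 1e-10)
  # Sobel t invariant to exchanging (beta1, se1) with (beta2, se2)
  t_swapped <- f1$beta2 * f1$beta1 /
    sqrt(f1$beta2^2 * f1$se_beta1^2 + f1$beta1^2 * f1$se_beta2^2)
  expect_equal(f1$t_sobel, t_swapped, tolerance = 1e-12)
})

test_that("tidy and glance expose broom-shaped summaries", {
  set.seed(68)
  g <- rbinom(100, 2, 0.3)
  x <- 0.5 * g + rnorm(100)
  y <- 0.5 * x + rnorm(100)
  fit <- mediation_test(g, y, x, model = "SME")
  td <- tidy(fit)
  expect_equal(td$term, c("total", "direct", "mediator_on_outcome",
                          "snp_on_mediator", "indirect"))
  expect_equal(td$estimate[5], td$estimate[3] * td$estimate[4])
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$model, "SME")
  expect_equal(gl$indirect, fit$indirect)
})

test_that("both models run and per-model FDR flags require positive mediation", {
  set.seed(69)
  res <- dplyr::bind_rows(lapply(1:30, function(i) {
    tr <- simulate_trio(trio_design(n_samples = 316, var_explained = 0.3,
                                    beta_xy = if (i <= 15) 0.5 else 0,
                                    seed = 1000 + i))
    cbind(pair = i, run_both_models(tr$g, e = tr$y, m = tr$x))
  }))
  expect_setequal(unique(res$model), c("SME", "SEM"))
  fl <- mediation_fdr(res, fdr = 0.05)
  expect_true(all(fl$prop_mediated[fl$evidence] > 0))
  # q-values computed within model strata
  for (mod in c("SME", "SEM")) {
    sub <- fl[fl$model == mod, ]
    expect_equal(sub$qvalue, fdr_qvalues(sub$p_sobel))
  }
})

test_that("direction summaries count sign patterns within nested strata", {
  pairs <- tibble::tibble(
    beta_e = c(1, 1, -1), beta_m = c(1, -1, 1), r_em = c(0.2, -0.1, -0.3),
    sobel_p = c(0.2, 0.01, 0.0005), corr_p = c(0.3, 0.2, 0.0002)
  )
  out <- direction_summary(pairs)
  expect_equal(out$frac_opposite[out$stratum == "all"], 2 / 3)
  expect_equal(out$n, c(3, 2, 1))            # nested strata shrink
  expect_equal(out$frac_negative_corr[out$stratum == "all"], 2 / 3)
  expect_true(all(diff(out$n) <= 0))
})

test_that("opposite-direction secondary CpGs obey the sign rule", {
  msig <- tibble::tibble(
    snp = "rs1", probe = c("cpgP", "cpgN", "cpgPos"),
    beta = c(0.3, -0.2, 0.4), p = c(1e-9, 1e-7, 1e-6),
    distance = c(1000, 5000, 8000)
  )
  anno <- tibble::tibble(probe = c("cpgP", "cpgN", "cpgPos"),
                         pos = c(1e6, 1.05e6, 1.1e6))
  hits <- find_opposite_cpgs("rs1", eqtl_beta = 0.5, primary_cpg = "cpgP",
                             meqtl_signif = msig, cpg_anno = anno)
  expect_equal(hits$secondary_cpg, "cpgN")
  expect_equal(hits$distance_to_primary, 5e4)
  none <- find_opposite_cpgs("rs1", eqtl_beta = -0.5, primary_cpg = "cpgN",
                             meqtl_signif = msig[2, ], cpg_anno = anno)
  expect_equal(nrow(none), 0L)
})

test_that("anti-correlated CpG clusters yield negative inter-CpG correlations", {
  set.seed(70)
  neg <- replicate(20, {
    rd <- region_design(n_snps = 8, block_structure = list(c(8, 0.3)),
                        causal_model = "PLEIOTROPY", causal_snp_indices = 4L,
                        var_g_m = 0.4, n_cpgs = 2, cpg_signs = c(1, -1),
                        seed = sample.int(1e6, 1), n_eqtl = 100,
                        n_meqtl = 300, n_overlap = 200)
    ds <- simulate_region(rd)
    cor(ds$methylation$values[, 1], ds$methylation$values[, 2]) < 0
  })
  expect_gte(mean(neg), 0.9)
})

test_that("conditional scans find true secondary signals and reject absent ones", {
  set.seed(71)
  # two independent strong causal SNPs
  second_hits <- replicate(20, {
    rd <- region_design(n_snps = 20, block_structure = list(c(10, 0.2), c(10, 0.2)),
                        causal_model = "PLEIOTROPY", causal_snp_indices = 5L,
                        var_g_e = 0.15, seed = sample.int(1e6, 1),
                        n_eqtl = 400, n_meqtl = 50, n_overlap = 20)
    ds <- simulate_region(rd)
    ge <- subset_geno(ds$genotypes, samples = ds$panels$eqtl)
    ph <- subset_pheno(ds$expression, samples = ds$panels$eqtl)
    # inject a second causal SNP in the other block
    g2 <- ge$dosages[, 15]
    ph$values[, 1] <- ph$values[, 1] + 0.6 * g2
    sec <- conditional_secondary_scan(ge, ph, "eprobe_1", "snp_0005")
    nrow(sec) == 1 &&
      ld_r2(ge$dosages[, sec$snp], g2) > 0.8
  })
  expect_gte(mean(second_hits), 0.9)

  # single causal SNP: no secondary signal
  no_hits <- replicate(20, {
    rd <- region_design(n_snps = 20, block_structure = list(c(20, 0.5)),
                        causal_model = "PLEIOTROPY", causal_snp_indices = 5L,
                        var_g_e = 0.2, seed = sample.int(1e6, 1),
                        n_eqtl = 400, n_meqtl = 50, n_overlap = 20)
    ds <- simulate_region(rd)
    ge <- subset_geno(ds$genotypes, samples = ds$panels$eqtl)
    ph <- subset_pheno(ds$expression, samples = ds$panels$eqtl)
    lead <- select_lead(cis_scan(ge, ph))$snp
    nrow(conditional_secondary_scan(ge, ph, "eprobe_1", lead)) == 0
  })
  expect_gte(mean(no_hits), 0.95)
})

test_that("a collinear duplicate of the primary cannot become secondary", {
  set.seed(72)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  dos <- cbind(a = g, b = g)  # exact duplicate
  rownames(dos) <- paste0("S", 1:n)
  geno <- genotype_matrix(dos, tibble::tibble(snp = c("a", "b"), chrom = "1",
                                              pos = c(1e6, 1.01e6)))
  ph <- phenotype_matrix(matrix(0.8 * g + rnorm(n), n, 1,
                                dimnames = list(paste0("S", 1:n), "p1")),
                         tibble::tibble(probe = "p1", chrom = "1", pos = 1e6))
  sec <- conditional_secondary_scan(geno, ph, "p1", "a")
  expect_equal(nrow(sec), 0L)
})
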