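test_that("phenotype transforms match their closed forms and reject bad input", {
  expr <- toy_pheno(matrix(c(8, 2, 4, 1), 2, 2), pos = c(1e6, 2e6),
                    scale = "raw-expression")
  tr <- transform_phenotypes(expr)
  expect_equal(tr$values[1, 1], 3)  # log2(8)
  expect_equal(tr$scale, "log-expression")

  meth <- toy_pheno(matrix(c(0.5, 0.25, 0.75, 0.9), 2, 2), pos = c(1e6, 2e6),
                    scale = "raw-methylation")
  tm <- transform_phenotypes(meth)
  expect_equal(tm$values[1, 1], 0)  # logit(0.5)
  expect_equal(tm$values[2, 1], log(0.25 / 0.75))

  bad <- toy_pheno(matrix(c(-1, 2, 3, 4), 2, 2), pos = c(1e6, 2e6),
                   scale = "raw-expression")
  expect_error(transform_phenotypes(bad), "positive")
})

test_that("quantile normalization equalizes permuted samples", {
  set.seed(4)
  v <- sort(rlnorm(20))
  x <- rbind(v, sample(v), sample(v))
  pheno <- toy_pheno(t(t(x)), pos = seq(1e6, by = 1000, length.out = 20),
                     scale = "raw-expression")
  qn <- transform_phenotypes(pheno, quantile_normalize = TRUE)
  expect_equal(unname(sort(qn$values[1, ])), unname(sort(qn$values[2, ])))
  expect_equal(unname(sort(qn$values[2, ])), unname(sort(qn$values[3, ])))
})

test_that("phenotype PCs match a dense eigendecomposition and are orthogonal", {
  set.seed(5)
  x <- matrix(rnorm(20), 5, 4)
  pheno <- toy_pheno(x, pos = seq(1e6, by = 1000, length.out = 4))
  pcs <- compute_phenotype_pcs(pheno, k = 2)
  # brute-force oracle: eigendecomposition of the covariance of centered data
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc))
  oracle <- xc %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    expect_equal(abs(cor(pcs[, j], oracle[, j])), 1, tolerance = 1e-8)
  }
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])),
            1e-8 * sqrt(sum(pcs[, 1]^2) * sum(pcs[, 2]^2)))

  # rank-1 dominance
  r1 <- outer(rnorm(30), rnorm(6)) + matrix(rnorm(180, sd = 1e-4), 30, 6)
  p1 <- toy_pheno(r1, pos = seq(1e6, by = 1000, length.out = 6))
  pc1 <- compute_phenotype_pcs(p1, k = 2)
  expect_gt(attr(pc1, "var_explained")[1], 0.99)
  expect_error(compute_phenotype_pcs(p1, k = 0), "positive")
})

test_that("cis_scan reproduces closed-form simple regression on a toy pair", {
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 1.2, 1.9, 0.3, 0.8, 2.2)
  geno <- genotype_matrix(matrix(g, 6, 1,
                                 dimnames = list(paste0("S", 1:6), "s1")),
                          tibble::tibble(snp = "s1", chrom = "1", pos = 1e6))
  pheno <- phenotype_matrix(matrix(y, 6, 1,
                                   dimnames = list(paste0("S", 1:6), "p1")),
                            tibble::tibble(probe = "p1", chrom = "1",
                                           pos = 1.1e6))
  res <- cis_scan(geno, pheno, min_samples = 6)
  # textbook least-squares oracle
  sxx <- sum((g - mean(g))^2)
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (g - mean(g))
  se <- sqrt(sum(resid^2) / 4 / sxx)
  expect_equal(res$beta, beta, tolerance = 1e-10)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(beta / se), 4), tolerance = 1e-10)
  expect_equal(res$n, 6)
})

test_that("cis_scan matches lm with covariates and handles missing values", {
  set.seed(6)
  n <- 40
  geno <- toy_geno(n = n, m = 3, seed = 6)
  X <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  rownames(X) <- geno$samples
  y <- 0.4 * geno$dosages[, 2] + 0.3 * X[, 1] + rnorm(n)
  y[c(3, 7)] <- NA
  pheno <- phenotype_matrix(matrix(y, n, 1,
                                   dimnames = list(geno$samples, "p1")),
                            tibble::tibble(probe = "p1", chrom = "1",
                                           pos = 1e6))
  res <- cis_scan(geno, pheno, covars = X)
  for (j in 1:3) {
    fit <- summary(lm(y ~ geno$dosages[, j] + X))$coefficients
    row <- res[res$snp == geno$snps$snp[j], ]
    expect_equal(row$beta, fit[2, 1], tolerance = 1e-10)
    expect_equal(row$se, fit[2, 2], tolerance = 1e-10)
    expect_equal(row$p, fit[2, 4], tolerance = 1e-10)
    expect_equal(row$n, n - 2)
  }
})

test_that("the cis window is strict and zero-variance SNPs are skipped", {
  n <- 20
  dos <- cbind(a = rbinom(n, 2, 0.4), b = rbinom(n, 2, 0.4), c = rep(1, n))
  rownames(dos) <- paste0("S", 1:n)
  geno <- genotype_matrix(dos, tibble::tibble(
    snp = c("a", "b", "c"), chrom = "1", pos = c(1e6, 1.5e6, 1.001e6)
  ))
  pheno <- phenotype_matrix(
    matrix(rnorm(n), n, 1, dimnames = list(paste0("S", 1:n), "p1")),
    tibble::tibble(probe = "p1", chrom = "1", pos = 1e6)
  )
  res <- cis_scan(geno, pheno, window = 5e5)
  expect_false("b" %in% res$snp)   # exactly 500 kb away: excluded
  expect_false("c" %in% res$snp)   # constant dosage: skipped
  expect_true("a" %in% res$snp)
  expect_match(attr(res, "skipped"), "zero dosage variance")
})

test_that("a perfect linear phenotype recovers beta with guarded P", {
  n <- 30
  g <- rbinom(n, 2, 0.4)
  geno <- genotype_matrix(matrix(g, n, 1,
                                 dimnames = list(paste0("S", 1:n), "s1")),
                          tibble::tibble(snp = "s1", chrom = "1", pos = 1e6))
  pheno <- phenotype_matrix(matrix(2.5 * g + 1, n, 1,
                                   dimnames = list(paste0("S", 1:n), "p1")),
                            tibble::tibble(probe = "p1", chrom = "1", pos = 1e6))
  res <- cis_scan(geno, pheno)
  expect_equal(res$beta, 2.5, tolerance = 1e-10)
  expect_gte(res$p, 1e-300)
})

test_that("cis_scan is invariant to sample order and phenotype shifts", {
  set.seed(7)
  geno <- toy_geno(n = 30, m = 4, seed = 7)
  y <- rnorm(30)
  mk <- function(yy, samp) {
    phenotype_matrix(matrix(yy, 30, 1, dimnames = list(samp, "p1")),
                     tibble::tibble(probe = "p1", chrom = "1", pos = 1e6))
  }
  base <- cis_scan(geno, mk(y, geno$samples))
  perm <- sample(30)
  shuffled <- cis_scan(
    genotype_matrix(geno$dosages[perm, ], geno$snps[, 1:3]),
    mk(y[perm], geno$samples[perm])
  )
  shifted <- cis_scan(geno, mk(y + 100, geno$samples))
  expect_equal(base$p, shuffled$p)
  expect_equal(base$beta, shifted$beta, tolerance = 1e-8)
})

test_that("null-consistent probes get adjusted P near 1", {
  set.seed(8)
  n <- 60
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  y <- rnorm(n)
  res <- permutation_adjusted_pvalue(y, G, n_perm = c(1000, 10000), seed = 1)
  expect_equal(res$perm_n, 1000)  # adaptive stop under the null
  if (res$best_p > 0.9) expect_gt(res$adj_p, 0.9)
  expect_true(res$adj_p > 0 && res$adj_p < 1)
})

test_that("the beta null fit recovers known shape parameters", {
  set.seed(21)
  x <- rbeta(5000, 1.4, 60)
  ab <- comolq:::fit_beta_ml(x)
  expect_lt(abs(ab[1] - 1.4) / 1.4, 0.1)
  expect_lt(abs(ab[2] - 60) / 60, 0.1)
})

test_that("q-values reproduce hand-computed BH and stay monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04, 1.0)
  expect_equal(fdr_qvalues(p, pi0 = 1), c(0.05, 0.05, 0.05, 0.05, 1.0))
  expect_equal(fdr_qvalues(rep(1, 5)), rep(1, 5))
  set.seed(9)
  p2 <- runif(500)^2
  q2 <- fdr_qvalues(p2)
  o <- order(p2)
  expect_true(all(diff(q2[o]) >= -1e-12))
  expect_error(fdr_qvalues(numeric(0)), "empty")
  expect_error(fdr_qvalues(c(0.5, 0)), "P-values")
})

test_that("lead selection applies the P, distance, coordinate tie-breaks", {
  assoc <- tibble::tibble(
    probe = "p1", snp = c("a", "b", "c"), chrom = "1",
    snp_pos = c(1e6, 2e6, 3e6), distance = c(1000, -500, 2000),
    beta = 1, se = 1, t = 1, p = c(0.5, 1e-8, 0.01), n = 100
  )
  expect_equal(select_lead(assoc)$snp, "b")
  tie <- assoc
  tie$p <- c(0.01, 0.01, 0.5)
  expect_equal(select_lead(tie)$snp, "b")   # smaller |distance|
  tie2 <- assoc
  tie2$p <- 0.01
  tie2$distance <- c(500, -500, 2000)
  expect_equal(select_lead(tie2)$snp, "a")  # lower coordinate
})

test_that("strong simulated signals put the causal SNP at or near the lead", {
  set.seed(11)
  hits <- replicate(40, {
    rd <- region_design(n_snps = 15, block_structure = list(c(15, 0.5)),
                        causal_model = "PLEIOTROPY", causal_snp_indices = 8L,
                        var_g_e = 0.25, seed = sample.int(1e6, 1),
                        n_eqtl = 316, n_meqtl = 20, n_overlap = 10)
    ds <- simulate_region(rd)
    ge <- subset_geno(ds$genotypes, samples = ds$panels$eqtl)
    a <- cis_scan(ge, subset_pheno(ds$expression, samples = ds$panels$eqtl))
    lead <- select_lead(a)$snp
    causal <- ge$snps$snp[8]
    lead == causal ||
      ld_r2(ge$dosages[, lead], ge$dosages[, causal]) > 0.8
  })
  expect_gte(mean(hits), 0.9)
})

test_that("probe-level scans control the FDR on null phenotypes", {
  set.seed(12)
  n <- 60
  geno <- toy_geno(n = n, m = 8, seed = 12)
  vals <- matrix(rnorm(n * 100), n)
  rownames(vals) <- geno$samples
  pheno <- toy_pheno(vals, pos = rep(1e6, 100))
  sc <- scan_probes(geno, pheno, n_perm = c(200, 200), seed = 13)
  expect_lte(mean(sc$probes$qvalue < 0.01), 0.02)
  expect_true(all(sc$probes$adj_p > 0 & sc$probes$adj_p < 1))
})
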