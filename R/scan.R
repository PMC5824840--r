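#' Cis-QTL scan: per SNP-probe linear associations
#'
#' For every SNP-probe pair on the same chromosome with
#' `|SNP position - probe anchor| < window`, fits
#' `phenotype ~ intercept + dosage + covariates` on complete cases and
#' reports the dosage effect, its standard error, t statistic, and
#' two-sided P from the t distribution with `n - p` residual degrees of
#' freedom. The window test is strict (`<`), so a SNP exactly `window` bp
#' from the anchor is excluded. Pairs whose dosage has zero variance in the
#' analysis sample are skipped (recorded in attribute `"skipped"`).
#'
#' @param geno A [genotype_matrix()].
#' @param pheno A [phenotype_matrix()] on its analysis scale.
#' @param covars Optional numeric covariate matrix (samples x covariates,
#'   rownames = sample IDs); an intercept is always added.
#' @param window Cis window in bp (default 500000).
#' @param min_samples Minimum shared sample count (default 10).
#' @return A tibble with one row per tested pair: `probe`, `snp`, `chrom`,
#'   `snp_pos`, `distance` (signed, SNP minus anchor), `beta`, `se`, `t`,
#'   `p`, `n`.
#' @export
cis_scan <- function(geno, pheno, covars = NULL, window = 5e5,
                     min_samples = 10) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(pheno, "pheno_matrix"))
  if (window <= 0) abort("`window` must be positive.")
  shared <- intersect(geno$samples, pheno$samples)
  if (!is.null(covars)) shared <- intersect(shared, rownames(covars))
  if (length(shared) < min_samples) {
    abort(sprintf("need at least %d shared samples.", min_samples))
  }
  G <- geno$dosages[shared, , drop = FALSE]
  Y <- pheno$values[shared, , drop = FALSE]
  X <- if (is.null(covars)) NULL else as.matrix(covars)[shared, , drop = FALSE]

  snps <- geno$snps
  probes <- pheno$probes
  skipped <- character(0)
  res <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    sel <- which(snps$chrom == probes$chrom[i] &
                   abs(snps$pos - probes$pos[i]) < window)
    if (!length(sel)) next
    y <- Y[, i]
    Gi <- G[, sel, drop = FALSE]
    fit <- marginal_assoc(y, Gi, X)
    bad <- !is.finite(fit$beta)
    if (any(bad)) {
      skipped <- c(skipped, paste0(probes$probe[i], ":", snps$snp[sel][bad],
                                   " zero dosage variance"))
    }
    keep <- !bad
    if (!any(keep)) next
    res[[i]] <- tibble::tibble(
      probe = probes$probe[i],
      snp = snps$snp[sel][keep],
      chrom = probes$chrom[i],
      snp_pos = snps$pos[sel][keep],
      distance = snps$pos[sel][keep] - probes$pos[i],
      beta = fit$beta[keep], se = fit$se[keep], t = fit$t[keep],
      p = fit$p[keep], n = fit$n[keep]
    )
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    out <- tibble::tibble(probe = character(0), snp = character(0),
                          chrom = character(0), snp_pos = numeric(0),
                          distance = numeric(0), beta = numeric(0),
                          se = numeric(0), t = numeric(0), p = numeric(0),
                          n = integer(0))
  }
  attr(out, "skipped") <- skipped
  out
}

# marginal association of y with each column of G, adjusting for X, by
# Frisch-Waugh projection; returns NaN beta for zero-variance dosages.
# Complete cases handled per pair only when missing data are present.
marginal_assoc <- function(y, G, X = NULL) {
  cc_all <- complete.cases(y, if (is.null(X)) y else X)
  has_na <- anyNA(G[cc_all, , drop = FALSE]) || !all(cc_all)
  if (!has_na) {
    n <- length(y)
    k <- design_rank(X, n)  # intercept + covariates
    yr <- drop(residualize(y, X))
    Gr <- residualize(G, X)
    raw_var <- col_vars(G)
    den <- colSums(Gr^2)
    num <- drop(crossprod(Gr, yr))
    beta <- unname(num / den)
    den <- unname(den)
    df <- n - k - 1L
    rss <- pmax(sum(yr^2) - beta^2 * den, 0)
    se <- sqrt(rss / df / den)
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df)
    p <- pmin(pmax(p, 1e-300), 1)
    zero <- raw_var == 0 | den < n * 1e-12
    beta[zero] <- NaN
    list(beta = beta, se = se, t = tval, p = p, n = rep(n, ncol(G)))
  } else {
    m <- ncol(G)
    beta <- se <- tval <- p <- rep(NaN, m)
    nn <- integer(m)
    for (j in seq_len(m)) {
      cc <- complete.cases(y, G[, j], if (is.null(X)) y else X)
      nn[j] <- sum(cc)
      if (nn[j] < 3 || var(G[cc, j]) == 0) next
      r <- marginal_assoc(y[cc], G[cc, j, drop = FALSE],
                          if (is.null(X)) NULL else X[cc, , drop = FALSE])
      beta[j] <- r$beta; se[j] <- r$se; tval[j] <- r$t; p[j] <- r$p
    }
    list(beta = beta, se = se, t = tval, p = p, n = nn)
  }
}

col_vars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Permutation-adjusted empirical P-value for one probe
#'
#' Implements the adaptive-permutation scheme of standard cis-QTL mappers:
#' the phenotype is residualized on the covariates once, the residuals are
#' permuted, and for each permutation the minimum nominal P across the
#' probe's cis-SNPs is recorded (permutation regressions drop the
#' covariates, the standard fast approximation). Permutation stops after
#' `n_perm[1]` rounds if at least 100 permutation minima beat the observed
#' best P, otherwise continues to `n_perm[2]`. A beta distribution is fit
#' to the permutation minima by maximum likelihood and the adjusted
#' empirical P is `BetaCDF(best nominal P; a, b)`. If the permutation
#' minima are degenerate (all identical) the plain `(r + 1) / (N + 1)`
#' empirical P is returned with `beta_a = beta_b = NA` and a warning.
#'
#' @param y Phenotype vector for the probe (analysis scale).
#' @param G Dosage matrix of the probe's cis-SNPs (samples x SNPs).
#' @param covars Optional covariate matrix.
#' @param n_perm Length-2 integer vector: adaptive lower and upper
#'   permutation counts (default `c(1000, 10000)`).
#' @param seed Optional integer seed for the permutation stream.
#' @return A one-row tibble: `best_p`, `n_cis`, `perm_n`, `beta_a`,
#'   `beta_b`, `adj_p`.
#' @export
permutation_adjusted_pvalue <- function(y, G, covars = NULL,
                                        n_perm = c(1000, 10000),
                                        seed = NULL) {
  G <- as.matrix(G)
  if (ncol(G) < 1) abort("need at least one cis-SNP.")
  if (!is.null(seed)) set.seed(derive_seed(seed, "permute"))
  cc <- complete.cases(y, G, if (is.null(covars)) y else covars)
  y <- y[cc]
  G <- G[cc, , drop = FALSE]
  X <- if (is.null(covars)) NULL else as.matrix(covars)[cc, , drop = FALSE]
  n <- length(y)

  obs <- marginal_assoc(y, G, X)
  best_p <- min(obs$p, na.rm = TRUE)

  # permutation minima via the |correlation| shortcut: with a common n and
  # df, the minimum nominal P equals the maximum |cor| of permuted
  # residuals with dosage
  yr <- drop(residualize(y, X))
  ok <- col_vars(G) > 0
  Gs <- scale(G[, ok, drop = FALSE])
  perm_min_p <- function(B) {
    P <- matrix(0, n, B)
    for (b in seq_len(B)) P[, b] <- sample(yr)
    Ps <- scale(P)
    R <- crossprod(Gs, Ps) / (n - 1)      # snps x B
    rmax <- apply(abs(R), 2, max)
    rmax <- pmin(rmax, 1 - 1e-12)
    tstat <- rmax * sqrt((n - 2) / (1 - rmax^2))
    pmin(pmax(2 * pt(-tstat, n - 2), 1e-300), 1)
  }
  mins <- perm_min_p(n_perm[1])
  if (sum(mins <= best_p) < 100 && n_perm[2] > n_perm[1]) {
    mins <- c(mins, perm_min_p(n_perm[2] - n_perm[1]))
  }
  N <- length(mins)

  if (length(unique(mins)) == 1L) {
    warn("degenerate permutation null; returning (r+1)/(N+1) empirical P.")
    adj <- (sum(mins <= best_p) + 1) / (N + 1)
    return(tibble::tibble(best_p = best_p, n_cis = ncol(G), perm_n = N,
                          beta_a = NA_real_, beta_b = NA_real_, adj_p = adj))
  }
  ab <- fit_beta_ml(mins)
  adj_p <- pbeta(best_p, ab[1], ab[2])
  adj_p <- min(max(adj_p, 1e-300), 1 - 1e-16)
  tibble::tibble(best_p = best_p, n_cis = ncol(G), perm_n = N,
                 beta_a = ab[1], beta_b = ab[2], adj_p = adj_p)
}

# maximum-likelihood beta fit (Nelder-Mead on log scale) from a
# moment-matched start; parameters bounded to (1e-3, 1e6)
fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-300), 1 - 1e-16)
  m <- mean(x); v <- var(x)
  v <- min(v, m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  nll <- function(la) {
    a <- exp(la[1]); b <- exp(la[2])
    if (a < 1e-3 || a > 1e6 || b < 1e-3 || b > 1e6) return(1e10)
    -sum(dbeta(x, a, b, log = TRUE))
  }
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  exp(fit$par)
}

#' Probe-level scan with permutation-adjusted P-values
#'
#' Runs [cis_scan()] probe by probe, computes each probe's
#' beta-distribution-adjusted empirical P via
#' [permutation_adjusted_pvalue()], attaches Storey q-values across probes
#' ([fdr_qvalues()]), and records each probe's lead SNP ([select_lead()]).
#'
#' @inheritParams cis_scan
#' @param n_perm Adaptive permutation bounds, default `c(1000, 10000)`.
#' @param seed Integer seed driving all permutation streams.
#' @return A list with `probes` (tibble: `probe`, `best_p`, `n_cis`,
#'   `perm_n`, `beta_a`, `beta_b`, `adj_p`, `qvalue`, `lead_snp`, plus the
#'   lead pair's `beta`, `se`, `p`, `snp_pos`, `distance`) and
#'   `associations` (the full [cis_scan()] table).
#' @export
scan_probes <- function(geno, pheno, covars = NULL, window = 5e5,
                        n_perm = c(1000, 10000), seed = 1L) {
  assoc <- cis_scan(geno, pheno, covars, window)
  if (!nrow(assoc)) abort("no cis SNP-probe pairs in the window.")
  shared <- intersect(geno$samples, pheno$samples)
  if (!is.null(covars)) shared <- intersect(shared, rownames(covars))
  X <- if (is.null(covars)) NULL else as.matrix(covars)[shared, , drop = FALSE]

  probe_ids <- unique(assoc$probe)
  rows <- purrr::map(probe_ids, function(pid) {
    snps_p <- assoc$snp[assoc$probe == pid]
    y <- pheno$values[shared, pid]
    G <- geno$dosages[shared, snps_p, drop = FALSE]
    pr <- permutation_adjusted_pvalue(
      y, G, X, n_perm = n_perm,
      seed = derive_seed(seed, paste0("probe_", pid))
    )
    lead <- select_lead(assoc[assoc$probe == pid, ])
    dplyr::bind_cols(
      tibble::tibble(probe = pid), pr,
      tibble::tibble(lead_snp = lead$snp, lead_beta = lead$beta,
                     lead_se = lead$se, lead_p = lead$p,
                     lead_snp_pos = lead$snp_pos, lead_distance = lead$distance)
    )
  })
  probes <- dplyr::bind_rows(rows)
  probes$qvalue <- fdr_qvalues(probes$adj_p)
  list(probes = probes, associations = assoc)
}

#' Storey q-values with smoothed pi0
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 by a cubic smoothing fit evaluated at lambda = 0.95, then returns
#' step-up monotonized q-values `pi0 * n * p / rank`. With fewer than 100
#' tests pi0 is fixed at 1, which reduces to Benjamini-Hochberg.
#'
#' @param p Vector of P-values in (0, 1].
#' @param pi0 Optional fixed null proportion (overrides estimation).
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_qvalues <- function(p, pi0 = NULL) {
  if (!length(p)) abort("empty P-value vector.")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    abort("P-values must lie in (0, 1].")
  }
  n <- length(p)
  if (is.null(pi0)) {
    if (n < 100) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = 0.95)$y
      pi0 <- min(max(pi0, 1 / n), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * n * p[o] / rank(p[o], ties.method = "max")[seq_along(o)]
  q <- pmin(cummin(pmin(q, 1)), 1)
  q[ro]
}

#' Select the lead SNP among one probe's cis associations
#'
#' The lead is the SNP with the smallest nominal P; exact ties are broken
#' by smaller absolute SNP-probe distance, then lower genomic coordinate.
#'
#' @param assoc A [cis_scan()] tibble restricted to one probe.
#' @return The winning association row (one-row tibble).
#' @export
select_lead <- function(assoc) {
  if (!nrow(assoc)) abort("no associations supplied.")
  assoc |>
    dplyr::arrange(.data$p, abs(.data$distance), .data$snp_pos) |>
    dplyr::slice(1L)
}
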