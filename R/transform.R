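#' Transform raw molecular phenotypes to their analysis scale
#'
#' Expression values are log2-transformed; methylation beta values are
#' logit-transformed, `ln(b / (1 - b))`, after clipping into
#' `[eps, 1 - eps]` so boundary betas remain finite. Optionally each
#' sample's values are quantile-normalized to the average empirical
#' distribution across samples.
#'
#' @param pheno A [phenotype_matrix()] on a raw scale.
#' @param quantile_normalize If `TRUE`, each sample's probe values are
#'   mapped to the mean order statistics across samples, so all samples
#'   share one empirical distribution. Default `FALSE`.
#' @param eps Clipping bound for methylation betas (default 1e-6).
#' @return A [phenotype_matrix()] on the transformed scale.
#' @export
transform_phenotypes <- function(pheno, quantile_normalize = FALSE, eps = 1e-6) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  v <- pheno$values
  if (pheno$scale == "raw-expression") {
    if (any(v <= 0, na.rm = TRUE)) {
      abort("expression values must be positive for log transformation.")
    }
    v <- log2(v)
    scale <- "log-expression"
  } else if (pheno$scale == "raw-methylation") {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort("methylation beta values must lie in [0, 1].")
    }
    v <- pmin(pmax(v, eps), 1 - eps)
    v <- qlogis(v)
    scale <- "logit-methylation"
  } else {
    abort("`pheno` is already on a transformed scale.")
  }
  if (quantile_normalize) v <- quantile_normalize_rows(v)
  phenotype_matrix(v, pheno$probes, scale = scale)
}

# map each row (sample) to the mean order statistics across rows
quantile_normalize_rows <- function(x) {
  ranks <- t(apply(x, 1, rank, ties.method = "average"))
  sorted <- t(apply(x, 1, sort))
  ref <- colMeans(sorted)
  out <- t(apply(ranks, 1, function(r) {
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  }))
  dimnames(out) <- dimnames(x)
  out
}

#' Top principal components of a phenotype panel
#'
#' Computes the top `k` principal-component score vectors of the
#' samples x probes matrix after centering each probe, for use as hidden
#' confounder covariates in QTL scans (expression and methylation PCs are
#' computed separately, with `k` chosen to maximize discoveries).
#'
#' @param pheno A [phenotype_matrix()].
#' @param k Number of components; must satisfy `0 < k < min(n, p)`.
#' @return A numeric matrix (samples x k) of PC scores, columns `PC1..PCk`
#'   ordered by decreasing variance explained, with attribute
#'   `"var_explained"` giving each component's share.
#' @export
compute_phenotype_pcs <- function(pheno, k) {
  stopifnot(inherits(pheno, "pheno_matrix"))
  x <- pheno$values
  if (k <= 0) abort("`k` must be positive.")
  if (k >= min(dim(x))) abort("`k` must be smaller than min(samples, probes).")
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- sv$d^2 / sum(sv$d^2)
  scores
}
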