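# internal numerical helpers

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible child seed from a root seed and a stage tag
#'
#' Each stochastic stage draws from its own stream so that re-running a
#' single stage with the same root seed reproduces it exactly, independent
#' of what ran before.
#'
#' @param seed Integer root seed.
#' @param tag Character stage label.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587L)
}

# residualize columns of y on design X (with intercept); returns matrix
residualize <- function(y, x = NULL) {
  y <- as.matrix(y)
  x <- if (is.null(x)) matrix(1, nrow(y), 1L) else cbind(1, as.matrix(x))
  qr_x <- qr(x)
  y - qr.fitted(qr_x, y)
}

# degrees of freedom consumed by a covariate design (incl. intercept)
design_rank <- function(x, n) {
  x <- if (is.null(x)) matrix(1, n, 1L) else cbind(1, as.matrix(x))
  qr(x)$rank
}

`%||%` <- rlang::`%||%`
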