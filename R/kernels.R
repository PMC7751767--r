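#' Spherical correlation function
#'
#' The spherical variogram correlation kernel: 1 at distance zero, decreasing
#' as `1 - 1.5 (d/r) + 0.5 (d/r)^3` and exactly zero at and beyond the range
#' `r`. Valid (positive semi-definite) in up to three spatial dimensions. A
#' range of zero is treated as the pure-nugget convention: correlation 1 at
#' d = 0 and 0 elsewhere.
#'
#' @param d distance(s), cm, >= 0. Vector or matrix.
#' @param r range parameter, cm, >= 0.
#' @return correlation value(s), same shape as `d`.
#' @export
spherical_correlation <- function(d, r) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (length(r) != 1L || r < 0) stop("range r must be a single non-negative number")
  if (r == 0) return(ifelse(d == 0, 1, 0) * 1.0)
  u <- d / r
  out <- ifelse(u < 1, 1 - 1.5 * u + 0.5 * u^3, 0)
  out[d == 0] <- 1
  out
}

#' Rational quadratic correlation function
#'
#' `corRatio(d; r) = 1 / (1 + (d/r)^2)`: 1 at distance zero, strictly
#' decreasing, approaching zero asymptotically. Used for the residual
#' covariance of phenotype regressions, where it gives in-field range
#' estimates.
#'
#' @param d distance(s), cm, >= 0.
#' @param r range parameter, cm, > 0.
#' @return correlation value(s), same shape as `d`.
#' @export
ratio_correlation <- function(d, r) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (length(r) != 1L || r <= 0) stop("range r must be a single positive number")
  1 / (1 + (d / r)^2)
}

#' Residual correlation matrix with nugget
#'
#' Builds `C = n I + (1 - n) K(r)` where `K` is a unit-diagonal spatial
#' correlation matrix. Multiplying by sigma^2 gives the residual covariance of
#' the spatial linear models: the nugget `n` is the i.i.d. fraction of the
#' residual variance, `1 - n` the spatially correlated fraction.
#'
#' @param dmat distance matrix (cm).
#' @param nugget nugget fraction in `[0, 1]`.
#' @param range_r range (cm).
#' @param kernel `"spherical"` or `"ratio"`.
#' @return correlation matrix with unit diagonal.
#' @export
nugget_correlation <- function(dmat, nugget, range_r,
                               kernel = c("spherical", "ratio")) {
  kernel <- match.arg(kernel)
  if (nugget < 0 || nugget > 1) stop("nugget must lie in [0, 1]")
  K <- if (kernel == "spherical") spherical_correlation(dmat, range_r)
       else ratio_correlation(dmat, range_r)
  C <- nugget * diag(nrow(dmat)) + (1 - nugget) * K
  diag(C) <- 1
  C
}
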