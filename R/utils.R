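#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the step-up false
#' discovery rate procedure: q_(i) = min_{j >= i} ( m * p_(j) / j ), capped at
#' 1, returned in the original input order. `NA` p-values stay `NA` and do not
#' count towards the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  # cummin over decreasing order enforces monotonicity of the step-up rule
  q[ok] <- pmin(1, cummin(m / seq(m, 1L) * pv[o]))[ro]
  q
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assert that a matrix is numeric with dimnames
#' @keywords internal
check_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("%s must be a numeric matrix", what))
  invisible(m)
}

#' Deterministic child seed derived from a master seed
#'
#' Derives stream-specific 32-bit seeds so that independent stages of a
#' simulation or analysis can be reseeded without correlated streams.
#' @param seed master integer seed.
#' @param stream integer stream index (>= 1).
#' @return an integer seed below 2^31.
#' @keywords internal
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

#' Z-score the rows of a matrix
#'
#' @param m numeric matrix (features x samples).
#' @return matrix of the same shape with each row centered and scaled to unit
#'   sample standard deviation; constant rows give an error.
#' @export
zscore_rows <- function(m) {
  check_matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  if (any(s == 0)) stop("cannot z-score constant feature(s): ",
                        paste(utils::head(rownames(m)[s == 0], 3), collapse = ", "))
  (m - mu) / s
}
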