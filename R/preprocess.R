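#' Filter genes by counts-per-million
#'
#' Keeps the genes reaching at least `min_cpm` counts per million (computed
#' against raw library sizes, i.e. column sums of the unfiltered matrix) in at
#' least `min_samples` sample(s).
#'
#' @param counts non-negative gene x sample count matrix.
#' @param min_cpm CPM threshold (comparison is `>=`).
#' @param min_samples number of samples that must reach the threshold.
#' @return the filtered count matrix, with attributes `n_kept` / `n_removed`.
#' @export
cpm_filter <- function(counts, min_cpm = 5, min_samples = 1L) {
  check_matrix(counts, "count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0] %||% which(lib == 0), collapse = ", "))
  cpm <- sweep(counts, 2L, lib, `/`) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Median-of-ratios size factors
#'
#' DESeq-style library normalization: a pseudo-reference is the per-gene
#' geometric mean across samples over the genes with nonzero counts in every
#' sample, and each sample's size factor is the median of its count/reference
#' ratios over those genes.
#'
#' @param counts count matrix (genes x samples).
#' @param pseudo_reference if `TRUE` and no gene is positive in all samples,
#'   fall back to computing geometric means over nonzero entries only.
#' @return named numeric vector of size factors (> 0), one per sample.
#' @export
median_of_ratios_size_factors <- function(counts, pseudo_reference = FALSE) {
  check_matrix(counts, "count matrix")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    if (!pseudo_reference)
      stop("no gene has nonzero counts in all samples; ",
           "set pseudo_reference = TRUE to use a nonzero-entry reference")
    logref <- apply(counts, 1L, function(x) mean(log(x[x > 0])))
    use <- is.finite(logref)
    sf <- apply(counts[use, , drop = FALSE], 2L, function(x) {
      r <- log(x[x > 0]) - logref[use][x > 0]
      exp(stats::median(r))
    })
  } else {
    sub <- counts[allpos, , drop = FALSE]
    logref <- rowMeans(log(sub))
    sf <- apply(sub, 2L, function(x) exp(stats::median(log(x) - logref)))
  }
  stats::setNames(sf, colnames(counts))
}

#' Log2 transform with a data-derived pseudocount
#'
#' Adds `0.5 * delta`, with `delta` the smallest nonzero entry of the whole
#' matrix, then takes log2. `delta` is stored so the transform can be inverted
#' exactly; [back_transform_linear()] restores the linear scale and subtracts
#' the pseudocount again so the matrix minimum returns to zero.
#'
#' @param m non-negative matrix (typically size-factor-normalized counts).
#' @return object of class `normalized_matrix`: list with `values` (log2
#'   matrix), `pseudocount_delta`, `size_factors` (optional, see
#'   [normalize_counts()]), `provenance`.
#' @export
log_transform_with_pseudocount <- function(m) {
  check_matrix(m)
  if (any(m < 0)) stop("matrix must be non-negative")
  nz <- m[m > 0]
  if (!length(nz)) stop("all-zero matrix: no nonzero entry to derive the pseudocount")
  delta <- min(nz)
  structure(list(values = log2(m + 0.5 * delta), pseudocount_delta = delta,
                 size_factors = NULL,
                 provenance = "log2(x + 0.5*delta)"),
            class = "normalized_matrix")
}

#' Invert the pseudocount log2 transform
#'
#' @param nm a `normalized_matrix` (or a log2 matrix plus `delta`).
#' @param values optional log2 matrix overriding `nm$values` (e.g. after
#'   residualization on the log scale).
#' @return linear-scale matrix with the pseudocount subtracted and negative
#'   round-off clipped at zero, so the matrix minimum is zero again.
#' @export
back_transform_linear <- function(nm, values = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- values %||% nm$values
  out <- 2^v - 0.5 * nm$pseudocount_delta
  pmax(out, 0)
}

#' Full count normalization: CPM filter, size factors, pseudocount log2
#'
#' @param counts raw count matrix.
#' @param min_cpm,min_samples CPM filter settings.
#' @return `normalized_matrix` with `size_factors` filled in and provenance
#'   listing the applied steps in order.
#' @export
normalize_counts <- function(counts, min_cpm = 5, min_samples = 1L) {
  filt <- cpm_filter(counts, min_cpm, min_samples)
  sf <- median_of_ratios_size_factors(filt)
  norm <- sweep(filt, 2L, sf, `/`)
  nm <- log_transform_with_pseudocount(norm)
  nm$size_factors <- sf
  nm$provenance <- c(sprintf("cpm_filter(min_cpm=%g, min_samples=%d): kept %d, removed %d",
                             min_cpm, min_samples, attr(filt, "n_kept"),
                             attr(filt, "n_removed")),
                     "median_of_ratios_size_factors", nm$provenance)
  nm
}

## two-sided Grubbs critical value at significance alpha for sample size n
grubbs_critical <- function(n, alpha = 0.01) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative two-sided Grubbs outlier masking
#'
#' Applied per feature row (on log2 intensities): while the most extreme value
#' has a Grubbs statistic `G = max|x - mean| / sd` above the two-sided
#' critical value at `alpha`, that value is set to `NA`. At most `n - 3`
#' values are removed per row. Rows ending with more than `max_missing_frac`
#' missing values are dropped.
#'
#' @param m feature x sample matrix, may already contain `NA`s.
#' @param alpha per-test significance level of the Grubbs test.
#' @param max_missing_frac rows with a greater missing fraction are removed.
#' @return list with `values` (masked matrix, dropped rows removed),
#'   `n_masked` (outliers converted to `NA`), `dropped` (row names removed by
#'   the missingness rule).
#' @export
grubbs_outlier_mask <- function(m, alpha = 0.01, max_missing_frac = 0.5) {
  check_matrix(m)
  n_masked <- 0L
  for (i in seq_len(nrow(m))) {
    repeat {
      x <- m[i, ]
      obs <- which(!is.na(x))
      if (length(obs) < 3) {
        warning("row ", rownames(m)[i] %||% i, " has fewer than 3 observed values; skipped")
        break
      }
      if (length(obs) == 3) break  # cap at n - 3 removals: keep >= 3 values
      v <- x[obs]
      s <- stats::sd(v)
      if (s == 0) break
      dev <- abs(v - mean(v))
      G <- max(dev) / s
      if (G > grubbs_critical(length(v), alpha)) {
        m[i, obs[which.max(dev)]] <- NA
        n_masked <- n_masked + 1L
      } else break
    }
  }
  miss <- rowMeans(is.na(m))
  drop <- miss > max_missing_frac
  list(values = m[!drop, , drop = FALSE], n_masked = n_masked,
       dropped = (rownames(m) %||% as.character(seq_len(nrow(m))))[drop])
}

#' Iterative low-rank SVD imputation
#'
#' Replaces missing entries by the corresponding entries of a rank-`rank`
#' truncated SVD reconstruction, iterating until the relative change of the
#' imputed entries falls below `tol`. Observed entries are never modified.
#' This stands in for Bayesian PCA imputation: both fill missing values from a
#' low-dimensional linear reconstruction of the complete entries.
#'
#' @param m matrix with `NA`s; every row and column needs >= 1 observed value.
#' @param rank reconstruction rank (default `min(n_col - 2, 48)`).
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return completed matrix.
#' @export
impute_missing <- function(m, rank = NULL, tol = 1e-6, max_iter = 500L) {
  check_matrix(m)
  miss <- is.na(m)
  if (!any(miss)) return(m)
  if (any(rowSums(!miss) == 0)) stop("row(s) with no observed value")
  if (any(colSums(!miss) == 0)) stop("column(s) with no observed value")
  rank <- rank %||% min(ncol(m) - 2L, 48L)
  rank <- max(1L, min(rank, nrow(m) - 1L, ncol(m) - 1L))
  rmean <- rowMeans(m, na.rm = TRUE)
  x <- m
  x[miss] <- rmean[row(m)[miss]]
  for (it in seq_len(max_iter)) {
    sv <- svd(x, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    newvals <- recon[miss]
    delta <- sqrt(sum((newvals - x[miss])^2)) /
      max(sqrt(sum(x[miss]^2)), .Machine$double.eps)
    x[miss] <- newvals
    if (delta < tol) return(x)
  }
  stop(sprintf("imputation did not converge in %d iterations (last relative change %.3g)",
               max_iter, delta))
}

#' Quantile normalization
#'
#' Gives every column the same distribution: the mean quantile vector across
#' columns. Ties within a column receive the mean of the quantile values they
#' span (average-rank convention), so the procedure is idempotent.
#'
#' @param m complete numeric matrix (features x samples).
#' @return quantile-normalized matrix.
#' @export
quantile_normalize <- function(m) {
  check_matrix(m)
  if (any(is.na(m))) stop("quantile normalization requires a complete matrix")
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  out <- apply(m, 2L, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    # tied entries share the mean of the quantile values their ranks span
    stats::ave(v, x, FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Full metabolite preprocessing
#'
#' log2 transform, iterative Grubbs outlier masking, >50% missingness filter,
#' low-rank imputation and quantile normalization, in that order.
#'
#' @param intensities metabolite x sample matrix (linear scale, may have `NA`s).
#' @param alpha Grubbs significance level.
#' @param rank imputation rank.
#' @return `normalized_matrix` (log2 scale) with provenance.
#' @export
normalize_metabolites <- function(intensities, alpha = 0.01, rank = NULL) {
  check_matrix(intensities)
  lg <- log2(intensities)
  masked <- grubbs_outlier_mask(lg, alpha = alpha)
  imputed <- impute_missing(masked$values, rank = rank)
  qn <- quantile_normalize(imputed)
  structure(list(values = qn, pseudocount_delta = NA_real_, size_factors = NULL,
                 provenance = c("log2",
                                sprintf("grubbs_outlier_mask(alpha=%g): %d masked, %d rows dropped",
                                        alpha, masked$n_masked, length(masked$dropped)),
                                "impute_missing", "quantile_normalize")),
            class = "normalized_matrix")
}
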