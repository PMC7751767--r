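#' Moran's I spatial autocorrelation test
#'
#' Global Moran's I with inverse-distance weights `w_ij = 1/d_ij`
#' (`w_ii = 0`), optionally row-standardized. The analytic p-value uses the
#' normal approximation under the randomization null (variance formula with
#' the sample kurtosis correction); a permutation p-value is available.
#'
#' @param x numeric plant vector (nonconstant).
#' @param layout a `field_layout`, or a precomputed weight matrix via `W`.
#' @param W optional weight matrix overriding the inverse-distance default.
#' @param row_standardize divide each row of `W` by its sum.
#' @param method `"analytic"` (randomization normal approximation) or
#'   `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed permutation seed.
#' @return list of class `moran_result`: `I`, `expected_I` (`-1/(N-1)`), `sd`,
#'   `p` (two-sided).
#' @export
morans_i <- function(x, layout = NULL, W = NULL, row_standardize = FALSE,
                     method = c("analytic", "permutation"), n_perm = 999L,
                     seed = 1L) {
  method <- match.arg(method)
  if (stats::var(x) == 0) stop("degenerate input: constant vector")
  if (is.null(W)) {
    d <- field_distances(layout)
    if (any(d[upper.tri(d)] == 0))
      stop("coincident plant positions give infinite inverse-distance weights")
    W <- 1 / d
    diag(W) <- 0
  }
  if (row_standardize) W <- W / rowSums(W)
  N <- length(x)
  stat <- function(z) {
    zc <- z - mean(z)
    (N / sum(W)) * drop(zc %*% W %*% zc) / sum(zc^2)
  }
  I <- stat(x)
  EI <- -1 / (N - 1)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  zc <- x - mean(x)
  b2 <- N * sum(zc^4) / sum(zc^2)^2
  varI <- (N * ((N^2 - 3 * N + 3) * S1 - N * S2 + 3 * S0^2) -
             b2 * ((N^2 - N) * S1 - 2 * N * S2 + 6 * S0^2)) /
    ((N - 1) * (N - 2) * (N - 3) * S0^2) - EI^2
  sdI <- sqrt(varI)
  if (method == "analytic") {
    p <- 2 * stats::pnorm(-abs(I - EI) / sdI)
  } else {
    set.seed(seed)
    perm <- replicate(n_perm, stat(x[sample.int(N)]))
    p <- (1 + sum(abs(perm - EI) >= abs(I - EI))) / (n_perm + 1)
  }
  structure(list(I = I, expected_I = EI, sd = sdI, p = p), class = "moran_result")
}

#' Moran screening of a feature matrix
#'
#' Runs [morans_i()] on every row and BH-adjusts the p-values.
#'
#' @param m feature x plant matrix.
#' @param layout a `field_layout`.
#' @param ... passed to [morans_i()].
#' @return data.frame with `feature`, `I`, `p`, `q` (constant rows get `NA`).
#' @export
moran_screen <- function(m, layout, ...) {
  check_matrix(m)
  W <- 1 / field_distances(layout)
  diag(W) <- 0
  res <- apply(m, 1L, function(x) {
    if (stats::var(x) == 0) return(c(NA_real_, NA_real_))
    r <- morans_i(x, W = W, ...)
    c(r$I, r$p)
  })
  out <- data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
                    I = res[1L, ], p = res[2L, ], stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Cluster spatially autocorrelated features
#'
#' Z-scores the profiles of the features passing the Moran q-threshold and
#' clusters them by Ward agglomeration (ward.D2 on squared Euclidean
#' distance, i.e. `hclust(ward.D2)` on Euclidean distances), cutting the tree
#' into `k` clusters. When `k` is `NULL` it is chosen to maximize the mean
#' silhouette width over `k = 2..k_max`.
#'
#' @param m residualized feature x plant matrix.
#' @param layout a `field_layout`.
#' @param moran_q_threshold keep features with Moran q below or equal to this.
#' @param k number of clusters (`NULL` = silhouette-selected).
#' @param k_max upper bound for the silhouette search.
#' @param moran_table optional precomputed [moran_screen()] result.
#' @return list of class `feature_clusters`: `membership` (named integer
#'   vector), `mean_profiles` (cluster x plant matrix of mean z-scored
#'   profiles), `k`, `moran` (the screen table); empty with a warning if
#'   fewer than 2 features pass.
#' @export
cluster_autocorrelated_features <- function(m, layout, moran_q_threshold = 0.01,
                                            k = NULL, k_max = 20L,
                                            moran_table = NULL) {
  mt <- moran_table %||% moran_screen(m, layout)
  pass <- !is.na(mt$q) & mt$q <= moran_q_threshold
  if (sum(pass) < 2) {
    warning("fewer than 2 features pass the Moran q-threshold; empty result")
    return(structure(list(membership = integer(0), mean_profiles = NULL,
                          k = 0L, moran = mt), class = "feature_clusters"))
  }
  z <- zscore_rows(m[pass, , drop = FALSE])
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  dmat <- NULL
  if (is.null(k)) {
    if (nrow(z) <= 3) {
      k <- 2L
    } else {
      dmat <- as.matrix(stats::dist(z))
      ks <- 2L:min(k_max, nrow(z) - 1L)
      sil <- vapply(ks, function(kk)
        mean_silhouette(stats::cutree(hc, kk), dmat), numeric(1))
      k <- ks[which.max(sil)]
    }
  }
  membership <- stats::cutree(hc, k)
  prof <- t(vapply(seq_len(k), function(ci)
    colMeans(z[membership == ci, , drop = FALSE]), numeric(ncol(z))))
  rownames(prof) <- sprintf("cluster_%d", seq_len(k))
  colnames(prof) <- colnames(m)
  structure(list(membership = membership, mean_profiles = prof, k = k,
                 moran = mt), class = "feature_clusters")
}

## mean silhouette width for a hard clustering given a distance matrix
mean_silhouette <- function(labels, dmat) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(dmat[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Correlate cluster mean profiles with phenotypes
#'
#' Pearson correlation between each cluster's mean z-scored profile and each
#' phenotype, with p-values BH-adjusted within each phenotype across clusters.
#'
#' @param clusters a `feature_clusters` object.
#' @param phenotypes trait x plant matrix (plants matching the cluster
#'   profiles by column name, or same order).
#' @return data.frame with `cluster`, `phenotype`, `r`, `p`, `q`.
#' @export
cluster_phenotype_correlation <- function(clusters, phenotypes) {
  stopifnot(inherits(clusters, "feature_clusters"))
  prof <- clusters$mean_profiles
  if (is.null(prof)) stop("empty cluster set")
  check_matrix(phenotypes, "phenotype matrix")
  shared <- intersect(colnames(prof), colnames(phenotypes)) %||% colnames(prof)
  if (!is.null(colnames(prof)) && !is.null(colnames(phenotypes))) {
    prof <- prof[, shared, drop = FALSE]
    phenotypes <- phenotypes[, shared, drop = FALSE]
  }
  if (ncol(prof) < 3) stop("fewer than 3 shared plants")
  out <- expand.grid(cluster = rownames(prof), phenotype = rownames(phenotypes),
                     stringsAsFactors = FALSE)
  ct <- Map(function(cl, ph) {
    t <- stats::cor.test(prof[cl, ], phenotypes[ph, ])
    c(unname(t$estimate), t$p.value)
  }, out$cluster, out$phenotype)
  out$r <- vapply(ct, `[`, numeric(1), 1L)
  out$p <- vapply(ct, `[`, numeric(1), 2L)
  out$q <- NA_real_
  for (ph in unique(out$phenotype)) {
    sel <- out$phenotype == ph
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  out
}

#' Correlation between inter-plant distance structures of two data layers
#'
#' Z-scores each layer's feature profiles, computes Euclidean distances
#' between plants within each layer (or uses field distances when a layout is
#' given), and Pearson-correlates the two upper-triangle distance vectors.
#' The optional permutation p-value is a Mantel test (plants permuted in one
#' layer).
#'
#' @param a feature x plant matrix.
#' @param b second layer: a matrix like `a`, or a `field_layout` whose
#'   physical plant distances are used.
#' @param n_perm Mantel permutations (0 = analytic-only: p is `NA`).
#' @param seed permutation seed.
#' @return list with `r`, `p` (permutation, or `NA`), `n_pairs`.
#' @export
layer_distance_correlation <- function(a, b, n_perm = 0L, seed = 1L) {
  da <- as.matrix(stats::dist(t(zscore_rows(a))))
  db <- if (is.data.frame(b)) field_distances(b)
        else as.matrix(stats::dist(t(zscore_rows(b))))
  if (!all(dim(da) == dim(db))) stop("layers cover different plant sets")
  if (nrow(da) < 4) stop("need >= 4 shared plants")
  ut <- upper.tri(da)
  r <- stats::cor(da[ut], db[ut])
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    n <- nrow(da)
    perm <- replicate(n_perm, {
      o <- sample.int(n)
      stats::cor(da[o, o][ut], db[ut])
    })
    p <- (1 + sum(abs(perm) >= abs(r))) / (n_perm + 1)
  }
  list(r = r, p = p, n_pairs = sum(ut))
}
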