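#' Spatially adjusted Pearson correlation for one gene pair
#'
#' Fits `y = beta x + eps` (no intercept; both profiles z-scored) with
#' residuals following the spherical-variogram-with-nugget correlation by
#' restricted maximum likelihood. When the optimum reduces to the i.i.d.
#' model (range to zero or nugget to one), the fit is exactly ordinary least
#' squares on the z-scored profiles, whose coefficient equals the Pearson
#' correlation; `fitted_by` records which route applied. The Wald p-value on
#' beta uses a t reference with `n_plants - 1` degrees of freedom.
#'
#' @param x,y z-scored log2 expression profiles over the same plants.
#' @param layout a `field_layout` (or pass a prebuilt `cache`).
#' @param cache optional [spatial_kernel_cache()].
#' @param control a [reml_control()].
#' @return list of class `pair_correlation`: `beta`, `p`, `se`, `sigma`,
#'   `nugget`, `range_r`, `fitted_by` (`"GLS"` / `"OLS-equivalent"`).
#' @export
spatially_adjusted_correlation <- function(x, y, layout = NULL, cache = NULL,
                                           control = reml_control()) {
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: constant profile")
  if (length(x) != length(y)) stop("profiles cover different plant sets")
  if (is.null(cache)) {
    if (is.null(layout)) stop("provide a layout or a kernel cache")
    cache <- spatial_kernel_cache(field_distances(layout), "spherical", control)
  }
  X <- matrix(x, ncol = 1L, dimnames = list(NULL, "beta"))
  fit <- reml_fit_one(y, X, cache, control)
  structure(list(beta = unname(fit$beta), p = unname(fit$pvalues),
                 se = unname(fit$se), sigma = fit$sigma, nugget = fit$nugget,
                 range_r = fit$range_r,
                 fitted_by = if (fit$fitted_by == "REML") "GLS" else "OLS-equivalent"),
            class = "pair_correlation")
}

#' Build the spatially adjusted co-expression network
#'
#' Tests all gene pairs with [spatially_adjusted_correlation()], Bonferroni-
#' corrects the p-values by the number of pairs tested, and keeps the pairs
#' with corrected p below or equal to `alpha` as undirected edges.
#'
#' @param m log2 gene x plant matrix (z-scored internally).
#' @param layout a `field_layout`.
#' @param alpha threshold on the Bonferroni-corrected p-value.
#' @param spatial set `FALSE` to skip the spatial fit entirely and use plain
#'   Pearson correlation (the comparison-network route).
#' @param control a [reml_control()].
#' @return object of class `coexpression_network`: `nodes`, `edges`
#'   (data.frame gene_a, gene_b, beta, p_raw, p_bonferroni, nugget, range_r,
#'   fitted_by), `pairs` (all tested pairs, for fixed-edge thresholding),
#'   `n_pairs_tested`, `spatial_fraction` (pairs with a retained nonzero
#'   range).
#' @export
build_network <- function(m, layout, alpha = 0.01, spatial = TRUE,
                          control = reml_control()) {
  check_matrix(m)
  if (ncol(m) < 3) stop("need at least 3 plants")
  if (nrow(m) < 2) stop("need at least 2 genes")
  genes <- rownames(m) %||% sprintf("g%d", seq_len(nrow(m)))
  z <- zscore_rows(m)
  idx <- utils::combn(nrow(z), 2L)
  n_pairs <- ncol(idx)
  if (spatial) {
    cache <- spatial_kernel_cache(field_distances(layout), "spherical", control)
    res <- vapply(seq_len(n_pairs), function(k) {
      pc <- spatially_adjusted_correlation(z[idx[1L, k], ], z[idx[2L, k], ],
                                           cache = cache, control = control)
      c(pc$beta, pc$p, pc$nugget, pc$range_r, pc$fitted_by == "GLS")
    }, numeric(5))
  } else {
    n <- ncol(z)
    res <- vapply(seq_len(n_pairs), function(k) {
      r <- sum(z[idx[1L, k], ] * z[idx[2L, k], ]) / (n - 1)
      # no-intercept OLS on z-scored profiles: beta = r, t with n - 1 df
      se <- sqrt(max(0, (sum(z[idx[2L, k], ]^2) - r^2 * sum(z[idx[1L, k], ]^2))) /
                   ((n - 1) * sum(z[idx[1L, k], ]^2)))
      p <- 2 * stats::pt(-abs(r / se), df = n - 1)
      c(r, p, 1, 0, 0)
    }, numeric(5))
  }
  pairs <- data.frame(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]],
                      beta = res[1L, ], p_raw = res[2L, ],
                      p_bonferroni = pmin(1, res[2L, ] * n_pairs),
                      nugget = res[3L, ], range_r = res[4L, ],
                      fitted_by = ifelse(res[5L, ] == 1, "GLS", "OLS-equivalent"),
                      stringsAsFactors = FALSE)
  edges <- pairs[pairs$p_bonferroni <= alpha, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, pairs = pairs,
                 n_pairs_tested = n_pairs,
                 spatial_fraction = mean(pairs$fitted_by == "GLS")),
            class = "coexpression_network")
}

#' Threshold a pair table to a fixed number of edges
#'
#' Keeps exactly the `k_edges` strongest pairs: ascending p-value, ties broken
#' by descending absolute coefficient, then lexicographic pair id, making the
#' selection deterministic.
#'
#' @param network a `coexpression_network` (its full `pairs` table is used)
#'   or a pair data.frame with columns `gene_a`, `gene_b`, `beta`, `p_raw`.
#' @param k_edges number of edges to keep.
#' @return a `coexpression_network` with exactly `k_edges` edges.
#' @export
threshold_to_edge_count <- function(network, k_edges) {
  pairs <- if (inherits(network, "coexpression_network")) network$pairs else network
  nodes <- if (inherits(network, "coexpression_network")) network$nodes
           else unique(c(pairs$gene_a, pairs$gene_b))
  if (nrow(pairs) < k_edges)
    stop(sprintf("only %d pairs available, cannot keep %d edges",
                 nrow(pairs), k_edges))
  o <- order(pairs$p_raw, -abs(pairs$beta), pairs$gene_a, pairs$gene_b)
  edges <- pairs[o[seq_len(k_edges)], , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, pairs = pairs,
                 n_pairs_tested = nrow(pairs),
                 spatial_fraction = if (!is.null(pairs$fitted_by))
                   mean(pairs$fitted_by == "GLS") else NA_real_),
            class = "coexpression_network")
}

#' Density of an undirected simple graph from node and edge counts
#'
#' @param n_nodes,n_edges counts.
#' @return `2E / (N (N - 1))`.
#' @export
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Topology statistics of a co-expression network
#'
#' Number of nodes and edges, density `2E/(N(N-1))`, average local clustering
#' coefficient (nodes of degree 0 or 1 contribute 0), and the fraction of
#' nodes without any annotation if an annotation table is supplied.
#'
#' @param network a `coexpression_network`, or a data.frame of edges with
#'   columns `gene_a`, `gene_b` (in which case `nodes` may be supplied).
#' @param annotations optional data.frame with columns `gene`, `term`.
#' @param nodes optional node set overriding the network's.
#' @return list with `n_nodes`, `n_edges`, `density`,
#'   `avg_clustering_coefficient`, `unannotated_fraction` (`NA` without
#'   annotations). Empty graphs return zeros with a warning.
#' @export
network_stats <- function(network, annotations = NULL, nodes = NULL) {
  edges <- if (inherits(network, "coexpression_network")) network$edges else network
  nodes <- nodes %||% if (inherits(network, "coexpression_network"))
    network$nodes else unique(c(edges$gene_a, edges$gene_b))
  N <- length(nodes)
  if (nrow(edges) == 0) {
    warning("empty graph")
    return(list(n_nodes = N, n_edges = 0L, density = 0,
                avg_clustering_coefficient = 0, unannotated_fraction = NA_real_))
  }
  adj <- adjacency_list(edges, nodes)
  deg <- lengths(adj)
  cc <- vapply(seq_along(nodes), function(i) {
    if (deg[i] < 2) return(0)
    nb <- adj[[i]]
    links <- 0L
    for (j in seq_along(nb)) {
      links <- links + sum(adj[[nb[j]]] %in% nb[-seq_len(j)])
    }
    2 * links / (deg[i] * (deg[i] - 1))
  }, numeric(1))
  unann <- NA_real_
  if (!is.null(annotations))
    unann <- mean(!nodes %in% unique(annotations$gene))
  list(n_nodes = N, n_edges = nrow(edges),
       density = graph_density(N, nrow(edges)),
       avg_clustering_coefficient = mean(cc),
       unannotated_fraction = unann)
}

## named list: node -> integer indices of its neighbours
adjacency_list <- function(edges, nodes) {
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  if (any(is.na(ia)) || any(is.na(ib))) stop("edge endpoint not in node set")
  if (any(ia == ib)) stop("self-loop in edge table")
  adj <- vector("list", length(nodes))
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  names(adj) <- nodes
  adj
}

#' Degree-preserving edge rewiring
#'
#' Randomizes a network by repeated double-edge swaps, preserving every
#' node's degree while destroying any functional signal; the standard negative
#' control for guilt-by-association benchmarks.
#'
#' @param network a `coexpression_network`.
#' @param n_swaps number of attempted swaps (default 10x the edge count).
#' @param seed integer seed.
#' @return a `coexpression_network` with rewired edges (beta/p columns
#'   dropped).
#' @export
rewire_network <- function(network, n_swaps = NULL, seed = 1L) {
  stopifnot(inherits(network, "coexpression_network"))
  e <- network$edges[, c("gene_a", "gene_b")]
  m <- nrow(e)
  n_swaps <- n_swaps %||% (10L * m)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- new.env(hash = TRUE)
  for (k in seq_len(m)) assign(key(e$gene_a[k], e$gene_b[k]), TRUE, envir = have)
  set.seed(seed)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(m, 2L)
    a1 <- e$gene_a[ij[1]]; b1 <- e$gene_b[ij[1]]
    a2 <- e$gene_a[ij[2]]; b2 <- e$gene_b[ij[2]]
    # swap partners: (a1,b2), (a2,b1)
    if (a1 == b2 || a2 == b1) next
    k1 <- key(a1, b2); k2 <- key(a2, b1)
    if (exists(k1, envir = have, inherits = FALSE) ||
        exists(k2, envir = have, inherits = FALSE) || k1 == k2) next
    rm(list = c(key(a1, b1), key(a2, b2)), envir = have)
    assign(k1, TRUE, envir = have); assign(k2, TRUE, envir = have)
    e$gene_b[ij[1]] <- b2; e$gene_b[ij[2]] <- b1
  }
  structure(list(nodes = network$nodes, edges = e, pairs = NULL,
                 n_pairs_tested = network$n_pairs_tested,
                 spatial_fraction = NA_real_),
            class = "coexpression_network")
}
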