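#' Regression random forest
#'
#' Bootstrap-aggregated CART regression trees with variance-reduction splits,
#' per-node feature subsampling and mean-decrease-in-impurity importances,
#' implemented in compiled code. Deterministic given `seed`.
#'
#' @param X sample x feature numeric matrix.
#' @param y numeric response.
#' @param n_trees number of trees (default 500).
#' @param max_features feature subsampling rule per split: `"sqrt"`,
#'   `"log2"`, `"none"` (all features) or a fraction such as `0.33`.
#' @param min_samples_split minimum node size eligible for splitting.
#' @param seed integer seed.
#' @return object of class `random_forest` with `importance` (MDI, summing to
#'   1 over features when any split occurred).
#' @export
random_forest <- function(X, y, n_trees = 500L, max_features = "sqrt",
                          min_samples_split = 2L, seed = 1L) {
  check_matrix(X, "feature matrix")
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  mtry <- if (identical(max_features, "sqrt")) ceiling(sqrt(p))
    else if (identical(max_features, "log2")) max(1L, ceiling(log2(p)))
    else if (identical(max_features, "none") || is.null(max_features)) p
    else if (is.numeric(max_features)) max(1L, ceiling(max_features * p))
    else stop("unknown max_features rule: ", max_features)
  model <- .rf_fit(X, as.numeric(y), as.integer(n_trees), as.integer(mtry),
                   as.integer(min_samples_split), as.integer(seed))
  structure(list(trees = model$trees,
                 importance = stats::setNames(model$importance,
                                              colnames(X) %||% paste0("f", seq_len(p))),
                 n_trees = n_trees, mtry = mtry,
                 min_samples_split = min_samples_split),
            class = "random_forest")
}

#' @param object a `random_forest`.
#' @param newdata sample x feature matrix.
#' @param ... unused.
#' @rdname random_forest
#' @export
predict.random_forest <- function(object, newdata, ...) {
  drop(.rf_predict(object[c("trees")], as.matrix(newdata)))
}
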