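#' Out-of-fold R-squared
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with the mean taken
#' over the observed values of the evaluation set. Zero when every prediction
#' equals that mean, negative when predictions do worse, one only for exact
#' predictions. `mode = "median"` computes the statistic per fold and returns
#' the median.
#'
#' @param predictions predicted values.
#' @param observed observed values, aligned with `predictions`.
#' @param mode `"pooled"` or `"median"`.
#' @param folds fold labels (required for `mode = "median"`).
#' @return a single R-squared value.
#' @export
oob_r2 <- function(predictions, observed, mode = c("pooled", "median"),
                   folds = NULL) {
  mode <- match.arg(mode)
  if (length(predictions) != length(observed) || length(observed) < 2)
    stop("need >= 2 aligned prediction/observation pairs")
  r2 <- function(p, o) 1 - sum((o - p)^2) / sum((o - mean(o))^2)
  if (mode == "pooled") return(r2(predictions, observed))
  if (is.null(folds)) stop("median mode needs fold labels")
  stats::median(vapply(split(seq_along(observed), folds), function(i) {
    if (stats::var(observed[i]) == 0) return(NA_real_)
    r2(predictions[i], observed[i])
  }, numeric(1)), na.rm = TRUE)
}

#' Permutation p-value for a performance score
#'
#' `p = (n + 1) / (k + 1)` where `n` counts permuted scores greater than or
#' equal to the true score and `k` is the number of permutations; bounded
#' below by `1/(k+1)`.
#'
#' @param true_score observed score.
#' @param permuted_scores scores of the permuted models.
#' @return list with `p`, `n_exceed`, `k`.
#' @export
permutation_pvalue <- function(true_score, permuted_scores) {
  k <- length(permuted_scores)
  if (k < 1) stop("need at least one permutation")
  n <- sum(permuted_scores >= true_score)
  list(p = (n + 1) / (k + 1), n_exceed = n, k = k)
}

#' Standard deviation of an empirical permutation p-value
#'
#' `sqrt(p* (1 - p*) / k)` for true p-value `p*` and `k` permutations; at the
#' critical `p* = 0.05` with 500 permutations this is 0.0097.
#'
#' @param p_star true p-value in `[0, 1]`.
#' @param k number of permutations.
#' @return the standard deviation.
#' @export
permutation_pvalue_sd <- function(p_star, k) {
  if (p_star < 0 || p_star > 1) stop("p_star must lie in [0, 1]")
  if (k < 1) stop("k must be >= 1")
  sqrt(p_star * (1 - p_star) / k)
}

#' Single-feature phenotype association with spatial errors
#'
#' Regresses a phenotype on one molecular feature profile with an intercept,
#' the residuals following `sigma^2 (n I + (1 - n) corRatio(d; r))`
#' (rational quadratic kernel with nugget), fitted by restricted maximum
#' likelihood with the same i.i.d. fallback as the expression models.
#'
#' @param phenotype numeric trait vector across plants.
#' @param feature_profile numeric feature vector (log2 scale, residualized).
#' @param layout a `field_layout`.
#' @param cache optional [spatial_kernel_cache()] with `kernel = "ratio"`.
#' @param control a [reml_control()].
#' @return list of class `single_feature_association`: `beta0`, `beta`, `se`,
#'   `p` (Wald t on `beta`), `r2` (squared correlation of fitted and
#'   observed), `nugget`, `range_r`, `fitted_by`.
#' @export
single_feature_gls <- function(phenotype, feature_profile, layout,
                               cache = NULL, control = reml_control()) {
  if (stats::var(feature_profile) == 0 || stats::var(phenotype) == 0)
    stop("degenerate input: constant profile")
  if (is.null(cache))
    cache <- spatial_kernel_cache(field_distances(layout), "ratio", control)
  X <- cbind(intercept = 1, x = feature_profile)
  fit <- reml_fit_one(phenotype, X, cache, control)
  fitted <- drop(X %*% fit$beta)
  structure(list(beta0 = unname(fit$beta[1L]), beta = unname(fit$beta[2L]),
                 se = unname(fit$se[2L]), p = unname(fit$pvalues[2L]),
                 r2 = stats::cor(fitted, phenotype)^2, nugget = fit$nugget,
                 range_r = fit$range_r, fitted_by = fit$fitted_by),
            class = "single_feature_association")
}

#' Batch single-feature associations with per-phenotype BH adjustment
#'
#' @param m feature x plant matrix.
#' @param phenotypes trait x plant matrix.
#' @param layout a `field_layout`.
#' @param control a [reml_control()].
#' @return data.frame with `phenotype`, `feature`, `beta`, `p`, `q` (BH
#'   within each phenotype), `r2`, `fitted_by`.
#' @export
single_feature_gls_batch <- function(m, phenotypes, layout,
                                     control = reml_control()) {
  cache <- spatial_kernel_cache(field_distances(layout), "ratio", control)
  rows <- list()
  for (ph in seq_len(nrow(phenotypes))) {
    res <- lapply(seq_len(nrow(m)), function(i) {
      fit <- single_feature_gls(phenotypes[ph, ], m[i, ], layout, cache, control)
      data.frame(phenotype = rownames(phenotypes)[ph] %||% as.character(ph),
                 feature = rownames(m)[i] %||% as.character(i),
                 beta = fit$beta, p = fit$p, r2 = fit$r2,
                 fitted_by = fit$fitted_by, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    df$q <- bh_adjust(df$p)
    rows[[ph]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## deterministic fold labels: k folds over n samples
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

## predictions of a glmnet path at given penalty values, without the
## overhead of stats::predict (nearest-lambda column lookup)
predict_enet <- function(fit, X, s) {
  j <- vapply(s, function(l) which.min(abs(fit$lambda - l)), integer(1))
  (cbind(1, X) %*% rbind(fit$a0, as.matrix(fit$beta)))[, j, drop = FALSE]
}

## train/predict for one hyperparameter configuration
fit_predict_learner <- function(learner, Xtr, ytr, Xte, hp, seed) {
  if (learner == "elastic_net") {
    fit <- glmnet::glmnet(Xtr, ytr, alpha = hp$rho, lambda = hp$lambda_seq,
                          standardize = FALSE, maxit = 1e6)
    drop(predict_enet(fit, Xte, hp$lambda)[, 1L])
  } else {
    rf <- random_forest(Xtr, ytr, n_trees = hp$n_trees,
                        max_features = hp$max_features,
                        min_samples_split = hp$min_samples_split, seed = seed)
    predict(rf, Xte)
  }
}

## expand the hyperparameter grid for a learner
learner_grid <- function(learner, config, reduced) {
  if (learner == "elastic_net") {
    alphas <- if (reduced) config$enet_alpha_grid else config$enet_alpha_grid
    rhos <- if (reduced) 0.5 else config$enet_rho_grid
    expand.grid(lambda = alphas, rho = rhos)
  } else {
    if (reduced)
      expand.grid(max_features = "sqrt", min_samples_split = 2L,
                  stringsAsFactors = FALSE)
    else
      expand.grid(max_features = c("sqrt", "0.33", "log2", "none"),
                  min_samples_split = config$rf_min_split_grid,
                  stringsAsFactors = FALSE)
  }
}

run_nested_cv <- function(X, y, learner, grid, config, folds, seed) {
  n <- length(y)
  k_out <- max(folds)
  preds <- rep(NA_real_, n)
  chosen <- vector("list", k_out)
  importances <- vector("list", k_out)
  flagged <- logical(k_out)
  for (fo in seq_len(k_out)) {
    te <- which(folds == fo); tr <- which(folds != fo)
    if (stats::var(y[tr]) == 0) { flagged[fo] <- TRUE; next }
    inner <- make_folds(length(tr), config$n_inner, child_seed(seed, 50L + fo))
    score <- numeric(nrow(grid))
    for (fi in seq_len(config$n_inner)) {
      itr <- tr[inner != fi]; ite <- tr[inner == fi]
      if (stats::var(y[ite]) == 0 || stats::var(y[itr]) == 0) next
      if (learner == "elastic_net") {
        # one glmnet path per rho covers the whole lambda grid
        for (rho in unique(grid$rho)) {
          lam <- sort(unique(grid$lambda[grid$rho == rho]), decreasing = TRUE)
          fit <- glmnet::glmnet(X[itr, , drop = FALSE], y[itr], alpha = rho,
                                lambda = lam, standardize = FALSE, maxit = 1e6)
          pr <- predict_enet(fit, X[ite, , drop = FALSE],
                             grid$lambda[grid$rho == rho])
          rows <- which(grid$rho == rho)
          for (j in seq_along(rows))
            score[rows[j]] <- score[rows[j]] +
              oob_r2(pr[, j], y[ite]) / config$n_inner
        }
      } else {
        for (j in seq_len(nrow(grid))) {
          hp <- list(n_trees = config$rf_trees_inner,
                     max_features = as.character(grid$max_features[j]),
                     min_samples_split = grid$min_samples_split[j])
          pr <- fit_predict_learner("random_forest", X[itr, , drop = FALSE],
                                    y[itr], X[ite, , drop = FALSE], hp,
                                    child_seed(seed, 1000L + fo * 37L + fi))
          score[j] <- score[j] + oob_r2(pr, y[ite]) / config$n_inner
        }
      }
    }
    best <- which.max(score)
    chosen[[fo]] <- grid[best, , drop = FALSE]
    if (learner == "elastic_net") {
      hp <- list(rho = grid$rho[best], lambda = grid$lambda[best],
                 lambda_seq = sort(unique(grid$lambda), decreasing = TRUE))
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = hp$rho,
                            lambda = hp$lambda_seq, standardize = FALSE,
                            maxit = 1e6)
      preds[te] <- drop(predict_enet(fit, X[te, , drop = FALSE], hp$lambda)[, 1L])
      j <- which.min(abs(fit$lambda - hp$lambda))
      importances[[fo]] <- stats::setNames(as.matrix(fit$beta)[, j],
                                           rownames(fit$beta))
    } else {
      hp <- list(n_trees = config$rf_trees,
                 max_features = as.character(grid$max_features[best]),
                 min_samples_split = grid$min_samples_split[best])
      rf <- random_forest(X[tr, , drop = FALSE], y[tr], n_trees = hp$n_trees,
                          max_features = hp$max_features,
                          min_samples_split = hp$min_samples_split,
                          seed = child_seed(seed, 2000L + fo))
      preds[te] <- predict(rf, X[te, , drop = FALSE])
      importances[[fo]] <- rf$importance
    }
  }
  use <- !is.na(preds)
  list(predictions = preds, folds = folds,
       pooled_r2 = oob_r2(preds[use], y[use]),
       median_r2 = oob_r2(preds[use], y[use], "median", folds[use]),
       pcc = stats::cor(preds[use], y[use]),
       chosen = chosen, importances = importances, flagged_folds = which(flagged))
}

#' Nested cross-validated phenotype prediction
#'
#' Learns a multi-feature model of one phenotype from molecular profiles
#' under 10-fold nested cross-validation: for each outer fold the
#' hyperparameters are tuned on 4 inner folds (selection by mean out-of-fold
#' R-squared), the winning configuration is refitted on the full outer
#' training set, and the held-out samples are predicted. Reported are the
#' pooled out-of-fold R-squared (one statistic over all held-out
#' predictions), the median of the per-fold R-squareds, and the Pearson
#' correlation between predictions and observations. Optional label
#' permutations rebuild the full pipeline (including tuning) on permuted
#' phenotypes and yield empirical p-values `(n + 1) / (k + 1)` per measure.
#'
#' @param features feature x plant matrix (z-scored per feature internally).
#' @param phenotype numeric trait vector across the same plants.
#' @param learner `"elastic_net"` (glmnet; shrinkage grid `alpha_grid`,
#'   L1-ratio grid `rho_grid`, iteration cap 1e6) or `"random_forest"`
#'   (500 trees; `max_features` grid sqrt/0.33/log2/none,
#'   `min_samples_split` grid 2:5).
#' @param n_outer,n_inner outer and inner fold counts.
#' @param k_perm number of phenotype permutations (0 = none).
#' @param reduced_grid use a one-point tuning grid for the non-lambda
#'   hyperparameters (cost cap for permutation runs and calibration studies).
#' @param enet_alpha_grid,enet_rho_grid elastic-net grids.
#' @param rf_trees,rf_trees_inner forest sizes for the refit and the inner
#'   tuning fits.
#' @param rf_min_split_grid forest minimum-node-size grid.
#' @param seed master seed: fold assignment, forests and permutations all
#'   derive from it.
#' @return object of class `model_performance`: `pooled_r2`, `median_r2`,
#'   `pcc`, `empirical_p` (named list, when `k_perm > 0`), `predictions`,
#'   `folds`, `chosen` hyperparameters per fold, `feature_importances`
#'   (median across folds: MDI for forests, coefficients for elastic nets),
#'   `flagged_folds`.
#' @export
nested_cv_fit <- function(features, phenotype,
                          learner = c("elastic_net", "random_forest"),
                          n_outer = 10L, n_inner = 4L, k_perm = 0L,
                          reduced_grid = FALSE,
                          enet_alpha_grid = 10^seq(-3, 0, length.out = 7),
                          enet_rho_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                          rf_trees = 500L, rf_trees_inner = 100L,
                          rf_min_split_grid = 2:5, seed = 1L) {
  learner <- match.arg(learner)
  check_matrix(features, "feature matrix")
  if (ncol(features) != length(phenotype))
    stop("feature columns must match phenotype length")
  if (length(phenotype) < 20) stop("need at least 20 samples")
  keep <- apply(features, 1L, stats::sd) > 0
  X <- t(zscore_rows(features[keep, , drop = FALSE]))
  y <- as.numeric(phenotype)
  config <- list(n_inner = n_inner, enet_alpha_grid = enet_alpha_grid,
                 enet_rho_grid = enet_rho_grid, rf_trees = rf_trees,
                 rf_trees_inner = rf_trees_inner,
                 rf_min_split_grid = rf_min_split_grid)
  grid <- learner_grid(learner, config, reduced_grid)
  folds <- make_folds(length(y), n_outer, child_seed(seed, 1L))
  true_fit <- run_nested_cv(X, y, learner, grid, config, folds, seed)
  emp <- NULL
  if (k_perm > 0) {
    perm_scores <- matrix(NA_real_, k_perm, 3L,
                          dimnames = list(NULL, c("pooled_r2", "median_r2", "pcc")))
    for (b in seq_len(k_perm)) {
      set.seed(child_seed(seed, 5000L + b))
      yp <- y[sample.int(length(y))]
      pf <- run_nested_cv(X, yp, learner, grid, config, folds,
                          child_seed(seed, 6000L + b))
      perm_scores[b, ] <- c(pf$pooled_r2, pf$median_r2, pf$pcc)
    }
    emp <- lapply(c(pooled_r2 = "pooled_r2", median_r2 = "median_r2",
                    pcc = "pcc"), function(msr)
      permutation_pvalue(true_fit[[msr]], perm_scores[, msr])$p)
  }
  imp <- NULL
  got <- !vapply(true_fit$importances, is.null, logical(1))
  if (any(got))
    imp <- apply(do.call(rbind, true_fit$importances[got]), 2L, stats::median)
  if (length(true_fit$flagged_folds))
    warning("fold(s) with constant training phenotype flagged: ",
            paste(true_fit$flagged_folds, collapse = ", "))
  structure(list(pooled_r2 = true_fit$pooled_r2,
                 median_r2 = true_fit$median_r2, pcc = true_fit$pcc,
                 empirical_p = emp, predictions = true_fit$predictions,
                 folds = folds, chosen = true_fit$chosen,
                 feature_importances = imp,
                 flagged_folds = true_fit$flagged_folds,
                 learner = learner, k_perm = k_perm),
            class = "model_performance")
}
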