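## Restricted maximum likelihood machinery for linear models with
## spatially correlated errors:
##   y = X beta + eps,  eps ~ N(0, sigma^2 * C),  C = n I + (1 - n) K(r)
## K is a unit-diagonal spatial correlation matrix (spherical or rational
## quadratic kernel). The nugget n and range r are profiled on a grid built
## once per field layout (each grid range gets one eigendecomposition of K,
## reused across features and nugget values), then refined locally by a
## golden-section search over r with an inner 1-D optimization over n.

#' Control parameters for spatial REML fits
#'
#' @param n_grid nugget values profiled in the grid stage.
#' @param r_grid range values (cm); `NULL` derives a log-spaced grid from the
#'   layout (minimum plant spacing up to twice the field diagonal).
#' @param n_r_grid number of grid ranges when `r_grid` is derived.
#' @param refine logical; run the local refinement stage after the grid.
#' @param refine_evals maximum kernel eigendecompositions spent on refinement.
#' @param min_ll_gain minimum restricted log-likelihood improvement over the
#'   i.i.d. submodel for an interior (spatial) optimum to be accepted;
#'   improvements below this are treated as non-convergence to a genuine
#'   spatial optimum and trigger the OLS fallback.
#' @param fallback_nugget nugget above which the fit is declared i.i.d.
#' @param fallback_range_frac fraction of the minimum plant spacing below
#'   which the range triggers the OLS fallback (default one half).
#' @return a list of class `reml_control`.
#' @export
reml_control <- function(n_grid = seq(0.05, 0.95, by = 0.1), r_grid = NULL,
                         n_r_grid = 15L, refine = TRUE, refine_evals = 12L,
                         min_ll_gain = 1e-4, fallback_nugget = 0.999,
                         fallback_range_frac = 0.5) {
  stopifnot(all(n_grid > 0 & n_grid < 1))
  structure(list(n_grid = n_grid, r_grid = r_grid, n_r_grid = n_r_grid,
                 refine = refine, refine_evals = refine_evals,
                 min_ll_gain = min_ll_gain, fallback_nugget = fallback_nugget,
                 fallback_range_frac = fallback_range_frac),
            class = "reml_control")
}

#' Precompute the kernel eigendecompositions for a range grid
#'
#' @param dmat plant distance matrix (cm).
#' @param kernel `"spherical"` or `"ratio"`.
#' @param control a [reml_control()].
#' @return list with `r_grid`, per-range eigendecompositions, spacing metadata.
#' @export
spatial_kernel_cache <- function(dmat, kernel = c("spherical", "ratio"),
                                 control = reml_control()) {
  kernel <- match.arg(kernel)
  pos <- dmat[upper.tri(dmat)]
  if (any(pos == 0)) stop("coincident plant positions: zero pairwise distance")
  min_sp <- min(pos)
  diam <- max(pos)
  r_grid <- control$r_grid %||%
    exp(seq(log(min_sp), log(2 * diam), length.out = control$n_r_grid))
  eigs <- lapply(r_grid, function(r) {
    K <- if (kernel == "spherical") spherical_correlation(dmat, r)
         else ratio_correlation(dmat, r)
    e <- eigen(K, symmetric = TRUE)
    list(values = e$values, Qt = t(e$vectors))
  })
  list(kernel = kernel, dmat = dmat, r_grid = r_grid, eigs = eigs,
       min_spacing = min_sp, diameter = diam)
}

## Restricted log-likelihood for one nugget given eigen-transformed data.
## yt, Xt: data rotated into the kernel eigenbasis; lam: kernel eigenvalues.
## C eigenvalues are n + (1 - n) lam. Returns LL, beta, sigma2, XtWX inverse.
reml_eval_eig <- function(yt, Xt, lam, nugget) {
  w <- 1 / (nugget + (1 - nugget) * lam)
  if (any(!is.finite(w)) || any(w <= 0)) return(list(ll = -Inf))
  N <- length(yt); p <- ncol(Xt)
  Xw <- Xt * w
  XtWX <- crossprod(Xw, Xt)
  XtWy <- crossprod(Xw, yt)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
  resid <- yt - Xt %*% beta
  rss <- sum(w * resid^2)
  # clamp: an exactly collinear pair gives rss 0; keep the fit well-defined
  sigma2 <- max(rss / (N - p), 1e-300)
  logdetC <- -sum(log(w))
  logdetXtWX <- 2 * sum(log(diag(R)))
  ll <- -0.5 * ((N - p) * (log(2 * pi * sigma2) + 1) + logdetC + logdetXtWX)
  list(ll = ll, beta = drop(beta), sigma2 = sigma2, XtWX_chol = R)
}

## Best nugget for a fixed range via stats::optimize plus the control grid.
reml_best_nugget <- function(yt, Xt, lam, control) {
  lls <- vapply(control$n_grid, function(n) reml_eval_eig(yt, Xt, lam, n)$ll,
                numeric(1))
  i <- which.max(lls)
  lo <- control$n_grid[max(1L, i - 1L)]
  hi <- control$n_grid[min(length(control$n_grid), i + 1L)]
  opt <- stats::optimize(function(n) reml_eval_eig(yt, Xt, lam, n)$ll,
                         lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
  if (opt$objective >= lls[i]) list(nugget = opt$maximum, ll = opt$objective)
  else list(nugget = control$n_grid[i], ll = lls[i])
}

## i.i.d. (OLS) restricted log-likelihood and fit, same normalization.
reml_eval_iid <- function(y, X) {
  N <- length(y); p <- ncol(X)
  fit <- reml_eval_eig(y, X, rep(1, N), 1)
  fit
}

#' Fit one response by spatial REML
#'
#' Internal engine shared by [fit_spatial_lme()], [spatially_adjusted_correlation()]
#' and [single_feature_gls()]. Profiles (nugget, range) on the cached grid,
#' refines the range by golden-section search (eigendecomposition per probed
#' range, inner 1-D nugget optimization), and falls back to ordinary least
#' squares when the optimum is at or indistinguishable from the i.i.d.
#' boundary.
#'
#' @param y response vector.
#' @param X fixed-effects design matrix.
#' @param cache a [spatial_kernel_cache()].
#' @param control a [reml_control()].
#' @return list with elements `beta`, `se`, `pvalues`, `sigma`, `nugget`,
#'   `range_r`, `fitted_by`, `loglik`, `loglik_iid`, `df`.
#' @keywords internal
reml_fit_one <- function(y, X, cache, control = reml_control()) {
  N <- length(y); p <- ncol(X)
  if (stats::var(y) == 0) stop("degenerate input: response has zero variance")
  iid <- reml_eval_iid(y, X)
  best <- list(ll = -Inf, r = NA_real_, nugget = NA_real_)
  for (j in seq_along(cache$r_grid)) {
    e <- cache$eigs[[j]]
    yt <- drop(e$Qt %*% y); Xt <- e$Qt %*% X
    o <- reml_best_nugget(yt, Xt, e$values, control)
    if (o$ll > best$ll) best <- list(ll = o$ll, r = cache$r_grid[j],
                                     nugget = o$nugget, j = j)
  }
  eval_r <- function(r) {
    K <- if (cache$kernel == "spherical") spherical_correlation(cache$dmat, r)
         else ratio_correlation(cache$dmat, r)
    e <- eigen(K, symmetric = TRUE)
    Qt <- t(e$vectors)
    o <- reml_best_nugget(drop(Qt %*% y), Qt %*% X, e$values, control)
    list(ll = o$ll, nugget = o$nugget)
  }
  if (isTRUE(control$refine) && is.finite(best$ll)) {
    # golden-section in log(r) between the grid neighbours of the best range
    lo <- log(cache$r_grid[max(1L, best$j - 1L)])
    hi <- log(cache$r_grid[min(length(cache$r_grid), best$j + 1L)])
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- eval_r(exp(x1)); f2 <- eval_r(exp(x2))
    evals <- 2L
    while (evals < control$refine_evals && (b - a) > 1e-3) {
      if (f1$ll > f2$ll) { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- eval_r(exp(x1))
      } else { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- eval_r(exp(x2))
      }
      evals <- evals + 1L
    }
    cand <- if (f1$ll > f2$ll) list(ll = f1$ll, r = exp(x1), nugget = f1$nugget)
            else list(ll = f2$ll, r = exp(x2), nugget = f2$nugget)
    if (cand$ll > best$ll) best <- cand
  }
  fallback <- !is.finite(best$ll) ||
    best$ll - iid$ll < control$min_ll_gain ||
    best$nugget > control$fallback_nugget ||
    best$r < control$fallback_range_frac * cache$min_spacing
  if (fallback) {
    fit <- iid; nugget <- 1; range_r <- 0; fitted_by <- "OLS-fallback"
    ll <- iid$ll
  } else {
    K <- if (cache$kernel == "spherical") spherical_correlation(cache$dmat, best$r)
         else ratio_correlation(cache$dmat, best$r)
    e <- eigen(K, symmetric = TRUE)
    Qt <- t(e$vectors)
    fit <- reml_eval_eig(drop(Qt %*% y), Qt %*% X, e$values, best$nugget)
    nugget <- best$nugget; range_r <- best$r; fitted_by <- "REML"
    ll <- fit$ll
  }
  covb <- chol2inv(fit$XtWX_chol) * fit$sigma2
  se <- sqrt(diag(covb))
  tstat <- fit$beta / se
  df <- N - p
  list(beta = stats::setNames(fit$beta, colnames(X)), se = se,
       pvalues = 2 * stats::pt(-abs(tstat), df = df),
       sigma = sqrt(fit$sigma2), nugget = nugget, range_r = range_r,
       fitted_by = fitted_by, loglik = ll, loglik_iid = iid$ll, df = df)
}

#' Fit the systematic-effects model with spatially correlated errors
#'
#' Models one feature profile (log2 expression of a gene, a metabolite level,
#' or a phenotype) across field-grown plants as intercept plus binary fixed
#' effects for sequencing batch, day of harvest (DOH) and SNP subgroup, with
#' residuals following a multivariate normal whose correlation is
#' `n I + (1 - n) corSpher(d; r)` (spherical variogram with nugget), fitted by
#' restricted maximum likelihood. When the optimizer drives the model to the
#' i.i.d. boundary (nugget near 1 or range below half the plant spacing) or
#' finds no real spatial optimum, ordinary least squares is used instead and
#' recorded as `fitted_by = "OLS-fallback"`.
#'
#' @param y numeric response across plants (same order as `layout`).
#' @param layout a [make_field_layout()] table.
#' @param effects subset of `c("batch", "doh", "snp")` to include as fixed
#'   effects; phenotype and metabolite runs typically drop `"batch"`.
#' @param kernel residual correlation kernel.
#' @param cache optional precomputed [spatial_kernel_cache()] for `layout`
#'   (pass when fitting many features on one layout).
#' @param control a [reml_control()].
#' @return object of class `lme_fit`: coefficients, their standard errors and
#'   Wald t p-values (df = plants - coefficients), `sigma`, `nugget`,
#'   `range_r`, `fitted_by`, restricted log-likelihoods, the fitted
#'   fixed-effect contribution (excluding intercept) and residuals.
#' @export
fit_spatial_lme <- function(y, layout, effects = c("batch", "doh", "snp"),
                            kernel = c("spherical", "ratio"), cache = NULL,
                            control = reml_control()) {
  kernel <- match.arg(kernel)
  if (length(effects))
    effects <- match.arg(effects, c("batch", "doh", "snp"), several.ok = TRUE)
  else effects <- character(0)
  if (length(y) != nrow(layout)) stop("response length does not match layout")
  if (any(!is.finite(y))) stop("response contains non-finite values")
  if (stats::var(y) == 0) stop("degenerate input: response has zero variance")
  X <- build_effects_design(layout, effects)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient fixed design; aliased effect(s): ",
         paste(aliased, collapse = ", "))
  }
  for (ef in effects) {
    col <- effect_column(layout, ef)
    if (min(table(col)) < 2)
      stop(sprintf("effect '%s' has a level with fewer than 2 plants", ef))
  }
  if (is.null(cache))
    cache <- spatial_kernel_cache(field_distances(layout), kernel, control)
  fit <- reml_fit_one(y, X, cache, control)
  fixed <- if (length(effects))
    drop(X[, -1L, drop = FALSE] %*% fit$beta[-1L]) else rep(0, length(y))
  out <- c(fit, list(effects = effects, fixed_part = fixed,
                     residuals = y - fit$beta[1L] - fixed, y = y))
  class(out) <- "lme_fit"
  out
}

effect_column <- function(layout, effect) {
  switch(effect, batch = layout$batch, doh = layout$doh, snp = layout$snp_group)
}

build_effects_design <- function(layout, effects) {
  X <- matrix(1, nrow(layout), 1L, dimnames = list(NULL, "intercept"))
  for (ef in effects) X <- cbind(X, stats::setNames(effect_column(layout, ef), NULL))
  colnames(X) <- c("intercept", effects)
  X
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("Spatial LME fit (", x$fitted_by, ")\n", sep = "")
  print(round(rbind(beta = x$beta, se = x$se, p = x$pvalues), 4))
  cat(sprintf("sigma = %.4g, nugget = %.3f, range = %.1f cm, REML LL = %.3f\n",
              x$sigma, x$nugget, x$range_r, x$loglik))
  invisible(x)
}

#' Variance decomposition of a spatial LME fit
#'
#' Decomposes the sample variance of a fitted feature into fixed-effect and
#' residual shares: `r2_fix = var(f) / (var(f) + var(eps))` with
#' `f = beta_b x_b + beta_d x_d + beta_s x_s` and `var(eps) = sigma^2`;
#' per-effect shares use the same denominator; `r2_resid = 1 - r2_fix`; the
#' residual share splits into a spatially autocorrelated part
#' `r2_cov = (1 - n) r2_resid` and an i.i.d. part `r2_iid = n r2_resid`.
#' `r2_fix` equals the sum of the per-effect shares only approximately, since
#' the effect covariates are not exactly orthogonal in a finite sample.
#'
#' @param fit an `lme_fit`.
#' @param layout the layout used for the fit.
#' @return list of class `variance_decomposition` with fields `r2_batch`,
#'   `r2_doh`, `r2_snp`, `r2_fix`, `r2_resid`, `r2_cov`, `r2_iid`.
#' @export
variance_decomposition <- function(fit, layout) {
  stopifnot(inherits(fit, "lme_fit"))
  var_f <- stats::var(fit$fixed_part)
  var_e <- fit$sigma^2
  denom <- var_f + var_e
  shares <- c(batch = 0, doh = 0, snp = 0)
  for (ef in fit$effects)
    shares[ef] <- stats::var(fit$beta[ef] * effect_column(layout, ef)) / denom
  r2_fix <- var_f / denom
  # complements computed by subtraction so the decomposition identities
  # (r2_fix + r2_resid = 1, r2_cov + r2_iid = r2_resid) hold exactly in
  # floating point, not just in exact arithmetic
  r2_resid <- 1 - r2_fix
  r2_cov <- (1 - fit$nugget) * r2_resid
  structure(list(r2_batch = unname(shares["batch"]),
                 r2_doh = unname(shares["doh"]),
                 r2_snp = unname(shares["snp"]),
                 r2_fix = r2_fix, r2_resid = r2_resid,
                 r2_cov = r2_cov, r2_iid = r2_resid - r2_cov),
            class = "variance_decomposition")
}

#' Remove systematic effects from a feature matrix
#'
#' Fits the spatial LME per feature (row) and subtracts the fitted batch /
#' day-of-harvest / SNP contributions, retaining the intercept, so that
#' downstream analyses see between-plant variability free of between-group
#' effects. Per-feature failures (for example constant features) are collected
#' rather than aborting the batch run.
#'
#' @param m feature x plant matrix (columns in layout order).
#' @param layout a `field_layout`.
#' @param effects fixed effects to remove.
#' @param kernel residual correlation kernel.
#' @param control a [reml_control()].
#' @return list with `residuals` (corrected matrix, intercept retained),
#'   `decomposition` (per-feature data.frame of R2 shares plus nugget, range
#'   and `fitted_by`), and `failures` (named character vector of per-feature
#'   error messages).
#' @export
residualize_matrix <- function(m, layout, effects = c("batch", "doh", "snp"),
                               kernel = "spherical", control = reml_control()) {
  check_matrix(m, "feature matrix")
  if (ncol(m) != nrow(layout)) stop("matrix columns must match layout plants")
  cache <- spatial_kernel_cache(field_distances(layout), kernel, control)
  out <- m
  rows <- list()
  failures <- character(0)
  ok <- rep(TRUE, nrow(m))
  feat_ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  for (i in seq_len(nrow(m))) {
    res <- tryCatch({
      fit <- fit_spatial_lme(m[i, ], layout, effects, kernel, cache, control)
      vd <- variance_decomposition(fit, layout)
      out[i, ] <- fit$beta[1L] + fit$residuals
      data.frame(feature = feat_ids[i],
                 sigma = fit$sigma, nugget = fit$nugget, range_r = fit$range_r,
                 fitted_by = fit$fitted_by,
                 r2_batch = vd$r2_batch, r2_doh = vd$r2_doh, r2_snp = vd$r2_snp,
                 r2_fix = vd$r2_fix, r2_resid = vd$r2_resid,
                 r2_cov = vd$r2_cov, r2_iid = vd$r2_iid,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[feat_ids[i]] <- res
      ok[i] <- FALSE
    } else rows[[length(rows) + 1L]] <- res
  }
  list(residuals = out[ok, , drop = FALSE],
       decomposition = do.call(rbind, rows),
       failures = failures)
}
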