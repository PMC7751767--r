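test_that("spherical correlation kernel", {
  expect_equal(spherical_correlation(0, 100), 1)
  expect_equal(spherical_correlation(100, 100), 0)
  expect_equal(spherical_correlation(50, 100), 0.3125)
  d <- seq(0, 300, by = 5)
  v <- spherical_correlation(d, 120)
  expect_true(all(diff(v) <= 1e-12))            # non-increasing
  expect_true(all(v[d >= 120] == 0))            # exactly 0 beyond the range
  expect_equal(spherical_correlation(0, 0), 1)  # pure-nugget convention
  expect_equal(spherical_correlation(3, 0), 0)
})

test_that("i.i.d. data reduce to the OLS solution", {
  layout <- fx_layout_small
  X <- fieldomics:::build_effects_design(layout, c("batch", "doh", "snp"))
  n_fallback <- 0L
  for (s in 1:20) {
    set.seed(s)
    y <- drop(X %*% c(5, 0.5, -0.3, 0.2)) + stats::rnorm(nrow(layout))
    fit <- fit_spatial_lme(y, layout)
    expect_gte(fit$loglik, fit$loglik_iid - 1e-8)   # REML optimum dominates
    if (fit$fitted_by == "OLS-fallback") {
      n_fallback <- n_fallback + 1L
      ols <- stats::lm(y ~ layout$batch + layout$doh + layout$snp_group)
      expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-8)
      expect_equal(unname(fit$pvalues),
                   unname(summary(ols)$coefficients[, 4]), tolerance = 1e-6)
    }
  }
  expect_gte(n_fallback, 5L)   # most i.i.d. fits hit the boundary
})

test_that("REML agrees with the nlme gls oracle on spatial data", {
  layout <- fx_layout_medium
  kernel <- list(sigma = 1, nugget = 0.3, range_r = 250)
  y <- 3 + 0.8 * layout$doh + sample_spatial_gp(layout, kernel, seed = 31)
  fit <- fit_spatial_lme(y, layout, effects = "doh")
  df <- data.frame(y = y, doh = layout$doh, x = layout$x_cm, y_cm = layout$y_cm)
  ref <- nlme::gls(y ~ doh, data = df,
                   correlation = nlme::corSpher(form = ~ x + y_cm, nugget = TRUE),
                   method = "REML")
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-2)
  expect_gte(fit$loglik, as.numeric(stats::logLik(ref)) - 0.05)
  expect_equal(fit$fitted_by, "REML")
})

test_that("degenerate and invalid inputs error cleanly", {
  layout <- fx_layout_small
  expect_error(fit_spatial_lme(rep(1, nrow(layout)), layout), "zero variance")
  bad <- layout
  bad$doh <- bad$batch   # aliased effects
  set.seed(1)
  expect_error(fit_spatial_lme(stats::rnorm(nrow(layout)), bad,
                               effects = c("batch", "doh")),
               "aliased")
})

test_that("estimates are invariant to plant order and translation", {
  layout <- fx_layout_small
  kernel <- list(sigma = 1, nugget = 0.4, range_r = 120)
  y <- sample_spatial_gp(layout, kernel, seed = 3) + 0.6 * layout$doh
  fit <- fit_spatial_lme(y, layout, effects = "doh")
  perm <- sample(seq_len(nrow(layout)))
  lp <- layout[perm, ]
  fitp <- fit_spatial_lme(y[perm], lp, effects = "doh")
  expect_equal(fitp$beta, fit$beta, tolerance = 1e-6)
  expect_equal(fitp$range_r, fit$range_r, tolerance = 1e-4)
  lt <- layout
  lt$x_cm <- lt$x_cm + 1000; lt$y_cm <- lt$y_cm + 500
  fitt <- fit_spatial_lme(y, lt, effects = "doh")
  expect_equal(fitt$beta, fit$beta, tolerance = 1e-8)
})

test_that("variance decomposition identities hold exactly on every fit", {
  layout <- fx_layout_medium
  for (s in 1:6) {
    set.seed(s)
    y <- 2 + stats::rnorm(1) * layout$batch + stats::rnorm(1) * layout$doh +
      stats::rnorm(nrow(layout), sd = 0.7)
    fit <- fit_spatial_lme(y, layout)
    vd <- variance_decomposition(fit, layout)
    expect_identical(vd$r2_fix + vd$r2_resid, 1)
    expect_identical(vd$r2_cov + vd$r2_iid, vd$r2_resid)
    expect_lt(abs(vd$r2_fix - (vd$r2_batch + vd$r2_doh + vd$r2_snp)), 0.1)
  }
})

test_that("balanced two-group design gives the hand-computed DOH share", {
  # var(beta_d x_d) set equal to var(eps) => r2_doh = 0.5
  x_d <- rep(c(0, 1), each = 50)
  layout <- data.frame(doh = x_d)
  fit <- structure(list(beta = c(intercept = 0, doh = 2),
                        fixed_part = 2 * x_d,
                        sigma = sqrt(stats::var(2 * x_d)),
                        nugget = 1, effects = "doh"),
                   class = "lme_fit")
  vd <- variance_decomposition(fit, layout)
  expect_equal(vd$r2_doh, 0.5)
  expect_equal(vd$r2_fix, 0.5)
  expect_equal(vd$r2_iid, 0.5)
})

test_that("residualization removes planted effects and keeps clean features", {
  layout <- fx_layout_medium
  set.seed(10)
  clean <- 4 + stats::rnorm(nrow(layout), sd = 0.5)
  affected <- 6 + 1 * layout$doh + stats::rnorm(nrow(layout), sd = 0.3)
  m <- rbind(clean = clean, affected = affected)
  # a model with no included effects leaves the feature untouched
  out0 <- residualize_matrix(m["clean", , drop = FALSE], layout,
                             effects = character(0))
  expect_equal(out0$residuals["clean", ], clean, tolerance = 1e-10)
  out <- residualize_matrix(m, layout, effects = "doh")
  res_diff <- mean(out$residuals["affected", layout$doh == 1]) -
    mean(out$residuals["affected", layout$doh == 0])
  expect_lt(abs(res_diff), 0.05)
  expect_equal(nrow(out$decomposition), 2)
  # per-feature failures are collected, not fatal
  m2 <- rbind(m, flat = rep(1, nrow(layout)))
  out2 <- residualize_matrix(m2, layout, effects = "doh")
  expect_named(out2$failures, "flat")
  expect_equal(nrow(out2$residuals), 2)
})

test_that("fraction of residual-dominated features recovers the planted share", {
  layout <- fx_layout_medium
  set.seed(99)
  n <- nrow(layout)
  n_feat <- 50; n_null <- 20   # 40% of features are effect-free
  m <- matrix(NA_real_, n_feat, n)
  for (i in seq_len(n_feat)) {
    eff <- if (i <= n_null) 0 else 2
    m[i, ] <- 5 + eff * layout$doh + stats::rnorm(n, sd = 0.5)
  }
  rownames(m) <- sprintf("f%02d", seq_len(n_feat))
  out <- residualize_matrix(m, layout, effects = "doh")
  frac <- mean(out$decomposition$r2_resid > 0.9)
  expect_equal(frac, 0.4, tolerance = 0.05)
})
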