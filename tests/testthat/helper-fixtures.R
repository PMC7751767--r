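# Shared fixtures, built once per test run. Small by design: tests that need
# other scales build their own.

fx_layout_small <- make_field_layout(5, 8, seed = 11)          # 40 plants
fx_layout_medium <- make_field_layout(6, 10, seed = 12)        # 60 plants

# fast lognormal dataset on the medium layout: 5 planted modules of 6 genes
fx_config_fast <- simulation_config(
  n_rows = 6L, n_cols = 10L, n_genes = 60L, n_metabolites = 20L,
  n_traits = 3L, n_modules = 5L, module_size = 6L,
  count_model = "lognormal", gene_noise_sd = 0.3, seed = 42L)
fx_dataset_fast <- simulate_field_dataset(fx_config_fast)

# no-intercept OLS on z-scored profiles: the closed-form oracle the spatial
# pair fit must reduce to for i.i.d. data
ols_pair_oracle <- function(x, y) {
  n <- length(x)
  beta <- sum(x * y) / sum(x^2)
  s2 <- (sum(y^2) - beta^2 * sum(x^2)) / (n - 1)
  se <- sqrt(s2 / sum(x^2))
  list(beta = beta, p = 2 * stats::pt(-abs(beta / se), df = n - 1))
}
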