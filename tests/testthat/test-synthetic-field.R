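test_that("field layout geometry and group coding", {
  layout <- make_field_layout(10, 56)
  expect_equal(nrow(layout), 560)
  expect_equal(max(layout$x_cm), 550)   # (56 - 1) * 10 cm
  expect_equal(max(layout$y_cm), 675)   # (10 - 1) * 75 cm
  expect_false(any(duplicated(layout[, c("x_cm", "y_cm")])))
  # 0 codes the majority group for every label
  for (col in c("batch", "doh", "snp_group")) {
    expect_setequal(unique(layout[[col]]), c(0L, 1L))
    expect_gt(sum(layout[[col]] == 0L), sum(layout[[col]] == 1L))
  }

  one <- make_field_layout(1, 1)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$x_cm, one$y_cm), c(0, 0))

  expect_error(make_field_layout(0, 5), "invalid config")
})

test_that("pairwise distances match a brute-force oracle", {
  layout <- make_field_layout(2, 3, within_row_spacing = 1,
                              between_row_spacing = 1)
  d <- field_distances(layout)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- sqrt((layout$x_cm[i] - layout$x_cm[j])^2 +
                           (layout$y_cm[i] - layout$y_cm[j])^2)
  expect_equal(unname(d), oracle, tolerance = 1e-12)
})

test_that("pure-nugget GP draws are i.i.d.", {
  layout <- make_field_layout(4, 5)
  draws <- t(vapply(1:2500, function(s)
    sample_spatial_gp(layout, list(sigma = 2, nugget = 1, range_r = 100), s),
    numeric(20)))
  cv <- stats::cov(draws)
  expect_equal(mean(diag(cv)), 4, tolerance = 0.15)
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off)), 0.35)      # ~4 sd of the Monte-Carlo error
  expect_lt(abs(mean(off)), 0.02)
})

test_that("GP correlation at half the range matches the spherical kernel", {
  # 5x5 grid with 100 cm spacing: many plant pairs at d = r/2 = 100 cm
  layout <- make_field_layout(5, 5, within_row_spacing = 100,
                              between_row_spacing = 100)
  kernel <- list(sigma = 1, nugget = 0.3, range_r = 200)
  draws <- t(vapply(1:4000, function(s) sample_spatial_gp(layout, kernel, s),
                    numeric(25)))
  cr <- stats::cor(draws)
  d <- field_distances(layout)
  at_half <- cr[d == 100 & upper.tri(d, diag = TRUE)]
  # corSpher(r/2) = 0.3125, damped by 1 - nugget
  expect_equal(mean(at_half), 0.7 * 0.3125, tolerance = 0.03)
  # and a fixed seed reproduces bit-identical draws
  expect_identical(sample_spatial_gp(layout, kernel, 7),
                   sample_spatial_gp(layout, kernel, 7))
})

test_that("expression generator honours planted structure", {
  cfg0 <- simulation_config(n_rows = 4, n_cols = 8, n_genes = 20,
                            n_modules = 2, module_size = 5,
                            module_loading = 0, affected_fraction = 0,
                            gene_noise_sd = 0, count_model = "lognormal",
                            seed = 5)
  layout <- make_field_layout(4, 8, seed = 5)
  truth0 <- build_synthetic_truth(layout, cfg0)
  m0 <- simulate_expression(layout, truth0, cfg0)
  expect_equal(max(apply(m0, 1, stats::var)), 0)

  # one gene with a planted DOH effect of 1 (log2): exact group difference
  truth1 <- truth0
  truth1$true_fixed_effects$genes[1, ] <- c(0, 1, 0)
  m1 <- log2(simulate_expression(layout, truth1, cfg0))
  diff <- mean(m1[1, layout$doh == 1]) - mean(m1[1, layout$doh == 0])
  expect_equal(diff, 1, tolerance = 1e-10)

  # module genes share a factor: their pairwise correlation beats background
  ds <- fx_dataset_fast
  lg <- log2(ds$counts)
  mod <- ds$truth$planted_go_modules[[1]]
  bg <- setdiff(rownames(lg), unlist(ds$truth$planted_go_modules))
  mean_cor <- function(g) {
    cm <- stats::cor(t(lg[g, ]))
    mean(cm[upper.tri(cm)])
  }
  expect_gt(mean_cor(mod), mean_cor(bg[1:20]) + 0.3)
})

test_that("phenotype generator couples traits to spatial factors", {
  ds <- fx_dataset_fast
  expect_false(any(attr(ds$phenotypes, "degenerate")))
  # trait 1 tracks factor 1; trait 3 is pure noise
  expect_gt(abs(cor(ds$phenotypes["trait_1", ],
                    ds$truth$latent_factor_fields["factor_1", ])), 0.5)
  expect_equal(sum(ds$truth$phenotype_coefficients["trait_3", ]), 0)

  # spatially coupled trait detected by Moran screening with high power
  hits <- vapply(1:40, function(s) {
    cfg <- simulation_config(n_rows = 6, n_cols = 10, n_genes = 20,
                             n_modules = 2, module_size = 5,
                             count_model = "lognormal",
                             phenotype_noise_sd = 0.2, seed = 1000 + s)
    layout <- make_field_layout(6, 10, seed = 1000 + s)
    tr <- build_synthetic_truth(layout, cfg)
    ph <- simulate_phenotypes(layout, tr, cfg)
    morans_i(ph["trait_1", ], layout)$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noise-only traits give uniform Moran p-values", {
  layout <- make_field_layout(6, 10, seed = 77)
  W <- 1 / field_distances(layout); diag(W) <- 0
  ps <- vapply(1:200, function(s) {
    set.seed(s); morans_i(stats::rnorm(60), W = W)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("annotation generator withholds the configured fraction", {
  genes <- sprintf("gene_%04d", 1:60)
  cfg <- simulation_config(n_genes = 60, n_modules = 5, module_size = 6,
                           withheld_fraction = 0, seed = 9)
  ann0 <- simulate_go_annotations(genes, cfg)
  expect_identical(ann0$annotations, ann0$truth)
  expect_equal(nrow(ann0$withheld), 0)

  cfg2 <- simulation_config(n_genes = 60, n_modules = 5, module_size = 6,
                            withheld_fraction = 0.2, seed = 9)
  ann2 <- simulate_go_annotations(genes, cfg2)
  expect_equal(nrow(ann2$withheld), round(0.2 * nrow(ann2$truth)))
  expect_equal(nrow(ann2$annotations) + nrow(ann2$withheld), nrow(ann2$truth))
  # ontology is a >= 3-level DAG: leaf -> mid -> root
  anc <- propagate_annotations(data.frame(gene = "g", term = "GO:L0001"),
                               ann2$ontology)
  expect_true("GO:ROOT" %in% anc$term)
  expect_gte(nrow(anc), 3)
})
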