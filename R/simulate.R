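#' Configuration for the synthetic field-trial generator
#'
#' Collects every knob of the synthetic data world in one validated object.
#' Defaults emulate a single-genotype maize field trial: a 10 x 56 grid with
#' 10 cm within-row and 75 cm between-row spacing, a few spatially
#' autocorrelated latent micro-environmental factors with spherical covariance
#' plus nugget, additive binary batch / day-of-harvest / SNP-subgroup effects
#' on a subset of features, Poisson-lognormal counts for transcripts,
#' lognormal metabolite intensities with values missing completely at random,
#' phenotypes linearly coupled to the latent factors, and gene modules planted
#' on shared factors and shared leaf ontology terms.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param within_row_spacing,between_row_spacing plant spacings in cm.
#' @param n_genes,n_metabolites,n_traits feature counts.
#' @param n_latent_factors number of latent spatial factors.
#' @param kernel_params list (one per factor) of `list(sigma, nugget, range_r)`
#'   for the spherical factor fields. Defaults use ranges of 150/300/600 cm
#'   (recycled), nugget 0.2, unit sigma: plausible micro-environmental scales
#'   inside a ~6 x 7 m field, not estimates from any real trial.
#' @param n_modules,module_size number and size of planted gene modules; each
#'   module loads on one latent factor (round robin) and shares one leaf
#'   ontology term.
#' @param module_loading loading of module genes on their factor (log2 scale).
#' @param effect_sd standard deviation of nonzero batch/DOH/SNP coefficients
#'   (log2 scale); `affected_fraction` of the features get a nonzero draw.
#' @param affected_fraction fraction of features with systematic effects.
#' @param gene_noise_sd i.i.d. log2-scale noise for genes (and metabolites).
#' @param count_model `"poisson-lognormal"` (counts) or `"lognormal"`
#'   (continuous, fast for tests).
#' @param base_log2_range range of gene baseline log2 expression.
#' @param lib_size_sd lognormal sd of per-plant library-size factors.
#' @param missing_rate metabolite missingness fraction, in `[0, 1)`.
#' @param phenotype_noise_sd trait i.i.d. noise sd.
#' @param withheld_fraction fraction of true gene annotations withheld from
#'   the emitted annotation table (kept as the recall oracle).
#' @param seed master seed; all generator streams derive from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_rows = 10L, n_cols = 56L,
                              within_row_spacing = 10, between_row_spacing = 75,
                              n_genes = 200L, n_metabolites = 60L, n_traits = 3L,
                              n_latent_factors = 3L, kernel_params = NULL,
                              n_modules = 5L, module_size = 12L,
                              module_loading = 1, effect_sd = 0.5,
                              affected_fraction = 0.3, gene_noise_sd = 0.5,
                              count_model = c("poisson-lognormal", "lognormal"),
                              base_log2_range = c(3, 10), lib_size_sd = 0.1,
                              missing_rate = 0.1, phenotype_noise_sd = 0.5,
                              withheld_fraction = 0.2, seed = 1L) {
  count_model <- match.arg(count_model)
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid config: missing_rate must be in [0, 1)")
  if (gene_noise_sd < 0 || phenotype_noise_sd < 0 || effect_sd < 0)
    stop("invalid config: negative dispersion/variance")
  if (is.null(kernel_params)) {
    ranges <- rep(c(150, 300, 600), length.out = n_latent_factors)
    kernel_params <- lapply(seq_len(n_latent_factors), function(i)
      list(sigma = 1, nugget = 0.2, range_r = ranges[i]))
  }
  for (kp in kernel_params) {
    if (kp$nugget < 0 || kp$nugget > 1) stop("invalid config: nugget must lie in [0, 1]")
    if (kp$range_r <= 0) stop("invalid config: range r must be > 0")
    if (kp$sigma < 0) stop("invalid config: sigma must be >= 0")
  }
  if (n_modules * module_size > n_genes)
    stop("invalid config: planted modules exceed the number of genes")
  if (module_size < 5) stop("invalid config: planted modules need >= 5 genes")
  structure(as.list(environment()), class = "simulation_config")
}

#' Draw one realization of a spatial Gaussian process on a field
#'
#' Samples a zero-mean multivariate normal over the plants with covariance
#' `sigma^2 (n I + (1 - n) corSpher(d; r))`. A small diagonal jitter is added
#' if the Cholesky factorization fails.
#'
#' @param layout a `field_layout`.
#' @param kernel list with `sigma`, `nugget`, `range_r`.
#' @param seed integer seed.
#' @param kernel_type `"spherical"` or `"ratio"`.
#' @return numeric vector, one value per plant.
#' @export
sample_spatial_gp <- function(layout, kernel, seed = 1L,
                              kernel_type = "spherical") {
  d <- field_distances(layout)
  C <- kernel$sigma^2 *
    nugget_correlation(d, kernel$nugget, kernel$range_r, kernel_type)
  L <- tryCatch(chol(C), error = function(e) {
    tryCatch(chol(C + diag(1e-8 * max(diag(C)), nrow(C))),
             error = function(e2)
               stop("covariance matrix is not positive semi-definite, even after jitter: ",
                    conditionMessage(e2)))
  })
  set.seed(seed)
  drop(crossprod(L, stats::rnorm(nrow(C))))
}

#' Build the ground truth of a synthetic field dataset
#'
#' Samples the latent spatial factor fields, gene/metabolite factor loadings
#' (planted modules load on one factor each, round robin), per-feature
#' systematic-effect coefficients and trait-factor coefficients.
#'
#' @param layout a `field_layout`.
#' @param config a [simulation_config()].
#' @return list of class `synthetic_truth` with `latent_factor_fields`
#'   (factor x plant), `gene_loadings`, `metabolite_loadings`,
#'   `phenotype_coefficients`, `true_fixed_effects` (per data layer),
#'   `planted_go_modules` (term -> gene ids).
#' @export
build_synthetic_truth <- function(layout, config) {
  stopifnot(inherits(config, "simulation_config"))
  nf <- config$n_latent_factors
  fac <- t(vapply(seq_len(nf), function(k)
    sample_spatial_gp(layout, config$kernel_params[[k]],
                      seed = child_seed(config$seed, 100L + k)),
    numeric(nrow(layout))))
  rownames(fac) <- sprintf("factor_%d", seq_len(nf))
  colnames(fac) <- layout$plant_id
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  load_g <- matrix(0, config$n_genes, nf, dimnames = list(gene_ids, rownames(fac)))
  modules <- list()
  for (mi in seq_len(config$n_modules)) {
    members <- gene_ids[seq((mi - 1L) * config$module_size + 1L,
                            mi * config$module_size)]
    f <- ((mi - 1L) %% nf) + 1L
    load_g[members, f] <- config$module_loading
    modules[[sprintf("GO:L%04d", mi)]] <- members
  }
  met_ids <- sprintf("met_%03d", seq_len(config$n_metabolites))
  set.seed(child_seed(config$seed, 200L))
  load_m <- matrix(0, config$n_metabolites, nf, dimnames = list(met_ids, rownames(fac)))
  # a third of the metabolites track a random factor
  idx <- sample.int(config$n_metabolites, max(1L, config$n_metabolites %/% 3L))
  load_m[cbind(idx, sample.int(nf, length(idx), replace = TRUE))] <- 1
  draw_effects <- function(ids, stream) {
    set.seed(child_seed(config$seed, stream))
    eff <- matrix(0, length(ids), 3L, dimnames = list(ids, c("batch", "doh", "snp")))
    hit <- stats::runif(length(ids)) < config$affected_fraction
    eff[hit, ] <- stats::rnorm(3L * sum(hit), 0, config$effect_sd)
    eff
  }
  # traits: trait 1 copies factor 1, trait 2 mixes factors, trait 3+ pure noise
  phen <- matrix(0, config$n_traits, nf,
                 dimnames = list(sprintf("trait_%d", seq_len(config$n_traits)),
                                 rownames(fac)))
  if (config$n_traits >= 1) phen[1L, 1L] <- 1
  if (config$n_traits >= 2 && nf >= 2) phen[2L, seq_len(min(2L, nf))] <- c(0.7, 0.7)
  structure(list(latent_factor_fields = fac, gene_loadings = load_g,
                 metabolite_loadings = load_m, phenotype_coefficients = phen,
                 true_fixed_effects = list(genes = draw_effects(gene_ids, 201L),
                                           metabolites = draw_effects(met_ids, 202L)),
                 planted_go_modules = modules),
            class = "synthetic_truth")
}

signal_matrix <- function(layout, loadings, effects, intercepts, factors,
                          noise_sd, seed) {
  n <- nrow(layout)
  sig <- intercepts + loadings %*% factors +
    effects[, "batch"] %o% layout$batch +
    effects[, "doh"] %o% layout$doh +
    effects[, "snp"] %o% layout$snp_group
  set.seed(seed)
  sig + matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig))
}

#' Simulate a transcript count matrix on a field layout
#'
#' The log2-scale signal of each gene is intercept + factor loadings times the
#' latent fields + batch/DOH/SNP effects + i.i.d. noise. Under the
#' Poisson-lognormal model, counts are Poisson draws around
#' `library_factor * 2^signal`; under the lognormal model the continuous
#' matrix `2^signal` is returned directly.
#'
#' @param layout a `field_layout`.
#' @param truth a [build_synthetic_truth()] object.
#' @param config a [simulation_config()].
#' @return gene x plant matrix (integer counts or positive reals).
#' @export
simulate_expression <- function(layout, truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (ncol(truth$gene_loadings) != nrow(truth$latent_factor_fields))
    stop("gene loadings do not conform to the latent factor fields")
  set.seed(child_seed(config$seed, 300L))
  intercepts <- stats::runif(config$n_genes, config$base_log2_range[1],
                             config$base_log2_range[2])
  sig <- signal_matrix(layout, truth$gene_loadings,
                       truth$true_fixed_effects$genes, intercepts,
                       truth$latent_factor_fields, config$gene_noise_sd,
                       child_seed(config$seed, 301L))
  dimnames(sig) <- list(rownames(truth$gene_loadings), layout$plant_id)
  if (config$count_model == "lognormal") return(2^sig)
  set.seed(child_seed(config$seed, 302L))
  libf <- exp(stats::rnorm(nrow(layout), 0, config$lib_size_sd))
  mu <- sweep(2^sig, 2L, libf, `*`)
  cnt <- matrix(stats::rpois(length(mu), mu), nrow(mu), dimnames = dimnames(sig))
  storage.mode(cnt) <- "integer"
  cnt
}

#' Simulate metabolite intensities with missingness
#'
#' Lognormal intensities built like the expression signal (no batch effect;
#' DOH and SNP effects only, matching how metabolite layers are modelled);
#' entries are then set missing completely at random at `missing_rate`.
#'
#' @inheritParams simulate_expression
#' @return metabolite x plant matrix with `NA`s.
#' @export
simulate_metabolites <- function(layout, truth, config) {
  eff <- truth$true_fixed_effects$metabolites
  eff[, "batch"] <- 0
  set.seed(child_seed(config$seed, 400L))
  intercepts <- stats::runif(config$n_metabolites, 10, 20)
  sig <- signal_matrix(layout, truth$metabolite_loadings, eff, intercepts,
                       truth$latent_factor_fields, config$gene_noise_sd,
                       child_seed(config$seed, 401L))
  dimnames(sig) <- list(rownames(truth$metabolite_loadings), layout$plant_id)
  m <- 2^sig
  if (config$missing_rate > 0) {
    set.seed(child_seed(config$seed, 402L))
    m[stats::runif(length(m)) < config$missing_rate] <- NA_real_
  }
  m
}

#' Simulate phenotypes coupled to the latent spatial factors
#'
#' Traits are linear combinations of the latent factor fields plus i.i.d.
#' noise; traits with a nonzero weight on a spatial factor are spatially
#' autocorrelated by construction. Zero-variance traits are flagged via the
#' `"degenerate"` attribute instead of silently returned.
#'
#' @inheritParams simulate_expression
#' @return trait x plant matrix with attribute `degenerate` (logical per trait).
#' @export
simulate_phenotypes <- function(layout, truth, config) {
  ph <- truth$phenotype_coefficients %*% truth$latent_factor_fields
  set.seed(child_seed(config$seed, 500L))
  ph <- ph + matrix(stats::rnorm(length(ph), 0, config$phenotype_noise_sd),
                    nrow(ph))
  dimnames(ph) <- list(rownames(truth$phenotype_coefficients), layout$plant_id)
  attr(ph, "degenerate") <- apply(ph, 1L, stats::var) == 0
  ph
}

#' Simulate a small ontology and gene annotation table with planted modules
#'
#' Emits a three-level is_a DAG (leaf terms -> mid-level terms -> root), one
#' leaf term per planted module, and a two-column gene -> term annotation
#' table in which module genes carry their module's leaf term. A configurable
#' fraction of the true annotations is withheld from the emitted table and
#' returned separately as the recall oracle for guilt-by-association
#' benchmarks.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param config a [simulation_config()]; uses `n_modules`, `module_size`,
#'   `withheld_fraction` and `seed`.
#' @param modules optional named list term -> gene ids (defaults to the
#'   round-robin planted modules over `gene_ids`).
#' @return list with `annotations` (emitted gene/term data.frame),
#'   `withheld` (held-out true annotations), `truth` (the full table),
#'   `ontology` (child/parent/relation edge data.frame).
#' @export
simulate_go_annotations <- function(gene_ids, config, modules = NULL) {
  if (is.null(modules)) {
    modules <- list()
    for (mi in seq_len(config$n_modules))
      modules[[sprintf("GO:L%04d", mi)]] <-
        gene_ids[seq((mi - 1L) * config$module_size + 1L, mi * config$module_size)]
  }
  leaves <- names(modules)
  n_mid <- max(1L, ceiling(length(leaves) / 2))
  mids <- sprintf("GO:M%04d", seq_len(n_mid))
  root <- "GO:ROOT"
  ontology <- rbind(
    data.frame(child = leaves, parent = mids[((seq_along(leaves) - 1L) %% n_mid) + 1L],
               relation = "is_a", stringsAsFactors = FALSE),
    data.frame(child = mids, parent = root, relation = "is_a",
               stringsAsFactors = FALSE))
  truth <- do.call(rbind, lapply(leaves, function(tm)
    data.frame(gene = modules[[tm]], term = tm, stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  n_hold <- as.integer(round(config$withheld_fraction * nrow(truth)))
  set.seed(child_seed(config$seed, 600L))
  hold <- sort(sample.int(nrow(truth), n_hold))
  list(annotations = truth[setdiff(seq_len(nrow(truth)), hold), , drop = FALSE],
       withheld = truth[hold, , drop = FALSE],
       truth = truth, ontology = ontology)
}

#' Generate a complete synthetic field dataset
#'
#' One call producing every input of the analysis pipeline with known ground
#' truth: layout, counts, metabolite intensities, phenotypes, annotations and
#' ontology.
#'
#' @param config a [simulation_config()].
#' @return list with `layout`, `counts`, `metabolites`, `phenotypes`,
#'   `annotations` (the [simulate_go_annotations()] result) and `truth`.
#' @export
simulate_field_dataset <- function(config = simulation_config()) {
  layout <- make_field_layout(config$n_rows, config$n_cols,
                              config$within_row_spacing,
                              config$between_row_spacing,
                              seed = child_seed(config$seed, 1L))
  truth <- build_synthetic_truth(layout, config)
  counts <- simulate_expression(layout, truth, config)
  mets <- simulate_metabolites(layout, truth, config)
  phen <- simulate_phenotypes(layout, truth, config)
  ann <- simulate_go_annotations(rownames(counts), config,
                                 modules = truth$planted_go_modules)
  list(layout = layout, counts = counts, metabolites = mets,
       phenotypes = phen, annotations = ann, truth = truth)
}
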