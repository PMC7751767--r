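#' Read / write feature matrices as TSV
#'
#' Matrices are stored features-in-rows, plants-in-columns, tab-separated,
#' with a header row of plant ids and the feature id in the first column.
#' Non-numeric cells fail validation with the offending cell named.
#'
#' @param path file path.
#' @rdname matrix_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = 1L,
                          colClasses = "character")
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !(m %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]]))
  num
}

#' @param m matrix to write.
#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles file paths, stage thresholds and seeds for [run_pipeline()].
#' Thresholds default to the pipeline's standard operating point: Moran
#' q <= 0.01, Bonferroni edge alpha 0.01, prediction q grid 1e-2..1e-11,
#' 5% low-expression exclusion before the CV trend, 10% variability flags.
#'
#' @param counts,metabolites,phenotypes,layout,annotations,ontology input
#'   file paths (TSV matrices, layout TSV, two-column annotation TSV, OBO);
#'   any may be `NULL` to skip the dependent stages.
#' @param moran_q,edge_alpha,trend_exclusion,hv_fraction thresholds.
#' @param prediction_q_grid descending q-value grid for performance curves.
#' @param n_clusters transcript cluster count (`NULL` = silhouette).
#' @param k_perm permutation count for phenotype models.
#' @param seed master seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metabolites = NULL,
                            phenotypes = NULL, layout = NULL,
                            annotations = NULL, ontology = NULL,
                            moran_q = 0.01, edge_alpha = 0.01,
                            trend_exclusion = 0.05, hv_fraction = 0.10,
                            prediction_q_grid = 10^-(2:11),
                            n_clusters = NULL, k_perm = 0L, seed = 1L) {
  stopifnot(moran_q > 0, moran_q <= 1, edge_alpha > 0, edge_alpha <= 1,
            trend_exclusion >= 0, trend_exclusion < 1,
            hv_fraction > 0, hv_fraction < 0.5)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> systematic-effect correction -> spatial
#' autocorrelation screening and clustering -> variability scoring ->
#' co-expression network -> function prediction -> phenotype prediction on
#' the configured inputs, writing each stage's tables plus a JSON manifest
#' (config, seeds, input hashes) into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest list, invisibly; stage outputs are files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[fieldomics] ", fmt), ...))
  inputs <- Filter(Negate(is.null),
                   config[c("counts", "metabolites", "phenotypes", "layout",
                            "annotations", "ontology")])
  for (p in inputs) if (!file.exists(p)) stop("input does not exist: ", p)
  manifest <- list(package_version = as.character(utils::packageVersion("fieldomics")),
                   seed = config$seed,
                   inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
                   stages = list())
  layout <- read_field_layout(config$layout)
  phen <- if (!is.null(config$phenotypes)) read_matrix_tsv(config$phenotypes)

  norm <- NULL
  if (!is.null(config$counts)) {
    counts <- read_matrix_tsv(config$counts)
    norm <- normalize_counts(counts)
    write_matrix_tsv(norm$values, file.path(out_dir, "expression_log2.tsv"))
    log_stage("preprocess: %d genes kept", nrow(norm$values))
    manifest$stages$preprocess <- list(genes = nrow(norm$values),
                                       provenance = norm$provenance)

    corr <- residualize_matrix(norm$values, layout)
    write_matrix_tsv(corr$residuals, file.path(out_dir, "expression_corrected.tsv"))
    utils::write.table(corr$decomposition,
                       file.path(out_dir, "variance_decomposition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("correct: %d features residualized, %d failures",
              nrow(corr$residuals), length(corr$failures))
    manifest$stages$correct <- list(features = nrow(corr$residuals),
                                    failures = length(corr$failures))

    moran <- moran_screen(corr$residuals, layout)
    utils::write.table(moran, file.path(out_dir, "moran.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n_auto <- sum(moran$q <= config$moran_q, na.rm = TRUE)
    log_stage("autocorr: %d/%d features at q <= %g", n_auto, nrow(moran),
              config$moran_q)
    manifest$stages$autocorr <- list(n_autocorrelated = n_auto)
    if (n_auto >= 2) {
      cl <- cluster_autocorrelated_features(corr$residuals, layout,
                                            config$moran_q,
                                            k = config$n_clusters,
                                            moran_table = moran)
      utils::write.table(data.frame(feature = names(cl$membership),
                                    cluster = cl$membership),
                         file.path(out_dir, "clusters.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(phen)) {
        cpc <- cluster_phenotype_correlation(cl, phen)
        utils::write.table(cpc, file.path(out_dir, "cluster_phenotype.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      manifest$stages$clusters <- list(k = cl$k)
    }

    lin <- back_transform_linear(norm, values = corr$residuals)
    ncv <- normcv_scores(lin, hv_fraction = config$hv_fraction)
    utils::write.table(ncv$table, file.path(out_dir, "normcv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("varscore: %d features scored, %d flagged highly variable",
              nrow(ncv$table), sum(ncv$table$highly_variable))
    manifest$stages$varscore <- list(scored = nrow(ncv$table))
    if (!is.null(config$annotations)) {
      raw_ann <- utils::read.table(config$annotations, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
      ranked <- ncv$table$feature[order(-ncv$table$norm_cv, ncv$table$feature)]
      godir <- rank_based_go_test(ranked, raw_ann)
      utils::write.table(godir, file.path(out_dir, "variability_go.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    net <- build_network(corr$residuals, layout, alpha = config$edge_alpha)
    utils::write.table(net$edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("network: %d nodes, %d edges (%.1f%% pairs spatially fitted)",
              length(net$nodes), nrow(net$edges), 100 * net$spatial_fraction)
    manifest$stages$network <- network_stats(net)

    if (!is.null(config$annotations)) {
      ann <- utils::read.table(config$annotations, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      if (!is.null(config$ontology))
        ann <- propagate_annotations(ann, config$ontology)
      pred <- neighborhood_enrichment(net, ann)
      utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      curve <- performance_curve(pred, ann, config$prediction_q_grid)
      utils::write.table(curve, file.path(out_dir, "performance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("predict-function: %d predictions", nrow(pred))
      manifest$stages$predict_function <- list(n_predictions = nrow(pred))
    }

    if (!is.null(phen)) {
      perf <- lapply(rownames(phen), function(tr) {
        mp <- nested_cv_fit(corr$residuals, phen[tr, ],
                            learner = "elastic_net", k_perm = config$k_perm,
                            seed = child_seed(config$seed, 9000L))
        list(trait = tr, pooled_r2 = mp$pooled_r2, median_r2 = mp$median_r2,
             pcc = mp$pcc, empirical_p = mp$empirical_p)
      })
      jsonlite::write_json(perf, file.path(out_dir, "phenotype_models.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage("predict-phenotype: %d traits modelled", length(perf))
      manifest$stages$predict_phenotype <- list(n_traits = length(perf))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes a [simulate_field_dataset()] result in the pipeline's on-disk
#' formats: layout TSV, count/metabolite/phenotype matrices, two-column
#' annotation TSV, OBO ontology and a JSON ground-truth summary.
#'
#' @param dataset a [simulate_field_dataset()] result.
#' @param dir output directory.
#' @return named vector of file paths.
#' @export
write_field_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(layout = file.path(dir, "layout.tsv"),
             counts = file.path(dir, "counts.tsv"),
             metabolites = file.path(dir, "metabolites.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             ontology = file.path(dir, "ontology.obo"),
             truth = file.path(dir, "truth.json"))
  write_field_layout(dataset$layout, paths["layout"])
  write_matrix_tsv(dataset$counts, paths["counts"])
  write_matrix_tsv(dataset$metabolites, paths["metabolites"])
  write_matrix_tsv(dataset$phenotypes, paths["phenotypes"])
  utils::write.table(dataset$annotations$annotations, paths["annotations"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_obo(dataset$annotations$ontology, paths["ontology"])
  jsonlite::write_json(list(planted_go_modules = dataset$truth$planted_go_modules,
                            withheld = dataset$annotations$withheld),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}
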