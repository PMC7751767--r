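#' Guilt-by-association function prediction by neighborhood enrichment
#'
#' For every gene with at least one network neighbor, tests each term
#' annotated to its neighbors for over-representation among the direct
#' (distance-1) neighbors relative to the annotated background, with an exact
#' hypergeometric upper tail: drawing `n` annotated neighbors from a
#' background of `N` annotated network genes of which `K` carry the term, the
#' p-value is `P[X >= k]` for `k` term-carrying neighbors. The focal gene is
#' never counted in its own neighborhood. BH adjustment is applied across all
#' gene-term tests of the network.
#'
#' @param network a `coexpression_network`.
#' @param annotations propagated annotation data.frame (`gene`, `term`).
#' @param exclude_known drop predictions of terms already annotated to the
#'   focal gene (reported via `novel` instead when `FALSE`).
#' @return data.frame of class `prediction_set`: `gene`, `term`, `k`
#'   (neighbors with the term), `n_neigh` (annotated neighbors), `K`
#'   (background genes with the term), `N` (background size), `p`, `q`,
#'   `novel` (term not among the gene's own annotations).
#' @export
neighborhood_enrichment <- function(network, annotations,
                                    exclude_known = FALSE) {
  stopifnot(inherits(network, "coexpression_network"))
  adj <- adjacency_list(network$edges, network$nodes)
  ann_genes <- intersect(network$nodes, unique(annotations$gene))
  background <- stats::setNames(seq_along(network$nodes), network$nodes)
  in_bg <- network$nodes %in% ann_genes
  N <- sum(in_bg)
  gene_terms <- split(annotations$term, annotations$gene)
  term_count <- table(annotations$term[annotations$gene %in% ann_genes &
                                         !duplicated(paste(annotations$gene, annotations$term))])
  rows <- list()
  for (i in seq_along(network$nodes)) {
    nb <- adj[[i]]
    if (!length(nb)) next
    g <- network$nodes[i]
    nb_ann <- nb[in_bg[nb]]
    n_draw <- length(nb_ann)
    if (!n_draw) next
    nb_terms <- table(unlist(lapply(network$nodes[nb_ann],
                                    function(x) unique(gene_terms[[x]]))))
    own <- unique(gene_terms[[g]])
    for (tm in names(nb_terms)) {
      k <- nb_terms[[tm]]
      K <- term_count[[tm]]
      p <- stats::phyper(k - 1L, K, N - K, n_draw, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, term = tm, k = k, n_neigh = n_draw, K = K, N = N,
                   p = p, novel = !(tm %in% own), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), term = character(0),
                         k = integer(0), n_neigh = integer(0), K = integer(0),
                         N = integer(0), p = numeric(0), novel = logical(0))
  if (exclude_known) out <- out[out$novel, , drop = FALSE]
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Gene-averaged recall / precision / F of function predictions
#'
#' Per gene with a non-empty gold-standard annotation set:
#' recall = |pred and known| / |known|, precision = |pred and known| / |pred|
#' (0 when the gene has no predictions at the threshold). Network values are
#' the means across those genes; F is the harmonic mean of the averaged
#' recall and precision, 0 when both are 0.
#'
#' @param predictions a `prediction_set`.
#' @param gold propagated gold-standard annotations (`gene`, `term`).
#' @param threshold_q keep predictions with `q <= threshold_q`.
#' @param genes gene universe to average over (default: genes with gold
#'   annotations among the prediction set's network genes; pass the network
#'   node set for network-wide averaging).
#' @return list with `recall`, `precision`, `F`, `n_genes`,
#'   `predicted_positives` (gene-term pairs retained at the threshold).
#' @export
gene_level_recall_precision <- function(predictions, gold, threshold_q = 0.01,
                                        genes = NULL) {
  if (nrow(gold) == 0) stop("empty gold standard")
  pred <- predictions[!is.na(predictions$q) & predictions$q <= threshold_q, ,
                      drop = FALSE]
  gold_terms <- split(gold$term, gold$gene)
  genes <- genes %||% names(gold_terms)
  genes <- intersect(genes, names(gold_terms))
  pred_terms <- split(pred$term, pred$gene)
  rec <- prec <- numeric(length(genes))
  for (j in seq_along(genes)) {
    known <- unique(gold_terms[[genes[j]]])
    ps <- unique(pred_terms[[genes[j]]])
    tp <- length(intersect(ps, known))
    rec[j] <- tp / length(known)
    prec[j] <- if (length(ps)) tp / length(ps) else 0
  }
  R <- mean(rec); P <- mean(prec)
  list(recall = R, precision = P,
       F = if (P + R > 0) 2 * P * R / (P + R) else 0,
       n_genes = length(genes), predicted_positives = nrow(pred))
}

#' Per-category recall / precision / F
#'
#' Classical set-overlap scoring for one term: `tp` = genes predicted for the
#' term that carry it in the gold standard, `fp` = predicted but not gold,
#' `fn` = gold network genes not predicted. Undefined ratios are 0.
#'
#' @param predictions a `prediction_set`.
#' @param gold propagated gold annotations.
#' @param term the category.
#' @param threshold_q prediction q-value threshold.
#' @param genes network gene universe for the fn count (default: all genes in
#'   `gold`).
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`, `F`.
#' @export
category_recall_precision <- function(predictions, gold, term,
                                      threshold_q = 0.01, genes = NULL) {
  genes <- genes %||% unique(gold$gene)
  pred_g <- unique(predictions$gene[!is.na(predictions$q) &
                                      predictions$q <= threshold_q &
                                      predictions$term == term])
  gold_g <- intersect(unique(gold$gene[gold$term == term]), genes)
  tp <- length(intersect(pred_g, gold_g))
  fp <- length(setdiff(pred_g, gold_g))
  fn <- length(setdiff(gold_g, pred_g))
  R <- if (tp + fn > 0) tp / (tp + fn) else 0
  P <- if (tp + fp > 0) tp / (tp + fp) else 0
  list(tp = tp, fp = fp, fn = fn, recall = R, precision = P,
       F = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

#' Performance curve over prediction FDR thresholds
#'
#' Gene-averaged (or single-category) recall, precision and F at every
#' q-value threshold, by default the decade grid from 1e-2 down to 1e-11.
#'
#' @param predictions a `prediction_set`.
#' @param gold propagated gold annotations.
#' @param thresholds descending q-value thresholds.
#' @param term optional: score one category instead of the gene average.
#' @param genes gene universe passed through to the scorers.
#' @return data.frame of class `performance_curve`: `threshold`, `recall`,
#'   `precision`, `F`, `predicted_positives`.
#' @export
performance_curve <- function(predictions, gold, thresholds = 10^-(2:11),
                              term = NULL, genes = NULL) {
  stopifnot(!is.unsorted(rev(thresholds)))
  rows <- lapply(thresholds, function(th) {
    if (is.null(term)) {
      s <- gene_level_recall_precision(predictions, gold, th, genes)
      data.frame(threshold = th, recall = s$recall, precision = s$precision,
                 F = s$F, predicted_positives = s$predicted_positives)
    } else {
      s <- category_recall_precision(predictions, gold, term, th, genes)
      pp <- sum(!is.na(predictions$q) & predictions$q <= th &
                  predictions$term == term)
      data.frame(threshold = th, recall = s$recall, precision = s$precision,
                 F = s$F, predicted_positives = pp)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_curve", "data.frame")
  out
}

#' Classify a network's relative prediction performance
#'
#' Compares a focal network's F-measure curve against an ensemble of sampled
#' comparison curves. The evaluated subrange keeps the thresholds where the
#' focal network or at least half of the sampled networks have nonzero F.
#' Over that subrange the root mean square deviation (RMSD) of the focal F to
#' the pointwise 25th, 50th and 75th percentile curves decides the label:
#' very good / good above the median (nearest percentile 75th / 50th), poor /
#' very poor below it, average when the focal curve tracks the median with
#' mixed signs. An empty subrange yields "insufficient information".
#'
#' @param focal_curve a `performance_curve` for the focal network.
#' @param sampled_curves list of `performance_curve`s on the same thresholds.
#' @return list of class `relative_performance`: `label`, `rmsd_to_p25`,
#'   `rmsd_to_p50`, `rmsd_to_p75`, `subrange` (thresholds used).
#' @export
classify_relative_performance <- function(focal_curve, sampled_curves) {
  if (length(sampled_curves) < 2) stop("need at least 2 sampled curves")
  thr <- focal_curve$threshold
  Fs <- vapply(sampled_curves, function(cv) {
    stopifnot(identical(cv$threshold, thr))
    cv$F
  }, numeric(length(thr)))
  n_nonzero <- rowSums(Fs > 0)
  sub <- focal_curve$F > 0 | n_nonzero >= length(sampled_curves) / 2
  if (!any(sub))
    return(structure(list(label = "insufficient information",
                          rmsd_to_p25 = NA_real_, rmsd_to_p50 = NA_real_,
                          rmsd_to_p75 = NA_real_, subrange = numeric(0)),
                     class = "relative_performance"))
  q <- apply(Fs[sub, , drop = FALSE], 1L, stats::quantile,
             probs = c(0.25, 0.5, 0.75), type = 7)
  f <- focal_curve$F[sub]
  rmsd <- function(ref) sqrt(mean((f - ref)^2))
  r25 <- rmsd(q[1L, ]); r50 <- rmsd(q[2L, ]); r75 <- rmsd(q[3L, ])
  dev50 <- f - q[2L, ]
  above <- mean(dev50 > 0) > 0.5 && mean(dev50) > 0
  below <- mean(dev50 < 0) > 0.5 && mean(dev50) < 0
  label <- if (above && r75 < r50) "very good"
    else if (above) "good"
    else if (below && r25 < r50) "very poor"
    else if (below) "poor"
    else "average"
  structure(list(label = label, rmsd_to_p25 = r25, rmsd_to_p50 = r50,
                 rmsd_to_p75 = r75, subrange = thr[sub]),
            class = "relative_performance")
}

#' Hypergeometric term enrichment for gene clusters
#'
#' Over-representation of each term in each cluster relative to an annotated
#' background, exact hypergeometric upper tail, BH-adjusted within each
#' cluster separately.
#'
#' @param gene_sets named list of gene id vectors (clusters); empty clusters
#'   are skipped.
#' @param annotations annotation data.frame (`gene`, `term`), typically
#'   propagated.
#' @param background character vector of background genes (default: all
#'   annotated genes).
#' @return data.frame `cluster`, `term`, `k`, `n`, `K`, `N`, `p`, `q`.
#' @export
cluster_go_enrichment <- function(gene_sets, annotations, background = NULL) {
  background <- unique(background %||% annotations$gene)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  ann <- ann[!duplicated(paste(ann$gene, ann$term)), , drop = FALSE]
  N <- length(background)
  term_count <- table(ann$term)
  gene_terms <- split(ann$term, ann$gene)
  rows <- list()
  for (cl in names(gene_sets)) {
    genes <- intersect(unique(gene_sets[[cl]]), background)
    n <- length(genes)
    if (!n) next
    counts <- table(unlist(lapply(genes, function(g) unique(gene_terms[[g]]))))
    cl_rows <- lapply(names(counts), function(tm) {
      k <- counts[[tm]]; K <- term_count[[tm]]
      data.frame(cluster = cl, term = tm, k = k, n = n, K = K, N = N,
                 p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
    cl_df <- do.call(rbind, cl_rows)
    cl_df$q <- bh_adjust(cl_df$p)
    rows[[cl]] <- cl_df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
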