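toy_ontology <- data.frame(
  child = c("L1", "L2", "M1", "M2", "D"), parent = c("M1", "M1", "R", "R", "L1"),
  relation = c("is_a", "is_a", "is_a", "part_of", "is_a"))

test_that("true-path propagation: chain, diamond, idempotence", {
  ann <- data.frame(gene = "g1", term = "D")
  out <- propagate_annotations(ann, toy_ontology)
  expect_setequal(out$term, c("D", "L1", "M1", "R"))
  # diamond: two paths to one ancestor count once
  diamond <- data.frame(child = c("X", "X", "A", "B"),
                        parent = c("A", "B", "R", "R"),
                        relation = "is_a")
  outd <- propagate_annotations(data.frame(gene = "g", term = "X"), diamond)
  expect_equal(sum(outd$term == "R"), 1)
  # idempotent on a closed set
  expect_identical(propagate_annotations(out, toy_ontology), out)
  # cycles error
  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"), relation = "is_a")
  expect_error(propagate_annotations(data.frame(gene = "g", term = "A"), cyc),
               "cycle")
})

test_that("OBO round trip preserves the edge set", {
  path <- tempfile(fileext = ".obo")
  write_obo(toy_ontology, path)
  back <- read_obo(path)
  o1 <- toy_ontology[order(toy_ontology$child, toy_ontology$parent), ]
  o2 <- back[order(back$child, back$parent), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, ignore_attr = TRUE)
  expect_setequal(attr(back, "terms"),
                  unique(c(toy_ontology$child, toy_ontology$parent)))
})

test_that("neighborhood enrichment reproduces the exact hypergeometric tail", {
  # focal gene g0 has 5 neighbours, 4 annotated to T; background: 50 annotated
  # genes of which 5 carry T
  nodes <- c("g0", sprintf("n%02d", 1:50))
  edges <- data.frame(gene_a = "g0", gene_b = sprintf("n%02d", 1:5))
  # n01..n04 carry T (neighbours), n50 carries T (non-neighbour); everyone
  # annotated to a filler term so the background is all 50 non-focal genes
  ann <- rbind(data.frame(gene = c(sprintf("n%02d", 1:4), "n50"), term = "T"),
               data.frame(gene = sprintf("n%02d", 1:50), term = "F"))
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "coexpression_network")
  pred <- neighborhood_enrichment(net, ann)
  pT <- pred$p[pred$gene == "g0" & pred$term == "T"]
  oracle <- sum(vapply(4:5, function(i)
    choose(5, i) * choose(45, 5 - i), numeric(1))) / choose(50, 5)
  expect_equal(pT, oracle, tolerance = 1e-12)
  # no test for terms absent from the neighbourhood
  expect_false(any(pred$term == "absent"))
  # focal gene is excluded from its own neighbourhood counts: neighbours of
  # n01 include g0, which is unannotated, so N stays 50 and g0 adds no counts
  expect_true(all(pred$N == 50))
})

test_that("hypergeometric tail matches exhaustive enumeration at small N", {
  for (case in list(c(N = 10, K = 4, n = 3, k = 2),
                    c(N = 15, K = 6, n = 5, k = 3),
                    c(N = 12, K = 3, n = 6, k = 1))) {
    N <- unname(case["N"]); K <- unname(case["K"])
    n <- unname(case["n"]); k <- unname(case["k"])
    sets <- utils::combn(N, n)
    hits <- colSums(sets <= K)   # items 1..K carry the term
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 mean(hits >= k), tolerance = 1e-12,
                 info = paste(case, collapse = ","))
  }
})

test_that("gene-level and category-level scoring follow the set arithmetic", {
  pred <- data.frame(gene = c("g1", "g1", "g2"), term = c("A", "C", "A"),
                     p = 1e-6, q = 1e-4, novel = TRUE)
  class(pred) <- c("prediction_set", "data.frame")
  gold <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                     term = c("A", "B", "A", "B"))
  s <- gene_level_recall_precision(pred, gold, threshold_q = 0.01)
  # g1: pred {A,C} vs known {A,B} -> R 0.5 P 0.5; g2: R 1 P 1; g3: R 0 P 0
  expect_equal(s$recall, mean(c(0.5, 1, 0)))
  expect_equal(s$precision, mean(c(0.5, 1, 0)))

  perfect <- gold; perfect$p <- 0; perfect$q <- 0
  class(perfect) <- c("prediction_set", "data.frame")
  sp <- gene_level_recall_precision(perfect, gold, 0.01)
  expect_equal(c(sp$recall, sp$precision, sp$F), c(1, 1, 1))

  none <- pred[0, ]
  s0 <- gene_level_recall_precision(none, gold, 0.01)
  expect_equal(c(s0$recall, s0$precision, s0$F), c(0, 0, 0))

  cs <- category_recall_precision(pred, gold, "A", 0.01,
                                  genes = c("g1", "g2", "g3"))
  expect_equal(cs$tp, 2); expect_equal(cs$fp, 0); expect_equal(cs$fn, 0)
  # direct-formula case: tp 3, fp 1, fn 1
  pred2 <- data.frame(gene = paste0("h", 1:4), term = "T", p = 0, q = 0)
  gold2 <- data.frame(gene = c(paste0("h", 1:3), "h9"), term = "T")
  c2 <- category_recall_precision(pred2, gold2, "T", 0.01,
                                  genes = c(paste0("h", 1:4), "h9"))
  expect_equal(c(c2$recall, c2$precision, c2$F), c(0.75, 0.75, 0.75))
})

test_that("performance curve is monotone and matches brute-force recomputation", {
  set.seed(31)
  genes <- paste0("g", 1:30)
  pred <- data.frame(gene = sample(genes, 60, replace = TRUE),
                     term = sample(c("A", "B", "C"), 60, replace = TRUE),
                     p = stats::runif(60)^4)
  pred <- pred[!duplicated(pred[, 1:2]), ]
  pred$q <- bh_adjust(pred$p)
  class(pred) <- c("prediction_set", "data.frame")
  gold <- data.frame(gene = sample(genes, 25, replace = TRUE),
                     term = sample(c("A", "B", "C"), 25, replace = TRUE))
  gold <- gold[!duplicated(gold), ]
  thr <- 10^-(1:6)
  curve <- performance_curve(pred, gold, thr)
  expect_true(all(diff(curve$predicted_positives) <= 0))
  expect_true(all(diff(curve$recall) <= 1e-12))
  for (i in seq_along(thr)) {
    s <- gene_level_recall_precision(pred, gold, thr[i])
    expect_equal(curve$F[i], s$F, tolerance = 1e-12)
  }
})

test_that("relative performance classes follow the percentile rule", {
  thr <- 10^-(2:6)
  mk <- function(f) {
    cv <- data.frame(threshold = thr, recall = f, precision = f, F = f,
                     predicted_positives = 10)
    class(cv) <- c("performance_curve", "data.frame")
    cv
  }
  set.seed(9)
  sampled <- lapply(1:40, function(i) mk(pmax(0, 0.5 - 0.05 * seq_along(thr) +
                                                stats::rnorm(5, 0, 0.02))))
  above <- classify_relative_performance(mk(rep(0.9, 5)), sampled)
  expect_equal(above$label, "very good")
  below <- classify_relative_performance(mk(rep(0.01, 5)), sampled)
  expect_equal(below$label, "very poor")
  med <- apply(vapply(sampled, function(cv) cv$F, numeric(5)), 1, stats::median)
  mid <- classify_relative_performance(mk(med), sampled)
  expect_equal(mid$label, "average")
  empty <- classify_relative_performance(mk(rep(0, 5)), lapply(1:10, function(i)
    mk(rep(0, 5))))
  expect_equal(empty$label, "insufficient information")
})

test_that("withheld-annotation recovery beats a rewired control, paired", {
  wins <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_rows = 5, n_cols = 8, n_genes = 40,
                             n_modules = 4, module_size = 7,
                             count_model = "lognormal", gene_noise_sd = 0.25,
                             affected_fraction = 0, withheld_fraction = 0.2,
                             seed = 3000 + s)
    ds <- simulate_field_dataset(cfg)
    m <- log2(ds$counts)
    net <- build_network(m, ds$layout, alpha = 0.05, spatial = FALSE)
    if (nrow(net$edges) < 10) return(NA)
    ann <- propagate_annotations(ds$annotations$annotations,
                                 ds$annotations$ontology)
    recall_of <- function(network) {
      pred <- neighborhood_enrichment(network, ann)
      hit <- with(ds$annotations$withheld,
                  mapply(function(g, tm)
                    any(pred$gene == g & pred$term == tm & pred$q <= 0.01),
                    gene, term))
      mean(hit)
    }
    recall_of(net) > recall_of(rewire_network(net, seed = s))
  }, logical(1))
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
})

test_that("cluster enrichment: exact tail, saturating term, null calibration", {
  genes <- paste0("g", 1:60)
  ann <- rbind(data.frame(gene = genes[1:6], term = "rare"),
               data.frame(gene = genes, term = "everything"))
  out <- cluster_go_enrichment(list(c1 = genes[1:6]), ann)
  expect_equal(out$p[out$term == "everything"], 1)
  expect_equal(out$p[out$term == "rare"],
               1 / choose(60, 6), tolerance = 1e-12)   # minimal tail value

  qs <- vapply(1:200, function(s) {
    set.seed(s)
    res <- cluster_go_enrichment(list(c1 = sample(genes, 10)), ann)
    min(res$q)
  }, numeric(1))
  expect_lte(mean(qs <= 0.05), 0.07)
})
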