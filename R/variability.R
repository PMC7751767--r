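#' Per-feature mean and coefficient of variation
#'
#' CVs are computed on linear-scale (non-log) data, using the sample
#' (denominator n-1) standard deviation. Features with zero mean cannot be
#' scored and are flagged.
#'
#' @param m linear-scale feature x plant matrix.
#' @return data.frame with `feature`, `mean`, `cv`, `cv2`, `scored` (FALSE
#'   for zero-mean features, whose cv is `NA`).
#' @export
coefficient_of_variation <- function(m) {
  check_matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  data.frame(feature = rownames(m) %||% as.character(seq_len(nrow(m))),
             mean = mu, cv = cv, cv2 = cv^2, scored = mu > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the CV^2 versus mean trend
#'
#' Transcripts: gamma-family GLM with identity link of the form
#' `CV^2 = a / mean + b`, fitted after excluding the `exclude_low` fraction of
#' features with the lowest mean (default 5%); falls back to nonlinear least
#' squares if the GLM does not converge. Metabolites: ordinary least squares
#' on `log10(CV^2) ~ log10(mean)`.
#'
#' @param means,cv2 per-feature means and squared CVs (linear scale).
#' @param model `"gamma-identity"` or `"loglog-linear"`.
#' @param exclude_low fraction of lowest-mean features excluded before the
#'   gamma fit (and from downstream ranking).
#' @return object of class `cv_trend`: coefficients `a`, `b` (gamma) or
#'   intercept/slope (loglog), the `model`, a `trend(mean)` evaluator and the
#'   logical `used` marking the features that survived the exclusion.
#' @export
fit_cv_trend <- function(means, cv2, model = c("gamma-identity", "loglog-linear"),
                         exclude_low = 0.05) {
  model <- match.arg(model)
  ok <- is.finite(means) & is.finite(cv2) & means > 0 & cv2 > 0
  used <- ok
  if (model == "gamma-identity") {
    cut <- stats::quantile(means[ok], exclude_low)
    used <- ok & means > cut
  }
  if (sum(used) < 10) stop("fewer than 10 features available for the trend fit")
  x <- means[used]; y <- cv2[used]
  if (model == "gamma-identity") {
    # OLS on the same curve gives starting values; clip to keep the identity
    # link's fitted values positive over the data range
    init <- stats::coef(stats::lm(y ~ I(1 / x)))
    init <- pmax(init, 1e-8)
    fit <- tryCatch({
      g <- suppressWarnings(stats::glm(y ~ I(1 / x),
                                       family = stats::Gamma(link = "identity"),
                                       start = init))
      if (!g$converged) stop("gamma GLM did not converge")
      stats::setNames(stats::coef(g), c("b", "a"))
    }, error = function(e) {
      nls <- tryCatch(stats::nls(y ~ a / x + b,
                                 start = list(a = unname(init[2]), b = unname(init[1]))),
                      error = function(e2)
                        stop("CV trend fit failed (GLM and NLS): ",
                             conditionMessage(e2)))
      stats::setNames(stats::coef(nls)[c("b", "a")], c("b", "a"))
    })
    a <- unname(fit["a"]); b <- unname(fit["b"])
    trend <- function(mu) a / mu + b
    structure(list(a = a, b = b, model = model, trend = trend, used = used,
                   excluded_fraction = exclude_low), class = "cv_trend")
  } else {
    co <- stats::coef(stats::lm(log10(y) ~ log10(x)))
    trend <- function(mu) 10^(co[[1]] + co[[2]] * log10(mu))
    structure(list(a = co[[2]], b = co[[1]], model = model, trend = trend,
                   used = used, excluded_fraction = 0), class = "cv_trend")
  }
}

#' Normalized-CV table with variability flags
#'
#' `normCV = log2( CV^2 / trend(mean) )`: zero for a feature exactly on the
#' mean-variance trend, positive for features more variable than their
#' expression level predicts. The top and bottom 10% of scored features by
#' decreasing normCV are flagged highly / lowly variable (ties broken by
#' feature id).
#'
#' @param m linear-scale feature x plant matrix.
#' @param model trend model (see [fit_cv_trend()]).
#' @param hv_fraction flagged fraction at each end.
#' @return list of class `normcv_table`: `table` (feature, mean, cv, cv2,
#'   norm_cv, highly_variable, lowly_variable), `trend` (the `cv_trend`).
#' @export
normcv_scores <- function(m, model = "gamma-identity", hv_fraction = 0.10) {
  cv <- coefficient_of_variation(m)
  tr <- fit_cv_trend(cv$mean, cv$cv2, model = model)
  tab <- cv[tr$used, , drop = FALSE]
  tab$norm_cv <- log2(tab$cv2 / tr$trend(tab$mean))
  o <- order(-tab$norm_cv, tab$feature)
  n_flag <- floor(hv_fraction * nrow(tab))
  tab$highly_variable <- tab$lowly_variable <- FALSE
  if (n_flag > 0) {
    tab$highly_variable[o[seq_len(n_flag)]] <- TRUE
    tab$lowly_variable[o[seq(nrow(tab) - n_flag + 1L, nrow(tab))]] <- TRUE
  }
  structure(list(table = tab, trend = tr), class = "normcv_table")
}

#' Rank-based term enrichment along a variability ranking
#'
#' Two-sided Mann-Whitney U test per annotation term, comparing the ranks of
#' the term's member features against all other ranked features, with BH
#' adjustment across terms and a direction label saying whether members sit
#' at the variable (top) or stable (bottom) end of the decreasing-normCV
#' ranking.
#'
#' @param ranked_features character vector, most variable first.
#' @param annotations data.frame with columns `gene`, `term`.
#' @param min_size terms with fewer ranked members are skipped.
#' @return data.frame with `term`, `n`, `U`, `p`, `q`, `direction`.
#' @export
rank_based_go_test <- function(ranked_features, annotations, min_size = 5L) {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  ann <- annotations[annotations$gene %in% ranked_features, , drop = FALSE]
  ranks <- stats::setNames(seq_along(ranked_features), ranked_features)
  rows <- lapply(split(ann$gene, ann$term), function(genes) {
    genes <- unique(genes)
    if (length(genes) < min_size || length(genes) == length(ranked_features))
      return(NULL)
    member <- ranks[genes]
    other <- ranks[setdiff(ranked_features, genes)]
    wt <- suppressWarnings(stats::wilcox.test(member, other))
    data.frame(n = length(genes), U = unname(wt$statistic), p = wt$p.value,
               direction = if (stats::median(member) < stats::median(other))
                 "variable-end" else "stable-end",
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(data.frame(term = character(0), n = integer(0),
                                    U = numeric(0), p = numeric(0),
                                    q = numeric(0), direction = character(0)))
  out <- do.call(rbind, rows[keep])
  out <- cbind(term = names(rows)[keep], out, stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("term", "n", "U", "p", "q", "direction")]
}
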