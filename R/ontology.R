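#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @return data.frame of edges with columns `child`, `parent`, `relation`,
#'   plus attribute `terms` (all term ids seen).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  edges <- list()
  terms <- character(0)
  id <- NULL; in_term <- FALSE; obsolete <- FALSE
  flushable <- function() !is.null(id) && !obsolete
  for (ln in lines) {
    if (ln == "[Term]") { in_term <- TRUE; id <- NULL; obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id: ")) {
      id <- sub("^id: ", "", ln); terms <- c(terms, id)
    } else if (startsWith(ln, "is_obsolete: true")) {
      obsolete <- TRUE
    } else if (startsWith(ln, "is_a: ") && flushable()) {
      parent <- sub(" !.*$", "", sub("^is_a: ", "", ln))
      edges[[length(edges) + 1L]] <- c(id, trimws(parent), "is_a")
    } else if (startsWith(ln, "relationship: part_of ") && flushable()) {
      parent <- sub(" !.*$", "", sub("^relationship: part_of ", "", ln))
      edges[[length(edges) + 1L]] <- c(id, trimws(parent), "part_of")
    }
  }
  out <- if (length(edges)) {
    e <- do.call(rbind, edges)
    data.frame(child = e[, 1], parent = e[, 2], relation = e[, 3],
               stringsAsFactors = FALSE)
  } else data.frame(child = character(0), parent = character(0),
                    relation = character(0), stringsAsFactors = FALSE)
  attr(out, "terms") <- unique(c(terms, out$parent))
  out
}

#' Write an ontology edge table as OBO
#'
#' @param ontology data.frame with `child`, `parent`, `relation`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_obo <- function(ontology, path) {
  terms <- unique(c(ontology$child, ontology$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (tm in terms) {
    writeLines(c("", "[Term]", paste0("id: ", tm), paste0("name: ", tm)), con)
    sel <- ontology$child == tm
    for (k in which(sel)) {
      if (ontology$relation[k] == "is_a")
        writeLines(paste0("is_a: ", ontology$parent[k]), con)
      else
        writeLines(paste0("relationship: part_of ", ontology$parent[k]), con)
    }
  }
  invisible(path)
}

## term -> character vector of all ancestors (transitive over is_a/part_of)
term_ancestors <- function(ontology) {
  terms <- unique(c(ontology$child, ontology$parent))
  parents <- split(ontology$parent, factor(ontology$child, levels = terms))
  anc <- stats::setNames(vector("list", length(terms)), terms)
  visiting <- stats::setNames(logical(length(terms)), terms)
  walk <- function(tm) {
    if (!is.null(anc[[tm]])) return(anc[[tm]])
    if (visiting[[tm]]) stop("cycle detected in ontology at term ", tm)
    visiting[[tm]] <<- TRUE
    ps <- unique(parents[[tm]])
    res <- ps
    for (p in ps) res <- union(res, walk(p))
    visiting[[tm]] <<- FALSE
    anc[[tm]] <<- res
    res
  }
  for (tm in terms) walk(tm)
  anc
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every gene annotated to a term is implicitly annotated to all its
#' ancestors along is_a and part_of edges. Idempotent; errors on cyclic
#' ontologies.
#'
#' @param annotations data.frame with columns `gene`, `term`.
#' @param ontology edge data.frame (`child`, `parent`, `relation`) or an
#'   OBO path.
#' @return data.frame `gene`, `term` closed under ancestor propagation
#'   (unique rows, sorted).
#' @export
propagate_annotations <- function(annotations, ontology) {
  if (is.character(ontology) && length(ontology) == 1L)
    ontology <- read_obo(ontology)
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  anc <- term_ancestors(ontology)
  per_gene <- split(annotations$term, annotations$gene)
  rows <- lapply(names(per_gene), function(g) {
    terms <- unique(per_gene[[g]])
    closed <- unique(c(terms, unlist(anc[intersect(terms, names(anc))])))
    data.frame(gene = g, term = closed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
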