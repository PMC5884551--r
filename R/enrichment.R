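# Term-level statistics: hypergeometric PSG enrichment, fold-change-based
# term perturbation, category unions and union-overlap tests.  Annotation
# is a flat gene-term table; no ontology-graph propagation.

#' Construct an annotation map
#'
#' @param gene,term equal-length character vectors: one row per
#'   gene-term association.
#' @param universe the gene universe; defaults to the annotated genes.
#'   Every annotated gene must belong to it.
#' @return An object of class \code{"annotation_map"} with forward
#'   (gene to terms) and inverse (term to genes) maps.
#' @export
annotation_map <- function(gene, term, universe = NULL) {
  stopifnot(length(gene) == length(term))
  if (is.null(universe)) universe <- unique(gene)
  if (!all(gene %in% universe)) {
    stop("invalid-argument: annotated genes outside the universe",
         call. = FALSE)
  }
  structure(list(gene2term = split(term, gene),
                 term2gene = lapply(split(gene, term), unique),
                 universe = unique(universe)),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map: %d genes, %d terms, universe %d\n",
              length(x$gene2term), length(x$term2gene), length(x$universe)))
  invisible(x)
}

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric (Fisher exact) overrepresentation p-value per
#' term for a gene set against the annotation universe, with
#' Benjamini-Hochberg correction across terms and significance at
#' q < 0.1.
#'
#' @param genes gene set (must lie in the universe).
#' @param ann an \code{\link{annotation_map}}.
#' @param q_threshold significance threshold on the q-value.
#' @return Data frame: term, overlap, set_size, term_size, universe_size,
#'   p_value, q_value, significant.
#' @export
hypergeom_enrich <- function(genes, ann, q_threshold = 0.1) {
  genes <- unique(genes)
  if (!all(genes %in% ann$universe)) {
    stop("invalid-argument: gene set outside the universe", call. = FALSE)
  }
  if (!length(genes)) {
    return(data.frame(term = character(0), overlap = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  }
  N <- length(ann$universe)
  K <- length(genes)
  rows <- lapply(names(ann$term2gene), function(tm) {
    members <- ann$term2gene[[tm]]
    m <- length(members)
    x <- length(intersect(genes, members))
    p <- phyper(x - 1, m, N - m, K, lower.tail = FALSE)
    data.frame(term = tm, overlap = x, set_size = K, term_size = m,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < q_threshold
  out[order(out$p_value, out$term), ]
}

#' Directional fold-change set test
#'
#' Per term and direction, a one-sided Welch t location test compares
#' member log2 fold-changes against non-member fold-changes ("up": members
#' shifted upward; "down": downward).  This is a simplified perturbation
#' test in the spirit of fold-change-based GO tools; q-values are
#' Benjamini-Hochberg per direction, significant at q < 0.1.
#'
#' @param lfc named numeric vector of per-gene log2 fold-changes.
#' @param ann an \code{\link{annotation_map}}.
#' @param q_threshold significance threshold on the q-value.
#' @return Data frame: term, direction, n_members, shift (member minus
#'   non-member mean), p_value, q_value, significant.  Terms with fewer
#'   than 2 members carrying fold-changes are skipped and listed in
#'   \code{attr(, "skipped")}.
#' @export
fc_set_test <- function(lfc, ann, q_threshold = 0.1) {
  stopifnot(!is.null(names(lfc)))
  skipped <- character(0)
  rows <- list()
  for (tm in names(ann$term2gene)) {
    members <- intersect(ann$term2gene[[tm]], names(lfc))
    nonmem <- setdiff(names(lfc), members)
    if (length(members) < 2 || length(nonmem) < 2) {
      skipped <- c(skipped, tm)
      next
    }
    x <- lfc[members]
    y <- lfc[nonmem]
    p_up <- t.test(x, y, alternative = "greater")$p.value
    p_dn <- t.test(x, y, alternative = "less")$p.value
    rows[[tm]] <- data.frame(
      term = tm, direction = c("up", "down"),
      n_members = length(members), shift = mean(x) - mean(y),
      p_value = c(p_up, p_dn), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) {
    r <- do.call(rbind, rows)
    rownames(r) <- NULL
    r
  } else {
    data.frame(term = character(0), direction = character(0),
               n_members = integer(0), shift = numeric(0),
               p_value = numeric(0))
  }
  out$q_value <- NA_real_
  for (d in c("up", "down")) {
    sel <- out$direction == d
    if (any(sel)) out$q_value[sel] <- bh_fdr(out$p_value[sel])
  }
  out$significant <- out$q_value < q_threshold
  attr(out, "skipped") <- skipped
  out
}

#' Union of genes across terms
#'
#' @param ann an \code{\link{annotation_map}}.
#' @param terms term ids (must exist in the map).
#' @return Sorted character vector: the union of the terms' gene sets.
#' @export
category_union <- function(ann, terms) {
  missing <- setdiff(terms, names(ann$term2gene))
  if (length(missing)) {
    stop("unknown-term: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sort(unique(unlist(ann$term2gene[unique(terms)])))
}

#' One-sided overlap test of two gene sets
#'
#' Fisher exact (hypergeometric upper tail) p-value for excess overlap of
#' two gene sets within a universe; the same tail statistic as
#' \code{\link{quadrant_fisher}} and \code{\link{hypergeom_enrich}}.
#'
#' @param set_a,set_b gene sets, both subsets of \code{universe}.
#' @param universe the gene universe (non-empty).
#' @return One-sided p-value.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (!length(universe)) {
    stop("invalid-argument: empty universe", call. = FALSE)
  }
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("invalid-argument: sets must lie within the universe",
         call. = FALSE)
  }
  x <- length(intersect(set_a, set_b))
  phyper(x - 1, length(set_b), length(universe) - length(set_b),
         length(set_a), lower.tail = FALSE)
}
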