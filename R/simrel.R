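#' Ontology tables for semantic similarity
#'
#' Bundles the three tables the relevance-based semantic similarity needs:
#' per-term annotation probabilities p(c), reflexive ancestor sets, and
#' gene-to-term annotations. Ancestor sets are made reflexive on
#' construction.
#'
#' @param term_prob named numeric vector, p(c) in (0, 1] per term.
#' @param ancestors named list, term -> character vector of ancestor terms.
#' @param annotations named list, gene -> character vector of terms.
#' @return an object of class `ontology_tables`.
#' @export
ontology_tables <- function(term_prob, ancestors, annotations) {
  stopifnot(is.numeric(term_prob), !is.null(names(term_prob)))
  if (any(term_prob <= 0 | term_prob > 1))
    stop("term probabilities must be in (0, 1]")
  ancestors <- lapply(names(term_prob), function(tm) {
    unique(c(tm, as.character(ancestors[[tm]])))
  })
  names(ancestors) <- names(term_prob)
  unknown <- setdiff(unique(unlist(ancestors)), names(term_prob))
  if (length(unknown))
    stop("ancestor term(s) missing a probability: ",
         paste(unknown, collapse = ", "))
  # specificity must not exceed that of any ancestor
  for (tm in names(ancestors)) {
    if (any(term_prob[tm] > term_prob[ancestors[[tm]]] + 1e-12))
      stop("p(c) exceeds p(ancestor) for term ", tm)
  }
  annotations <- lapply(annotations, function(ts) {
    ts <- as.character(ts)
    if (!all(ts %in% names(term_prob))) stop("term not in ontology")
    unique(ts)
  })
  structure(list(term_prob = term_prob, ancestors = ancestors,
                 annotations = annotations),
            class = "ontology_tables")
}

#' Relevance similarity between two ontology terms
#'
#' Scores a term pair by the most informative common ancestor:
#' `max over common ancestors c of 2 log p(c) / (log p(c1) + log p(c2)) *
#' (1 - p(c))`. A pair whose only common ancestor is the root (p = 1)
#' scores 0; a term against itself scores `1 - p(c)`.
#'
#' @param c1,c2 term identifiers present in `onto`.
#' @param onto an [ontology_tables()] object.
#' @return similarity in \[0, 1\].
#' @export
simrel_terms <- function(c1, c2, onto) {
  stopifnot(inherits(onto, "ontology_tables"))
  p <- onto$term_prob
  if (!c1 %in% names(p) || !c2 %in% names(p)) stop("term not in ontology")
  common <- intersect(onto$ancestors[[c1]], onto$ancestors[[c2]])
  if (!length(common)) return(0)
  denom <- log(p[[c1]]) + log(p[[c2]])
  if (denom == 0) return(0)  # both terms uninformative (p = 1)
  pc <- p[common]
  max(c(0, 2 * log(pc) / denom * (1 - pc)))
}

#' Relevance similarity between two genes
#'
#' Aggregates term-pair similarities over the annotation sets of the two
#' genes. The default is the best-match average (mean of the row-wise and
#' column-wise maxima of the term-pair similarity matrix); `"max"` and
#' `"avg"` are available as alternatives. Genes without annotations fall
#' back to `unannotated`.
#'
#' @param g1,g2 gene identifiers.
#' @param onto an [ontology_tables()] object.
#' @param combine aggregation rule: `"bma"` (default), `"max"` or `"avg"`.
#' @param unannotated similarity returned when either gene lacks
#'   annotations (default 0).
#' @return similarity in \[0, 1\].
#' @export
simrel_genes <- function(g1, g2, onto, combine = c("bma", "max", "avg"),
                         unannotated = 0) {
  combine <- match.arg(combine)
  t1 <- onto$annotations[[g1]]
  t2 <- onto$annotations[[g2]]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2))
    return(unannotated)
  s <- outer(t1, t2, Vectorize(function(a, b) simrel_terms(a, b, onto)))
  switch(combine,
         max = max(s),
         avg = mean(s),
         bma = (sum(apply(s, 1, max)) + sum(apply(s, 2, max))) /
           (length(t1) + length(t2)))
}

#' Pairwise gene similarity matrix
#'
#' Evaluates [simrel_genes()] for every gene pair. Unannotated genes get
#' the `unannotated` similarity to all other genes, a diagonal of 1, and a
#' warning listing them.
#'
#' @param genes character vector of gene ids.
#' @inheritParams simrel_genes
#' @return symmetric numeric matrix with unit diagonal, dimnames = genes.
#' @export
simrel_matrix <- function(genes, onto, combine = c("bma", "max", "avg"),
                          unannotated = 0) {
  combine <- match.arg(combine)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  miss <- genes[!vapply(genes,
                        function(g) length(onto$annotations[[g]]) > 0,
                        logical(1))]
  if (length(miss))
    warning("unannotated gene(s): ", paste(miss, collapse = ", "))
  n <- length(genes)
  sim <- matrix(unannotated, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      sim[i, j] <- sim[j, i] <-
        simrel_genes(genes[i], genes[j], onto, combine, unannotated)
    }
  }
  diag(sim) <- 1
  validate_similarity(sim)
}

#' Validate a similarity matrix
#'
#' @param sim numeric matrix; must be square, named, symmetric (to 1e-8)
#'   and with entries in \[0, 1\].
#' @return the matrix (exactly symmetrised), invisibly usable downstream.
#' @export
validate_similarity <- function(sim) {
  stopifnot(is.matrix(sim), is.numeric(sim))
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (is.null(rownames(sim)) || !identical(rownames(sim), colnames(sim)))
    stop("similarity matrix needs matching row and column gene ids")
  if (anyDuplicated(rownames(sim))) stop("duplicate gene ids")
  if (max(abs(sim - t(sim))) > 1e-8)
    stop("similarity matrix is asymmetric beyond 1e-8")
  if (anyNA(sim) || min(sim) < 0 || max(sim) > 1)
    stop("similarity entries must lie in [0, 1]")
  (sim + t(sim)) / 2
}
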