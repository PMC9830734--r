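#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that a module of `N_m` genes drawn from a
#' universe of `N` genes contains at least `N_gm` of the `N_g`
#' ground-truth genes:
#' `p = sum_{k = N_gm}^{N_g} C(N_g, k) C(N - N_g, N_m - k) / C(N, N_m)`,
#' with out-of-support terms (`N_m - k < 0` or `N_m - k > N - N_g`)
#' contributing zero. The sum is accumulated in log space.
#'
#' @param N universe size.
#' @param N_g ground-truth genes in the universe.
#' @param N_m module size.
#' @param N_gm overlap between module and ground truth.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_p <- function(N, N_g, N_m, N_gm) {
  counts <- c(N, N_g, N_m, N_gm)
  if (any(counts != round(counts)) || any(counts < 0) ||
      N_g > N || N_m > N || N_gm > min(N_g, N_m))
    stop("inconsistent counts")
  k <- seq(N_gm, N_g)
  k <- k[N_m - k >= 0 & N_m - k <= N - N_g]
  if (!length(k)) return(0)
  lt <- lchoose(N_g, k) + lchoose(N - N_g, N_m - k) - lchoose(N, N_m)
  m <- max(lt)
  min(exp(m) * sum(exp(lt - m)), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via `stats::p.adjust`), with
#' input validation; adjusted values are clipped at 1, monotone in the
#' sorted order, and returned in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Gene sets
#'
#' @param name set label.
#' @param genes character vector of unique gene ids (nonempty).
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set must be nonempty")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' Enrichment of a module against a ground-truth gene set
#'
#' Counts the module/ground-truth overlap inside the chosen universe and
#' computes the hypergeometric upper-tail p-value, reported alongside
#' `-log10(p)`.
#'
#' @param module character vector of module gene ids (subset of
#'   `universe`).
#' @param truth a [gene_set()] (or character vector) of ground-truth
#'   genes.
#' @param universe character vector of universe gene ids (nonempty); by
#'   convention the nodes of the constructed network, optionally the full
#'   assayed gene list.
#' @return one-row data frame: `module_label`, `N`, `N_g`, `N_m`, `N_gm`,
#'   `p`, `neg_log10_p`.
#' @export
enrich_module <- function(module, truth, universe) {
  if (inherits(truth, "gene_set")) {
    label <- truth$name
    truth <- truth$genes
  } else {
    label <- "truth"
    truth <- as.character(truth)
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  module <- unique(as.character(module))
  if (!all(module %in% universe)) stop("module must lie in the universe")
  N <- length(universe)
  N_g <- length(intersect(truth, universe))
  N_m <- length(module)
  N_gm <- length(intersect(module, truth))
  p <- hypergeom_p(N, N_g, N_m, N_gm)
  data.frame(module_label = label, N = N, N_g = N_g, N_m = N_m,
             N_gm = N_gm, p = p, neg_log10_p = -log10(p),
             stringsAsFactors = FALSE)
}
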