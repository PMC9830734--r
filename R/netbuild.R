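#' Select differentially expressed genes
#'
#' Welch two-sample t-test per gene between the two sample classes, with
#' Benjamini-Hochberg adjustment; genes with adjusted p below `alpha` are
#' reported. Genes with zero variance in both classes carry no signal and
#' are assigned p = 1 so that flat probes pass through without error.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param labels per-sample class vector (two classes, e.g. disease and
#'   control), length `ncol(values)`.
#' @param alpha adjusted-p threshold in (0, 1); default 0.05.
#' @return list with `genes` (selected gene ids, input order) and `p_adj`
#'   (named vector of BH-adjusted p-values for every gene).
#' @export
select_degs <- function(values, labels, alpha = 0.05) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (is.null(rownames(values))) stop("expression matrix needs gene ids")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) stop("one label per sample required")
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly two sample classes required")
  i1 <- labels == cls[1]
  i2 <- labels == cls[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("insufficient replicates")

  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  v1 <- apply(values[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(values[, i2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, nrow(values))
  ok <- se2 > 0
  tt <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # zero pooled variance with unequal means: infinitely strong evidence
  p[!ok & m1 != m2] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  names(p_adj) <- rownames(values)
  list(genes = rownames(values)[p_adj < alpha], p_adj = p_adj)
}

#' Gaussian copula mutual information
#'
#' Rank-transforms each margin to an empirical Gaussian copula (normal
#' quantiles of fractional ranks r/(n+1), average ranks on ties) and
#' returns the Gaussian mutual information -0.5 * log(1 - rho^2) of the
#' transformed pair, clipped at zero. The correlation magnitude is capped
#' at 1 - 1e-12 so perfectly dependent inputs yield a finite estimate.
#'
#' @param x,y numeric vectors of equal length (at least 8), no missing
#'   values.
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return nonnegative mutual information estimate.
#' @export
gcmi <- function(x, y, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 8) stop("gcmi needs at least 8 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (min(x) == max(x) || min(y) == max(y)) {
    warning("constant input: copula rank transform degenerate, returning 0")
    return(0)
  }
  gx <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
  gy <- stats::qnorm(rank(y, ties.method = "average") / (n + 1))
  rho <- stats::cor(gx, gy)
  cap <- 1 - 1e-12
  rho <- min(max(rho, -cap), cap)
  mi <- max(-0.5 * log1p(-rho^2), 0)
  if (unit == "bits") mi / log(2) else mi
}

#' Build the weighted gene co-expression network
#'
#' Nodes are the differentially expressed genes with at least one
#' interaction partner among the DEGs; an edge is kept only if the gene
#' pair is present in the protein-protein interaction network (co-expression
#' absent from the PPIN is set to zero, i.e. dropped), and its weight is
#' the Gaussian copula mutual information of the two expression profiles.
#' Zero-weight edges and nodes isolated by the masking are removed.
#'
#' @param values expression matrix (genes x samples, rownames = gene ids).
#' @param degs character vector of DEG ids, a subset of `rownames(values)`.
#' @param ppin two-column data frame (or more; extra columns ignored) of
#'   interacting gene-symbol pairs. Matching is exact and case-sensitive.
#' @return a weighted `igraph` network.
#' @export
build_gcn <- function(values, degs, ppin) {
  stopifnot(is.matrix(values), is.data.frame(ppin), ncol(ppin) >= 2)
  degs <- as.character(degs)
  if (!all(degs %in% rownames(values))) stop("degs must be rows of values")
  a <- as.character(ppin[[1]])
  b <- as.character(ppin[[2]])
  keep <- a != b & a %in% degs & b %in% degs
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  if (!length(lo)) stop("empty network: no PPIN interaction links two DEGs")
  w <- vapply(seq_along(lo), function(i) {
    gcmi(values[lo[i], ], values[hi[i], ])
  }, numeric(1))
  pos <- w > 0
  if (!any(pos)) stop("empty network: all masked edge weights are zero")
  weighted_network(data.frame(from = lo[pos], to = hi[pos],
                              weight = w[pos], stringsAsFactors = FALSE))
}
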