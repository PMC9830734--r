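#' Construct a weighted network from an edge table
#'
#' Networks in moganet are undirected `igraph` objects with a `name` vertex
#' attribute (gene identifiers) and a strictly positive `weight` edge
#' attribute. This helper builds and validates one from a three-column
#' edge table.
#'
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @param vertices optional character vector of vertex names (fixing the
#'   vertex order); defaults to the names appearing in `edges`, sorted
#'   (so isolated nodes are dropped).
#' @return an undirected weighted `igraph` graph.
#' @export
weighted_network <- function(edges, vertices = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3)
  edges <- data.frame(from = as.character(edges[[1]]),
                      to = as.character(edges[[2]]),
                      weight = as.numeric(edges[[3]]),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$weight)) stop("non-numeric edge weight")
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (is.null(vertices)) {
    vertices <- sort(unique(c(edges$from, edges$to)), method = "radix")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  validate_network(g)
  g
}

#' Validate the weighted-network contract
#'
#' Checks that a graph is undirected, simple, has named vertices and
#' strictly positive edge weights.
#'
#' @param g an `igraph` graph.
#' @return `g`, invisibly.
#' @export
validate_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("network must be undirected")
  if (igraph::any_loop(g)) stop("self-loops are not allowed")
  if (igraph::any_multiple(g)) stop("multi-edges are not allowed")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    stop("vertices must be named")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w) || anyNA(w)) stop("every edge needs a numeric weight")
    if (any(w <= 0)) stop("edge weights must be positive")
  }
  invisible(g)
}

# Integer adjacency lists, one vector per vertex. Most algorithms here work
# on vertex indices and only map back to names at the I/O boundary.
adjacency_list <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

# Sparse symmetric weight matrix (dgCMatrix); zero diagonal.
weight_matrix <- function(g) {
  igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
}

# Internal evaluation cache shared by objectives and the evolutionary loop.
network_cache <- function(g) {
  list(graph = g,
       n = igraph::vcount(g),
       ids = igraph::V(g)$name,
       adj = adjacency_list(g),
       W = weight_matrix(g))
}

#' Normalized mutual information between two partitions
#'
#' Thin wrapper over `igraph::compare(..., method = "nmi")`, used to score
#' recovered partitions against planted ground truth.
#'
#' @param a,b membership vectors of equal length (any label coding).
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "nmi")
}

# Derive a fixed number of 31-bit sub-seeds from one master seed, so the
# phases of a run (init, variation, ...) use decoupled streams.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
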