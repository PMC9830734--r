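# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration) and share no code
# with the package implementation.

# Brute-force Davies-Bouldin evaluation: literal formula, explicit loops.
brute_dbi <- function(assignment, sim, eps = 1e-9,
                      mode = c("similarity", "distance")) {
  mode <- match.arg(mode)
  D <- if (mode == "distance") 1 - sim else sim
  ids <- sort(unique(assignment))
  stopifnot(length(ids) >= 2)
  medoids <- numeric(length(ids))
  S <- numeric(length(ids))
  for (i in seq_along(ids)) {
    members <- which(assignment == ids[i])
    best <- -Inf; med <- NA
    for (m in members) {
      avg <- mean(sim[m, members])
      if (avg > best + 1e-15) { best <- avg; med <- m }
    }
    medoids[i] <- med
    S[i] <- mean(sapply(members, function(x) D[x, med]))
  }
  total <- 0
  for (i in seq_along(ids)) {
    worst <- -Inf
    for (j in seq_along(ids)) {
      if (j == i) next
      r <- (S[i] + S[j]) / (D[medoids[i], medoids[j]] + eps)
      if (r > worst) worst <- r
    }
    total <- total + worst
  }
  total / length(ids)
}

# Exhaustive hypergeometric upper tail: enumerate every possible module
# draw of size N_m from a universe of N genes whose first N_g are "truth",
# and count draws with overlap >= N_gm.
enum_hypergeom <- function(N, N_g, N_m, N_gm) {
  if (N_m == 0) return(if (N_gm == 0) 1 else 0)
  draws <- utils::combn(N, N_m)
  hits <- colSums(draws <= N_g)
  mean(hits >= N_gm)
}

# Connected components of a pointer graph by plain breadth-first search
# over the undirected edges {v, g[v]}; labels numbered by smallest member.
bfs_components <- function(genotype) {
  n <- length(genotype)
  nbrs <- vector("list", n)
  for (v in seq_len(n)) {
    u <- genotype[v]
    if (u != v) {
      nbrs[[v]] <- c(nbrs[[v]], u)
      nbrs[[u]] <- c(nbrs[[u]], v)
    }
  }
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      k <- k + 1L
      queue <- v
      comp[v] <- k
      while (length(queue)) {
        x <- queue[1]; queue <- queue[-1]
        for (u in nbrs[[x]]) {
          if (comp[u] == 0L) { comp[u] <- k; queue <- c(queue, u) }
        }
      }
    }
  }
  comp
}

# Unit-weight graph from an edge matrix (2 columns of 1-based indices).
unit_graph <- function(edges, n = max(edges)) {
  weighted_network(
    data.frame(from = sprintf("n%02d", edges[, 1]),
               to = sprintf("n%02d", edges[, 2]), weight = 1),
    vertices = sprintf("n%02d", seq_len(n)))
}

# Complete graph K_n with given edge weight.
complete_graph <- function(n, weight = 1) {
  p <- t(utils::combn(n, 2))
  weighted_network(
    data.frame(from = sprintf("n%02d", p[, 1]),
               to = sprintf("n%02d", p[, 2]), weight = weight),
    vertices = sprintf("n%02d", seq_len(n)))
}

# Toy 4-term ontology: root above A, B and C children of A.
# p = {root: 1, A: 0.5, B: 0.2, C: 0.1}
toy_ontology <- function() {
  ontology_tables(
    term_prob = c(root = 1, A = 0.5, B = 0.2, C = 0.1),
    ancestors = list(root = "root", A = c("A", "root"),
                     B = c("B", "A", "root"), C = c("C", "A", "root")),
    annotations = list(g1 = "B", g2 = "C", g3 = c("B", "C"), g4 = "A"))
}

# Random connected-ish weighted graph for property tests.
random_weighted_graph <- function(n, p = 0.3) {
  pairs <- t(utils::combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  edges <- data.frame(from = sprintf("n%02d", pairs[keep, 1]),
                      to = sprintf("n%02d", pairs[keep, 2]),
                      weight = runif(sum(keep), 0.1, 1))
  weighted_network(edges, vertices = sprintf("n%02d", seq_len(n)))
}

# Random symmetric similarity matrix with unit diagonal.
random_similarity <- function(n) {
  s <- matrix(runif(n * n), n, n)
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  dimnames(s) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  s
}
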