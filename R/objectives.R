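# Split an assignment vector into a list of module index sets, ordered by
# module id. Errors on gaps are not needed: any integer labels work.
partition_modules <- function(assignment) {
  split(seq_along(assignment), assignment)
}

# Renumber module labels 1..k by smallest member index (canonical form for
# decoded genotypes and written outputs).
canonical_assignment <- function(assignment) {
  first <- !duplicated(assignment)
  match(assignment, assignment[first])
}

#' Davies-Bouldin index over a gene similarity matrix
#'
#' Cluster-validity objective scoring a partition by the ratio of
#' within-module dispersion to between-centre separation:
#' `(1/C) * sum_i max_{j != i} (S_i + S_j) / (dist(v_i, v_j) + eps)`.
#' The module centre `v_i` is the medoid (member with maximal mean
#' similarity to its co-members, ties to the lowest index) and
#' `S_i` is the mean of `dist(x, v_i)` over members. `dist` is, by
#' default, the semantic similarity itself (the form used during
#' evolution); `mode = "distance"` reads it as `1 - sim` for users who
#' want a true dissimilarity.
#'
#' @param assignment integer module label per node (node order = rows of
#'   `sim`).
#' @param sim symmetric similarity matrix in \[0, 1\] covering all nodes.
#' @param eps guard added to the denominator (default 1e-9).
#' @param mode `"similarity"` (default) or `"distance"`.
#' @param single_module_penalty value returned for a one-module partition,
#'   where the max over other modules is empty (default 1e6; the
#'   evolutionary loop substitutes a population-calibrated constant).
#' @param details if `TRUE`, also return the largest pairwise ratio seen
#'   (used to calibrate the single-module penalty).
#' @return the index (smaller = tighter, better-separated modules), or a
#'   list `(value, max_ratio)` when `details = TRUE`.
#' @export
dbi <- function(assignment, sim, eps = 1e-9,
                mode = c("similarity", "distance"),
                single_module_penalty = 1e6, details = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(assignment) == nrow(sim))
  mods <- partition_modules(assignment)
  k <- length(mods)
  if (k == 1) {
    val <- single_module_penalty
    return(if (details) list(value = val, max_ratio = NA_real_) else val)
  }
  D <- if (mode == "distance") 1 - sim else sim
  medoid <- integer(k)
  S <- numeric(k)
  for (i in seq_len(k)) {
    m <- mods[[i]]
    msim <- colMeans(sim[m, m, drop = FALSE])
    medoid[i] <- m[order(-msim, m)][1L]
    S[i] <- mean(D[m, medoid[i]])
  }
  ratio <- outer(S, S, "+") / (D[medoid, medoid, drop = FALSE] + eps)
  diag(ratio) <- -Inf
  val <- mean(apply(ratio, 1, max))
  if (details) list(value = val, max_ratio = max(ratio[is.finite(ratio)]))
  else val
}

#' Weighted clustering coefficient of a module
#'
#' Sums, over module members, the weighted aggregation of each member's
#' within-module neighbourhood: a member with neighbour set `R` (restricted
#' to the module) contributes `2 * sum_{l<k in R} E(l, k) / (|R| (|R|-1))`;
#' members with fewer than two within-module neighbours contribute 0.
#'
#' @param net weighted `igraph` network (or an internal cache).
#' @param module integer vector of member vertex indices (nonempty).
#' @return the module score (e.g. 3.0 for a unit-weight triangle).
#' @export
cc_module <- function(net, module) {
  cache <- if (is.list(net) && !igraph::is_igraph(net)) net
           else network_cache(net)
  stopifnot(length(module) >= 1)
  module <- as.integer(module)
  total <- 0
  inmod <- logical(cache$n)
  inmod[module] <- TRUE
  for (x in module) {
    R <- cache$adj[[x]]
    R <- R[inmod[R]]
    r <- length(R)
    if (r < 2) next
    # sum(W[R,R]) counts each unordered neighbour pair twice
    total <- total + sum(cache$W[R, R]) / (r * (r - 1))
  }
  total
}

#' Weighted within/between module contrast
#'
#' Partition-selection criterion
#' `sum_i O(C_i)/|C_i|^2 - B(C_i)/(|C_i| |C_i'|)` where `O` sums internal
#' edge weights over ordered pairs (each undirected edge twice) and `B`
#' sums the weights crossing the module boundary; a module spanning the
#' whole network has its boundary term defined as 0.
#'
#' @param assignment integer module label per vertex.
#' @param net weighted `igraph` network (or internal cache).
#' @return the criterion value; larger favours dense, well-separated
#'   modules.
#' @export
w_prime <- function(assignment, net) {
  cache <- if (is.list(net) && !igraph::is_igraph(net)) net
           else network_cache(net)
  stopifnot(length(assignment) == cache$n)
  mods <- partition_modules(assignment)
  n <- cache$n
  total <- 0
  for (m in mods) {
    sz <- length(m)
    O <- sum(cache$W[m, m])
    deg_sum <- sum(cache$W[m, , drop = FALSE])
    B <- deg_sum - O
    term <- O / sz^2
    if (n > sz) term <- term - B / (sz * (n - sz))
    total <- total + term
  }
  total
}

#' Pareto dominance of minimisation objective vectors
#'
#' @param a,b numeric objective vectors of equal length.
#' @return `TRUE` iff `a` is componentwise no worse than `b` and strictly
#'   better in at least one component.
#' @export
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

#' Tchebycheff scalarisation
#'
#' `max_j lambda_j * |F_j - z_j|`: the scalar subproblem value of an
#' objective vector under a weight vector and reference point.
#'
#' @param F objective vector.
#' @param lam weight vector (nonnegative, same length).
#' @param z reference point.
#' @return nonnegative scalar.
#' @export
tchebycheff <- function(F, lam, z) {
  max(lam * abs(F - z))
}

#' Evaluate both fitness objectives of a partition
#'
#' `f1` is the similarity-based Davies-Bouldin index; `f2` is
#' `cc_sign * max_i CC'(C_i)`. With the default `cc_sign = -1` the
#' minimising optimiser maximises the aggregation of the densest module;
#' `cc_sign = +1` gives the literal minimisation.
#'
#' @param assignment integer module label per vertex.
#' @param net weighted `igraph` network (or internal cache).
#' @param sim similarity matrix aligned with the vertex order.
#' @param cc_sign -1 (default) or +1.
#' @param dbi_mode `"similarity"` or `"distance"` (see [dbi()]).
#' @param eps denominator guard for [dbi()].
#' @param single_module_penalty see [dbi()].
#' @return named numeric vector `c(f1, f2)`, both minimised downstream.
#' @export
objective_vector <- function(assignment, net, sim, cc_sign = -1,
                             dbi_mode = c("similarity", "distance"),
                             eps = 1e-9, single_module_penalty = 1e6) {
  dbi_mode <- match.arg(dbi_mode)
  cache <- if (is.list(net) && !igraph::is_igraph(net)) net
           else network_cache(net)
  f1 <- dbi(assignment, sim, eps, dbi_mode, single_module_penalty)
  f2 <- cc_sign * max(vapply(partition_modules(assignment),
                             function(m) cc_module(cache, m), numeric(1)))
  c(f1 = f1, f2 = f2)
}
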