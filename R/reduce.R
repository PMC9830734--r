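#' Grow a local module around a node
#'
#' Implements the local-module heuristic used for pre-simplification:
#' starting from node `a`, take its unassigned neighbour `a_k` of largest
#' degree, then the unassigned neighbour `a_kk` of `a_k` sharing the most
#' common neighbours with `a_k`, all joint neighbours of `a_k` and `a_kk`,
#' and finally every neighbour of the module whose number of connections
#' into it exceeds half of its own degree. All candidates are restricted to
#' `unassigned`; degenerate cases collapse to `{a}`. Ties are broken by
#' lowest vertex index.
#'
#' @param net weighted `igraph` network.
#' @param a vertex index of the anchor node; must be in `unassigned`.
#' @param unassigned integer vector of still-unassigned vertex indices.
#' @param adj optional precomputed adjacency list (internal reuse).
#' @return sorted integer vector of module member indices.
#' @export
find_local_module <- function(net, a, unassigned, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_list(net)
  a <- as.integer(a)
  n <- length(adj)
  un <- logical(n)
  un[unassigned] <- TRUE
  if (!un[a]) stop("anchor node is not unassigned")
  deg <- lengths(adj)

  nb_a <- adj[[a]][un[adj[[a]]]]
  if (!length(nb_a)) return(a)
  a_k <- nb_a[order(-deg[nb_a], nb_a)][1L]

  cand <- setdiff(adj[[a_k]][un[adj[[a_k]]]], a)
  if (!length(cand)) return(a)
  ncommon <- vapply(cand, function(v) {
    length(intersect(adj[[v]], adj[[a_k]]))
  }, integer(1))
  a_kk <- cand[order(-ncommon, cand)][1L]

  lm <- unique(c(a, a_k, a_kk, intersect(adj[[a_k]], adj[[a_kk]])))
  lm <- lm[un[lm]]

  # boundary expansion: neighbours wired into the module beyond half their
  # degree (counting edges, not weights) join it
  cand <- setdiff(unique(unlist(adj[lm])), lm)
  cand <- cand[un[cand]]
  if (length(cand)) {
    inside <- vapply(cand, function(v) sum(adj[[v]] %in% lm), integer(1))
    lm <- c(lm, cand[inside > deg[cand] / 2])
  }
  sort(unique(lm))
}

#' Pre-simplify a network into local modules with triangle contraction
#'
#' Repeatedly draws a random unassigned node, grows its local module with
#' [find_local_module()] and assigns a local-module id, until every node
#' belongs to a module. Within each local module containing at least one
#' triangle, the triangle of maximal total internal edge weight (ties:
#' lowest vertex indices) is contracted to a single supernode; merged
#' parallel edges sum their weights and self-loops are dropped.
#'
#' @param net weighted `igraph` network (nonempty).
#' @param rng_seed integer seed driving the random node draws.
#' @return list with `reduced` (a `reduced_network`: quotient `graph`,
#'   `expansion` map supernode -> original vertex indices, and the
#'   `original` graph) and `node_table` (data frame: `node`, `gene`,
#'   `lm_id`, `module_id` (0 = unassigned), `vw`, `va`).
#' @export
presimplify <- function(net, rng_seed = 1L) {
  validate_network(net)
  n <- igraph::vcount(net)
  if (n == 0) stop("network is empty")
  adj <- adjacency_list(net)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(rng_seed))

  lm_id <- integer(n)
  next_id <- 0L
  while (any(lm_id == 0L)) {
    pool <- which(lm_id == 0L)
    a <- pool[sample.int(length(pool), 1L)]
    lm <- find_local_module(net, a, pool, adj)
    next_id <- next_id + 1L
    lm_id[lm] <- next_id
  }

  groups <- contraction_groups(net, lm_id)
  reduced <- quotient_network(net, groups)
  node_table <- data.frame(node = seq_len(n),
                           gene = igraph::V(net)$name,
                           lm_id = lm_id,
                           module_id = 0L,
                           vw = NA_real_, va = NA_real_,
                           stringsAsFactors = FALSE)
  list(reduced = reduced, node_table = node_table)
}

# One group per reduced vertex: for each local module with a triangle, the
# heaviest internal triangle becomes a single group; all other nodes stay
# singletons.
contraction_groups <- function(net, lm_id) {
  W <- weight_matrix(net)
  groups <- list()
  grouped <- logical(length(lm_id))
  for (id in sort(unique(lm_id))) {
    members <- which(lm_id == id)
    if (length(members) >= 3) {
      sub <- igraph::induced_subgraph(net, members)
      tri <- igraph::triangles(sub)
      if (length(tri)) {
        tri <- matrix(members[as.integer(tri)], nrow = 3)
        tri <- apply(tri, 2, sort)
        tw <- apply(tri, 2, function(v) {
          W[v[1], v[2]] + W[v[1], v[3]] + W[v[2], v[3]]
        })
        best <- order(-tw, tri[1, ], tri[2, ], tri[3, ])[1L]
        groups[[length(groups) + 1L]] <- tri[, best]
        grouped[tri[, best]] <- TRUE
      }
    }
  }
  c(groups, as.list(which(!grouped)))
}

# Quotient graph over vertex groups: cross-group edge weights are summed,
# intra-group edges vanish. Groups must partition the vertex set.
quotient_network <- function(net, groups) {
  n <- igraph::vcount(net)
  memb <- integer(n)
  for (s in seq_along(groups)) memb[groups[[s]]] <- s
  stopifnot(all(memb > 0))
  names_red <- vapply(groups, function(v) {
    paste(igraph::V(net)$name[sort(v)], collapse = "|")
  }, character(1))
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight
  a <- memb[el[, 1]]
  b <- memb[el[, 2]]
  keep <- a != b
  edges <- NULL
  if (any(keep)) {
    lo <- pmin(a, b)[keep]
    hi <- pmax(a, b)[keep]
    key <- paste(lo, hi)
    ww <- tapply(w[keep], key, sum)
    pair <- do.call(rbind, lapply(strsplit(names(ww), " "), as.integer))
    edges <- data.frame(from = names_red[pair[, 1]],
                        to = names_red[pair[, 2]],
                        weight = as.numeric(ww), stringsAsFactors = FALSE)
  }
  graph <- if (is.null(edges)) {
    igraph::make_empty_graph(0, directed = FALSE) + igraph::vertices(names_red)
  } else {
    igraph::graph_from_data_frame(edges, directed = FALSE,
                                  vertices = names_red)
  }
  expansion <- lapply(groups, sort)
  names(expansion) <- names_red
  # align expansion with the graph's vertex order
  expansion <- expansion[igraph::V(graph)$name]
  structure(list(graph = graph, expansion = expansion, original = net),
            class = "reduced_network")
}

#' k-core vertex weight
#'
#' Weight of a node as the density times the order of the highest k-core
#' of the subgraph induced by the node and its immediate neighbours
#' (unweighted degrees; density 2E / (|V| (|V| - 1))). Isolated nodes
#' weigh 0.
#'
#' @param net weighted `igraph` network.
#' @param i vertex index.
#' @param adj optional precomputed adjacency list.
#' @return nonnegative vertex weight.
#' @export
vertex_weight <- function(net, i, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_list(net)
  i <- as.integer(i)
  nb <- adj[[i]]
  if (!length(nb)) return(0)
  sub <- igraph::induced_subgraph(net, c(i, nb))
  core <- igraph::coreness(sub)
  k <- max(core)
  h <- igraph::induced_subgraph(sub, which(core >= k))
  nv <- igraph::vcount(h)
  if (nv < 2) return(0)
  dens <- 2 * igraph::ecount(h) / (nv * (nv - 1))
  dens * k
}

#' Boundary correction of local modules
#'
#' Refines the pre-simplification modules on the original network. For each
#' node, `vw` is the k-core vertex weight ([vertex_weight()]) and `va` the
#' summed edge weight to co-members of its local module. A node is retained
#' in its module when `vw > 2` and `vw` is at least the module mean of
#' `vw`; all others are marked unassigned. Each local module then picks a
#' seed (the retained member of largest `va`; if none is retained, the
#' member of largest `va`), and unassigned neighbours of the seed's growing
#' module are absorbed breadth-first. Nodes never absorbed become singleton
#' modules, so the result partitions all nodes.
#'
#' @param net weighted `igraph` network (the original, un-contracted one).
#' @param node_table node table from [presimplify()] (column `lm_id`
#'   populated).
#' @return the node table with `vw`, `va` and a complete `module_id`
#'   column (every node >= 1).
#' @export
boundary_correction <- function(net, node_table) {
  validate_network(net)
  n <- igraph::vcount(net)
  stopifnot(nrow(node_table) == n, all(node_table$lm_id >= 1L))
  adj <- adjacency_list(net)
  W <- weight_matrix(net)
  lm_id <- node_table$lm_id

  vw <- vapply(seq_len(n), function(i) vertex_weight(net, i, adj), numeric(1))
  va <- vapply(seq_len(n), function(i) {
    co <- setdiff(which(lm_id == lm_id[i]), i)
    if (length(co)) sum(W[i, co]) else 0
  }, numeric(1))

  module_id <- integer(n)
  lms <- sort(unique(lm_id))
  retained <- logical(n)
  for (id in lms) {
    members <- which(lm_id == id)
    keep <- vw[members] > 2 & vw[members] >= mean(vw[members])
    retained[members[keep]] <- TRUE
    module_id[members[keep]] <- id
  }

  for (id in lms) {
    members <- which(lm_id == id)
    cand <- members[retained[members]]
    if (!length(cand)) {
      # no member survives the retention rule: seed from the full module
      cand <- members
      message("local module ", id,
              " has no retained node; seeding from its max-va member")
    }
    seed <- cand[order(-va[cand], cand)][1L]
    module_id[seed] <- id
    frontier <- which(module_id == id)
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), integer(0))
      nxt <- nxt[module_id[nxt] == 0L]
      module_id[nxt] <- id
      frontier <- nxt
    }
  }

  left <- which(module_id == 0L)
  if (length(left)) {
    module_id[left] <- max(lms) + seq_along(left)
  }
  node_table$vw <- vw
  node_table$va <- va
  node_table$module_id <- module_id
  node_table
}
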