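#' Configuration of the evolutionary search
#'
#' Defaults follow the reference settings of the method: population 50,
#' 100 generations, neighbourhood size 40 and mutation rate 0.1.
#'
#' @param pop population size (>= 2).
#' @param max_gen number of generations (>= 0; 0 evaluates only the
#'   initial population).
#' @param nm subproblem neighbourhood size, `2 <= nm <= pop`.
#' @param mutation_rate per-position mutation probability in \[0, 1\].
#' @param rng_seed master seed; every stream of the run derives from it.
#' @param cc_sign sign applied to the clustering-coefficient objective
#'   (-1 default; see [objective_vector()]).
#' @param dbi_mode how the Davies-Bouldin objective reads the semantic
#'   similarity: `"distance"` (default for the search; dist = 1 - sim, so
#'   minimisation favours functionally coherent modules) or
#'   `"similarity"` (the literal formula; see [dbi()]).
#' @param mate_scope `"neighborhood"` (mate drawn from the subproblem
#'   neighbourhood, default) or `"global"`.
#' @param replace_scope `"all"` (replace every improved neighbour,
#'   default) or `"one"`.
#' @param eps denominator guard for [dbi()].
#' @return a validated `moga_config` list.
#' @export
moga_config <- function(pop = 50L, max_gen = 100L, nm = 40L,
                        mutation_rate = 0.1, rng_seed = 1L,
                        cc_sign = -1, dbi_mode = "distance",
                        mate_scope = c("neighborhood", "global"),
                        replace_scope = c("all", "one"),
                        eps = 1e-9) {
  pop <- as.integer(pop); max_gen <- as.integer(max_gen); nm <- as.integer(nm)
  if (pop < 2) stop("pop must be at least 2")
  if (nm < 2 || nm > pop) stop("nm must satisfy 2 <= nm <= pop")
  if (max_gen < 0) stop("max_gen must be nonnegative")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  structure(list(pop = pop, max_gen = max_gen, nm = nm,
                 mutation_rate = mutation_rate,
                 rng_seed = as.integer(rng_seed),
                 cc_sign = cc_sign, dbi_mode = dbi_mode,
                 mate_scope = match.arg(mate_scope),
                 replace_scope = match.arg(replace_scope),
                 eps = eps),
            class = "moga_config")
}

#' Decode a locus-based genotype into a partition
#'
#' Each position of the genotype points at a neighbour (or at itself);
#' modules are the connected components of the resulting pointer graph,
#' numbered 1..k by smallest member index.
#'
#' @param genotype integer vector, `genotype[v]` in
#'   `neighbors(v) U {v}`.
#' @param net weighted `igraph` network, or a precomputed adjacency list.
#' @return integer assignment vector (module id per vertex).
#' @export
decode <- function(genotype, net) {
  adj <- if (igraph::is_igraph(net)) adjacency_list(net) else net
  n <- length(genotype)
  stopifnot(n == length(adj))
  for (v in seq_len(n)) {
    if (genotype[v] != v && !(genotype[v] %in% adj[[v]]))
      stop("corrupt genotype: position ", v, " points outside its neighbourhood")
  }
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (v in seq_len(n)) {
    rv <- find(v); rg <- find(genotype[v])
    if (rv != rg) parent[max(rv, rg)] <- min(rv, rg)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  canonical_assignment(roots)
}

# One random valid genotype: uniform over self-or-neighbour per position.
random_genotype <- function(adj) {
  vapply(seq_along(adj), function(v) {
    opts <- c(v, adj[[v]])
    opts[sample.int(length(opts), 1L)]
  }, integer(1))
}

# Majority refinement: sweep positions, replacing each pointer by the most
# frequent pointer value among the node's neighbours, restricted to the
# node's own valid options (ties: smallest index). Stops once 2N
# consecutive positions pass unchanged, with a hard sweep cap.
refine_genotype <- function(g, adj, max_sweeps = 25L) {
  n <- length(g)
  unchanged <- 0L
  for (sweep in seq_len(max_sweeps)) {
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      if (length(nb)) {
        vals <- g[nb]
        valid <- vals[vals == v | vals %in% nb]
        if (length(valid)) {
          cnt <- table(valid)
          top <- as.integer(names(cnt)[cnt == max(cnt)])
          best <- min(top)
          if (best != g[v]) {
            g[v] <- best
            unchanged <- 0L
            next
          }
        }
      }
      unchanged <- unchanged + 1L
      if (unchanged >= 2L * n) return(g)
    }
  }
  g
}

#' Initialise a population of locus-based genotypes
#'
#' Each individual starts with uniform random self-or-neighbour pointers
#' and is then refined position by position toward the pointer value most
#' of the node's neighbours share, until a full pass changes nothing.
#'
#' @param net weighted `igraph` network (or adjacency list).
#' @param cfg a [moga_config()] (only `pop` is used here; the caller is
#'   responsible for seeding the RNG).
#' @return list of integer genotypes.
#' @export
init_population <- function(net, cfg) {
  adj <- if (igraph::is_igraph(net)) adjacency_list(net) else net
  lapply(seq_len(cfg$pop), function(i) {
    refine_genotype(random_genotype(adj), adj)
  })
}

#' Uniform weight vectors and subproblem neighbourhoods
#'
#' Weight vectors `lambda_i = ((i-1)/(pop-1), 1-(i-1)/(pop-1))` on the
#' two-objective simplex; the neighbourhood of subproblem i holds the `nm`
#' subproblem indices with smallest Euclidean distance to `lambda_i`
#' (including i itself; ties broken by index).
#'
#' @param cfg a [moga_config()].
#' @return list with `lambda` (pop x 2 matrix) and `neighbors` (list of
#'   integer index vectors).
#' @export
weight_vectors_and_neighbors <- function(cfg) {
  pop <- cfg$pop
  l1 <- (seq_len(pop) - 1) / (pop - 1)
  lambda <- cbind(l1, 1 - l1)
  dimnames(lambda) <- NULL
  neighbors <- lapply(seq_len(pop), function(i) {
    d <- sqrt((lambda[, 1] - lambda[i, 1])^2 + (lambda[, 2] - lambda[i, 2])^2)
    order(d, seq_len(pop))[seq_len(cfg$nm)]
  })
  list(lambda = lambda, neighbors = neighbors)
}

#' Two-point crossover of locus-based genotypes
#'
#' Draws positions `1 <= i <= j <= N` and returns the first parent with
#' positions i..j taken from the second. Pointer options are per-position,
#' so the child is always a valid genotype.
#'
#' @param p1,p2 integer genotypes of equal length.
#' @return child genotype.
#' @export
two_point_crossover <- function(p1, p2) {
  n <- length(p1)
  stopifnot(length(p2) == n)
  ij <- sort(sample.int(n, 2L, replace = TRUE))
  child <- p1
  child[ij[1]:ij[2]] <- p2[ij[1]:ij[2]]
  child
}

#' Neighbour-based mutation
#'
#' Each position, independently with probability `rate`, has its pointer
#' resampled uniformly from the node's other valid options (self and
#' neighbours, excluding the current value); positions without an
#' alternative are left alone.
#'
#' @param genotype integer genotype.
#' @param net weighted `igraph` network (or adjacency list).
#' @param rate per-position mutation probability.
#' @return mutated genotype (always valid).
#' @export
neighbor_mutation <- function(genotype, net, rate) {
  adj <- if (igraph::is_igraph(net)) adjacency_list(net) else net
  n <- length(genotype)
  hit <- which(stats::runif(n) < rate)
  for (v in hit) {
    opts <- setdiff(c(v, adj[[v]]), genotype[v])
    if (length(opts)) genotype[v] <- opts[sample.int(length(opts), 1L)]
  }
  genotype
}

# Expand a reduced-network assignment to the original vertices.
expand_assignment <- function(assignment, reduced) {
  n_orig <- igraph::vcount(reduced$original)
  out <- integer(n_orig)
  for (s in seq_along(reduced$expansion)) {
    out[reduced$expansion[[s]]] <- assignment[s]
  }
  canonical_assignment(out)
}

# Non-dominated archive update; entries carry objectives, genotype and the
# expanded assignment. Duplicate (objectives, assignment) pairs are dropped.
archive_insert <- function(archive, entry) {
  for (e in archive) {
    if (dominates(e$objectives, entry$objectives)) return(archive)
    if (identical(e$objectives, entry$objectives) &&
        identical(e$assignment, entry$assignment)) return(archive)
  }
  keep <- !vapply(archive, function(e) {
    dominates(entry$objectives, e$objectives)
  }, logical(1))
  c(archive[keep], list(entry))
}

#' Run the decomposition-based multi-objective evolutionary search
#'
#' MOEA/D with Tchebycheff scalarisation over locus-based genotypes on the
#' reduced network. Objectives are evaluated on the partition expanded to
#' the original network, so the semantic Davies-Bouldin index sees
#' gene-level similarities and the clustering coefficient the original
#' edge weights; contracted supernodes move between modules as blocks.
#' Each generation, every subproblem mates within its neighbourhood,
#' produces a child by two-point crossover plus neighbour mutation, and
#' the child replaces every neighbouring incumbent whose Tchebycheff value
#' it improves; the reference point tracks the componentwise objective
#' minimum. An unbounded external archive keeps the non-dominated
#' solutions seen.
#'
#' @param reduced a `reduced_network` from [presimplify()].
#' @param sim similarity matrix covering the original network's genes
#'   (dimnames = gene ids).
#' @param cfg a [moga_config()].
#' @return object of class `moga_result`: `archive` (list of entries with
#'   `genotype`, `objectives`, `assignment` on the original vertices),
#'   `z_history` ((max_gen + 1) x 2 matrix of the reference point),
#'   `archive_sizes`, `config`, and the calibrated
#'   `single_module_penalty`.
#' @export
evolve <- function(reduced, sim, cfg = moga_config()) {
  stopifnot(inherits(reduced, "reduced_network"),
            inherits(cfg, "moga_config"))
  cache <- network_cache(reduced$original)
  if (!all(cache$ids %in% rownames(sim)))
    stop("similarity matrix does not cover all network genes")
  sim <- sim[cache$ids, cache$ids]
  adj_red <- adjacency_list(reduced$graph)

  seeds <- derive_seeds(cfg$rng_seed, 2L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  evaluate <- function(genotype, penalty) {
    assignment <- expand_assignment(decode(genotype, adj_red), reduced)
    list(genotype = genotype, assignment = assignment,
         objectives = objective_vector(assignment, cache, sim,
                                       cc_sign = cfg$cc_sign,
                                       dbi_mode = cfg$dbi_mode,
                                       eps = cfg$eps,
                                       single_module_penalty = penalty))
  }

  set.seed(seeds[1])
  genotypes <- init_population(adj_red, cfg)

  # calibrate the single-module sentinel from the initial population:
  # 10x the largest pairwise dispersion/separation ratio observed
  ratios <- vapply(genotypes, function(g) {
    a <- expand_assignment(decode(g, adj_red), reduced)
    dbi(a, sim, cfg$eps, cfg$dbi_mode, details = TRUE)$max_ratio
  }, numeric(1))
  penalty <- if (all(is.na(ratios))) 1e6 else 10 * max(ratios, na.rm = TRUE)

  popn <- lapply(genotypes, evaluate, penalty = penalty)
  wv <- weight_vectors_and_neighbors(cfg)
  z <- do.call(pmin, lapply(popn, `[[`, "objectives"))

  archive <- list()
  for (e in popn) archive <- archive_insert(archive, e)
  z_history <- matrix(NA_real_, cfg$max_gen + 1L, 2,
                      dimnames = list(NULL, c("f1", "f2")))
  z_history[1L, ] <- z
  archive_sizes <- integer(cfg$max_gen + 1L)
  archive_sizes[1L] <- length(archive)

  set.seed(seeds[2])
  if (cfg$max_gen > 0) {
    for (gen in seq_len(cfg$max_gen)) {
      for (j in seq_len(cfg$pop)) {
        mate_pool <- if (cfg$mate_scope == "neighborhood") {
          setdiff(wv$neighbors[[j]], j)
        } else {
          setdiff(seq_len(cfg$pop), j)
        }
        if (!length(mate_pool)) mate_pool <- wv$neighbors[[j]]
        mate <- mate_pool[sample.int(length(mate_pool), 1L)]
        child_g <- two_point_crossover(popn[[j]]$genotype,
                                       popn[[mate]]$genotype)
        child_g <- neighbor_mutation(child_g, adj_red, cfg$mutation_rate)
        child <- evaluate(child_g, penalty)
        z <- pmin(z, child$objectives)
        for (k in wv$neighbors[[j]]) {
          if (tchebycheff(child$objectives, wv$lambda[k, ], z) <
              tchebycheff(popn[[k]]$objectives, wv$lambda[k, ], z)) {
            popn[[k]] <- child
            if (cfg$replace_scope == "one") break
          }
        }
        archive <- archive_insert(archive, child)
      }
      z_history[gen + 1L, ] <- z
      archive_sizes[gen + 1L] <- length(archive)
    }
  }

  structure(list(archive = archive, z_history = z_history,
                 archive_sizes = archive_sizes, config = cfg,
                 single_module_penalty = penalty),
            class = "moga_result")
}

#' Select the final partition and its core module
#'
#' Scores every archived non-dominated partition (already expanded to the
#' original network) by the within/between contrast criterion
#' [w_prime()] and returns the best one together with its largest module
#' (ties: first archive entry, then lowest module id).
#'
#' @param result a `moga_result` from [evolve()], or a bare archive list.
#' @param reduced the `reduced_network` the search ran on.
#' @return list with `assignment` (module id per original vertex, named by
#'   gene), `w_prime`, `module` (gene ids of the largest module) and
#'   `module_id`.
#' @export
select_final <- function(result, reduced) {
  archive <- if (inherits(result, "moga_result")) result$archive else result
  if (!length(archive)) stop("empty Pareto front")
  cache <- network_cache(reduced$original)
  scores <- vapply(archive, function(e) {
    w_prime(e$assignment, cache)
  }, numeric(1))
  best <- which.max(scores)  # first maximum wins ties
  assignment <- stats::setNames(archive[[best]]$assignment, cache$ids)
  sizes <- table(assignment)
  module_id <- as.integer(names(sizes)[order(-sizes,
                                             as.integer(names(sizes)))][1L])
  list(assignment = assignment,
       w_prime = scores[best],
       module = cache$ids[assignment == module_id],
       module_id = module_id)
}
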