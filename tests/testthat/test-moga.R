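test_that("decode turns pointer graphs into the expected partitions", {
  tri_plus <- unit_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)), n = 6)
  adj <- moganet:::adjacency_list(tri_plus)
  # identity pointers: all singletons
  expect_equal(decode(1:6, adj), 1:6)
  # a 3-cycle of pointers among the triangle, rest self
  expect_equal(decode(c(2L, 3L, 1L, 4L, 5L, 6L), adj),
               c(1L, 1L, 1L, 2L, 3L, 4L))
  # invalid pointer
  expect_error(decode(c(5L, 3L, 1L, 4L, 5L, 6L), adj), "corrupt genotype")
})

test_that("decode equals an independent breadth-first component oracle", {
  set.seed(61)
  for (i in 1:20) {
    g <- random_weighted_graph(30, p = 0.15)
    adj <- moganet:::adjacency_list(g)
    genotype <- vapply(1:30, function(v) {
      opts <- c(v, adj[[v]])
      opts[sample.int(length(opts), 1)]
    }, integer(1))
    got <- decode(genotype, adj)
    oracle <- bfs_components(genotype)
    # same partition up to labelling
    expect_equal(partition_nmi(got, oracle), 1)
    # and both use smallest-member numbering
    expect_equal(got, oracle)
  }
})

test_that("initialisation is deterministic and aligns with planted cliques", {
  pn <- gen_planted_network(20, 2, p_in = 1, p_out = 0.05, seed = 2)
  adj <- moganet:::adjacency_list(pn$network)
  cfg <- moga_config(pop = 20, max_gen = 1, nm = 5)
  set.seed(77)
  pop1 <- init_population(adj, cfg)
  set.seed(77)
  pop2 <- init_population(adj, cfg)
  expect_identical(pop1, pop2)
  # genotypes are always valid
  for (g in pop1) {
    for (v in seq_along(g)) expect_true(g[v] == v || g[v] %in% adj[[v]])
  }
  # majority-pointer refinement separates the two cliques for most
  # individuals
  hit <- sum(vapply(pop1, function(g) {
    partition_nmi(decode(g, adj), pn$labels) >= 0.99
  }, logical(1)))
  expect_gte(hit, 18)
})

test_that("weight vectors are uniform and neighbourhoods sorted by distance", {
  wv <- weight_vectors_and_neighbors(moga_config(pop = 3, nm = 2))
  expect_equal(wv$lambda, cbind(c(0, 0.5, 1), c(1, 0.5, 0)))
  # nm = pop: every neighbourhood is the full index set
  wv_full <- weight_vectors_and_neighbors(moga_config(pop = 4, nm = 4))
  for (nb in wv_full$neighbors) expect_setequal(nb, 1:4)
  # pop = 5, nm = 2: the first subproblem's closest pair is {1, 2}
  wv5 <- weight_vectors_and_neighbors(moga_config(pop = 5, nm = 2))
  expect_setequal(wv5$neighbors[[1]], c(1, 2))
})

test_that("two-point crossover keeps genotypes valid and respects boundaries", {
  p1 <- c(1L, 2L, 3L, 4L, 5L)
  p2 <- c(5L, 4L, 3L, 2L, 1L)
  set.seed(8)
  for (i in 1:50) {
    child <- two_point_crossover(p1, p2)
    expect_true(all(child == p1 | child == p2))
  }
  # identical parents: child is the parent regardless of cut points
  expect_identical(two_point_crossover(p1, p1), p1)
})

test_that("neighbour mutation flips at the configured rate", {
  g <- complete_graph(10)
  adj <- moganet:::adjacency_list(g)
  genotype <- rep(1L, 10); genotype[1] <- 2L
  set.seed(9)
  expect_identical(neighbor_mutation(genotype, adj, 0), genotype)
  # rate 1: every position must change (alternatives always exist in K10)
  mut <- neighbor_mutation(genotype, adj, 1)
  expect_true(all(mut != genotype))
  for (v in 1:10) expect_true(mut[v] == v || mut[v] %in% adj[[v]])
  # rate 0.1 over many positions: binomial 3-sigma band
  path <- unit_graph(cbind(1:999, 2:1000))
  adjp <- moganet:::adjacency_list(path)
  base <- seq_len(1000)  # all self-pointers; all positions have options
  set.seed(10)
  changed <- sum(neighbor_mutation(base, adjp, 0.1) != base)
  expect_true(abs(changed - 100) <= 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("a zero-generation run archives the non-dominated initial population", {
  pn <- gen_planted_network(24, 3, 0.9, 0.05, seed = 3)
  red <- presimplify(pn$network, 3)$reduced
  sim <- gen_similarity(pn$labels, seed = 3)
  cfg <- moga_config(pop = 10, max_gen = 0, nm = 4, rng_seed = 3)
  res <- evolve(red, sim, cfg)
  expect_gte(length(res$archive), 1)
  # archive is mutually non-dominated
  for (i in seq_along(res$archive)) {
    for (j in seq_along(res$archive)) {
      if (i != j) expect_false(dominates(res$archive[[i]]$objectives,
                                         res$archive[[j]]$objectives))
    }
  }
})

test_that("evolution is reproducible, keeps genotypes valid, and shrinks the reference point", {
  pn <- gen_planted_network(32, 4, 0.9, 0.05, seed = 4)
  red <- presimplify(pn$network, 4)$reduced
  sim <- gen_similarity(pn$labels, seed = 4)
  cfg <- moga_config(pop = 12, max_gen = 8, nm = 5, rng_seed = 11)
  res1 <- evolve(red, sim, cfg)
  res2 <- evolve(red, sim, cfg)
  expect_identical(res1$archive, res2$archive)
  expect_identical(res1$z_history, res2$z_history)
  # z* is componentwise non-increasing over generations
  expect_true(all(diff(res1$z_history[, 1]) <= 1e-12))
  expect_true(all(diff(res1$z_history[, 2]) <= 1e-12))
  # archived assignments are proper partitions of the original nodes
  for (e in res1$archive) {
    expect_equal(length(e$assignment), igraph::vcount(pn$network))
    expect_true(all(e$assignment >= 1))
  }
})

test_that("the final solution maximises the contrast criterion and extracts the largest module", {
  edges <- data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3"), weight = 1)
  g <- weighted_network(edges)
  # hand-built archive over an identity reduction
  red <- moganet:::quotient_network(g, as.list(1:6))
  archive <- list(
    list(genotype = NULL, objectives = c(f1 = 1, f2 = -1),
         assignment = rep(1L, 6)),
    list(genotype = NULL, objectives = c(f1 = 2, f2 = -2),
         assignment = c(1L, 1L, 1L, 2L, 2L, 2L)))
  fin <- select_final(archive, red)
  expect_equal(unname(fin$w_prime), 4 / 3)
  expect_equal(unname(fin$assignment), c(1L, 1L, 1L, 2L, 2L, 2L))
  # largest-module extraction with unequal sizes
  archive2 <- list(list(genotype = NULL, objectives = c(f1 = 0, f2 = 0),
                        assignment = c(1L, 1L, 1L, 1L, 2L, 3L)))
  fin2 <- select_final(archive2, red)
  expect_setequal(fin2$module, c("a1", "a2", "a3", "b1"))
  expect_error(select_final(list(), red), "empty")
})
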