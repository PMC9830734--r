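test_that("dbi matches the hand-evaluated two-singleton case", {
  sim <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  # two singleton modules, eps = 0: S_i = sim(x, x) = 1,
  # denominator sim(a, b) = 0.5 -> (1+1)/0.5 averaged over both = 4
  expect_equal(dbi(c(1, 2), sim, eps = 0), 4)
  # single module returns the configured penalty
  expect_equal(dbi(c(1, 1), sim, single_module_penalty = 123), 123)
})

test_that("dbi agrees with a brute-force evaluation on random instances", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    k <- sample(2:4, 1)
    assignment <- sample(k, n, replace = TRUE)
    assignment[sample(n, k)] <- 1:k  # ensure no empty module
    sim <- random_similarity(n)
    for (mode in c("similarity", "distance")) {
      expect_equal(dbi(assignment, sim, mode = mode),
                   brute_dbi(assignment, sim, mode = mode),
                   tolerance = 1e-10)
    }
  }
})

test_that("module clustering coefficient has its closed-form values", {
  tri <- complete_graph(3)
  expect_equal(cc_module(tri, 1:3), 3)
  # P3: endpoints have one within-module neighbour, the middle node's
  # neighbours are not adjacent
  p3 <- unit_graph(cbind(1:2, 2:3))
  expect_equal(cc_module(p3, 1:3), 0)
  expect_equal(cc_module(complete_graph(3, weight = 0.5), 1:3), 1.5)
})

test_that("module clustering coefficient is linear and monotone in edge weights", {
  set.seed(31)
  for (i in 1:100) {
    w <- runif(3, 0.05, 1)
    g <- weighted_network(data.frame(from = c("a", "a", "b"),
                                     to = c("b", "c", "c"), weight = w))
    # triangle closed form: each member contributes the weight of the
    # edge opposite to it, so the module score is the total weight
    expect_equal(cc_module(g, 1:3), sum(w), tolerance = 1e-12)
  }
  # monotonicity in a single weight
  base <- c(0.3, 0.5, 0.7)
  vals <- sapply(c(0.2, 0.4, 0.8), function(w1) {
    g <- weighted_network(data.frame(from = c("a", "a", "b"),
                                     to = c("b", "c", "c"),
                                     weight = c(w1, base[2], base[3])))
    cc_module(g, 1:3)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("w_prime follows the ordered-pair convention on two triangles", {
  edges <- data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3"), weight = 1)
  g <- weighted_network(edges)
  # planted split: O = 6 per module (each edge twice), no boundary
  expect_equal(w_prime(c(1, 1, 1, 2, 2, 2), g), 4 / 3)
  # merged: O = 12 over 36, boundary term vanishes for the full graph
  expect_equal(w_prime(rep(1, 6), g), 1 / 3)
  # empty graph scores zero under any partition
  empty <- weighted_network(data.frame(from = "x", to = "y", weight = 1),
                            vertices = c("x", "y", "z"))
  empty <- igraph::delete_edges(empty, 1)
  expect_equal(w_prime(c(1, 2, 1), empty), 0)
})

test_that("objective vector wires both fitness functions with the sign flag", {
  edges <- data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3"), weight = 1)
  g <- weighted_network(edges)
  sim <- random_similarity(6)
  rownames(sim) <- colnames(sim) <- igraph::V(g)$name
  part <- c(1, 1, 1, 2, 2, 2)
  f <- objective_vector(part, g, sim)
  expect_equal(unname(f["f2"]), -3)
  expect_equal(unname(objective_vector(part, g, sim, cc_sign = 1)["f2"]), 3)
  # purity: repeated evaluation is identical
  expect_identical(f, objective_vector(part, g, sim))
})

test_that("dominance is a strict partial order and Tchebycheff behaves at the reference", {
  expect_true(dominates(c(1, 2), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  set.seed(41)
  vecs <- matrix(sample(0:3, 300, replace = TRUE), ncol = 2)
  for (i in 1:100) {
    a <- vecs[sample(150, 1), ]; b <- vecs[sample(150, 1), ]
    c_ <- vecs[sample(150, 1), ]
    expect_false(dominates(a, a))                       # irreflexive
    expect_false(dominates(a, b) && dominates(b, a))    # antisymmetric
    if (dominates(a, b) && dominates(b, c_))            # transitive
      expect_true(dominates(a, c_))
  }
  expect_equal(tchebycheff(c(3, 7), c(1, 0), c(1, 2)), 2)
  expect_equal(tchebycheff(c(5, 5), c(0.5, 0.5), c(5, 5)), 0)
  expect_equal(tchebycheff(c(2, 4), c(0.25, 0.75), c(0, 0)), 3)
})

test_that("w_prime prefers the planted partition to random relabelings", {
  set.seed(51)
  wins <- 0
  for (i in 1:30) {
    pn <- gen_planted_network(40, 4, 0.9, 0.05, seed = i)
    truth <- as.integer(pn$labels)
    random <- sample(4, 40, replace = TRUE)
    if (w_prime(truth, pn$network) > w_prime(random, pn$network))
      wins <- wins + 1
  }
  expect_gte(wins, 29)
})
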