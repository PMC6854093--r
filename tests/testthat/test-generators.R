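# Simulators: deterministic special cases, closed-form expectations, and the
# full reproducibility contract.

test_that("complete seed graphs have the expected size", {
  expect_equal(igraph::ecount(seed_complete(5)), 10)
  k1 <- seed_complete(1)
  expect_equal(c(igraph::vcount(k1), igraph::ecount(k1)), c(1, 0))
  expect_equal(igraph::ecount(seed_complete(3)), 3)
  expect_error(seed_complete(0), "k")
})

test_that("two-clique composite seed has 50 nodes, both cliques, pendant degree 1", {
  set.seed(5)
  g <- seed_two_clique_composite()
  expect_equal(igraph::vcount(g), 50)
  A <- adj_matrix(g)
  expect_true(all(A[1:7, 1:7][upper.tri(diag(7))] == 1))
  expect_true(all(A[8:17, 8:17][upper.tri(diag(10))] == 1))
  expect_true(all(igraph::degree(g)[18:50] == 1))
  expect_true(all(A[18:50, 18:50] == 0)) # pendants attach only to clique nodes
  # mean edge count: 66 within-clique + 70 * 0.67 cross + 33 pendant = 145.9
  set.seed(99)
  draws <- replicate(500, igraph::ecount(seed_two_clique_composite()))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 145.9), 3 * se)
})

test_that("inverse geometric seed follows the farther-than-R rule", {
  set.seed(8)
  g <- seed_inverse_geometric(40, d = 2, R = 1.5)
  expect_equal(igraph::vcount(g), 40)
  # R = 0 with distinct coordinates: every pair connected
  set.seed(9)
  expect_equal(igraph::ecount(seed_inverse_geometric(10, d = 2, R = 0)), 45)
  # per-pair edge probability: ||x_i - x_j||^2 ~ 2 * chisq_2, so
  # P(dist > R) = exp(-R^2 / 4) = 0.5698 for R = 1.5
  set.seed(10)
  m <- replicate(200, igraph::ecount(seed_inverse_geometric(30, d = 2, R = 1.5)))
  p_hat <- mean(m) / choose(30, 2)
  p_true <- exp(-1.5^2 / 4)
  expect_lt(abs(p_hat - p_true), 0.02)
  # invert flag flips the rule
  set.seed(11)
  gi <- seed_inverse_geometric(10, d = 2, R = 0, invert = TRUE)
  expect_equal(igraph::ecount(gi), 0)
})

test_that("ER growth hits degenerate cases and the closed-form mean edge count", {
  spec1 <- model_spec("er_growth", n = 6, p = 1, seed = seed_spec("complete", k = 1))
  set.seed(1)
  expect_equal(igraph::ecount(generate_network(spec1)), 15) # K6
  spec0 <- model_spec("er_growth", n = 100, p = 0, seed = seed_spec("complete", k = 5))
  set.seed(1)
  g0 <- generate_network(spec0)
  expect_equal(c(igraph::vcount(g0), igraph::ecount(g0)), c(100, 10))
  spec <- model_spec("er_growth", n = 100, p = 0.1, seed = seed_spec("complete", k = 5))
  set.seed(2)
  m <- replicate(300, igraph::ecount(generate_network(spec)))
  expected <- 10 + (choose(100, 2) - 10) * 0.1
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - expected), 3 * se)
  expect_error(generate_network(model_spec("er_growth", n = 3, p = 0.5,
                                           seed = seed_spec("complete", k = 5))),
               "seed")
})

test_that("DMC limiting parameterizations behave as the mechanism dictates", {
  # q_mod = 0, q_con = 1 preserves completeness by induction
  spec <- model_spec("dmc", n = 10, q_mod = 0, q_con = 1, seed = seed_spec("complete", k = 3))
  set.seed(3)
  expect_equal(igraph::ecount(generate_network(spec)), choose(10, 2))
  # q_mod = 1, q_con = 0 conserves the seed edge count exactly
  for (s in 1:20) {
    set.seed(s)
    seedg <- rand_graph(6, 0.5)
    spec <- model_spec("dmc", n = 40, q_mod = 1, q_con = 0,
                       seed = seed_spec("explicit", graph = seedg))
    g <- generate_network(spec)
    expect_equal(igraph::ecount(g), igraph::ecount(seedg))
  }
  # zero growth steps return the seed unchanged
  spec <- model_spec("dmc", n = 4, q_mod = 0.5, q_con = 0.5,
                     seed = seed_spec("explicit", graph = igraph::make_ring(4)))
  set.seed(4)
  g <- generate_network(spec)
  expect_true(igraph::isomorphic(g, igraph::make_ring(4)))
})

test_that("DMR deletion and attachment behave as specified", {
  # q_del = 1, q_new = 0, singletons kept: only seed edges survive
  spec <- model_spec("dmr", n = 50, q_del = 1, q_new = 0, remove_singletons = FALSE,
                     seed = seed_spec("complete", k = 5))
  set.seed(5)
  g <- generate_network(spec)
  expect_equal(igraph::ecount(g), 10)
  expect_equal(sum(igraph::degree(g) == 0), 45)
  # q_del = 0, q_new = 0: the duplicate copies its parent's degree exactly
  spec <- model_spec("dmr", n = 6, q_del = 0, q_new = 0,
                     seed = seed_spec("explicit", graph = igraph::make_ring(5)))
  set.seed(6)
  g <- generate_network(spec)
  expect_equal(igraph::degree(g)[6], 2)
  # non-terminating configuration is rejected after the attempt cap
  spec <- model_spec("dmr", n = 8, q_del = 1, q_new = 0, remove_singletons = TRUE,
                     seed = seed_spec("complete", k = 5))
  set.seed(7)
  expect_error(generate_network(spec), "singleton")
})

test_that("DMR singleton removal still reaches the target node count", {
  spec <- model_spec("dmr", n = 60, q_del = 0.9, q_new = 0.5, remove_singletons = TRUE,
                     seed = seed_spec("complete", k = 5))
  set.seed(8)
  g <- generate_network(spec)
  expect_equal(igraph::vcount(g), 60)
  expect_true(all(igraph::degree(g) > 0))
})

test_that("triangle-closure acceptance probability applies base, bonus and increments", {
  expect_equal(triangle_closure_probability(0, 0.3, 0.1, 0.05), 0.3)
  expect_equal(triangle_closure_probability(1, 0.3, 0.1, 0.05), 0.4)
  expect_equal(triangle_closure_probability(3, 0.9, 0.2, 0.1), 1)
  expect_equal(triangle_closure_probability(0:3, 0.3, 0.1, 0.05), c(0.3, 0.4, 0.45, 0.5))
})

test_that("triangle-closure sampler returns exact node and edge counts", {
  spec <- model_spec("triangle_closure", n = 100, m = 2000, p0 = 0.3, p1 = 0.1, p_delta = 0.05)
  set.seed(9)
  g <- generate_network(spec)
  expect_equal(c(igraph::vcount(g), igraph::ecount(g)), c(100, 2000))
  spec0 <- model_spec("triangle_closure", n = 5, m = 0, p0 = 0.3, p1 = 0, p_delta = 0)
  set.seed(10)
  g0 <- generate_network(spec0)
  expect_equal(c(igraph::vcount(g0), igraph::ecount(g0)), c(5, 0))
  expect_error(model_spec("triangle_closure", n = 4, m = 7, p0 = 0.3, p1 = 0, p_delta = 0), "C\\(n, 2\\)")
  degen <- model_spec("triangle_closure", n = 4, m = 2, p0 = 0, p1 = 0, p_delta = 0)
  set.seed(11)
  expect_error(generate_network(degen), "rejected")
})

test_that("every generator is bit-reproducible under a fixed seed", {
  specs <- list(
    model_spec("er_growth", n = 50, p = 0.1, seed = seed_spec("complete", k = 5)),
    model_spec("dmc", n = 50, q_mod = 0.2, q_con = 0.1, seed = seed_spec("complete", k = 5)),
    model_spec("dmr", n = 50, q_del = 0.2, q_new = 0.1, seed = seed_spec("complete", k = 5)),
    model_spec("triangle_closure", n = 30, m = 100, p0 = 0.3, p1 = 0.1, p_delta = 0.05))
  for (spec in specs) {
    set.seed(123); g1 <- generate_network(spec)
    set.seed(123); g2 <- generate_network(spec)
    expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  }
})

test_that("generators always return simple graphs of the requested size", {
  set.seed(31)
  specs <- list(
    model_spec("er_growth", n = 80, p = 0.05, seed = seed_spec("complete", k = 8)),
    model_spec("dmc", n = 80, q_mod = 0.4, q_con = 0.3, seed = seed_spec("complete", k = 5)),
    model_spec("dmr", n = 80, q_del = 0.3, q_new = 0.5, seed = seed_spec("two_clique_composite")),
    model_spec("triangle_closure", n = 40, m = 200, p0 = 0.3, p1 = 0.1, p_delta = 0.03))
  for (spec in specs) {
    g <- generate_network(spec)
    expect_equal(igraph::vcount(g), spec$n)
    expect_true(igraph::is_simple(g))
  }
})
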