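# Proximity, separation, exposure classification and the tissue filter.

path_graph <- function(nodes) {
  g <- igraph::make_graph(rep(nodes, each = 2)[-c(1, 2 * length(nodes))],
                          directed = FALSE)
  g
}

test_that("closest distance follows the averaged-minimum definition", {
  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(closest_distance(p3, "a", "c"), 2)
  expect_equal(closest_distance(p3, c("a", "b", "c"), c("a", "b", "c")), 0)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  # each disease node takes its nearest target: c at 1, l3 at 2
  expect_equal(closest_distance(star, c("l1", "l2"), c("c", "l3")), 1.5)
})

test_that("closest distance is directional and drops off-component members", {
  p4 <- path_graph(c("a", "b", "c", "d"))
  expect_equal(closest_distance(p4, "a", c("a", "d")), 1.5)
  expect_equal(closest_distance(p4, c("a", "d"), "a"), 0)  # asymmetric

  g <- igraph::make_graph(c("a", "b", "b", "c", "x", "y"),
                          directed = FALSE)
  expect_warning(d <- closest_distance(g, "a", c("c", "x")),
                 "largest connected component")
  expect_equal(d, 2)
  expect_error(suppressWarnings(closest_distance(g, "x", "a")), "empty")
})

test_that("closest distance matches a Floyd-Warshall oracle on random graphs", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    g <- random_test_graph(n, p = 0.2)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    fw <- oracle_floyd_warshall(adj)
    nodes <- igraph::V(g)$name
    xs <- sample(nodes, sample(2:4, 1))
    ys <- sample(nodes, sample(2:5, 1))
    want <- mean(apply(fw[match(ys, nodes), match(xs, nodes),
                          drop = FALSE], 1, min))
    expect_equal(closest_distance(g, xs, ys), want)
  }
})

test_that("separation score reproduces the nearest-neighbor conventions", {
  ab <- igraph::make_graph(c("a", "b"), directed = FALSE)
  s <- separation_score(ab, c("a", "b"), c("a", "b"))
  expect_equal(s$d_ab, 0)
  expect_equal(s$d_aa, 1)
  expect_equal(s$s_ab, -1)

  p4 <- path_graph(c("a", "b", "c", "d"))
  single <- separation_score(p4, "a", "d")
  expect_equal(single$s_ab, 3)      # singleton within-terms are 0

  halves <- separation_score(p4, c("a", "b"), c("c", "d"))
  expect_equal(halves$d_ab, 1.5)
  expect_equal(halves$s_ab, 0.5)
})

test_that("a module is never separated from itself", {
  set.seed(21)
  for (rep in 1:30) {
    g <- random_test_graph(sample(10:25, 1), p = 0.2)
    a <- sample(igraph::V(g)$name, sample(2:5, 1))
    expect_lte(separation_score(g, a, a)$s_ab, 0)
  }
})

test_that("proximity z is negative for a set overlapping itself and seed-reproducible", {
  set.seed(8)
  g <- random_test_graph(50, p = 0.1)
  hubs <- names(sort(igraph::degree(g), decreasing = TRUE))[1:5]
  res <- proximity_zscore(g, hubs, hubs, n_permutations = 50, seed = 1)
  expect_equal(res$d_xy, 0)
  if (!res$flagged) expect_lt(res$z, 0)

  res2 <- proximity_zscore(g, hubs, hubs, n_permutations = 50, seed = 1)
  expect_identical(res, res2)
  res3 <- proximity_zscore(g, hubs, hubs, n_permutations = 50, seed = 2)
  expect_false(identical(res$mu, res3$mu))

  degenerate <- proximity_zscore(g, hubs, hubs, n_permutations = 1, seed = 1)
  expect_true(degenerate$flagged)
  expect_true(is.na(degenerate$z))
})

test_that("null sampling agrees with exhaustive enumeration on a regular toy graph", {
  # 20-cycle: every node has degree 2, so the degree-matched null is uniform
  # over all 2-subsets for X and Y alike; enumerate all pairs exactly
  g <- igraph::make_ring(20)
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  nodes <- igraph::V(g)$name
  dm <- igraph::distances(g)
  pairs <- utils::combn(20, 2)
  np <- ncol(pairs)
  vals <- matrix(NA_real_, np, np)
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      xs <- pairs[, i]; ys <- pairs[, j]
      vals[i, j] <- (min(dm[ys[1], xs]) + min(dm[ys[2], xs])) / 2
    }
  }
  mu_exact <- mean(vals)
  sd_exact <- sd(vals)
  res <- proximity_zscore(g, c("v01", "v05"), c("v10", "v17"),
                          n_permutations = 100, seed = 3)
  expect_lt(abs(res$mu - mu_exact), 3 * sd_exact / sqrt(100))
  expect_lt(abs(res$sigma - sd_exact),
            3 * sd_exact / sqrt(2 * (100 - 1)))
})

test_that("planted exposure scenarios are recovered and identical drugs never complementary", {
  for (sc in c("complementary", "overlapping", "single", "non")) {
    net <- gen_ppi_with_modules(sim_config(5), sc)
    call <- suppressWarnings(classify_exposure(net$graph, net$disease,
                                               net$drugA, net$drugB,
                                               n_permutations = 100,
                                               seed = 5))
    expect_equal(call$category, sc)
  }
  net <- gen_ppi_with_modules(sim_config(9), "complementary")
  same <- suppressWarnings(classify_exposure(net$graph, net$disease,
                                             net$drugA, net$drugA,
                                             n_permutations = 100, seed = 9))
  expect_lte(same$s_ab, 0)
  expect_false(same$category == "complementary")
})

test_that("tissue filter keeps strictly expressed proteins and reports sizes", {
  set.seed(13)
  g <- random_test_graph(10, p = 0.3)
  nodes <- igraph::V(g)$name
  all_on <- setNames(rep(5, 10), nodes)
  kept <- tissue_filter(g, all_on)
  expect_equal(igraph::ecount(kept), igraph::ecount(g))

  boundary <- setNames(rep(1.0, 10), nodes)
  expect_error(tissue_filter(g, boundary), "empty")

  tpm <- setNames(c(rep(0.2, 4), rep(3, 6)), nodes)
  sub <- tissue_filter(g, tpm)
  keep <- nodes[tpm > 1]
  el <- igraph::as_edgelist(g)
  want_edges <- sum(el[, 1] %in% keep & el[, 2] %in% keep)
  expect_equal(igraph::ecount(sub), want_edges)
  expect_equal(attr(sub, "n_nodes_after"), 6)
  expect_equal(attr(sub, "n_edges_before"), igraph::ecount(g))
})
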