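test_that("closed-form metric values hold on canonical graphs", {
  # path a-b-c: the interior vertex carries the single shortest path
  p <- igraph::make_graph(~ a - b, b - c)
  igraph::E(p)$weight <- c(0.7, 2.3)
  expect_equal(unname(weighted_betweenness(p)), c(0, 1, 0))
  # its interior vertex has two unconnected partners
  expect_equal(unname(weighted_local_transitivity(p)), c(NA_real_, 0, NA_real_))

  # star with 4 leaves: all C(4,2) leaf pairs route through the center
  s <- igraph::make_star(5, mode = "undirected")
  igraph::V(s)$name <- letters[1:5]
  igraph::E(s)$weight <- 1
  expect_equal(unname(weighted_betweenness(s)), c(6, 0, 0, 0, 0))
  # closed form for stars: leaves at 1/sqrt(n)
  expect_equal(unname(eigenvector_centrality(s)), c(1, rep(0.5, 4)))

  # triangle: fully closed neighborhood, complete graph: full symmetry
  tr <- igraph::make_full_graph(3)
  igraph::V(tr)$name <- letters[1:3]
  igraph::E(tr)$weight <- c(1, 2, 3)
  expect_equal(unname(weighted_local_transitivity(tr)), rep(1, 3))
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  igraph::E(k5)$weight <- 1
  expect_equal(unname(eigenvector_centrality(k5)), rep(1, 5))
  expect_equal(unname(weighted_betweenness(k5)), rep(0, 5))
})

test_that("degree and strength equal adjacency row/column sums", {
  set.seed(101)
  for (i in 1:25) {
    g <- rand_wgraph(sample(3:8, 1), p = stats::runif(1, 0.3, 0.7),
                     directed = TRUE)
    ds <- degree_strength(g)
    o <- oracle_strength(g)
    expect_equal(ds$in_strength, unname(o$in_strength))
    expect_equal(ds$out_strength, unname(o$out_strength))
    expect_equal(ds$in_degree, unname(as.integer(o$in_degree)))
    expect_equal(ds$out_degree, unname(as.integer(o$out_degree)))
  }
  expect_error(degree_strength(rand_wgraph(4)), "directed")
})

test_that("weighted betweenness matches exhaustive shortest-path counting", {
  set.seed(202)
  for (i in 1:40) {
    g <- rand_wgraph(sample(4:8, 1), p = stats::runif(1, 0.3, 0.6))
    expect_equal(weighted_betweenness(g), oracle_betweenness(g),
                 tolerance = 1e-10)
  }
  # equal weights force ties; fractional counting must agree
  cyc <- igraph::make_ring(6)
  igraph::V(cyc)$name <- letters[1:6]
  igraph::E(cyc)$weight <- 0.5
  expect_equal(weighted_betweenness(cyc), oracle_betweenness(cyc))
  expect_error(weighted_betweenness(igraph::set_edge_attr(cyc, "weight", value = -1)),
               "positive")
})

test_that("the Floyd-Warshall betweenness oracle agrees with raw path enumeration", {
  set.seed(303)
  for (i in 1:8) {
    g <- rand_wgraph(5, p = 0.5)
    expect_equal(oracle_betweenness(g), enum_betweenness(g), tolerance = 1e-10)
  }
})

test_that("local transitivity matches the Barrat triple-loop formula", {
  set.seed(404)
  for (i in 1:40) {
    g <- rand_wgraph(sample(4:8, 1), p = stats::runif(1, 0.35, 0.7))
    expect_equal(weighted_local_transitivity(g), oracle_barrat(g),
                 tolerance = 1e-12)
  }
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  set.seed(505)
  for (i in 1:40) {
    g <- rand_wgraph(sample(4:8, 1), p = stats::runif(1, 0.4, 0.8))
    expect_equal(quietly(eigenvector_centrality(g)), oracle_eigen(g),
                 tolerance = 1e-8)
  }
})

test_that("directed strength is conserved and monotone weight rescaling behaves", {
  set.seed(606)
  g <- rand_wgraph(8, p = 0.5, directed = TRUE)
  ds <- degree_strength(g)
  expect_equal(sum(ds$in_strength), sum(ds$out_strength))
  expect_equal(sum(ds$in_strength), sum(igraph::E(g)$weight))

  gu <- rand_wgraph(8, p = 0.5)
  gs <- igraph::set_edge_attr(gu, "weight",
                              value = 7.3 * igraph::E(gu)$weight)
  expect_equal(weighted_betweenness(gu), weighted_betweenness(gs))
  expect_equal(weighted_local_transitivity(gu), weighted_local_transitivity(gs))
  expect_equal(quietly(eigenvector_centrality(gu)),
               quietly(eigenvector_centrality(gs)), tolerance = 1e-9)
})

test_that("equal weights reduce weighted betweenness to the unweighted count", {
  set.seed(707)
  for (i in 1:10) {
    g <- rand_wgraph(7, p = 0.5)
    g1 <- igraph::set_edge_attr(g, "weight", value = 1)
    expect_equal(unname(weighted_betweenness(g1)),
                 as.numeric(igraph::betweenness(g1, weights = NA,
                                                normalized = FALSE)))
  }
})

test_that("metrics_table joins attributes, keeps isolates, and is deterministic", {
  roster <- toy_roster(c("F01", "F02", "F03", "M01"), year = 1)
  obs <- toy_obs(list(
    list(1, "F01", "F02", 30, 600),
    list(1, "F02", "F01", 12, 600),
    list(1, "F01", "M01", 6, 300)
  ))
  nets <- quietly(network_sequence(obs, roster))
  m <- quietly(metrics_table(nets))
  # 4 nodes mixed + 1 male + 3 female rows
  expect_equal(nrow(m), 4 + 1 + 3)
  iso <- m[m$id == "F03" & m$composition == "mixed", ]
  expect_equal(iso$in_degree, 0)
  expect_equal(iso$out_strength, 0)
  expect_equal(iso$betweenness, 0)
  expect_true(is.na(iso$local_transitivity))
  expect_equal(iso$eigenvector_centrality, 0, tolerance = 1e-10)
  expect_equal(m$age[m$id == "F02" & m$composition == "mixed"],
               roster$age[roster$id == "F02"])
  m2 <- quietly(metrics_table(quietly(network_sequence(obs, roster))))
  expect_identical(m, m2)
})

test_that("full synthetic community yields one record per node-year-composition", {
  cfg <- sim_config(seed = 9)
  ds <- simulate_dataset(cfg)
  m <- quietly(compute_metrics(ds$observations, ds$roster,
                               compositions = "mixed"))
  expect_equal(nrow(m), 38 * 7)
  expect_true(all(m$in_degree <= 37 & m$out_degree <= 37))
  expect_true(all(m$in_strength >= 0 & m$betweenness >= 0))
  expect_true(all(m$eigenvector_centrality >= 0 &
                    m$eigenvector_centrality <= 1 + 1e-12))
})
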