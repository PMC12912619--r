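test_that("degree, clustering and betweenness on canonical small graphs", {
  k4 <- graph_complete(4)
  expect_equal(nodal_degree(k4)$degree, rep(3, 4))
  expect_equal(clustering(k4)$nodal_cc, rep(1, 4))
  expect_equal(betweenness(k4)$betweenness, rep(0, 4))
  expect_equal(characteristic_path_length(shortest_paths(k4))$lp, 1)
  expect_equal(global_efficiency(shortest_paths(k4))$eglob, 1)

  p3 <- graph_path3()
  expect_equal(nodal_degree(p3)$degree, c(1, 2, 1))
  expect_equal(betweenness(p3)$betweenness, c(0, 1, 0))
  d <- shortest_paths(p3)
  expect_equal(d[1, 3], 2)
  expect_equal(characteristic_path_length(d)$lp, 4 / 3)
  expect_equal(global_efficiency(d)$eglob, (1 + 1 + 0.5) / 3)

  s5 <- graph_star(5)
  expect_equal(clustering(s5)$nodal_cc, rep(0, 6))
  expect_equal(betweenness(s5)$betweenness[1], choose(5, 2))
  expect_equal(local_efficiency(s5)$nodal_local_efficiency[1], 0)

  e5 <- matrix(0L, 5, 5)
  expect_equal(nodal_degree(e5)$degree, rep(0, 5))
  lp <- characteristic_path_length(shortest_paths(e5))
  expect_true(is.na(lp$lp))
  expect_true(lp$disconnected)
})

test_that("disconnected components yield infinite cross distances", {
  a <- matrix(0L, 4, 4)
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1L
  d <- shortest_paths(a)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  expect_equal(characteristic_path_length(d)$inf_frac, 8 / 12)
})

test_that("K4 minus one edge matches triangle-enumeration clustering", {
  a <- graph_complete(4)
  a[1, 2] <- a[2, 1] <- 0L
  expect_equal(clustering(a)$nodal_cc, oracle_clustering(a))
  # hand enumeration: nodes 1,2 keep a closed pair; 3,4 lose one of three links
  expect_equal(clustering(a)$nodal_cc, c(1, 1, 2 / 3, 2 / 3))
})

test_that("distances match a Floyd-Warshall oracle on random graphs", {
  set.seed(42)
  for (rep in 1:200) {
    a <- random_adjacency(7, runif(1, 0.1, 0.6))
    expect_identical(shortest_paths(a), oracle_floyd_warshall(a))
  }
})

test_that("all metrics match igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:30) {
    a <- random_adjacency(10, runif(1, 0.15, 0.7))
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    m <- graph_metrics(a)
    expect_equal(m$degree, igraph::degree(g), ignore_attr = TRUE)
    expect_equal(m$betweenness, igraph::betweenness(g), ignore_attr = TRUE,
                 tolerance = 1e-10)
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(m$nodal_cc, ifelse(is.nan(cc), 0, cc), tolerance = 1e-10)
    expect_equal(m$eglob, igraph::global_efficiency(g), tolerance = 1e-10)
  }
})

test_that("nodal metrics are permutation-equivariant", {
  set.seed(8)
  a <- random_adjacency(12, 0.3)
  m <- graph_metrics(a)
  for (rep in 1:20) {
    p <- sample(12)
    mp <- graph_metrics(a[p, p])
    expect_equal(mp$degree, m$degree[p])
    expect_equal(mp$betweenness, m$betweenness[p], tolerance = 1e-10)
    expect_equal(mp$nodal_cc, m$nodal_cc[p], tolerance = 1e-10)
    expect_equal(mp$nodal_efficiency, m$nodal_efficiency[p], tolerance = 1e-10)
    expect_equal(mp$eglob, m$eglob, tolerance = 1e-10)
    expect_equal(mp$cp, m$cp, tolerance = 1e-10)
  }
})

test_that("metric ranges respect their normalization bounds", {
  set.seed(9)
  for (rep in 1:50) {
    a <- random_adjacency(9, runif(1, 0.05, 0.9))
    m <- graph_metrics(a)
    expect_true(all(m$nodal_cc >= 0 & m$nodal_cc <= 1))
    expect_true(all(m$nodal_efficiency >= 0 & m$nodal_efficiency <= 1))
    expect_true(all(m$nodal_local_efficiency >= 0 & m$nodal_local_efficiency <= 1))
    expect_true(all(m$betweenness[m$degree <= 1] == 0))
    expect_true(m$average_degree >= 0 && m$average_degree <= 8)
  }
})

test_that("rewiring preserves the degree sequence and is seeded", {
  set.seed(10)
  for (rep in 1:100) {
    a <- random_adjacency(10, runif(1, 0.2, 0.6))
    if (sum(a) / 2 < 2) next
    b <- random_rewire(a)
    expect_equal(rowSums(b), rowSums(a))
    expect_equal(diag(b), rep(0L, 10), ignore_attr = TRUE)
    expect_true(all(b %in% c(0L, 1L)))
  }
  a <- random_adjacency(10, 0.4)
  set.seed(123); b1 <- random_rewire(a)
  set.seed(123); b2 <- random_rewire(a)
  expect_identical(b1, b2)
})

test_that("a triangle admits no degree-preserving swap", {
  tri <- graph_complete(3)
  expect_warning(out <- random_rewire(tri, 50), "no valid")
  expect_identical(unname(out == 1L), unname(tri == 1L))
  expect_warning(random_rewire(matrix(0L, 3, 3)), "fewer than 2")
})

test_that("small-world normalization against itself is exactly 1", {
  set.seed(11)
  a <- random_adjacency(15, 0.3)
  sw <- small_world(a, n_random = 5, n_swaps = 0)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$gamma, 1)
})

test_that("Erdos-Renyi graphs have gamma and lambda near 1", {
  set.seed(12)
  a <- random_adjacency(60, 0.15)
  sw <- small_world(a, n_random = 30)
  expect_lt(abs(sw$gamma - 1), max(3 * sw$cp_rand_sd / sw$cp_rand_mean, 0.15))
  expect_lt(abs(sw$lambda - 1), max(3 * sw$lp_rand_sd / sw$lp_rand_mean, 0.1))
})

test_that("a Watts-Strogatz ring is small-world (sigma > 1)", {
  set.seed(13)
  a <- ws_ring(60, 6, 0.1)
  sw <- small_world(a, n_random = 30)
  expect_gt(sw$sigma, 1)
})

test_that("ensemble AUC aggregation follows the trapezoidal rule", {
  ch <- generate_worked_fixture()
  nets <- build_individual_networks(ch$suvr, ch$demographics$group, "CN")
  ens <- binarize_ensemble(nets$networks[[5]])
  mt <- metrics_over_ensemble(ens, small_world = FALSE)
  grid <- mt$sparsity_grid
  # closed-form check against the definition on the actual metric values
  y <- mt$global$eglob
  expect_equal(mt$auc_global[["eglob"]],
               sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2))
  # constant metric integrates to value times grid width
  const <- rep(0.4, 31)
  expect_equal(sum(diff(grid) * (head(const, -1) + tail(const, -1)) / 2),
               0.4 * (0.35 - 0.05))
  # average degree is non-decreasing along the nested grid
  expect_true(all(diff(mt$global$average_degree) >= 0))
  expect_true(all(diff(mt$global$eglob) >= -1e-12))
})

test_that("a linear metric integrates to the trapezoid closed form", {
  grid <- default_sparsity_grid()
  y <- 2 * grid + 0.1
  a <- grid[1]; b <- grid[length(grid)]
  closed <- (b - a) * (2 * (a + b) / 2 + 0.1)
  expect_equal(sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2), closed)
})
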