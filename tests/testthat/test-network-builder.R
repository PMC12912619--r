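test_that("reference network equals hand-computed Pearson correlations", {
  # 5-subject x 3-ROI toy table, textbook formula oracle
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6), c = c(5, 3, 4, 1, 2))
  ren <- build_reference_network(x)
  pearson <- function(u, v) {
    num <- sum((u - mean(u)) * (v - mean(v)))
    num / sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(ren$matrix[i, j], pearson(x[, i], x[, j]), tolerance = 1e-12)
  expect_equal(ren$n_reference, 5L)
})

test_that("perfect and inverted copies give correlations +1 and -1", {
  x <- cbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5), c = -c(1, 3, 2, 5) + 10)
  ren <- build_reference_network(x)
  expect_equal(ren$matrix["a", "b"], 1)
  expect_equal(ren$matrix["a", "c"], -1)
})

test_that("zero-variance ROIs are named in the error", {
  x <- cbind(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(build_reference_network(x), "flat")
  expect_error(build_reference_network(x[1:2, ]), "at least 3")
})

test_that("perturbed network equals direct recomputation", {
  set.seed(3)
  x <- matrix(rnorm(60, 1, 0.2), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  row <- c(a = 1.1, b = 0.9, c = 1.0)
  cdn <- build_perturbed_network(x, row)
  expect_equal(cdn$matrix, cor(rbind(x, row)), tolerance = 1e-12)
  # duplicating an existing subject equals recomputing with the duplication
  cdn2 <- build_perturbed_network(x, x[7, ])
  expect_equal(cdn2$matrix, cor(rbind(x, x[7, ])), tolerance = 1e-12)
  # name-matched rows are reordered
  cdn3 <- build_perturbed_network(x, row[c("c", "a", "b")])
  expect_equal(cdn3$matrix, cdn$matrix)
  expect_error(build_perturbed_network(x, c(1, 2)), "2 values")
})

test_that("appending the control mean moves correlations less than the leverage bound", {
  set.seed(4)
  x <- matrix(rnorm(100, 1, 0.1), 25, 4)
  colnames(x) <- paste0("r", 1:4)
  cdn <- build_perturbed_network(x, colMeans(x))
  ren <- build_reference_network(x)
  # oracle: direct recomputation; a mean-valued subject has minimal leverage
  delta <- abs(cdn$matrix - ren$matrix)
  expect_lt(max(delta), 0.05)
  expect_equal(cdn$matrix, cor(rbind(x, colMeans(x))), tolerance = 1e-12)
})

test_that("degenerate perfectly-correlated input never leaks NaN", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(build_perturbed_network(x, c(a = 2.5, b = 2.5)) -> cdn, NA)
  expect_false(anyNA(cdn$matrix))
})

test_that("perturbation Z-score follows the published formula", {
  ren <- structure(list(matrix = matrix(c(1, 0.59, 0.59, 1), 2,
                                        dimnames = list(c("a", "b"), c("a", "b"))),
                        roi_names = c("a", "b"), n_reference = 172L),
                   class = "reference_network")
  cdn <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = dimnames(ren$matrix))
  net <- perturbation_zscore(ren, cdn)
  # independent one-line oracle for the spot value
  oracle <- (0.6 - 0.59) / ((1 - 0.6^2) / (172 - 1))
  expect_equal(round(net$z_matrix["a", "b"], 4), 2.6719)
  expect_equal(net$z_matrix["a", "b"], oracle, tolerance = 1e-12)
  # zero perturbation gives exactly zero
  net0 <- perturbation_zscore(ren, ren$matrix)
  expect_true(all(net0$z_matrix == 0))
  # sqrt variant available for sensitivity analysis
  nets <- perturbation_zscore(ren, cdn, denominator = "sqrt")
  expect_equal(nets$z_matrix["a", "b"], (0.6 - 0.59) / sqrt((1 - 0.36) / 171),
               tolerance = 1e-12)
})

test_that("Z sign equals perturbation sign and the diagonal is zero", {
  set.seed(5)
  x <- matrix(rnorm(200, 1, 0.15), 20, 10)
  colnames(x) <- paste0("r", 1:10)
  ren <- build_reference_network(x)
  for (k in 1:5) {
    row <- rnorm(10, 1, 0.15)
    net <- perturbation_zscore(ren, build_perturbed_network(x, row))
    expect_equal(sign(net$z_matrix), sign(net$delta))
    expect_equal(diag(net$z_matrix), rep(0, 10), ignore_attr = TRUE)
    expect_equal(net$z_matrix, t(net$z_matrix))
    expect_true(all(is.finite(net$z_matrix)))
  }
})

test_that("saturated edges are clipped with a warning, not NaN", {
  ren <- structure(list(matrix = matrix(c(1, 0.5, 0.5, 1), 2),
                        roi_names = c("a", "b"), n_reference = 10L),
                   class = "reference_network")
  cdn <- matrix(c(1, 1, 1, 1), 2)
  expect_warning(net <- perturbation_zscore(ren, cdn), "saturated")
  expect_true(all(is.finite(net$z_matrix)))
})

test_that("Fisher transform is arctanh with domain guards", {
  m <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  f <- fisher_transform(m)
  expect_equal(f[1, 2], 0.5493, tolerance = 5e-5)     # atanh oracle, 4 d.p.
  expect_equal(f[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(f[1, 3], 0)
  expect_equal(diag(f), rep(0, 3))
  expect_equal(fisher_transform(-m), -f)              # odd function
  expect_error(fisher_transform(matrix(c(1, 2, 2, 1), 2)), "outside")
  # Z-scored individual networks are a domain mismatch
  ren <- build_reference_network(matrix(rnorm(30), 10, 3,
                                        dimnames = list(NULL, c("a", "b", "c"))))
  net <- perturbation_zscore(ren, build_perturbed_network(
    matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))[, ], rnorm(3)))
  expect_error(fisher_transform(net), "not Z-scored|Z-scored")
})

test_that("binarization keeps floor(s*M) strongest positive edges, nested", {
  set.seed(6)
  R <- 26
  w <- matrix(0, R, R)
  w[upper.tri(w)] <- rnorm(R * (R - 1) / 2, 0.5, 1)  # plenty of positive weights
  w <- w + t(w)
  ens <- binarize_ensemble(w, default_sparsity_grid())
  expect_length(ens$adjacency, 31L)
  M <- R * (R - 1) / 2
  for (k in seq_along(ens$sparsity_grid)) {
    expected <- min(floor(ens$sparsity_grid[k] * M), sum(w[upper.tri(w)] > 0))
    expect_equal(sum(ens$adjacency[[k]]) / 2, expected)
    expect_equal(diag(ens$adjacency[[k]]), rep(0L, R))
  }
  expect_equal(sum(ens$adjacency[[which(ens$sparsity_grid == 0.10)]]) / 2, 32)
  # nesting: edges at smaller s are a subset of edges at larger s
  for (k in 2:31)
    expect_true(all(ens$adjacency[[k]][ens$adjacency[[k - 1]] == 1] == 1))
})

test_that("all-negative weights give empty graphs with a warning", {
  w <- matrix(-abs(rnorm(25)), 5, 5); w <- (w + t(w)) / 2; diag(w) <- 0
  expect_warning(ens <- binarize_ensemble(w, c(0.1, 0.3)), "no positive")
  expect_true(all(vapply(ens$adjacency, sum, numeric(1)) == 0))
})

test_that("binarization tie-breaking and grid validation are deterministic", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  w <- w + t(w)
  e1 <- binarize_ensemble(w, c(0.34))   # floor(0.34 * 6) = 2 edges
  e2 <- binarize_ensemble(w, c(0.34))
  expect_identical(e1$adjacency, e2$adjacency)
  # ties resolved by (row, column) lexicographic order: (1,2) then (1,3)
  expect_equal(which(e1$adjacency[[1]][upper.tri(e1$adjacency[[1]])] == 1L), c(1L, 2L))
  expect_error(binarize_ensemble(w, c(0, 0.2)), "\\(0, 1\\]")
  expect_error(binarize_ensemble(w, c(0.3, 0.2)), "increasing")
})

test_that("individual networks for a cohort align with per-subject construction", {
  ch <- generate_worked_fixture()
  nets <- build_individual_networks(ch$suvr, ch$demographics$group, "CN")
  expect_length(nets$networks, nrow(ch$suvr$values))
  cn_idx <- which(ch$demographics$group == "CN")
  refmat <- ch$suvr$values[cn_idx, ]
  s <- 30  # a non-reference subject
  manual <- perturbation_zscore(
    build_reference_network(refmat),
    build_perturbed_network(refmat, ch$suvr$values[s, ]))
  expect_equal(nets$networks[[s]]$z_matrix, manual$z_matrix, tolerance = 1e-12)
})
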