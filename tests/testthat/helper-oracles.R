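# Brute-force graph oracles, independent of the package's implementations:
# Floyd-Warshall distances, path-enumeration betweenness, direct triangle
# counting, and efficiency definitions evaluated from the distance matrix.

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all shortest paths between s and t by exhaustive simple-path enumeration
oracle_all_shortest_paths <- function(adj, s, t, dmat) {
  if (!is.finite(dmat[s, t]) || s == t) return(list())
  target_len <- dmat[s, t]
  paths <- list()
  recurse <- function(v, path) {
    if (length(path) - 1 > target_len) return()
    if (v == t) {
      if (length(path) - 1 == target_len) paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(adj[v, ] == 1))
      if (!(w %in% path)) recurse(w, c(path, w))
  }
  recurse(s, s)
  paths
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dmat <- oracle_floyd_warshall(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_shortest_paths(adj, s, t, dmat)
    if (length(paths) == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / length(paths)
    }
  }
  bc
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- sum(adj[nb, nb]) / 2
    cc[v] <- 2 * tri / (k * (k - 1))
  }
  cc
}

oracle_global_efficiency <- function(dmat) {
  n <- nrow(dmat)
  if (n < 2) return(0)
  inv <- 1 / dmat
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  le <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    sub <- adj[nb, nb, drop = FALSE]
    le[v] <- oracle_global_efficiency(oracle_floyd_warshall(sub))
  }
  le
}

oracle_lp <- function(dmat) {
  off <- dmat[row(dmat) != col(dmat)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) NA_real_ else mean(fin)
}

# named small graphs
graph_path3 <- function() {
  a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L; a
}
graph_complete <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}
graph_star <- function(n) { # hub = node 1, n leaves
  a <- matrix(0L, n + 1, n + 1); a[1, 2:(n + 1)] <- a[2:(n + 1), 1] <- 1L; a
}

random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Watts-Strogatz ring: n nodes, each connected to k/2 neighbors either side,
# each edge rewired with probability p (simple graph preserved)
ws_ring <- function(n, k, p) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i + s - 1) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i + s - 1) %% n) + 1
    if (a[i, j] == 1L && runif(1) < p) {
      cand <- which(a[i, ] == 0L & seq_len(n) != i)
      if (length(cand) > 0) {
        newj <- cand[sample.int(length(cand), 1)]
        a[i, j] <- a[j, i] <- 0L
        a[i, newj] <- a[newj, i] <- 1L
      }
    }
  }
  a
}
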