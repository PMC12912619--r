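# Graph-theoretic properties of binarized deposition networks.
#
# Ten properties are computed per binary graph: global — average degree,
# mean clustering coefficient Cp, characteristic path length Lp, global
# efficiency Eglob, local efficiency Eloc, and the small-world triple
# (gamma = Cp/Cp_rand, lambda = Lp/Lp_rand, sigma = gamma/lambda) normalized
# against degree-preserving Maslov-Sneppen randomizations; nodal — degree
# centrality, betweenness centrality, nodal clustering, nodal efficiency,
# nodal local efficiency. Disconnected graphs: Lp is the mean over connected
# ordered pairs with the infinite-pair fraction reported; the efficiency
# metrics are the disconnection-robust quantities.

check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop_("adjacency must be square")
  if (max(abs(adj - t(adj))) > 0) stop_("adjacency must be symmetric")
  if (!all(adj %in% c(0, 1))) stop_("adjacency must be 0/1")
  if (any(diag(adj) != 0)) stop_("adjacency must have a zero diagonal")
  storage.mode(adj) <- "integer"
  adj
}

#' Nodal degree and average degree
#' @param adj Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return List with `degree` (per node) and `average_degree`.
#' @export
nodal_degree <- function(adj) {
  adj <- check_adjacency(adj)
  d <- rowSums(adj)
  list(degree = d, average_degree = mean(d))
}

#' Nodal clustering coefficients and their mean Cp
#'
#' Nodal CC is 2 * triangles(v) / (deg(v) * (deg(v) - 1)), zero for degree
#' below 2; Cp averages over all nodes.
#' @inheritParams nodal_degree
#' @return List with `nodal_cc` and `cp`.
#' @export
clustering <- function(adj) {
  adj <- check_adjacency(adj)
  m <- graph_metrics_cpp(adj)
  list(nodal_cc = m$nodal_cc, cp = m$cp)
}

#' All-pairs hop distances (breadth-first search)
#' @inheritParams nodal_degree
#' @return Numeric matrix of distances, `Inf` for unreachable pairs.
#' @export
shortest_paths <- function(adj) {
  bfs_distances_cpp(check_adjacency(adj))
}

#' Characteristic path length
#'
#' Mean of finite off-diagonal distances over connected ordered pairs.
#' @param distances Distance matrix from [shortest_paths()].
#' @return List with `lp` (NA when no pair is connected), `disconnected`
#'   flag, and `inf_frac`, the fraction of infinite off-diagonal pairs.
#' @export
characteristic_path_length <- function(distances) {
  off <- distances[row(distances) != col(distances)]
  fin <- off[is.finite(off)]
  list(lp = if (length(fin) > 0L) mean(fin) else NA_real_,
       disconnected = any(!is.finite(off)),
       inf_frac = mean(!is.finite(off)))
}

#' Global efficiency
#'
#' Mean over ordered pairs of inverse distance (zero for unreachable pairs),
#' plus nodal efficiency (per-node mean inverse distance to all others).
#' @param distances Distance matrix from [shortest_paths()].
#' @return List with `eglob` and `nodal_efficiency`.
#' @export
global_efficiency <- function(distances) {
  n <- nrow(distances)
  inv <- 1 / distances
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  list(eglob = sum(inv) / (n * (n - 1)), nodal_efficiency = rowSums(inv) / (n - 1))
}

#' Local efficiency
#'
#' Nodal local efficiency of v is the global efficiency of the subgraph
#' induced by v's neighbors (zero for degree below 2); Eloc is its mean.
#' @inheritParams nodal_degree
#' @return List with `eloc` and `nodal_local_efficiency`.
#' @export
local_efficiency <- function(adj) {
  adj <- check_adjacency(adj)
  m <- graph_metrics_cpp(adj)
  list(eloc = m$eloc, nodal_local_efficiency = m$nodal_local_efficiency)
}

#' Betweenness centrality (Brandes accumulation)
#'
#' Fractional shortest-path counts over unordered pairs (s, t), s != t != v.
#' @inheritParams nodal_degree
#' @return List with `betweenness` (raw), `betweenness_normalized`
#'   (divided by (R-1)(R-2)/2) and `average_bc` (raw scale).
#' @export
betweenness <- function(adj) {
  adj <- check_adjacency(adj)
  bc <- betweenness_cpp(adj)
  n <- nrow(adj)
  norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  list(betweenness = bc, betweenness_normalized = bc / norm, average_bc = mean(bc))
}

#' Degree-preserving randomization (Maslov-Sneppen double-edge swaps)
#'
#' Repeatedly swaps endpoint pairs of two edges, rejecting swaps that would
#' create self-loops or multi-edges, so the degree sequence is preserved
#' exactly. Driven by R's RNG: results are reproducible under `set.seed()`.
#'
#' @inheritParams nodal_degree
#' @param n_swaps Number of successful swaps to attempt (default 10x edges).
#' @return Randomized adjacency matrix; attribute `swaps_done` counts the
#'   swaps actually performed (a warning is emitted when none succeeded).
#' @export
random_rewire <- function(adj, n_swaps = NULL) {
  adj <- check_adjacency(adj)
  m <- sum(adj) / 2
  if (m < 2) { warn_("fewer than 2 edges; returning input unchanged"); return(adj) }
  if (is.null(n_swaps)) n_swaps <- ceiling(10 * m)
  out <- rewire_cpp(adj, as.integer(n_swaps))
  if (attr(out, "swaps_done") == 0L && n_swaps > 0L)
    warn_("no valid degree-preserving swap exists; returning input unchanged")
  dimnames(out) <- dimnames(adj)
  out
}

#' Small-world metrics against a randomized ensemble
#'
#' lambda = Lp / mean(Lp_rand), gamma = Cp / mean(Cp_rand),
#' sigma = gamma / lambda, averaging over `n_random` degree-preserving
#' rewired graphs. With `n_swaps = 0` the ensemble is the graph itself and
#' all three equal 1 exactly.
#'
#' @inheritParams random_rewire
#' @param n_random Ensemble size.
#' @return List with `sigma`, `lambda`, `gamma`, ensemble means and SDs.
#' @export
small_world <- function(adj, n_random = 100L, n_swaps = NULL) {
  adj <- check_adjacency(adj)
  base <- graph_metrics_cpp(adj)
  lp_r <- cp_r <- numeric(n_random)
  for (r in seq_len(n_random)) {
    radj <- if (is.null(n_swaps) || n_swaps > 0) random_rewire(adj, n_swaps) else adj
    m <- graph_metrics_cpp(radj)
    lp_r[r] <- m$lp
    cp_r[r] <- m$cp
  }
  lp_rand <- mean(lp_r, na.rm = TRUE)
  cp_rand <- mean(cp_r, na.rm = TRUE)
  lambda <- if (is.finite(base$lp) && is.finite(lp_rand) && lp_rand > 0) base$lp / lp_rand else NA_real_
  gamma <- if (is.finite(cp_rand) && cp_rand > 0) base$cp / cp_rand else NA_real_
  if (!is.finite(gamma)) warn_("randomized clustering is zero; gamma undefined")
  list(sigma = if (is.finite(lambda) && is.finite(gamma) && lambda > 0) gamma / lambda else NA_real_,
       lambda = lambda, gamma = gamma,
       lp_rand_mean = lp_rand, lp_rand_sd = sd(lp_r, na.rm = TRUE),
       cp_rand_mean = cp_rand, cp_rand_sd = sd(cp_r, na.rm = TRUE))
}

#' All ten properties of one binary graph
#'
#' Convenience wrapper returning every global and nodal metric for a single
#' adjacency matrix (small-world metrics excluded; see [small_world()]).
#' @inheritParams nodal_degree
#' @return Named list of global scalars and nodal vectors.
#' @export
graph_metrics <- function(adj) {
  adj <- check_adjacency(adj)
  graph_metrics_cpp(adj)
}

#' Metrics across a sparsity-grid ensemble
#'
#' Computes every global and nodal property at each threshold of a
#' [binarize_ensemble()] result and aggregates each metric across the grid
#' by the trapezoidal rule (thresholds where a metric is undefined are
#' excluded from that metric's AUC and counted in `n_undefined`).
#'
#' @param ensemble A `binary_graph_ensemble`.
#' @param small_world Normalize Cp and Lp against rewired ensembles to get
#'   sigma/lambda/gamma (the expensive part; TRUE by default).
#' @param n_random Randomized graphs per threshold for the normalization.
#' @param swap_factor Successful swaps per edge in each randomization.
#' @param nodal Compute the five nodal metric families.
#' @return Object of class `metric_table`: list with `global` (data.frame,
#'   one row per threshold), `nodal` (list of threshold x ROI matrices),
#'   `auc_global` (named vector), `auc_nodal` (list of per-ROI vectors),
#'   `sparsity_grid`, `subject_id`.
#' @export
metrics_over_ensemble <- function(ensemble, small_world = TRUE, n_random = 100L,
                                  swap_factor = 10, nodal = TRUE) {
  stopifnot(inherits(ensemble, "binary_graph_ensemble"))
  res <- ensemble_metrics_cpp(ensemble$n_nodes,
                              ensemble$edge_order[, "i"] - 1L,
                              ensemble$edge_order[, "j"] - 1L,
                              as.integer(ensemble$edge_counts),
                              nodal, small_world,
                              as.integer(n_random), swap_factor)
  glob <- as.data.frame(res$global)
  glob <- data.frame(sparsity = ensemble$sparsity_grid, glob)
  grid <- ensemble$sparsity_grid
  gnames <- c("average_degree", "cp", "lp", "eglob", "eloc", "avg_bc",
              "sigma", "lambda", "gamma")
  auc_global <- vapply(gnames, function(nm) trapz(grid, glob[[nm]]), numeric(1L))
  n_undef <- vapply(gnames, function(nm) sum(!is.finite(glob[[nm]])), integer(1L))
  out <- list(global = glob, auc_global = auc_global, n_undefined = n_undef,
              sparsity_grid = grid, subject_id = ensemble$subject_id,
              roi_names = ensemble$roi_names)
  if (nodal) {
    nodal_mats <- res$nodal
    nodal_mats <- lapply(nodal_mats, function(m) {
      colnames(m) <- ensemble$roi_names %||% paste0("V", seq_len(ncol(m)))
      m
    })
    out$nodal <- nodal_mats
    out$auc_nodal <- lapply(nodal_mats, function(m)
      apply(m, 2L, function(y) trapz(grid, y)))
  }
  structure(out, class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("metric table for subject %s: %d thresholds\n",
              x$subject_id, length(x$sparsity_grid)))
  print(round(x$auc_global, 4))
  invisible(x)
}

#' Cohort-level nodal and global metric AUC tables
#'
#' Runs the full individual-network and metric pipeline for every subject:
#' reference network from the reference group, add-one-subject Z network,
#' binarization over the grid, metrics, and trapezoidal AUC aggregation.
#' Returns compact subject-level feature tables for statistics and
#' classification.
#'
#' @param suvr A [suvr_matrix()] for all subjects.
#' @param groups Group label per subject.
#' @param reference_group Reference group label.
#' @param grid Sparsity grid.
#' @param small_world,n_random,swap_factor See [metrics_over_ensemble()].
#' @param seed Seed governing the randomized-graph ensembles.
#' @return List with `global_auc` (subjects x global metrics data.frame),
#'   `nodal_auc` (list of subjects x ROI matrices per nodal metric),
#'   `strength` (subjects x ROI nodal strength of the unbinarized Z
#'   network), `groups`, `reference`.
#' @export
cohort_network_features <- function(suvr, groups, reference_group = "CN",
                                    grid = default_sparsity_grid(),
                                    small_world = TRUE, n_random = 100L,
                                    swap_factor = 10, seed = 1L) {
  nets <- build_individual_networks(suvr, groups, reference_group)
  n <- length(nets$networks)
  R <- length(nets$reference$roi_names)
  roi <- nets$reference$roi_names
  gnames <- c("average_degree", "cp", "lp", "eglob", "eloc", "avg_bc",
              "sigma", "lambda", "gamma")
  nnames <- c("degree", "nodal_cc", "betweenness", "nodal_efficiency",
              "nodal_local_efficiency")
  global_auc <- matrix(NA_real_, n, length(gnames), dimnames = list(names(nets$networks), gnames))
  nodal_auc <- lapply(setNames(nnames, nnames), function(x)
    matrix(NA_real_, n, R, dimnames = list(names(nets$networks), roi)))
  strength <- matrix(NA_real_, n, R, dimnames = list(names(nets$networks), roi))
  with_seed(derive_seed(seed, "metrics"), {
    for (s in seq_len(n)) {
      net <- nets$networks[[s]]
      strength[s, ] <- nodal_strength(net)
      ens <- binarize_ensemble(net, grid)
      mt <- metrics_over_ensemble(ens, small_world = small_world,
                                  n_random = n_random, swap_factor = swap_factor)
      global_auc[s, ] <- mt$auc_global[gnames]
      for (nm in nnames) nodal_auc[[nm]][s, ] <- mt$auc_nodal[[nm]]
    }
  })
  list(global_auc = as.data.frame(global_auc), nodal_auc = nodal_auc,
       strength = strength, groups = as.character(groups),
       reference = nets$reference)
}

#' Write a metric table as tidy CSV
#'
#' One row per (threshold, metric, node-or-global).
#' @param mt A `metric_table`.
#' @param path Output path.
#' @export
write_metric_table <- function(mt, path) {
  rows <- list()
  for (nm in setdiff(names(mt$global), "sparsity")) {
    rows[[nm]] <- data.frame(subject_id = mt$subject_id,
                             sparsity = mt$global$sparsity, metric = nm,
                             node = "global", value = mt$global[[nm]],
                             stringsAsFactors = FALSE)
  }
  if (!is.null(mt$nodal)) {
    for (nm in names(mt$nodal)) {
      m <- mt$nodal[[nm]]
      rows[[paste0("n_", nm)]] <- data.frame(
        subject_id = mt$subject_id,
        sparsity = rep(mt$global$sparsity, ncol(m)),
        metric = nm, node = rep(colnames(m), each = nrow(m)),
        value = as.vector(m), stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
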