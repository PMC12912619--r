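# Individual-specific deposition network construction.
#
# The reference network REN_n is the ROI x ROI Pearson correlation of SUVRs
# across the n control subjects. Adding one test subject gives the perturbed
# network CDN_{n+1}; the individual-specific network is the edge-wise
# Z-score of the perturbation delta = CDN - REN,
#
#     z = delta / ((1 - CDN^2) / (n - 1)),
#
# with n the reference-group size. The denominator carries no square root,
# matching the perturbation statistic as published for individual
# differential structural covariance networks; a square-root variant is
# available for sensitivity analysis via `denominator = "sqrt"`.

#' Build the control reference network
#'
#' @param suvr_cn A [suvr_matrix()] restricted to the reference (control)
#'   subjects, or a plain numeric matrix (subjects x ROIs).
#' @return Object of class `reference_network` with elements `matrix`
#'   (ROI x ROI Pearson correlations), `roi_names`, `n_reference`.
#' @export
build_reference_network <- function(suvr_cn) {
  x <- if (inherits(suvr_cn, "suvr_matrix")) suvr_cn$values else as.matrix(suvr_cn)
  if (nrow(x) < 3L) stop_("need at least 3 reference subjects, got %d", nrow(x))
  v <- apply(x, 2L, stats::var)
  if (any(v <= 0))
    stop_("zero-variance ROI(s) in reference group: %s",
          paste(colnames(x)[v <= 0], collapse = ", "))
  m <- cor(x)
  structure(list(matrix = m, roi_names = colnames(x), n_reference = nrow(x)),
            class = "reference_network")
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("reference network: %d ROIs, n = %d reference subjects\n",
              length(x$roi_names), x$n_reference))
  invisible(x)
}

#' Build the add-one-subject perturbed network
#'
#' Recomputes the ROI correlation matrix over the n reference subjects plus
#' one added subject.
#'
#' @param suvr_cn Reference-group SUVR (as in [build_reference_network()]).
#' @param subject_row Numeric vector of the added subject's ROI SUVRs, in
#'   the same ROI order, or a named vector matched by name.
#' @param subject_id Optional identifier carried on the result.
#' @return Object of class `perturbed_network`.
#' @export
build_perturbed_network <- function(suvr_cn, subject_row, subject_id = NA_character_) {
  x <- if (inherits(suvr_cn, "suvr_matrix")) suvr_cn$values else as.matrix(suvr_cn)
  if (!is.null(names(subject_row)) && !is.null(colnames(x))) {
    if (!setequal(names(subject_row), colnames(x)))
      stop_("subject ROIs do not match the reference ROIs")
    subject_row <- subject_row[colnames(x)]
  }
  if (length(subject_row) != ncol(x))
    stop_("subject row has %d values, reference has %d ROIs",
          length(subject_row), ncol(x))
  m <- cor(rbind(x, subject_row))
  if (anyNA(m)) stop_("zero-variance ROI after adding the subject")
  structure(list(matrix = m, added_subject_id = subject_id,
                 n_total = nrow(x) + 1L),
            class = "perturbed_network")
}

#' Edge-wise perturbation Z-score
#'
#' Converts the perturbation delta = CDN - REN into the individual-specific
#' network. Off-diagonal entries with |CDN| at 1 are clipped to
#' 1 - 1e-12 before the denominator (with a warning) so the output stays
#' finite; the diagonal is forced to zero.
#'
#' @param ren A `reference_network`.
#' @param cdn A `perturbed_network` (or bare correlation matrix).
#' @param denominator `"plain"` (default): (1 - CDN^2)/(n - 1);
#'   `"sqrt"`: sqrt of that quantity.
#' @return Object of class `individual_network` with `delta`, `z_matrix`,
#'   `subject_id`, `n_reference`.
#' @export
perturbation_zscore <- function(ren, cdn, denominator = c("plain", "sqrt")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(ren, "reference_network"))
  cdnm <- if (inherits(cdn, "perturbed_network")) cdn$matrix else as.matrix(cdn)
  if (!identical(dim(cdnm), dim(ren$matrix)))
    stop_("reference and perturbed networks are not conformable")
  n <- ren$n_reference
  if (n < 3L) stop_("reference size must be >= 3")
  delta <- cdnm - ren$matrix
  diag(delta) <- 0
  c2 <- cdnm
  sat <- abs(c2) >= 1 - 1e-12
  diag(sat) <- FALSE
  if (any(sat)) {
    warn_("%d off-diagonal edge(s) saturated at |correlation| = 1; clipped", sum(sat) / 2)
    c2[sat] <- sign(c2[sat]) * (1 - 1e-12)
  }
  den <- (1 - c2^2) / (n - 1)
  if (denominator == "sqrt") den <- sqrt(den)
  z <- delta / den
  diag(z) <- 0
  sid <- if (inherits(cdn, "perturbed_network")) cdn$added_subject_id else NA_character_
  structure(list(subject_id = sid, delta = delta, z_matrix = z,
                 roi_names = ren$roi_names, n_reference = n,
                 fisher_applied = FALSE, denominator = denominator),
            class = "individual_network")
}

#' @export
print.individual_network <- function(x, ...) {
  cat(sprintf("individual network for subject %s: %d ROIs (reference n = %d)\n",
              x$subject_id, length(x$roi_names), x$n_reference))
  invisible(x)
}

#' Fisher's Z (arctanh) transform of a correlation matrix
#'
#' Applies the variance-stabilizing arctanh entry-wise. Only defined for
#' correlation-valued matrices: entries at +/-1 are clipped by `eps` with a
#' warning, and matrices flagged as already Z-scored are rejected because
#' arctanh is undefined beyond [-1, 1].
#'
#' @param mat Correlation-valued symmetric matrix, or a
#'   `reference_network`/`perturbed_network`.
#' @param eps Clipping distance from +/-1.
#' @return Transformed matrix, symmetric with zero diagonal.
#' @export
fisher_transform <- function(mat, eps = 1e-7) {
  if (inherits(mat, "individual_network"))
    stop_("fisher_transform applies to correlation matrices, not Z-scored networks")
  m <- if (inherits(mat, c("reference_network", "perturbed_network"))) mat$matrix else as.matrix(mat)
  off <- m; diag(off) <- 0
  if (max(abs(off)) > 1) stop_("entries outside [-1, 1]: not a correlation matrix")
  clip <- abs(off) > 1 - eps & off != 0
  if (any(clip)) {
    warn_("%d entr%s at |r| ~ 1 clipped before arctanh", sum(clip),
          if (sum(clip) == 1L) "y" else "ies")
    off[clip] <- sign(off[clip]) * (1 - eps)
  }
  out <- atanh(off)
  diag(out) <- 0
  out
}

#' Binarize an individual network over a sparsity grid
#'
#' Negative and zero edge weights are discarded; at each sparsity level s
#' the strongest floor(s * M) positive edges are kept (M = R(R-1)/2 possible
#' edges), or all positive edges if fewer exist. Equal weights are broken by
#' (row, column) lexicographic order, so ensembles are deterministic, and
#' the retained edge sets are nested along the grid.
#'
#' @param net An `individual_network` (or bare symmetric weight matrix).
#' @param grid Strictly increasing sparsity thresholds in (0, 1]; the
#'   default 0.05..0.35 step 0.01 gives 31 levels.
#' @return Object of class `binary_graph_ensemble`: list with
#'   `sparsity_grid`, `adjacency` (list of 0/1 matrices), `edge_order`
#'   (matrix of ranked positive edges), `edge_counts`, `subject_id`.
#' @export
binarize_ensemble <- function(net, grid = default_sparsity_grid()) {
  if (any(grid <= 0) || any(grid > 1)) stop_("sparsity grid must lie in (0, 1]")
  if (is.unsorted(grid, strictly = TRUE)) stop_("sparsity grid must be strictly increasing")
  w <- if (inherits(net, "individual_network")) net$z_matrix else as.matrix(net)
  if (!is_symmetric(w, tol = 1e-8)) stop_("weight matrix must be symmetric")
  R <- nrow(w)
  M <- R * (R - 1L) / 2L
  ut <- which(upper.tri(w))
  wv <- w[ut]
  ui <- ((ut - 1L) %% R) + 1L
  uj <- ((ut - 1L) %/% R) + 1L
  pos <- which(wv > 0)
  if (length(pos) == 0L) warn_("no positive edge weights; all graphs are empty")
  ord <- pos[order(-wv[pos], ui[pos], uj[pos])]
  ri <- ui[ord]
  rj <- uj[ord]
  counts <- pmin(floor(grid * M), length(ord))
  adj <- vector("list", length(grid))
  A <- matrix(0L, R, R)
  placed <- 0L
  for (k in seq_along(grid)) {
    while (placed < counts[k]) {
      placed <- placed + 1L
      A[ri[placed], rj[placed]] <- 1L
      A[rj[placed], ri[placed]] <- 1L
    }
    adj[[k]] <- A
  }
  sid <- if (inherits(net, "individual_network")) net$subject_id else NA_character_
  structure(list(sparsity_grid = grid, adjacency = adj,
                 edge_order = cbind(i = ri, j = rj), edge_counts = counts,
                 n_nodes = R, subject_id = sid,
                 roi_names = if (inherits(net, "individual_network")) net$roi_names else colnames(w)),
            class = "binary_graph_ensemble")
}

#' @export
print.binary_graph_ensemble <- function(x, ...) {
  cat(sprintf("binary graph ensemble: %d nodes, %d thresholds (%.2f..%.2f), %d..%d edges\n",
              x$n_nodes, length(x$sparsity_grid), min(x$sparsity_grid),
              max(x$sparsity_grid), min(x$edge_counts), max(x$edge_counts)))
  invisible(x)
}

#' Default sparsity grid: 0.05 to 0.35, step 0.01
#' @export
default_sparsity_grid <- function() seq(0.05, 0.35, by = 0.01)

#' Individual networks for a whole cohort
#'
#' Builds the reference network from the reference group and the
#' add-one-subject Z network for every subject. Controls are added one by
#' one to the reference group like every other subject; for a subject who
#' is part of the reference, the default `reference_handling = "loo"`
#' scores them against the correlation network of the other n-1 controls
#' (leave-one-out), so that every subject perturbs a reference that does
#' not already contain them. The alternative `"duplicate"` adds the control
#' as an (n+1)-th copy on top of the full reference; that reading biases
#' control Z values toward the subject's own contribution and inflates
#' false positives in control-versus-patient comparisons, so it is not the
#' default.
#'
#' @param suvr A [suvr_matrix()] covering all subjects.
#' @param groups Group label per subject.
#' @param reference_group Label of the reference group (default "CN").
#' @param denominator Passed to [perturbation_zscore()].
#' @param reference_handling `"loo"` or `"duplicate"`, see above.
#' @return List with `reference` (the full-group `reference_network`) and
#'   `networks` (named list of `individual_network` objects, one per
#'   subject).
#' @export
build_individual_networks <- function(suvr, groups, reference_group = "CN",
                                      denominator = "plain",
                                      reference_handling = c("loo", "duplicate")) {
  stopifnot(inherits(suvr, "suvr_matrix"))
  reference_handling <- match.arg(reference_handling)
  groups <- as.character(groups)
  if (length(groups) != nrow(suvr$values))
    stop_("groups length != subject count")
  ref_idx <- which(groups == reference_group)
  if (length(ref_idx) < 4L)
    stop_("reference group '%s' has %d subjects; need >= 4",
          reference_group, length(ref_idx))
  refmat <- suvr$values[ref_idx, , drop = FALSE]
  ren <- build_reference_network(refmat)
  nets <- lapply(seq_len(nrow(suvr$values)), function(s) {
    in_ref <- s %in% ref_idx
    if (in_ref && reference_handling == "loo") {
      others <- refmat[ref_idx != s, , drop = FALSE]
      ren_s <- build_reference_network(others)
      cdn <- build_perturbed_network(others, suvr$values[s, ],
                                     subject_id = suvr$subject_ids[s])
      perturbation_zscore(ren_s, cdn, denominator = denominator)
    } else {
      cdn <- build_perturbed_network(refmat, suvr$values[s, ],
                                     subject_id = suvr$subject_ids[s])
      perturbation_zscore(ren, cdn, denominator = denominator)
    }
  })
  names(nets) <- suvr$subject_ids
  list(reference = ren, networks = nets)
}

#' Nodal strength of an individual network
#'
#' Mean Z over each region's incident edges (weighted-degree analog on the
#' unbinarized network). This is the most direct per-region readout of
#' injected edge-correlation shifts and the default statistic of the
#' recovery validation.
#'
#' @param net An `individual_network` (or symmetric weight matrix).
#' @return Named numeric vector, one value per region.
#' @export
nodal_strength <- function(net) {
  w <- if (inherits(net, "individual_network")) net$z_matrix else as.matrix(net)
  s <- rowSums(w) / (ncol(w) - 1L)
  names(s) <- if (inherits(net, "individual_network")) net$roi_names else colnames(w)
  s
}

#' Export a square matrix with ROI-name headers as CSV
#' @param mat Matrix or network object with a `matrix`/`z_matrix` element.
#' @param path Output path.
#' @export
write_network_csv <- function(mat, path) {
  m <- if (inherits(mat, "individual_network")) mat$z_matrix
       else if (inherits(mat, c("reference_network", "perturbed_network"))) mat$matrix
       else as.matrix(mat)
  write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
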