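# Synthetic SUVR cohort generator.
#
# Subjects are drawn from group-specific multivariate normal distributions
# on the regional-SUVR scale. The generative family is normal because the
# downstream networks are Pearson-correlation objects, which normality
# characterizes exactly. Group-level connectivity differences are injected
# as edge-wise shifts on the correlation scale followed by a nearest-PSD
# projection, so the injected quantity is exactly what the perturbation
# Z-score is built to detect.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Nearest positive semi-definite projection
#'
#' Eigenvalue clipping at `eps`: eigenvalues below `eps` are raised to it and
#' the matrix is re-symmetrized. Used after injecting correlation shifts.
#'
#' @param mat Symmetric matrix.
#' @param eps Eigenvalue floor.
#' @return Symmetric PSD matrix.
#' @export
nearest_psd <- function(mat, eps = 1e-8) {
  if (!is_symmetric(mat, tol = 1e-8)) stop_("matrix must be symmetric")
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= eps) return((mat + t(mat)) / 2)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Single-factor base covariance
#'
#' Builds a positive-definite ROI covariance from one latent factor: the
#' correlation between regions i and j is `loadings[i] * loadings[j]`, the
#' pattern produced when a global amyloid burden factor drives all regions.
#'
#' @param n_roi Number of regions.
#' @param loadings Factor loadings, recycled/interpolated to length `n_roi`.
#' @param sds Per-ROI standard deviations (recycled).
#' @return Covariance matrix.
#' @export
factor_covariance <- function(n_roi, loadings = seq(0.35, 0.8, length.out = n_roi),
                              sds = 0.10) {
  if (length(loadings) != n_roi) loadings <- seq(min(loadings), max(loadings), length.out = n_roi)
  if (any(abs(loadings) >= 1)) stop_("|loadings| must be < 1")
  sds <- rep_len(sds, n_roi)
  C <- outer(loadings, loadings)
  diag(C) <- 1
  outer(sds, sds) * C
}

#' Shift covariance entries on the correlation scale
#'
#' Converts to correlation, adds `delta` to the named edges, projects back to
#' the PSD cone (eigenvalue clipping), renormalizes the diagonal to 1 and
#' restores the original marginal variances. Shifts that push any entry out
#' of [-1, 1] are rejected.
#'
#' @param cov ROI x ROI covariance (or correlation) matrix.
#' @param edges Two-column matrix/data.frame of edge indices (or a vector of
#'   length 2 for a single edge). Indices are 1-based positions or ROI names
#'   matching `dimnames(cov)`.
#' @param delta Correlation shift, scalar or one value per edge.
#' @return Covariance matrix with the same diagonal as the input.
#' @export
inject_edge_perturbation <- function(cov, edges, delta) {
  if (is.vector(edges) && length(edges) == 2L) edges <- matrix(edges, ncol = 2L)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop_("edges must have two columns")
  if (is.character(edges)) {
    if (is.null(rownames(cov))) stop_("named edges require dimnames on cov")
    idx <- cbind(match(edges[, 1L], rownames(cov)), match(edges[, 2L], rownames(cov)))
    if (anyNA(idx)) stop_("unknown ROI name in edges")
    edges <- idx
  }
  storage.mode(edges) <- "integer"
  n <- nrow(cov)
  if (any(edges < 1L | edges > n)) stop_("edge index out of range")
  if (any(edges[, 1L] == edges[, 2L])) stop_("edges must be off-diagonal")
  delta <- rep_len(delta, nrow(edges))
  if (all(delta == 0)) return(cov)
  sds <- sqrt(diag(cov))
  C <- cov / outer(sds, sds)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    r <- C[i, j] + delta[k]
    if (abs(r) > 1)
      stop_("shift of %+.2f takes correlation (%d,%d) to %.2f, outside [-1, 1]",
            delta[k], i, j, r)
    C[i, j] <- C[j, i] <- r
  }
  C <- nearest_psd(C)
  d <- sqrt(diag(C))
  if (any(d <= 0)) stop_("perturbed matrix could not be projected to a valid correlation")
  C <- C / outer(d, d)
  outer(sds, sds) * C
}

group_levels <- c("CN", "EMCI", "LMCI", "AD")

# Baseline demographic distributions per diagnostic group: age mean/sd in
# years, male fraction, MMSE mean/sd.
default_demographics <- function() {
  data.frame(group = group_levels,
             age_mean = c(75.89, 72.99, 72.75, 74.41),
             age_sd = c(7.97, 7.04, 7.37, 8.40),
             male_frac = c(74 / 172, 81 / 159, 74 / 141, 58 / 140),
             mmse_mean = c(28.77, 27.8, 25.58, 21.45),
             mmse_sd = c(1.67, 4.26, 3.56, 4.26),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic SUVR cohort
#'
#' Collects and validates everything [generate_cohort()] needs: group sizes,
#' ROI names, per-group mean SUVR vectors, a base covariance, optional
#' group-specific edge-correlation perturbations, and demographic
#' distributions. Defaults reproduce the study conditions of a four-group
#' amyloid PET cohort: 26 cerebellar regions, group mean cerebellar SUVR
#' 0.55 (CN), 0.58 (EMCI), 0.60 (LMCI), 0.63 (AD), and a single-factor
#' covariance giving subject-level compartment-mean SD of about 0.06.
#'
#' @param n_per_group Named integer vector of subjects per group.
#' @param roi_names Character vector of ROI labels.
#' @param group_means Named list: per-group numeric vector of ROI mean SUVR.
#'   A scalar per group is expanded with a fixed ROI offset profile.
#' @param base_covariance PSD ROI x ROI covariance shared by all groups.
#' @param edge_perturbations NULL or data.frame with columns
#'   `group`, `roi_i`, `roi_j`, `delta` (correlation-scale shifts applied to
#'   that group's covariance).
#' @param noise_sd Residual independent noise SD added per ROI.
#' @param age_slope SUVR increase per year of age above 73 (default 0:
#'   demographics independent of SUVR).
#' @param demographics Per-group demographic distribution table; see
#'   the package source for the default layout.
#' @param compartment Compartment tag for all ROIs in the generated template.
#' @param seed Integer seed; identical specs and seeds give identical cohorts.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(CN = 172, EMCI = 159, LMCI = 141, AD = 140),
                           roi_names = template_labels(build_roi_template(), "cerebellar"),
                           group_means = list(CN = 0.55, EMCI = 0.58, LMCI = 0.60, AD = 0.63),
                           base_covariance = factor_covariance(length(roi_names)),
                           edge_perturbations = NULL,
                           noise_sd = 0.01,
                           age_slope = 0,
                           demographics = default_demographics(),
                           compartment = "cerebellar",
                           seed = 1L) {
  n_per_group <- unlist(n_per_group)
  roi_names <- unlist(roi_names)
  if (is.list(base_covariance)) base_covariance <- do.call(rbind, base_covariance)
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% group_levels))
    stop_("n_per_group must be named with groups among %s",
          paste(group_levels, collapse = ", "))
  if (any(n_per_group < 3L)) stop_("need at least 3 subjects per group")
  if (anyDuplicated(roi_names)) stop_("roi_names must be unique")
  R <- length(roi_names)
  if (!identical(dim(base_covariance), c(R, R)))
    stop_("base_covariance must be %d x %d", R, R)
  if (!is_symmetric(base_covariance, tol = 1e-8)) stop_("base_covariance must be symmetric")
  if (min(eigen(base_covariance, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_("base_covariance is not positive semi-definite")
  if (!all(names(n_per_group) %in% names(group_means)))
    stop_("group_means must cover every group in n_per_group")
  group_means <- group_means[names(n_per_group)]
  offsets <- seq(-0.05, 0.05, length.out = R)
  offsets <- offsets - mean(offsets)
  group_means <- lapply(group_means, function(m) {
    if (length(m) == 1L) m + offsets else if (length(m) == R) m else
      stop_("group mean vectors must be length 1 or %d", R)
  })
  if (!is.null(edge_perturbations)) {
    ep <- as.data.frame(edge_perturbations)
    need <- c("group", "roi_i", "roi_j", "delta")
    if (!all(need %in% names(ep)))
      stop_("edge_perturbations needs columns %s", paste(need, collapse = ", "))
    if (!all(ep$group %in% names(n_per_group)))
      stop_("edge_perturbations reference unknown groups")
    if (any(abs(ep$delta) > 1)) stop_("|delta| must be <= 1")
    edge_perturbations <- ep
  }
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  structure(list(n_per_group = n_per_group, roi_names = roi_names,
                 group_means = group_means, base_covariance = base_covariance,
                 edge_perturbations = edge_perturbations, noise_sd = noise_sd,
                 age_slope = age_slope, demographics = demographics,
                 compartment = compartment, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic cohort spec: %s subjects, %d ROIs, %d edge perturbation(s), seed %d\n",
              paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = " "),
              length(x$roi_names),
              if (is.null(x$edge_perturbations)) 0L else nrow(x$edge_perturbations),
              x$seed))
  invisible(x)
}

group_covariance <- function(spec, group) {
  cov <- spec$base_covariance
  ep <- spec$edge_perturbations
  if (!is.null(ep)) {
    ep <- ep[ep$group == group, , drop = FALSE]
    if (nrow(ep) > 0L) {
      idx_i <- if (is.character(ep$roi_i)) match(ep$roi_i, spec$roi_names) else ep$roi_i
      idx_j <- if (is.character(ep$roi_j)) match(ep$roi_j, spec$roi_names) else ep$roi_j
      if (anyNA(idx_i) || anyNA(idx_j)) stop_("edge perturbation references unknown ROI")
      cov <- inject_edge_perturbation(cov, cbind(idx_i, idx_j), ep$delta)
    }
  }
  cov + diag(spec$noise_sd^2, nrow(cov))
}

#' Generate a synthetic cohort
#'
#' Draws each group's subjects from a multivariate normal with the group's
#' ROI mean vector and (possibly edge-perturbed) covariance, then draws
#' demographics (age, sex, MMSE) from the spec's group-level distributions.
#' SUVR values are floored at 0.01 (draws at or below zero are not valid
#' ratios; with the default calibration this affects essentially no draws).
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `cohort_tables`: list with elements `suvr`
#'   (a [suvr_matrix()]), `demographics` (data.frame with subject_id, group,
#'   age, sex, mmse) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  R <- length(spec$roi_names)
  template <- structure(
    data.frame(label = spec$roi_names, compartment = spec$compartment,
               stringsAsFactors = FALSE),
    class = c("roi_template", "data.frame"), atlas_source = "synthetic")
  with_seed(spec$seed, {
    vals <- list(); demo <- list()
    for (g in names(spec$n_per_group)) {
      n <- spec$n_per_group[[g]]
      covg <- group_covariance(spec, g)
      x <- MASS::mvrnorm(n, mu = spec$group_means[[g]], Sigma = covg)
      dg <- spec$demographics[spec$demographics$group == g, ]
      if (nrow(dg) != 1L) stop_("demographics table must have one row for group %s", g)
      age <- pmin(pmax(rnorm(n, dg$age_mean, dg$age_sd), 55), 95)
      sex <- ifelse(runif(n) < dg$male_frac, "M", "F")
      mmse <- round(pmin(pmax(rnorm(n, dg$mmse_mean, dg$mmse_sd), 0), 30))
      if (spec$age_slope != 0) x <- x + spec$age_slope * (age - 73)
      x[x <= 0.01] <- 0.01
      vals[[g]] <- x
      demo[[g]] <- data.frame(group = g, age = age, sex = sex, mmse = mmse,
                              stringsAsFactors = FALSE)
    }
    values <- do.call(rbind, vals)
    colnames(values) <- spec$roi_names
    demo <- do.call(rbind, demo)
    ids <- sprintf("S%04d", seq_len(nrow(values)))
    demo <- data.frame(subject_id = ids, demo, row.names = NULL,
                       stringsAsFactors = FALSE)
    structure(list(suvr = suvr_matrix(values, ids, template),
                   demographics = demo, spec = spec),
              class = "cohort_tables")
  })
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%s), %d ROIs\n",
              nrow(x$suvr$values),
              paste(names(table(x$demographics$group)),
                    table(x$demographics$group), sep = "=", collapse = " "),
              ncol(x$suvr$values)))
  invisible(x)
}

#' Small deterministic end-to-end fixture
#'
#' An 8-ROI, 12-subjects-per-group cohort under a fixed seed, sized so the
#' full pipeline runs in seconds in examples and tests.
#'
#' @param seed Fixture seed.
#' @return A `cohort_tables` object.
#' @export
generate_worked_fixture <- function(seed = 20260921L) {
  roi <- paste0("ROI_", 1:8)
  spec <- synthetic_spec(
    n_per_group = c(CN = 12, EMCI = 12, LMCI = 12, AD = 12),
    roi_names = roi,
    base_covariance = factor_covariance(8),
    seed = seed)
  generate_cohort(spec)
}

#' Write cohort tables as CSV
#'
#' Writes `suvr.csv` (subject_id + one column per ROI) and
#' `demographics.csv` (subject_id, group, age, sex, mmse) into `dir`.
#'
#' @param cohort A `cohort_tables` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "suvr.csv")
  p2 <- file.path(dir, "demographics.csv")
  write_suvr_table(cohort$suvr, p1)
  write.csv(cohort$demographics, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
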