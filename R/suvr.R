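#' Construct a validated SUVR matrix
#'
#' A `suvr_matrix` holds dimensionless standardized uptake value ratios
#' (regional mean uptake divided by whole-pons uptake) for a set of subjects
#' over the regions of an ROI template. Values must be finite and strictly
#' positive; columns follow the template ordering.
#'
#' @param values Numeric matrix, subjects x ROIs.
#' @param subject_ids Character vector of unique subject identifiers.
#' @param template An [build_roi_template()] object whose labels match the
#'   column names of `values` (order-insensitive; reordered here).
#' @param correction Provenance flag, `"none"` or `"PVEc-GTM"`; no
#'   partial-volume computation is performed by this package.
#' @return Object of class `suvr_matrix`.
#' @export
suvr_matrix <- function(values, subject_ids, template, correction = "none") {
  correction <- match.arg(correction, c("none", "PVEc-GTM"))
  if (!is.matrix(values)) values <- as.matrix(values)
  if (length(subject_ids) != nrow(values))
    stop_("subject_ids length (%d) != number of rows (%d)",
          length(subject_ids), nrow(values))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    stop_("duplicate subject ids: %s",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  labels <- template_labels(template)
  if (is.null(colnames(values)))
    colnames(values) <- if (ncol(values) == length(labels)) labels else
      stop_("values has no column names and does not match the template size")
  missing <- setdiff(labels, colnames(values))
  if (length(missing) > 0L)
    stop_("missing ROI columns: %s", paste(missing, collapse = ", "))
  values <- values[, labels, drop = FALSE]
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_("non-finite or non-positive SUVR at subject '%s', ROI '%s'",
          subject_ids[bad[1L, 1L]], labels[bad[1L, 2L]])
  rownames(values) <- subject_ids
  structure(list(values = values, subject_ids = subject_ids,
                 template = template, correction = correction),
            class = "suvr_matrix")
}

#' @export
print.suvr_matrix <- function(x, ...) {
  cat(sprintf("SUVR matrix: %d subjects x %d ROIs (correction: %s)\n",
              nrow(x$values), ncol(x$values), x$correction))
  invisible(x)
}

#' @export
dim.suvr_matrix <- function(x) dim(x$values)

#' Compute SUVR from regional uptake and a pons reference
#'
#' Divides every subject's regional mean uptake by that subject's whole-pons
#' mean uptake. Scale-equivariant per subject: rescaling a subject's uptakes
#' and pons value together leaves the SUVR row unchanged.
#'
#' @param roi_uptake Numeric matrix of regional mean uptake, subjects x ROIs,
#'   with ROI column names matching `template`.
#' @param pons_uptake Numeric vector of per-subject whole-pons mean uptake.
#' @param subject_ids Subject identifiers (default: rownames of `roi_uptake`).
#' @param template ROI template.
#' @param correction Provenance flag, see [suvr_matrix()].
#' @return A `suvr_matrix`.
#' @export
compute_suvr <- function(roi_uptake, pons_uptake,
                         subject_ids = rownames(roi_uptake), template,
                         correction = "none") {
  roi_uptake <- as.matrix(roi_uptake)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(roi_uptake)))
  if (length(pons_uptake) != nrow(roi_uptake))
    stop_("pons_uptake length (%d) != number of subjects (%d)",
          length(pons_uptake), nrow(roi_uptake))
  bad <- which(!is.finite(pons_uptake) | pons_uptake <= 0)
  if (length(bad) > 0L)
    stop_("non-positive pons uptake for subject '%s'", subject_ids[bad[1L]])
  suvr_matrix(sweep(roi_uptake, 1L, pons_uptake, "/"), subject_ids, template,
              correction = correction)
}

#' Read and write SUVR tables as CSV
#'
#' The on-disk format is a header CSV whose first column is `subject_id`
#' followed by one column per ROI. Columns may arrive in any order; they are
#' reordered to the template on load. Validation failures name the offending
#' row and column.
#'
#' @param path CSV file path.
#' @param template ROI template the columns must cover.
#' @param correction Provenance flag, see [suvr_matrix()].
#' @return A `suvr_matrix`.
#' @export
load_suvr_table <- function(path, template, correction = "none") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop_("SUVR CSV must have a 'subject_id' column")
  ids <- as.character(df$subject_id)
  vals <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(nonnum) > 0L)
    stop_("non-numeric SUVR columns: %s", paste(nonnum, collapse = ", "))
  suvr_matrix(as.matrix(vals), ids, template, correction = correction)
}

#' @rdname load_suvr_table
#' @param suvr A `suvr_matrix` to write.
#' @export
write_suvr_table <- function(suvr, path) {
  df <- data.frame(subject_id = suvr$subject_ids, suvr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-group summary of compartment-mean SUVR
#'
#' For each subject the mean SUVR over the regions of one compartment is
#' taken; groups are then summarized by the mean, median and quartiles of
#' those per-subject means (the layout used for baseline cohort tables).
#'
#' @param suvr A `suvr_matrix`.
#' @param groups Factor or character vector of group labels, one per subject.
#' @param compartment Compartment name from the template (e.g. "cerebellar").
#' @return data.frame with one row per group.
#' @export
summarize_group_suvr <- function(suvr, groups, compartment = "cerebellar") {
  if (length(groups) != length(suvr$subject_ids))
    stop_("groups length (%d) != subject count (%d)",
          length(groups), length(suvr$subject_ids))
  labels <- template_labels(suvr$template, compartment)
  if (length(labels) == 0L) stop_("unknown compartment '%s'", compartment)
  subj_mean <- rowMeans(suvr$values[, labels, drop = FALSE])
  groups <- as.character(groups)
  small <- names(which(table(groups) < 2L))
  if (length(small) > 0L)
    stop_("groups with fewer than 2 subjects: %s", paste(small, collapse = ", "))
  out <- do.call(rbind, lapply(split(subj_mean, groups), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v), sd = sd(v),
               q25 = q[1L], median = q[2L], q75 = q[3L])
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$compartment <- compartment
  out
}
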