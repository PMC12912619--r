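#' AAL116 atlas labels
#'
#' The 116 region labels of the Automated Anatomical Labeling atlas in their
#' conventional order, with a coarse lobe tag per label. This is the label
#' universe from which the default cerebellar (26 regions: 9 bilateral
#' lobule pairs plus 8 vermis segments) and cortical (72 regions) templates
#' are selected.
#'
#' @return A data.frame with columns `label` and `lobe`.
#' @export
aal116_labels <- function() {
  bilat <- function(x) as.vector(rbind(paste0(x, "_L"), paste0(x, "_R")))
  frontal <- bilat(c("Precentral", "Frontal_Sup", "Frontal_Sup_Orb",
                     "Frontal_Mid", "Frontal_Mid_Orb", "Frontal_Inf_Oper",
                     "Frontal_Inf_Tri", "Frontal_Inf_Orb", "Rolandic_Oper",
                     "Supp_Motor_Area", "Olfactory", "Frontal_Sup_Medial",
                     "Frontal_Med_Orb", "Rectus"))
  insula_cingulate <- bilat(c("Insula", "Cingulum_Ant", "Cingulum_Mid",
                              "Cingulum_Post"))
  medial_temporal <- bilat(c("Hippocampus", "ParaHippocampal", "Amygdala"))
  occipital <- bilat(c("Calcarine", "Cuneus", "Lingual", "Occipital_Sup",
                       "Occipital_Mid", "Occipital_Inf", "Fusiform"))
  parietal <- bilat(c("Postcentral", "Parietal_Sup", "Parietal_Inf",
                      "SupraMarginal", "Angular", "Precuneus",
                      "Paracentral_Lobule"))
  subcortical <- bilat(c("Caudate", "Putamen", "Pallidum", "Thalamus"))
  temporal <- bilat(c("Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
                      "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"))
  cerebellum <- c(bilat(c("Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3",
                          "Cerebelum_4_5", "Cerebelum_6", "Cerebelum_7b",
                          "Cerebelum_8", "Cerebelum_9", "Cerebelum_10")),
                  paste0("Vermis_", c("1_2", "3", "4_5", "6", "7", "8", "9", "10")))
  labels <- c(frontal, insula_cingulate, medial_temporal, occipital, parietal,
              subcortical, temporal, cerebellum)
  lobe <- c(rep("frontal", length(frontal)),
            rep("insula_cingulate", length(insula_cingulate)),
            rep("medial_temporal", length(medial_temporal)),
            rep("occipital", length(occipital)),
            rep("parietal", length(parietal)),
            rep("subcortical", length(subcortical)),
            rep("temporal", length(temporal)),
            rep("cerebellum", length(cerebellum)))
  data.frame(label = labels, lobe = lobe, stringsAsFactors = FALSE)
}

#' Default ROI selection rules
#'
#' Regex-based selection rules mapping atlas labels to the cerebellar and
#' cortical compartments. The cerebellar rule selects the 26 cerebellar
#' lobule and vermis labels. The cortical rule targets the regions with
#' higher amyloid burden (frontal, temporal, parietal cortices and the
#' precuneus, together with adjacent cingulate, insular, medial-temporal
#' and cuneus labels) for a total of 72 regions; the authoritative
#' composition of the 72-region set is configurable because published
#' region lists at this granularity vary.
#'
#' @return Named list of two character vectors of regular expressions.
#' @export
default_selection_rules <- function() {
  list(
    cerebellar = c("^Cerebelum_", "^Vermis_"),
    cortical = c("^Precentral", "^Frontal_", "^Rolandic_Oper", "^Supp_Motor_Area",
                 "^Olfactory", "^Rectus", "^Paracentral_Lobule",
                 "^Heschl", "^Temporal_", "^Fusiform",
                 "^Hippocampus", "^ParaHippocampal", "^Amygdala",
                 "^Postcentral", "^Parietal_", "^SupraMarginal", "^Angular",
                 "^Precuneus",
                 "^Cingulum_", "^Insula", "^Cuneus")
  )
}

#' Build an ROI template from an atlas label list
#'
#' Selects and tags regions of interest from a full atlas label list using
#' per-compartment regular-expression rules. With the shipped AAL116 labels
#' and default rules this yields 26 cerebellar and 72 cortical regions.
#'
#' @param atlas_labels Character vector of atlas labels (default: AAL116).
#' @param selection_rules Named list of character vectors of regexes, one
#'   element per compartment (default: [default_selection_rules()]).
#' @param atlas_source Free-text provenance tag stored on the template.
#' @return An object of class `roi_template`: a data.frame with columns
#'   `label` and `compartment`, ordered cerebellar-first then atlas order.
#' @export
build_roi_template <- function(atlas_labels = aal116_labels()$label,
                               selection_rules = default_selection_rules(),
                               atlas_source = "AAL116") {
  if (length(atlas_labels) == 0L) stop_("atlas label list is empty")
  if (anyDuplicated(atlas_labels)) stop_("atlas labels must be unique")
  if (length(selection_rules) == 0L) stop_("selection rules are empty")
  rows <- list()
  for (comp in names(selection_rules)) {
    pats <- selection_rules[[comp]]
    hit <- Reduce(`|`, lapply(pats, function(p) grepl(p, atlas_labels)))
    if (!any(hit)) stop_("selection rules for compartment '%s' match no labels", comp)
    rows[[comp]] <- data.frame(label = atlas_labels[hit], compartment = comp,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$label))
    stop_("labels assigned to more than one compartment: %s",
          paste(out$label[duplicated(out$label)], collapse = ", "))
  counts <- table(out$compartment)
  if (any(counts < 2L))
    stop_("each compartment needs at least 2 regions (got: %s)",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(out, class = c("roi_template", "data.frame"),
            atlas_source = atlas_source)
}

#' @export
print.roi_template <- function(x, ...) {
  counts <- table(x$compartment)
  cat("ROI template (", attr(x, "atlas_source"), "): ",
      paste(names(counts), counts, sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

template_labels <- function(template, compartment = NULL) {
  if (is.null(compartment)) return(template$label)
  template$label[template$compartment == compartment]
}

#' Write / read an ROI template as two-column CSV
#'
#' @param template An `roi_template`.
#' @param path File path.
#' @export
write_roi_template <- function(template, path) {
  write.csv(as.data.frame(template)[, c("label", "compartment")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_template
#' @export
read_roi_template <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "compartment") %in% names(df)))
    stop_("ROI template CSV needs columns 'label' and 'compartment'")
  structure(df[, c("label", "compartment")],
            class = c("roi_template", "data.frame"), atlas_source = path)
}
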