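# Atlas definition: 90-region AAL-style parcellation with hemisphere
# labels, left/right homologue pairs, and a six-lobe partition.

# Base names of the 45 homologue pairs, in standard AAL order, with the
# lobe each pair belongs to.  Lobe assignment follows the common grouping
# used in connectome studies of temporal lobe epilepsy: per hemisphere
# temporal 9, subcortical 7, frontal 13, parietal 7, occipital 6,
# cingulate 3 (so 18/14/26/14/12/6 bilaterally).
.aal90_pairs <- data.frame(
  base = c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup",
    "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
    "Temporal_Inf"
  ),
  lobe = c(
    "frontal", "frontal", "frontal", "frontal",
    "frontal", "frontal", "frontal",
    "frontal", "frontal", "frontal", "subcortical",
    "frontal", "frontal", "frontal", "subcortical",
    "cingulate", "cingulate", "cingulate", "temporal",
    "temporal", "subcortical", "occipital", "occipital", "occipital",
    "occipital", "occipital", "occipital", "temporal",
    "parietal", "parietal", "parietal", "parietal",
    "parietal", "parietal", "parietal", "subcortical", "subcortical",
    "subcortical", "subcortical", "temporal", "temporal",
    "temporal", "temporal", "temporal",
    "temporal"
  ),
  stringsAsFactors = FALSE
)

.lobe_counts <- c(temporal = 18L, subcortical = 14L, frontal = 26L,
                  parietal = 14L, occipital = 12L, cingulate = 6L)

#' Default 90-region atlas
#'
#' Builds the default atlas over 90 cortical and subcortical regions in
#' standard AAL ordering: regions alternate left/right so that regions
#' `2k - 1` (left) and `2k` (right) form the k-th homologue pair.  Each
#' region carries a hemisphere label and one of six lobe labels
#' (temporal, subcortical, frontal, parietal, occipital, cingulate with
#' 18/14/26/14/12/6 regions respectively).
#'
#' @return A `conn_atlas` data frame with columns `roi`, `hemisphere`,
#'   `homologue` (name of the mirror region) and `lobe`.
#' @export
#' @examples
#' atlas <- aal90_atlas()
#' table(atlas$lobe)
aal90_atlas <- function() {
  base <- .aal90_pairs$base
  df <- data.frame(
    roi = as.vector(rbind(paste0(base, "_L"), paste0(base, "_R"))),
    hemisphere = rep(c("left", "right"), times = length(base)),
    homologue = as.vector(rbind(paste0(base, "_R"), paste0(base, "_L"))),
    lobe = rep(.aal90_pairs$lobe, each = 2L),
    stringsAsFactors = FALSE
  )
  as_conn_atlas(df)
}

#' Construct an atlas from a data frame
#'
#' @param df Data frame with columns `roi`, `hemisphere`, `homologue`,
#'   `lobe`.
#' @param strict If `TRUE` (default) the atlas must describe exactly 90
#'   regions with the canonical lobe counts 18/14/26/14/12/6; with
#'   `strict = FALSE` only structural consistency (unique names, valid
#'   mutual homologue pairs) is enforced, which permits small toy
#'   atlases.
#' @return A `conn_atlas` object.
#' @export
as_conn_atlas <- function(df, strict = TRUE) {
  required <- c("roi", "hemisphere", "homologue", "lobe")
  if (!all(required %in% names(df)))
    stop("atlas must have columns ", paste(required, collapse = ", "))
  df <- as.data.frame(df)[, required]
  class(df) <- c("conn_atlas", "data.frame")
  validate_atlas(df, strict = strict)
  df
}

#' Validate an atlas
#'
#' Checks region uniqueness, that every region belongs to exactly one
#' left/right homologue pair whose two members carry the same lobe label,
#' and (when `strict`) that there are exactly 90 regions with lobe counts
#' temporal 18, subcortical 14, frontal 26, parietal 14, occipital 12,
#' cingulate 6.
#'
#' @inheritParams as_conn_atlas
#' @param atlas A `conn_atlas`.
#' @return `atlas`, invisibly; errors describe the violated invariant.
#' @export
validate_atlas <- function(atlas, strict = TRUE) {
  if (anyDuplicated(atlas$roi))
    stop("atlas ROI names are not unique")
  if (!all(atlas$hemisphere %in% c("left", "right")))
    stop("atlas hemisphere labels must be 'left' or 'right'")
  idx <- match(atlas$homologue, atlas$roi)
  if (anyNA(idx))
    stop("atlas homologue names missing from ROI list: ",
         paste(atlas$homologue[is.na(idx)], collapse = ", "))
  n <- nrow(atlas)
  if (any(idx == seq_len(n)) || !identical(idx[idx], seq_len(n)))
    stop("homologue mapping must pair each ROI with a distinct mirror ROI")
  if (any(atlas$hemisphere[idx] == atlas$hemisphere))
    stop("homologue pairs must span opposite hemispheres")
  if (any(atlas$lobe[idx] != atlas$lobe))
    stop("homologue pairs must share a lobe label")
  if (strict) {
    if (n != 90L) stop("atlas must have exactly 90 ROIs, found ", n)
    counts <- table(factor(atlas$lobe, levels = names(.lobe_counts)))
    bad <- counts != .lobe_counts
    if (any(bad))
      stop("lobe counts deviate from 18/14/26/14/12/6: ",
           paste(sprintf("%s=%d (expected %d)", names(.lobe_counts)[bad],
                         as.integer(counts[bad]), .lobe_counts[bad]),
                 collapse = ", "))
  }
  invisible(atlas)
}

#' Read an atlas from CSV
#'
#' Expects columns `roi`, `hemisphere`, `homologue`, `lobe`; extra
#' columns are ignored.
#'
#' @param path CSV file path.
#' @inheritParams as_conn_atlas
#' @return A `conn_atlas`.
#' @export
read_atlas <- function(path, strict = TRUE) {
  as_conn_atlas(read.csv(path, stringsAsFactors = FALSE), strict = strict)
}

# Integer index of each ROI's homologue.
homologue_index <- function(atlas) match(atlas$homologue, atlas$roi)

# ROI indices of a named region set: "whole_brain", a lobe, or a
# hemisphere-tagged lobe such as "temporal_left".
region_set_indices <- function(region_set, atlas) {
  if (region_set == "whole_brain") return(seq_len(nrow(atlas)))
  parts <- strsplit(region_set, "_")[[1]]
  lobe <- parts[1]
  if (!lobe %in% names(.lobe_counts))
    stop("unknown region set: ", region_set)
  keep <- atlas$lobe == lobe
  if (length(parts) > 1L) {
    hemi <- parts[2]
    if (!hemi %in% c("left", "right"))
      stop("unknown region set: ", region_set)
    keep <- keep & atlas$hemisphere == hemi
  }
  which(keep)
}

#' Names of the supported region sets
#'
#' Whole brain, each lobe (both hemispheres combined), and each lobe
#' restricted to one hemisphere.
#'
#' @return Character vector of region-set names accepted by
#'   [abnormality_load()].
#' @export
region_sets <- function() {
  lobes <- names(.lobe_counts)
  c("whole_brain", lobes,
    paste0(rep(lobes, each = 2L), "_", c("left", "right")))
}
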