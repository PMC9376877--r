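#' Default 72-region atlas
#'
#' The region set used throughout the package: the 68 cortical regions of the
#' Desikan-Killiany parcellation (34 per hemisphere, FreeSurfer `aparc`
#' naming with `lh_`/`rh_` prefixes) plus the bilateral hippocampus and
#' amygdala from the subcortical segmentation (`aseg` naming). Cortical
#' regions carry mean thickness (mm) in the gray matter modality; subcortical
#' regions carry volume (mm^3) and are adjusted for total intracranial
#' volume.
#'
#' @return A data frame with columns `region` (character, ordered as used in
#'   all matrices), `hemisphere` (`"L"`/`"R"`) and `kind`
#'   (`"cortical_thickness"` or `"subcortical_volume"`). 72 rows.
#' @examples
#' atlas <- desikan_atlas()
#' nrow(atlas)          # 72
#' table(atlas$kind)    # 68 cortical, 4 subcortical
#' @export
desikan_atlas <- function() {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
  region <- c(paste0("lh_", cortical), paste0("rh_", cortical),
              "Left-Hippocampus", "Right-Hippocampus",
              "Left-Amygdala", "Right-Amygdala")
  hemisphere <- c(rep("L", 34L), rep("R", 34L), "L", "R", "L", "R")
  kind <- c(rep("cortical_thickness", 68L), rep("subcortical_volume", 4L))
  data.frame(region = region, hemisphere = hemisphere, kind = kind,
             stringsAsFactors = FALSE)
}

#' Diagnostic group labels
#'
#' The four groups of the amyloid-stratified design: cognitively normal
#' amyloid-negative and -positive, and amyloid-positive MCI and AD.
#' @return Character vector of the four group labels in study order.
#' @export
group_levels <- function() c("CN_Aneg", "CN_Apos", "MCI_Apos", "AD_Apos")
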