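#' Regional cohort container
#'
#' Bundles a subject-by-region measurement matrix for one modality with the
#' per-subject covariates used downstream: age, sex, total intracranial
#' volume (volumetric modality only), CSF amyloid-beta 42 and diagnostic
#' group.
#'
#' @param values Numeric matrix, subjects x regions; column names must match
#'   `region_names`.
#' @param modality `"gray_matter"` or `"amyloid"`.
#' @param region_names Ordered character vector of region labels.
#' @param subject_ids Unique subject identifiers.
#' @param age Numeric, years.
#' @param sex Numeric or integer coded 0/1 (coding choice does not affect
#'   any downstream result; see [residualize()]).
#' @param tiv Total intracranial volume in mm^3, or `NULL` for modalities
#'   that do not use it.
#' @param csf_abeta42 CSF amyloid-beta 42 in pg/ml (already on the assay
#'   scale; [clamp_csf()] applies the assay ceiling).
#' @param group Character vector of group labels, one of [group_levels()].
#' @return An object of class `regional_cohort`.
#' @export
regional_cohort <- function(values, modality, region_names, subject_ids,
                            age, sex, tiv = NULL, csf_abeta42 = NULL,
                            group = NULL) {
  modality <- match.arg(modality, c("gray_matter", "amyloid"))
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(subject_ids) != n)
    stop_mxad("subject_ids length (%d) != number of rows (%d)",
              length(subject_ids), n)
  if (anyDuplicated(subject_ids))
    stop_mxad("duplicate subject id: %s",
              subject_ids[duplicated(subject_ids)][1L])
  if (ncol(values) != length(region_names))
    stop_mxad("values has %d columns but %d region names given",
              ncol(values), length(region_names))
  if (anyNA(values)) stop_mxad("missing values in measurement matrix")
  if (length(age) != n || anyNA(age)) stop_mxad("age must be complete, length %d", n)
  if (length(sex) != n || anyNA(sex)) stop_mxad("sex must be complete, length %d", n)
  if (length(unique(sex)) > 2L) stop_mxad("sex must be binary-coded")
  if (!is.null(tiv)) {
    if (length(tiv) != n || anyNA(tiv)) stop_mxad("tiv must be complete, length %d", n)
    if (any(tiv <= 0)) stop_mxad("tiv must be strictly positive")
  }
  if (!is.null(group)) {
    bad <- setdiff(unique(group), group_levels())
    if (length(bad)) stop_mxad("unknown group label: %s", bad[1L])
    if (length(group) != n) stop_mxad("group must have length %d", n)
  }
  if (modality == "amyloid" && any(values <= 0))
    stop_mxad("SUVR values must be strictly positive")
  colnames(values) <- region_names
  rownames(values) <- subject_ids
  structure(list(values = values, modality = modality,
                 region_names = region_names,
                 subject_ids = as.character(subject_ids),
                 age = as.numeric(age), sex = as.numeric(sex),
                 tiv = if (is.null(tiv)) NULL else as.numeric(tiv),
                 csf_abeta42 = if (is.null(csf_abeta42)) NULL
                               else as.numeric(csf_abeta42),
                 group = group),
            class = "regional_cohort")
}

#' @export
print.regional_cohort <- function(x, ...) {
  cat(sprintf("<regional_cohort> %s: %d subjects x %d regions\n",
              x$modality, nrow(x$values), ncol(x$values)))
  if (!is.null(x$group)) print(table(x$group))
  invisible(x)
}

#' Subset a cohort to one diagnostic group
#' @param cohort A [regional_cohort()].
#' @param group One of [group_levels()].
#' @return A `regional_cohort` containing only that group's subjects.
#' @export
subset_group <- function(cohort, group) {
  stopifnot(inherits(cohort, "regional_cohort"))
  if (is.null(cohort$group)) stop_mxad("cohort has no group labels")
  keep <- cohort$group == group
  if (!any(keep)) stop_mxad("no subjects in group %s", group)
  regional_cohort(cohort$values[keep, , drop = FALSE], cohort$modality,
                  cohort$region_names, cohort$subject_ids[keep],
                  cohort$age[keep], cohort$sex[keep],
                  tiv = cohort$tiv[keep], csf_abeta42 = cohort$csf_abeta42[keep],
                  group = cohort$group[keep])
}

#' Apply the CSF amyloid-beta 42 assay ceiling
#'
#' The immunoassay is not validated above 1700 pg/ml; concentrations above
#' the ceiling are replaced by 1700 pg/ml.
#'
#' @param value CSF amyloid-beta 42 in pg/ml; must be positive and non-missing.
#' @return Clamped value(s), `min(value, 1700)`.
#' @examples
#' clamp_csf(1800)  # 1700
#' clamp_csf(500)   # 500
#' @export
clamp_csf <- function(value) {
  if (length(value) == 0L || anyNA(value))
    stop_mxad("CSF value missing")
  if (any(value <= 0)) stop_mxad("CSF value must be positive")
  pmin(value, 1700)
}

#' Classify amyloid status from CSF amyloid-beta 42
#'
#' Amyloid positivity is defined by the established cutoff
#' CSF amyloid-beta 42 < 976.6 pg/ml (strict inequality).
#'
#' @param value Clamped CSF amyloid-beta 42 in pg/ml.
#' @return Character vector, `"Apos"` or `"Aneg"`.
#' @examples
#' classify_abeta(900)    # "Apos"
#' classify_abeta(976.6)  # "Aneg"
#' @export
classify_abeta <- function(value) {
  if (length(value) == 0L || anyNA(value)) stop_mxad("CSF value missing")
  ifelse(value < 976.6, "Apos", "Aneg")
}

#' Adjust regional volumes for total intracranial volume
#'
#' Head-size correction for subcortical volumes:
#' `Adjusted_i = Observed_i - beta * (TIV_i - mean(TIV))`, where `beta` is
#' the least-squares slope of the regional volume regressed on TIV over a
#' reference subject subset and `mean(TIV)` is taken over all analyzed
#' subjects.
#'
#' @param volumes Per-subject volumes (mm^3) for one region.
#' @param tiv Per-subject total intracranial volume (mm^3), strictly positive.
#' @param beta_source Integer or logical index of the subjects used to
#'   estimate the slope (default: all). At least 3 subjects with TIV
#'   variance are required.
#' @return Adjusted volumes, same length as `volumes`.
#' @export
adjust_tiv <- function(volumes, tiv, beta_source = seq_along(volumes)) {
  stopifnot(length(volumes) == length(tiv))
  if (any(tiv <= 0)) stop_mxad("tiv must be strictly positive")
  v0 <- volumes[beta_source]
  t0 <- tiv[beta_source]
  if (length(v0) < 3L) stop_mxad("beta_source must contain >= 3 subjects")
  if (stats::var(t0) == 0)
    stop_mxad("degenerate regression: zero TIV variance in beta_source")
  beta <- stats::cov(v0, t0) / stats::var(t0)
  volumes - beta * (tiv - mean(tiv))
}

#' Residualize regional values on age and sex
#'
#' Per-region ordinary least squares on an intercept, age and binary sex;
#' returns the residuals. Residuals have zero mean and zero sample
#' correlation with both covariates, and are invariant to affine recoding of
#' either covariate.
#'
#' @param values Subjects x regions numeric matrix.
#' @param age Numeric covariate, years.
#' @param sex Binary-coded covariate.
#' @return Residual matrix of the same shape.
#' @export
residualize <- function(values, age, sex) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 4L) stop_mxad("need >= 4 subjects to residualize on age and sex")
  X <- cbind(intercept = 1, age = age, sex = sex)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    offending <- if (stats::var(sex) == 0) "sex"
                 else if (stats::var(age) == 0) "age"
                 else "age/sex"
    stop_mxad("rank-deficient design: covariate '%s' is constant or collinear",
              offending)
  }
  qr.resid(qx, values)
}

#' Read a subject table into a regional cohort
#'
#' Expects a delimited table with one row per subject and columns
#' `subject_id`, `age`, `sex`, `group`, `csf_abeta42`, optionally `tiv`, and
#' one column per atlas region. Region columns may appear in any order; they
#' are reordered to atlas order.
#'
#' @param path Path to a CSV/TSV file (separator sniffed from the extension;
#'   `.tsv` implies tab).
#' @param modality `"gray_matter"` or `"amyloid"`.
#' @param atlas Atlas data frame as from [desikan_atlas()].
#' @return A validated [regional_cohort()].
#' @export
load_cohort <- function(path, modality, atlas = desikan_atlas()) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "sex", "group")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop_mxad("missing column '%s' in %s", miss[1L], path)
  miss_r <- setdiff(atlas$region, names(tab))
  if (length(miss_r))
    stop_mxad("missing region column '%s' in %s", miss_r[1L], path)
  if (anyDuplicated(tab$subject_id))
    stop_mxad("duplicate subject id: %s",
              tab$subject_id[duplicated(tab$subject_id)][1L])
  values <- as.matrix(tab[, atlas$region, drop = FALSE])
  storage.mode(values) <- "double"
  regional_cohort(values, modality, atlas$region, tab$subject_id,
                  tab$age, tab$sex,
                  tiv = if ("tiv" %in% names(tab)) tab$tiv else NULL,
                  csf_abeta42 = if ("csf_abeta42" %in% names(tab))
                                  tab$csf_abeta42 else NULL,
                  group = tab$group)
}

#' Write a regional cohort as a delimited subject table
#'
#' Inverse of [load_cohort()]: one row per subject, covariate columns then
#' region columns in atlas order.
#'
#' @param cohort A [regional_cohort()].
#' @param path Output file path (`.tsv` writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "regional_cohort"))
  tab <- data.frame(subject_id = cohort$subject_ids, age = cohort$age,
                    sex = cohort$sex, group = cohort$group %||% NA,
                    csf_abeta42 = cohort$csf_abeta42 %||% NA,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(cohort$tiv)) tab$tiv <- cohort$tiv
  tab <- cbind(tab, as.data.frame(cohort$values, check.names = FALSE))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess the volumetric modality: TIV adjustment of subcortical volumes
#'
#' Applies [adjust_tiv()] to every subcortical-volume region of a gray
#' matter cohort. The slope is estimated on a reference group (default the
#' amyloid-negative controls, a common choice for nuisance-slope
#' estimation); the TIV centering uses the mean over all subjects.
#'
#' @param cohort A gray matter [regional_cohort()] with `tiv`.
#' @param atlas Atlas data frame; its `kind` column selects the volume regions.
#' @param beta_group Group whose subjects define the regression slope;
#'   `NULL` uses all subjects.
#' @return The cohort with adjusted subcortical volumes.
#' @export
adjust_tiv_cohort <- function(cohort, atlas = desikan_atlas(),
                              beta_group = "CN_Aneg") {
  stopifnot(inherits(cohort, "regional_cohort"))
  if (is.null(cohort$tiv)) stop_mxad("cohort has no TIV; nothing to adjust")
  vol_regions <- atlas$region[atlas$kind == "subcortical_volume"]
  vol_regions <- intersect(vol_regions, cohort$region_names)
  src <- if (is.null(beta_group)) seq_along(cohort$tiv)
         else which(cohort$group == beta_group)
  for (r in vol_regions) {
    cohort$values[, r] <- adjust_tiv(cohort$values[, r], cohort$tiv,
                                     beta_source = src)
  }
  cohort
}
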