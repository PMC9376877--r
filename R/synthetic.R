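# Run code under a local RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Configuration for the synthetic two-modality cohort generator
#'
#' Defines the generative model used to emulate the structure of an
#' amyloid-stratified aging cohort: four diagnostic groups, 72 regions with
#' a planted modular correlation structure in each layer, age/sex
#' confounding, multiplicative head-size (TIV) scaling of subcortical
#' volumes, and group-dependent amyloid burden in both the SUVR means and
#' the CSF amyloid-beta 42 values used for stratification.
#'
#' @param group_sizes Named integer vector of subjects per group. The
#'   default reproduces the study composition: 135 amyloid-negative CN, 67
#'   amyloid-positive CN, 179 amyloid-positive MCI, 132 amyloid-positive AD.
#' @param n_modules Number of planted communities; regions are split into
#'   contiguous, near-equal blocks.
#' @param within_module_corr,between_module_corr Target correlations inside
#'   and between planted modules (gray matter layer; amyloid inherits them
#'   plus the group effect).
#' @param layer_disagreement Fraction of regions reassigned to a different
#'   module in the amyloid layer; 0 means both layers share the planted
#'   partition (expected persistence 1).
#' @param covariate_effects List with `age` and `sex` slopes on the latent
#'   z-scale, shared by all regions (this common dependence is the
#'   confounding the partial-correlation step must remove).
#' @param noise_sd Standard deviation of i.i.d. measurement noise added on
#'   the latent scale (attenuates all correlations by
#'   `1/(1 + noise_sd^2)`).
#' @param effect_size Uniform increment of the amyloid-layer correlations
#'   (within- and between-module alike) at full disease stage, emulating
#'   the global rise of amyloid covariance with increasing burden; groups
#'   receive it scaled by stage weights 0, 1/3, 2/3, 1 along the
#'   CN-negative to AD continuum. Raises every node's amyloid-layer
#'   connectivity strength without changing the modular contrast.
#' @param atlas Atlas data frame defining region names and kinds.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(group_sizes = c(CN_Aneg = 135L, CN_Apos = 67L,
                                             MCI_Apos = 179L, AD_Apos = 132L),
                             n_modules = 3L,
                             within_module_corr = 0.5,
                             between_module_corr = 0.1,
                             layer_disagreement = 0,
                             covariate_effects = list(age = -0.02, sex = 0.3),
                             noise_sd = 0.2,
                             effect_size = 0.25,
                             atlas = desikan_atlas(),
                             seed = 1L) {
  stopifnot(all(names(group_sizes) %in% group_levels()),
            all(group_sizes >= 16L),
            within_module_corr > between_module_corr,
            between_module_corr >= 0, effect_size >= 0,
            abs(within_module_corr + effect_size) < 1,
            layer_disagreement >= 0, layer_disagreement <= 1)
  n_regions <- nrow(atlas)
  module_assignment <- sort(rep_len(seq_len(n_modules), n_regions))
  structure(list(group_sizes = group_sizes, n_regions = n_regions,
                 n_modules = n_modules,
                 module_assignment = module_assignment,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 layer_disagreement = layer_disagreement,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, effect_size = effect_size,
                 atlas = atlas, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Block correlation matrix with planted community structure
#'
#' Builds the N x N correlation matrix with `within` on off-diagonal entries
#' inside a module, `between` elsewhere and 1 on the diagonal. If the
#' construction is not positive definite it is repaired by eigenvalue
#' clipping followed by rescaling to unit diagonal.
#'
#' @param module_assignment Integer module label per region.
#' @param within,between Target correlations, `within > between >= 0`.
#' @param n_regions Number of regions (defaults to the assignment length).
#' @return Positive-definite correlation matrix.
#' @export
planted_covariance <- function(module_assignment, within, between,
                               n_regions = length(module_assignment)) {
  stopifnot(within > between, between >= 0, abs(within) < 1,
            length(module_assignment) == n_regions)
  same <- outer(module_assignment, module_assignment, "==")
  sigma <- ifelse(same, within, between)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    e <- eigen(sigma, symmetric = TRUE)
    lam <- pmax(e$values, 1e-8)
    sigma <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(sigma))
    sigma <- sigma / outer(d, d)
    diag(sigma) <- 1
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_mxad("planted covariance cannot be repaired to positive definite")
  }
  sigma
}

# Stage weight of each group along the amyloid continuum; scales the
# amyloid-layer connectivity effect.
stage_weight <- function(group) {
  c(CN_Aneg = 0, CN_Apos = 1 / 3, MCI_Apos = 2 / 3, AD_Apos = 1)[group]
}

#' Generate a synthetic two-modality cohort
#'
#' Draws per-group regional values from multivariate normal distributions
#' with the planted block correlation structure, adds shared age/sex
#' effects and i.i.d. noise, maps the latent scale to modality units
#' (cortical thickness in mm, subcortical volume in mm^3 scaled by TIV,
#' amyloid SUVR), and draws CSF amyloid-beta 42 from truncated normals so
#' that [classify_abeta()] reproduces the configured group membership
#' exactly (amyloid-negative values may exceed the 1700 pg/ml assay ceiling,
#' exercising [clamp_csf()]).
#'
#' @param config A [synthetic_config()].
#' @return List with elements `gray_matter` and `amyloid`, each a
#'   [regional_cohort()] holding all groups, plus `planted` (per-layer
#'   module assignments actually used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    atlas <- config$atlas
    nR <- config$n_regions
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    ids <- sprintf("S%04d", seq_len(n))
    age <- rtrunc_norm(n, 73, 6, 55, 90)
    sex <- stats::rbinom(n, 1L, 0.5)
    tiv <- rtrunc_norm(n, 1.5e6, 1.5e5, 1.1e6, 1.9e6)

    # CSF amyloid-beta 42 consistent with group membership by construction
    csf <- numeric(n)
    aneg <- groups == "CN_Aneg"
    csf[aneg] <- rtrunc_norm(sum(aneg), 1300, 200, 980, 2200)
    csf_mean <- c(CN_Apos = 850, MCI_Apos = 750, AD_Apos = 650)
    for (g in names(csf_mean)) {
      idx <- groups == g
      csf[idx] <- rtrunc_norm(sum(idx), csf_mean[[g]], 80, 250, 970)
    }

    # amyloid-layer module assignment: optionally reassign a fraction
    planted_gm <- config$module_assignment
    planted_amy <- planted_gm
    n_move <- round(config$layer_disagreement * nR)
    if (n_move > 0) {
      moved <- sample.int(nR, n_move)
      planted_amy[moved] <- ((planted_gm[moved]) %% config$n_modules) + 1L
    }

    draw_layer <- function(planted, extra_by_group = NULL) {
      vals <- matrix(0, n, nR)
      for (g in names(config$group_sizes)) {
        idx <- which(groups == g)
        extra <- if (is.null(extra_by_group)) 0 else extra_by_group[[g]]
        sigma <- planted_covariance(planted,
                                    config$within_module_corr + extra,
                                    config$between_module_corr + extra, nR)
        z <- MASS::mvrnorm(length(idx), mu = rep(0, nR), Sigma = sigma)
        z <- z + matrix(stats::rnorm(length(idx) * nR, 0, config$noise_sd),
                        length(idx), nR)
        vals[idx, ] <- z
      }
      vals + config$covariate_effects$age * (age - 73) +
        config$covariate_effects$sex * sex
    }

    z_gm <- draw_layer(planted_gm)
    extra <- lapply(stats::setNames(nm = names(config$group_sizes)),
                    function(g) config$effect_size * stage_weight(g))
    z_amy <- draw_layer(planted_amy, extra)

    # map latent scale to modality units
    cortical <- atlas$kind == "cortical_thickness"
    gm_vals <- matrix(0, n, nR, dimnames = list(ids, atlas$region))
    gm_vals[, cortical] <- 2.5 + 0.15 * z_gm[, cortical]
    gm_vals[, !cortical] <- (3800 + 400 * z_gm[, !cortical]) * (tiv / 1.5e6)

    suvr_mean <- c(CN_Aneg = 1.05, CN_Apos = 1.25, MCI_Apos = 1.35,
                   AD_Apos = 1.45)
    amy_vals <- suvr_mean[groups] + 0.12 * z_amy
    amy_vals <- pmax(amy_vals, 0.2)
    dimnames(amy_vals) <- list(ids, atlas$region)

    list(gray_matter = regional_cohort(gm_vals, "gray_matter", atlas$region,
                                       ids, age, sex, tiv = tiv,
                                       csf_abeta42 = csf, group = groups),
         amyloid = regional_cohort(amy_vals, "amyloid", atlas$region, ids,
                                   age, sex, csf_abeta42 = csf,
                                   group = groups),
         planted = list(gray_matter = planted_gm, amyloid = planted_amy))
  })
}
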