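#' End-to-end run configuration
#'
#' Bundles every knob of a full analysis run. A saved configuration (see
#' the `config.yaml` written by [run_pipeline()]) plus the package version
#' reproduces a run bit for bit.
#'
#' @param out_dir Output directory (created if missing).
#' @param synthetic A [synthetic_config()], used when no input paths are
#'   given.
#' @param input_gray,input_amyloid Optional paths to subject tables read by
#'   [load_cohort()]; both or neither.
#' @param d_min,d_max,d_step Binarization density grid.
#' @param gamma,omega,n_restarts Community detection settings.
#' @param measures Measures to test between groups.
#' @param contrasts List of `c(group_a, group_b)` pairs. Default: every
#'   amyloid-positive group against the amyloid-negative controls, plus
#'   AD versus MCI.
#' @param n_perm Permutation replicates per contrast.
#' @param weight_mode Negative-weight convention for weighted analyses.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synthetic = synthetic_config(),
                       input_gray = NULL, input_amyloid = NULL,
                       d_min = 0.02, d_max = 0.30, d_step = 0.01,
                       gamma = 1, omega = 1, n_restarts = 100L,
                       measures = c("strength", "degree_overlap",
                                    "participation", "clustering"),
                       contrasts = list(c("CN_Apos", "CN_Aneg"),
                                        c("MCI_Apos", "CN_Aneg"),
                                        c("AD_Apos", "CN_Aneg"),
                                        c("AD_Apos", "MCI_Apos")),
                       n_perm = 10000L, weight_mode = "positive",
                       seed = 1L) {
  if (xor(is.null(input_gray), is.null(input_amyloid)))
    stop_mxad("provide both modality tables or neither")
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 input_gray = input_gray, input_amyloid = input_amyloid,
                 d_min = d_min, d_max = d_max, d_step = d_step,
                 gamma = gamma, omega = omega,
                 n_restarts = as.integer(n_restarts),
                 measures = measures, contrasts = contrasts,
                 n_perm = as.integer(n_perm), weight_mode = weight_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(region = rownames(m) %||% as.character(seq_len(nrow(m))),
                   m, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full multiplex connectome pipeline
#'
#' Stages, in order: load or synthesize the two-modality cohort; subject
#' preprocessing (CSF ceiling, amyloid classification check, TIV adjustment
#' of subcortical volumes); per-group layer construction; weighted analysis
#' (overlapping strength, multilayer communities with persistence); density
#' sweep with binary nodal metrics; permutation group comparisons with
#' density-averaged p-values and FDR masks. All tables are written as CSV
#' under `config$out_dir` together with the configuration and seeds
#' (`config.yaml`, `run_info.json`).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohorts`,
#'   `multiplexes`, `strength`, `partitions`, `binary_metrics`,
#'   `comparisons`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: data
  if (!is.null(config$input_gray)) {
    gm <- load_cohort(config$input_gray, "gray_matter")
    amy <- load_cohort(config$input_amyloid, "amyloid")
  } else {
    synth <- generate_cohort(config$synthetic)
    gm <- synth$gray_matter
    amy <- synth$amyloid
  }

  # stage 2: subject preprocessing
  gm$csf_abeta42 <- clamp_csf(gm$csf_abeta42)
  amy$csf_abeta42 <- clamp_csf(amy$csf_abeta42)
  status <- classify_abeta(gm$csf_abeta42)
  expected <- ifelse(grepl("Apos$", gm$group), "Apos", "Aneg")
  if (!all(status == expected))
    stop_mxad("stage preprocess: %d subjects have CSF status inconsistent with group label",
              sum(status != expected))
  gm <- adjust_tiv_cohort(gm)
  write_cohort(gm, file.path(config$out_dir, "cohort_gray_matter.csv"))
  write_cohort(amy, file.path(config$out_dir, "cohort_amyloid.csv"))

  groups <- intersect(group_levels(), unique(gm$group))
  densities <- seq(config$d_min, config$d_max, by = config$d_step)
  mxs <- list(); strength_tab <- list(); partitions <- list()
  binary_tab <- list()
  for (g in groups) {
    mx <- build_group_multiplex(gm, amy, g)
    mxs[[g]] <- mx
    write_matrix_csv(mx$layers$gray_matter$weights,
                     file.path(config$out_dir,
                               sprintf("layer_gray_matter_%s.csv", g)))
    write_matrix_csv(mx$layers$amyloid$weights,
                     file.path(config$out_dir,
                               sprintf("layer_amyloid_%s.csv", g)))

    s <- overlapping_strength(mx, config$weight_mode)
    strength_tab[[g]] <- data.frame(group = g, region = names(s),
                                    strength = as.numeric(s),
                                    stringsAsFactors = FALSE)

    cfg <- modularity_config(gamma = config$gamma, omega = config$omega,
                             n_restarts = config$n_restarts,
                             seed = derive_seed(config$seed, match(g, groups)))
    part <- louvain_multilayer(mx, cfg, config$weight_mode)
    partitions[[g]] <- part
    utils::write.table(
      data.frame(group = g, region = rownames(part$labels),
                 gray_matter = part$labels[, 1L],
                 amyloid = part$labels[, 2L]),
      file.path(config$out_dir, sprintf("communities_%s.csv", g)),
      sep = ",", row.names = FALSE, quote = FALSE)

    sweep <- density_sweep(mx, config$d_min, config$d_max, config$d_step)
    bt <- metrics_over_sweep(sweep)
    bt$group <- g
    binary_tab[[g]] <- bt
  }
  utils::write.table(do.call(rbind, strength_tab),
                     file.path(config$out_dir, "overlapping_strength.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, binary_tab),
                     file.path(config$out_dir, "binary_metrics.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(group = groups,
               Q = vapply(partitions, `[[`, 0, "Q"),
               n_communities = vapply(partitions, `[[`, 0L, "n_communities"),
               persistence = vapply(partitions, `[[`, 0, "persistence")),
    file.path(config$out_dir, "partition_summary.csv"),
    sep = ",", row.names = FALSE, quote = FALSE)

  # stage 6: group comparisons
  comparisons <- list(); comp_rows <- list()
  for (k in seq_along(config$contrasts)) {
    ct <- config$contrasts[[k]]
    if (!all(ct %in% groups)) next
    pair_a <- list(gray_matter = subset_group(gm, ct[1L]),
                   amyloid = subset_group(amy, ct[1L]))
    pair_b <- list(gray_matter = subset_group(gm, ct[2L]),
                   amyloid = subset_group(amy, ct[2L]))
    for (m in config$measures) {
      pr <- permutation_test(pair_a, pair_b, m, densities,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, 100L + 10L * k +
                                                  match(m, config$measures)),
                             weight_mode = config$weight_mode)
      key <- sprintf("%s_vs_%s_%s", ct[1L], ct[2L], m)
      comparisons[[key]] <- pr
      comp_rows[[key]] <- data.frame(
        measure = m, contrast = sprintf("%s_vs_%s", ct[1L], ct[2L]),
        region = names(pr$p_mean),
        observed_diff = rowMeans(pr$observed_diff),
        p_mean = pr$p_mean, significant = pr$fdr_mask,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (length(comp_rows))
    utils::write.table(do.call(rbind, c(comp_rows, make.row.names = FALSE)),
                       file.path(config$out_dir, "group_comparisons.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)

  cfg_out <- config
  cfg_out$synthetic$atlas <- NULL  # recoverable from desikan_atlas()
  yaml::write_yaml(lapply(unclass(cfg_out), function(x)
    if (is.list(x) && !is.null(attr(x, "class"))) unclass(x) else x),
    file.path(config$out_dir, "config.yaml"))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("mxad")),
         seed = config$seed, groups = groups,
         n_densities = length(densities)),
    file.path(config$out_dir, "run_info.json"), auto_unbox = TRUE)

  invisible(list(cohorts = list(gray_matter = gm, amyloid = amy),
                 multiplexes = mxs,
                 strength = do.call(rbind, strength_tab),
                 partitions = partitions,
                 binary_metrics = do.call(rbind, binary_tab),
                 comparisons = comparisons))
}
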