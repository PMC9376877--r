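# Group-level nodal measure recomputed from subject data for an index set:
# residualize -> partial correlation -> (optionally binarize per density)
# -> nodal measure. Returns a regions x n_stat matrix (1 column for the
# weighted strength, one per density for binary measures).
group_measure_matrix <- function(y_gm, y_amy, age, sex, idx, measure,
                                 densities, weight_mode = "positive",
                                 binarize_mode = "signed") {
  n_regions <- ncol(y_gm)
  corr_of <- function(y) {
    res <- residualize(y[idx, , drop = FALSE], age[idx], sex[idx])
    w <- stats::cor(res)
    diag(w) <- 0
    w
  }
  w1 <- corr_of(y_gm)
  w2 <- corr_of(y_amy)
  if (measure == "strength") {
    s <- rowSums(apply_weight_mode(w1, weight_mode)) +
      rowSums(apply_weight_mode(w2, weight_mode))
    return(matrix(s, ncol = 1L))
  }
  er1 <- edge_ranks(w1, binarize_mode)
  er2 <- edge_ranks(w2, binarize_mode)
  n_pairs <- n_regions * (n_regions - 1) / 2
  out <- matrix(0, n_regions, length(densities))
  for (d in seq_along(densities)) {
    e_target <- round(densities[d] * n_pairs)
    sel1 <- er1$rank <= e_target
    sel2 <- er2$rank <= e_target
    k1 <- tabulate(c(er1$i[sel1], er1$j[sel1]), n_regions)
    k2 <- tabulate(c(er2$i[sel2], er2$j[sel2]), n_regions)
    out[, d] <- switch(
      measure,
      degree_overlap = {
        both <- sel1 & sel2
        tabulate(c(er1$i[both], er1$j[both]), n_regions)
      },
      participation = {
        o <- k1 + k2
        p <- numeric(n_regions)
        nz <- o > 0
        p[nz] <- 2 * (1 - (k1[nz] / o[nz])^2 - (k2[nz] / o[nz])^2)
        p
      },
      clustering = {
        a1 <- matrix(0, n_regions, n_regions)
        a1[cbind(er1$i[sel1], er1$j[sel1])] <- 1
        a1 <- a1 + t(a1)
        a2 <- matrix(0, n_regions, n_regions)
        a2[cbind(er2$i[sel2], er2$j[sel2])] <- 1
        a2 <- a2 + t(a2)
        num <- diag(a1 %*% a2 %*% a1) + diag(a2 %*% a1 %*% a2)
        den <- k1 * (k1 - 1) + k2 * (k2 - 1)
        ifelse(den > 0, num / den, 0)
      },
      overlapping_degree = k1 + k2,
      stop_mxad("unknown measure '%s'", measure))
  }
  out
}

#' Permutation test of a nodal multiplex measure between two groups
#'
#' Nonparametric group comparison: the observed per-region difference of
#' the group-level measure (group A minus group B) is referred to a null
#' distribution built by randomly reallocating subjects into two groups of
#' the original sizes and rebuilding both groups' networks from scratch in
#' every replicate — residualization, partial correlation and, for binary
#' measures, binarization at every density of the grid. Covariates travel
#' with the subject, the unit of exchangeability under the null that both
#' groups share one generative process. Two-tailed p-values use the add-one
#' convention `p = (#{|null| >= |obs|} + 1) / (n_perm + 1)`, the
#' permutation equivalent of thresholding at the 95% interval of the null
#' for a test at 0.05. For binary measures the per-density p-values are
#' averaged across the density grid; the weighted strength has no density
#' loop. Significance is assessed per region after Benjamini-Hochberg FDR
#' correction over the regions.
#'
#' @param a,b Lists with elements `gray_matter` and `amyloid`, each a
#'   single-group [regional_cohort()] (as produced by [subset_group()]).
#' @param measure One of `"strength"` (weighted), `"degree_overlap"`,
#'   `"participation"`, `"clustering"`, `"overlapping_degree"` (binary,
#'   computed over `densities`).
#' @param densities Density grid for binary measures; ignored for
#'   `"strength"`. Default 2%-30% in 1% steps.
#' @param n_perm Number of permutation replicates (default 10000; >= 100
#'   required). 1000 is a practical fast mode.
#' @param seed Integer seed; identical seeds give identical results.
#' @param q FDR level for the significance mask.
#' @param weight_mode,binarize_mode Negative-weight and ranking conventions,
#'   as elsewhere.
#' @param keep_null Store the full null difference array (may be large);
#'   default keeps it only below 2e7 entries.
#' @return A `permutation_result`: observed differences, per-density raw
#'   p-values, density-averaged `p_mean`, FDR mask at `q`, and metadata.
#' @export
permutation_test <- function(a, b, measure = c("strength", "degree_overlap",
                                               "participation", "clustering",
                                               "overlapping_degree"),
                             densities = seq(0.02, 0.30, by = 0.01),
                             n_perm = 10000L, seed = 1L, q = 0.05,
                             weight_mode = "positive",
                             binarize_mode = "signed",
                             keep_null = NULL) {
  measure <- match.arg(measure)
  for (side in list(a, b)) {
    stopifnot(inherits(side$gray_matter, "regional_cohort"),
              inherits(side$amyloid, "regional_cohort"))
    if (!identical(side$gray_matter$region_names,
                   side$amyloid$region_names))
      stop_mxad("modalities disagree on region order")
  }
  if (!identical(a$gray_matter$region_names, b$gray_matter$region_names))
    stop_mxad("groups disagree on atlas")
  if (n_perm < 100L) stop_mxad("n_perm must be >= 100")
  regions <- a$gray_matter$region_names
  y_gm <- rbind(a$gray_matter$values, b$gray_matter$values)
  y_amy <- rbind(a$amyloid$values, b$amyloid$values)
  age <- c(a$gray_matter$age, b$gray_matter$age)
  sex <- c(a$gray_matter$sex, b$gray_matter$sex)
  n_a <- nrow(a$gray_matter$values)
  n_b <- nrow(b$gray_matter$values)
  if (min(n_a, n_b) < 6L)
    stop_mxad("groups must have >= 6 subjects (got %d, %d)", n_a, n_b)
  if (measure == "strength") densities <- NA_real_
  n_stat <- if (measure == "strength") 1L else length(densities)

  stat_of <- function(idx_a, idx_b) {
    group_measure_matrix(y_gm, y_amy, age, sex, idx_a, measure, densities,
                         weight_mode, binarize_mode) -
      group_measure_matrix(y_gm, y_amy, age, sex, idx_b, measure, densities,
                           weight_mode, binarize_mode)
  }

  obs <- stat_of(seq_len(n_a), n_a + seq_len(n_b))
  keep_null <- keep_null %||%
    (as.numeric(n_perm) * length(regions) * n_stat <= 2e7)
  exceed <- matrix(0L, length(regions), n_stat)
  null_store <- if (keep_null)
    array(NA_real_, c(n_perm, length(regions), n_stat)) else NULL
  with_local_seed(seed, {
    for (r in seq_len(n_perm)) {
      pi_a <- sample.int(n_a + n_b, n_a)
      d_null <- stat_of(pi_a, setdiff(seq_len(n_a + n_b), pi_a))
      exceed <- exceed + (abs(d_null) >= abs(obs))
      if (keep_null) null_store[r, , ] <- d_null
    }
  })
  p_raw <- (exceed + 1) / (n_perm + 1)
  p_mean <- average_p_across_densities(p_raw)
  mask <- fdr_bh(p_mean, q)
  dimnames(obs) <- dimnames(p_raw) <-
    list(regions, if (measure == "strength") "weighted" else
      formatC(densities, format = "g"))
  names(p_mean) <- names(mask) <- regions
  structure(list(measure = measure,
                 group_a = a$gray_matter$group[1L] %||% "A",
                 group_b = b$gray_matter$group[1L] %||% "B",
                 observed_diff = obs, null_diffs = null_store,
                 p_raw = p_raw, p_mean = p_mean, fdr_mask = mask,
                 q = q, densities = densities, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: %s vs %s, %d permutations\n  %d/%d regions significant at FDR q = %g\n",
    x$measure, x$group_a, x$group_b, x$n_perm, sum(x$fdr_mask),
    length(x$fdr_mask), x$q))
  invisible(x)
}

#' Average per-density p-values across the density grid
#'
#' Arithmetic mean per region over the densities at which a binary measure
#' was tested. A single column (the weighted case) passes through.
#'
#' @param p_raw Regions x densities matrix of p-values.
#' @return Numeric vector, one averaged p per region.
#' @export
average_p_across_densities <- function(p_raw) {
  p_raw <- as.matrix(p_raw)
  if (ncol(p_raw) < 1L) stop_mxad("no densities to average over")
  if (anyNA(p_raw)) {
    gaps <- which(colSums(is.na(p_raw)) > 0)
    stop_mxad("missing p-values at density column(s): %s",
              paste(gaps, collapse = ", "))
  }
  rowMeans(p_raw)
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control across the regions of one (measure, contrast)
#' family.
#'
#' @param p P-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical vector: `TRUE` where the region survives correction.
#' @export
fdr_bh <- function(p, q = 0.05) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}
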