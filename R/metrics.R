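# Apply the configured treatment of negative partial correlations before
# weighted sums. Default keeps positive weights only, matching the
# binarization convention and keeping strengths non-negative.
apply_weight_mode <- function(w, weight_mode = c("positive", "absolute", "raw")) {
  switch(match.arg(weight_mode),
         positive = pmax(w, 0),
         absolute = abs(w),
         raw = w)
}

#' Nodal overlapping strength of a weighted multiplex
#'
#' The sum of a node's connectivity strength over both layers:
#' `s_i = s_i^[1] + s_i^[2]` with `s_i^[alpha]` the weighted degree of node
#' `i` in layer `alpha`.
#'
#' @param mx A [weighted_multiplex()].
#' @param weight_mode Treatment of negative weights: `"positive"` (default,
#'   negatives set to 0), `"absolute"` or `"raw"`.
#' @return Named numeric vector, one strength per node.
#' @export
overlapping_strength <- function(mx, weight_mode = "positive") {
  stopifnot(inherits(mx, "weighted_multiplex"))
  w1 <- apply_weight_mode(mx$layers$gray_matter$weights, weight_mode)
  w2 <- apply_weight_mode(mx$layers$amyloid$weights, weight_mode)
  rowSums(w1) + rowSums(w2)
}

# Per-layer binary degrees; shared by the binary measures.
layer_degrees <- function(mx) {
  list(k1 = rowSums(mx$layers$gray_matter$adjacency),
       k2 = rowSums(mx$layers$amyloid$adjacency))
}

#' Nodal degree overlap of a binary multiplex
#'
#' Counts, for each node, the edges present in both layers simultaneously:
#' `d_i = sum_j a_ij^[1] a_ij^[2]`.
#'
#' @param mx A [binary_multiplex()].
#' @return Named integer-valued vector per node.
#' @export
degree_overlap <- function(mx) {
  stopifnot(inherits(mx, "binary_multiplex"))
  rowSums(mx$layers$gray_matter$adjacency * mx$layers$amyloid$adjacency)
}

#' Nodal multiplex participation coefficient
#'
#' Measures how evenly a node's edges distribute over the two layers:
#' `p_i = (M / (M - 1)) * (1 - sum_alpha (k_i^[alpha] / o_i)^2)` with
#' `o_i = k_i^[1] + k_i^[2]` the overlapping degree and `M = 2` layers.
#' Equal nonzero degrees give `p_i = 1`; degree confined to one layer gives
#' `p_i = 0`. Nodes isolated in both layers (`o_i = 0`, the expression is
#' 0/0) are assigned 0 and flagged via the `isolated` attribute.
#'
#' @param mx A [binary_multiplex()].
#' @return Numeric vector in [0, 1] per node.
#' @export
multiplex_participation <- function(mx) {
  stopifnot(inherits(mx, "binary_multiplex"))
  k <- layer_degrees(mx)
  o <- k$k1 + k$k2
  p <- numeric(length(o))
  nz <- o > 0
  p[nz] <- 2 * (1 - (k$k1[nz] / o[nz])^2 - (k$k2[nz] / o[nz])^2)
  names(p) <- names(k$k1)
  attr(p, "isolated") <- which(!nz)
  p
}

#' Nodal multiplex clustering coefficient
#'
#' Ratio of 2-triangles (triangles using edges from both layers: `i-j` and
#' `m-i` in layer alpha, `j-m` in the other layer beta) to 1-triads centered
#' on the node:
#' `c_i = num_i / ((M - 1) * sum_alpha k_i^[alpha] (k_i^[alpha] - 1))`
#' where `num_i` sums `(a_ij^[alpha] a_jm^[beta] a_mi^[alpha])^(1/3)` over
#' ordered layer pairs `alpha != beta` and ordered node pairs `j != m`
#' (both distinct from `i`). With binary adjacency the cube root is the
#' identity; it is retained in the definition for weighted generality.
#' Nodes with zero denominator get 0.
#'
#' @param mx A [binary_multiplex()].
#' @return Numeric vector in [0, 1] per node.
#' @export
multiplex_clustering <- function(mx) {
  stopifnot(inherits(mx, "binary_multiplex"))
  a1 <- mx$layers$gray_matter$adjacency
  a2 <- mx$layers$amyloid$adjacency
  # diagonal of A^[alpha] A^[beta] A^[alpha] counts ordered (j, m) walks
  # i-j-m-i; j = m is impossible (zero diagonal), j,m != i likewise.
  num <- diag(a1 %*% a2 %*% a1) + diag(a2 %*% a1 %*% a2)
  k <- layer_degrees(mx)
  den <- (2 - 1) * (k$k1 * (k$k1 - 1) + k$k2 * (k$k2 - 1))
  c_i <- ifelse(den > 0, num / den, 0)
  names(c_i) <- names(k$k1)
  c_i
}

#' Binary nodal metrics over a density sweep
#'
#' Computes degree overlap, multiplex participation, multiplex clustering
#' and per-layer degrees for every density of a sweep, in a tidy long
#' format ready for density averaging and export.
#'
#' @param sweep Named list of [binary_multiplex()] from [density_sweep()].
#' @return Data frame with columns `density`, `measure`, `region`, `value`.
#' @export
metrics_over_sweep <- function(sweep) {
  if (length(sweep) == 0L) stop_mxad("empty density sweep")
  rows <- lapply(sweep, function(mx) {
    regions <- colnames(mx$layers$gray_matter$adjacency) %||%
      as.character(seq_len(mx$n_nodes))
    k <- layer_degrees(mx)
    vals <- list(degree_overlap = as.numeric(degree_overlap(mx)),
                 participation = as.numeric(multiplex_participation(mx)),
                 clustering = as.numeric(multiplex_clustering(mx)),
                 overlapping_degree = as.numeric(k$k1 + k$k2))
    do.call(rbind, lapply(names(vals), function(m) {
      data.frame(density = mx$density, measure = m, region = regions,
                 value = vals[[m]], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$density, out$measure, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
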