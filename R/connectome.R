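#' Weighted layer constructor
#'
#' A single layer of the multiplex: a symmetric N x N matrix of edge
#' weights with zero diagonal, entries in [-1, 1] (partial correlations).
#'
#' @param weights Symmetric numeric matrix, zero diagonal.
#' @param layer_tag `"gray_matter"` or `"amyloid"`.
#' @return Object of class `weighted_layer`.
#' @export
weighted_layer <- function(weights, layer_tag) {
  weights <- as.matrix(weights)
  if (!isSymmetric(unname(weights), tol = 1e-10))
    stop_mxad("layer weights must be symmetric")
  if (any(abs(diag(weights)) > 0)) stop_mxad("layer diagonal must be zero")
  if (any(abs(weights) > 1 + 1e-10))
    stop_mxad("layer weights must lie in [-1, 1]")
  structure(list(weights = weights, layer_tag = layer_tag),
            class = "weighted_layer")
}

#' Binary layer constructor
#' @param adjacency Symmetric 0/1 matrix, zero diagonal.
#' @param density Fraction of possible edges present.
#' @param layer_tag Layer label.
#' @return Object of class `binary_layer`.
#' @export
binary_layer <- function(adjacency, density, layer_tag) {
  adjacency <- as.matrix(adjacency)
  if (!all(adjacency %in% c(0, 1))) stop_mxad("adjacency must be 0/1")
  if (!isSymmetric(unname(adjacency))) stop_mxad("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop_mxad("adjacency diagonal must be zero")
  structure(list(adjacency = adjacency, density = density,
                 layer_tag = layer_tag),
            class = "binary_layer")
}

#' Two-layer weighted multiplex
#'
#' The weighted supra-adjacency representation: intra-layer matrices on the
#' diagonal blocks; interlayer identity coupling is implicit and
#' materialized only inside community detection.
#'
#' @param gray_matter,amyloid [weighted_layer()] objects sharing node count
#'   and order.
#' @return Object of class `weighted_multiplex`.
#' @export
weighted_multiplex <- function(gray_matter, amyloid) {
  stopifnot(inherits(gray_matter, "weighted_layer"),
            inherits(amyloid, "weighted_layer"))
  if (!identical(dim(gray_matter$weights), dim(amyloid$weights)))
    stop_mxad("layers must share node count")
  cn1 <- colnames(gray_matter$weights); cn2 <- colnames(amyloid$weights)
  if (!is.null(cn1) && !is.null(cn2) && !identical(cn1, cn2))
    stop_mxad("layers must share node order")
  structure(list(layers = list(gray_matter = gray_matter, amyloid = amyloid),
                 n_nodes = nrow(gray_matter$weights)),
            class = "weighted_multiplex")
}

#' Two-layer binary multiplex at a common density
#' @param gray_matter,amyloid [binary_layer()] objects with equal edge counts.
#' @return Object of class `binary_multiplex`.
#' @export
binary_multiplex <- function(gray_matter, amyloid) {
  stopifnot(inherits(gray_matter, "binary_layer"),
            inherits(amyloid, "binary_layer"))
  if (!identical(dim(gray_matter$adjacency), dim(amyloid$adjacency)))
    stop_mxad("layers must share node count")
  e1 <- sum(gray_matter$adjacency) / 2
  e2 <- sum(amyloid$adjacency) / 2
  if (e1 != e2)
    stop_mxad("density mismatch: %d vs %d edges", e1, e2)
  structure(list(layers = list(gray_matter = gray_matter, amyloid = amyloid),
                 n_nodes = nrow(gray_matter$adjacency),
                 density = gray_matter$density),
            class = "binary_multiplex")
}

#' Partial-correlation layer from a single-group cohort
#'
#' Edges are Pearson correlations of the age/sex-residualized regional
#' values for every region pair — the partial correlation between regions
#' given the covariates. The diagonal is zero.
#'
#' @param cohort A single-group [regional_cohort()].
#' @return A [weighted_layer()] tagged with the cohort's modality.
#' @export
partial_corr_layer <- function(cohort) {
  stopifnot(inherits(cohort, "regional_cohort"))
  n <- nrow(cohort$values)
  if (n < 3L + 3L)
    stop_mxad("need at least %d subjects for partial correlation", 6L)
  res <- residualize(cohort$values, cohort$age, cohort$sex)
  sds <- apply(res, 2L, stats::sd)
  tol <- 1e-10 * max(sds, 1)
  if (any(sds <= tol))
    stop_mxad("region '%s' is constant after residualization",
              cohort$region_names[which(sds <= tol)[1L]])
  w <- stats::cor(res)
  diag(w) <- 0
  dimnames(w) <- list(cohort$region_names, cohort$region_names)
  weighted_layer(w, cohort$modality)
}

#' Build the weighted multiplex for one diagnostic group
#'
#' Convenience wrapper: subsets both modality cohorts to `group`, builds the
#' two partial-correlation layers and assembles the multiplex.
#'
#' @param gray_matter,amyloid Full-cohort [regional_cohort()] objects.
#' @param group One of [group_levels()].
#' @return A [weighted_multiplex()].
#' @export
build_group_multiplex <- function(gray_matter, amyloid, group) {
  weighted_multiplex(partial_corr_layer(subset_group(gray_matter, group)),
                     partial_corr_layer(subset_group(amyloid, group)))
}

# Ranks of the upper-triangle weights: 1 = strongest edge. Ties broken by
# (weight desc, then lexicographic (i, j)) for reproducibility over float
# ties. mode = "signed" ranks raw weights (strongest positive correlations
# first); "absolute" ranks |w|.
edge_ranks <- function(weights, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  n <- nrow(weights)
  up <- upper_pairs(n)
  w <- weights[upper.tri(weights)]
  key <- if (mode == "absolute") abs(w) else w
  ord <- order(-key, up$i, up$j)
  rk <- integer(length(w))
  rk[ord] <- seq_along(w)
  list(rank = rk, i = up$i, j = up$j, w = w)
}

#' Binarize a weighted layer at a target density
#'
#' Keeps exactly `round(D * N * (N - 1) / 2)` edges: the `E` strongest by
#' signed weight (configurable to absolute value). Ties are broken by node
#' index, so the edge set is deterministic.
#'
#' @param layer A [weighted_layer()].
#' @param density Target density `D` in (0, 1).
#' @param mode `"signed"` (default, strongest positive correlations kept) or
#'   `"absolute"`.
#' @return A [binary_layer()] with exactly `E` edges.
#' @export
binarize_at_density <- function(layer, density, mode = "signed") {
  stopifnot(inherits(layer, "weighted_layer"), density > 0, density < 1)
  n <- nrow(layer$weights)
  n_pairs <- n * (n - 1) / 2
  e_target <- round(density * n_pairs)
  if (e_target < 1) stop_mxad("density %.4f keeps no edges", density)
  er <- edge_ranks(layer$weights, mode)
  keep <- er$rank <= e_target
  if (mode == "signed" && sum(er$w > 0) < e_target)
    warning(sprintf("layer %s: only %d positive weights for %d edges; %s",
                    layer$layer_tag, sum(er$w > 0), e_target,
                    "negative weights admitted by rank"), call. = FALSE)
  a <- matrix(0, n, n, dimnames = dimnames(layer$weights))
  a[cbind(er$i[keep], er$j[keep])] <- 1
  a <- a + t(a)
  binary_layer(a, density, layer$layer_tag)
}

#' Density sweep: binary multiplexes over a density grid
#'
#' Binarizes both layers independently at each density of the grid (default
#' 2% to 30% in 1% steps, 29 densities), so that at every density both
#' layers — and all groups processed with the same grid — have the same
#' number of edges.
#'
#' @param mx A [weighted_multiplex()].
#' @param d_min,d_max,step Density grid parameters.
#' @param mode Passed to [binarize_at_density()].
#' @return Named list of [binary_multiplex()], one per density; names are
#'   the density values.
#' @export
density_sweep <- function(mx, d_min = 0.02, d_max = 0.30, step = 0.01,
                          mode = "signed") {
  stopifnot(inherits(mx, "weighted_multiplex"), d_min < d_max)
  densities <- seq(d_min, d_max, by = step)
  out <- lapply(densities, function(d) {
    binary_multiplex(binarize_at_density(mx$layers$gray_matter, d, mode),
                     binarize_at_density(mx$layers$amyloid, d, mode))
  })
  names(out) <- formatC(densities, format = "g")
  out
}

#' Small-world index of a binary layer
#'
#' `sigma = (C / C_rand) / (L / L_rand)` with `C` the average clustering
#' coefficient, `L` the characteristic path length (computed on the largest
#' connected component if the graph is disconnected, with a flag), and the
#' `rand` terms means over degree-preserving (Maslov-Sneppen) rewired
#' references.
#'
#' @param layer A [binary_layer()].
#' @param n_random Number of rewired reference graphs.
#' @param seed Integer seed controlling the rewiring.
#' @return List with `sigma`, `C`, `L`, `C_rand`, `L_rand` and
#'   `disconnected` flag.
#' @export
small_world_index <- function(layer, n_random = 20L, seed = 1L) {
  stopifnot(inherits(layer, "binary_layer"))
  g <- igraph::graph_from_adjacency_matrix(layer$adjacency, mode = "undirected")
  comp <- igraph::components(g)
  disconnected <- comp$no > 1L
  if (max(comp$csize) < 0.9 * igraph::vcount(g))
    warning("largest component below 90% of nodes", call. = FALSE)
  measure <- function(gr) {
    cc <- igraph::transitivity(gr, type = "localaverage", isolates = "zero")
    sub <- igraph::largest_component(gr)
    list(C = cc, L = igraph::mean_distance(sub, directed = FALSE))
  }
  obs <- measure(g)
  rand <- with_local_seed(seed, {
    vapply(seq_len(n_random), function(k) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = 10 * igraph::ecount(g)))
      m <- measure(gr)
      c(m$C, m$L)
    }, numeric(2L))
  })
  c_rand <- mean(rand[1L, ]); l_rand <- mean(rand[2L, ])
  list(sigma = (obs$C / c_rand) / (obs$L / l_rand),
       C = obs$C, L = obs$L, C_rand = c_rand, L_rand = l_rand,
       disconnected = disconnected)
}
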