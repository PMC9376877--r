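#' Configuration for multilayer community detection
#'
#' @param gamma Resolution parameter, > 0. Larger values yield more,
#'   smaller communities. Default 1.
#' @param omega Inter-layer coupling weight, >= 0. Larger values pull a
#'   node's replicas in the two layers into the same community. Default 1.
#' @param n_restarts Number of seed-controlled restarts of the generalized
#'   Louvain optimizer; the best-modularity partition is kept (ties by
#'   first found). Default 100.
#' @param max_passes Safety cap on aggregation levels x sweeps before the
#'   optimizer reports non-convergence.
#' @param seed Integer seed controlling restart randomization.
#' @return List of class `modularity_config`.
#' @export
modularity_config <- function(gamma = 1, omega = 1, n_restarts = 100L,
                              max_passes = 1000L, seed = 1L) {
  stopifnot(gamma > 0, omega >= 0, n_restarts >= 1L)
  structure(list(gamma = gamma, omega = omega,
                 n_restarts = as.integer(n_restarts),
                 max_passes = as.integer(max_passes),
                 seed = as.integer(seed)),
            class = "modularity_config")
}

# Supra-modularity matrix for the two-layer multiplex:
# diagonal blocks W^[a] - gamma * s_i s_j / (2 m_a) (Newman-Girvan null,
# the closed-form expectation of strength-preserving edge randomization),
# off-diagonal blocks omega * I (identity interlayer coupling). Also
# returns 2*mu, the total weight including coupling, used to normalize Q.
supra_modularity_matrix <- function(mx, config, weight_mode = "positive") {
  stopifnot(inherits(mx, "weighted_multiplex"))
  n <- mx$n_nodes
  blocks <- lapply(mx$layers, function(ly) {
    w <- apply_weight_mode(ly$weights, weight_mode)
    two_m <- sum(w)
    if (two_m <= 0) stop_mxad("layer %s has zero total weight", ly$layer_tag)
    s <- rowSums(w)
    list(b = w - config$gamma * outer(s, s) / two_m, two_m = two_m)
  })
  b <- matrix(0, 2L * n, 2L * n)
  b[seq_len(n), seq_len(n)] <- blocks[[1L]]$b
  b[n + seq_len(n), n + seq_len(n)] <- blocks[[2L]]$b
  diag(b[seq_len(n), n + seq_len(n)]) <- config$omega
  b[n + seq_len(n), seq_len(n)] <- t(b[seq_len(n), n + seq_len(n)])
  list(B = b, two_mu = blocks[[1L]]$two_m + blocks[[2L]]$two_m +
         2 * config$omega * n)
}

as_label_matrix <- function(partition, n) {
  labels <- if (inherits(partition, "multilayer_partition"))
    partition$labels else partition
  labels <- as.matrix(labels)
  if (nrow(labels) != n || ncol(labels) != 2L)
    stop_mxad("partition must assign labels to %d nodes in 2 layers", n)
  labels
}

#' Two-layer modularity of a partition
#'
#' Evaluates the multilayer modularity quality function for a two-layer
#' multiplex: intra-layer terms `w_ij^[a] - gamma * w0_ij^[a]` with
#' Newman-Girvan null `w0_ij^[a] = s_i^[a] s_j^[a] / (2 m^[a])`, plus an
#' interlayer reward `2 * omega` for every node whose replicas share a
#' community, all restricted to same-community pairs and normalized by the
#' total weight `2 * mu` (intra-layer weight of both layers plus
#' `2 * omega * N` coupling weight). Any positive rescaling of the
#' normalization leaves the optimizing partition unchanged; reported Q
#' values are comparable only under this convention.
#'
#' @param mx A [weighted_multiplex()].
#' @param partition A [multilayer_partition()] or an N x 2 label matrix
#'   (columns = layers) over a shared label space.
#' @param config A [modularity_config()].
#' @param weight_mode Treatment of negative weights (default positive-only).
#' @return Scalar Q.
#' @export
multilayer_modularity <- function(mx, partition, config = modularity_config(),
                                  weight_mode = "positive") {
  labels <- as_label_matrix(partition, mx$n_nodes)
  sm <- supra_modularity_matrix(mx, config, weight_mode)
  g <- c(labels[, 1L], labels[, 2L])
  same <- outer(g, g, "==")
  sum(sm$B[same]) / sm$two_mu
}

# One Louvain level: greedy local moving on modularity matrix B.
# Sweeps nodes in random order, moving each to the community with maximal
# gain, until a full sweep makes no move. Returns membership (consecutive
# integers) and whether anything moved.
louvain_pass <- function(B, max_sweeps) {
  n <- nrow(B)
  comm <- seq_len(n)
  moved_any <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in sample.int(n)) {
      b <- B[i, ]
      b[i] <- 0
      cs <- rowsum(b, comm)          # gain of joining each community
      own <- as.character(comm[i])
      best <- which.max(cs)
      best_lab <- as.integer(rownames(cs)[best])
      if (cs[best] > cs[own, 1L] + 1e-12 && best_lab != comm[i]) {
        comm[i] <- best_lab
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) return(list(comm = match(comm, unique(comm)),
                            moved = moved_any, sweeps = sweep))
  }
  NULL  # did not stabilize
}

# Full generalized Louvain on a supra-modularity matrix: local moving +
# aggregation, repeated until the partition is a fixed point.
genlouvain_once <- function(B, max_passes) {
  n0 <- nrow(B)
  membership <- seq_len(n0)
  passes <- 0L
  repeat {
    res <- louvain_pass(B, max_sweeps = max_passes)
    if (is.null(res))
      stop_mxad("generalized Louvain did not converge within %d sweeps (%d nodes)",
                max_passes, nrow(B))
    passes <- passes + res$sweeps
    if (passes > max_passes)
      stop_mxad("generalized Louvain exceeded %d passes", max_passes)
    membership <- res$comm[membership]
    if (!res$moved || max(res$comm) == nrow(B)) break
    agg <- rowsum(t(rowsum(B, res$comm)), res$comm)
    if (nrow(agg) == nrow(B)) break
    B <- agg
  }
  membership
}

#' Multilayer community detection by generalized Louvain
#'
#' Maximizes the two-layer modularity (see [multilayer_modularity()]) over
#' partitions of the 2N node-layer replicas by greedy local moving and
#' aggregation, iterated until the partition is a fixed point. The best of
#' `n_restarts` randomized restarts by Q is returned; identical seeds give
#' identical partitions. Community labels are shared across layers, so the
#' per-layer assignments are directly comparable and persistence is well
#' defined.
#'
#' @param mx A [weighted_multiplex()].
#' @param config A [modularity_config()].
#' @param weight_mode Treatment of negative weights (default positive-only).
#' @return A `multilayer_partition`: list with `labels` (N x 2 integer
#'   matrix, columns `gray_matter`/`amyloid`), `Q`, `n_communities`,
#'   `persistence` and `config`.
#' @export
louvain_multilayer <- function(mx, config = modularity_config(),
                               weight_mode = "positive") {
  stopifnot(inherits(mx, "weighted_multiplex"))
  n <- mx$n_nodes
  sm <- supra_modularity_matrix(mx, config, weight_mode)
  best <- NULL
  with_local_seed(config$seed, {
    for (r in seq_len(config$n_restarts)) {
      memb <- genlouvain_once(sm$B, config$max_passes)
      g <- match(memb, unique(memb))
      same <- outer(g, g, "==")
      q <- sum(sm$B[same]) / sm$two_mu
      if (is.null(best) || q > best$Q + 1e-12) best <- list(g = g, Q = q)
    }
  })
  labels <- cbind(gray_matter = best$g[seq_len(n)],
                  amyloid = best$g[n + seq_len(n)])
  rn <- colnames(mx$layers$gray_matter$weights)
  if (!is.null(rn)) rownames(labels) <- rn
  structure(list(labels = labels, Q = best$Q,
                 n_communities = length(unique(as.vector(labels))),
                 persistence = mean(labels[, 1L] == labels[, 2L]),
                 config = config),
            class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf(
    "<multilayer_partition> %d nodes, %d communities, Q = %.4f, persistence = %.3f (gamma = %g, omega = %g)\n",
    nrow(x$labels), x$n_communities, x$Q, x$persistence,
    x$config$gamma, x$config$omega))
  invisible(x)
}

#' Persistence of a two-layer partition
#'
#' The normalized count of nodes keeping the same community label in both
#' layers: between 0 (no node persists) and 1 (every node persists).
#'
#' @param partition A `multilayer_partition` or N x 2 label matrix.
#' @return Scalar in [0, 1].
#' @export
persistence <- function(partition) {
  labels <- if (inherits(partition, "multilayer_partition"))
    partition$labels else as.matrix(partition)
  if (ncol(labels) != 2L) stop_mxad("persistence is defined for two layers")
  mean(labels[, 1L] == labels[, 2L])
}

#' Normalized variation of information between two partitions
#'
#' `VI = H(A | B) + H(B | A)`, normalized by `log(N)`; 0 if and only if the
#' partitions are identical up to relabeling.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar normalized VI in [0, 1].
#' @export
variation_of_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_mxad("label vectors differ in length (%d vs %d)",
              length(labels_a), length(labels_b))
  n <- length(labels_a)
  if (n < 2L) return(0)
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- sum(tab[tab > 0] *
              log(tab[tab > 0] / outer(pa, pb)[as.matrix(tab) > 0]))
  vi <- ent(pa) + ent(pb) - 2 * mi
  max(0, vi) / log(n)
}

#' Resolution / coupling grid sweep with VI-based model selection
#'
#' Runs [louvain_multilayer()] at every (gamma, omega) grid point, computes
#' the pairwise normalized variation of information between all resulting
#' partitions (on the concatenated two-layer labels), and selects the grid
#' point whose partition has minimal mean VI distance to all others — a
#' stability criterion; the selection can be overridden downstream.
#'
#' @param mx A [weighted_multiplex()].
#' @param gammas,omegas Numeric grids (defaults: the study grids).
#' @param config Base [modularity_config()]; gamma/omega are overridden per
#'   grid point and restart seeds derived deterministically.
#' @return List with `partitions` (per grid point), `vi_matrix`
#'   (G x G, G = length(gammas) * length(omegas)), `table` (data frame:
#'   gamma, omega, Q, n_communities, persistence, mean_vi), and `selected`
#'   (row of `table` minimizing mean VI).
#' @export
sweep_gamma_omega <- function(mx,
                              gammas = c(0.5, 0.8, 0.9, 1, 1.1, 1.2, 2),
                              omegas = c(0.25, 0.5, 0.75, 1),
                              config = modularity_config()) {
  stopifnot(length(gammas) >= 1L, length(omegas) >= 1L)
  grid <- expand.grid(gamma = gammas, omega = omegas,
                      KEEP.OUT.ATTRS = FALSE)
  parts <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- modularity_config(gamma = grid$gamma[k], omega = grid$omega[k],
                             n_restarts = config$n_restarts,
                             max_passes = config$max_passes,
                             seed = derive_seed(config$seed, k))
    parts[[k]] <- louvain_multilayer(mx, cfg)
  }
  g <- nrow(grid)
  vi <- matrix(0, g, g)
  for (a in seq_len(g - 1L)) for (b in seq((a + 1L), g)) {
    vi[a, b] <- vi[b, a] <- variation_of_information(
      as.vector(parts[[a]]$labels), as.vector(parts[[b]]$labels))
  }
  tab <- data.frame(gamma = grid$gamma, omega = grid$omega,
                    Q = vapply(parts, `[[`, 0, "Q"),
                    n_communities = vapply(parts, `[[`, 0L, "n_communities"),
                    persistence = vapply(parts, `[[`, 0, "persistence"),
                    mean_vi = if (g > 1L) rowSums(vi) / (g - 1L) else 0)
  sel <- which.min(tab$mean_vi)
  list(partitions = parts, vi_matrix = vi, table = tab,
       selected = tab[sel, , drop = FALSE])
}
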