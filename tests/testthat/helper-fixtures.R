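# Fixture generators and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (explicit loops, no shared code
# with the implementation).

random_symmetric <- function(n, min = -1, max = 1) {
  w <- matrix(stats::runif(n * n, min, max), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

random_weighted_mx <- function(n) {
  weighted_multiplex(weighted_layer(random_symmetric(n), "gray_matter"),
                     weighted_layer(random_symmetric(n), "amyloid"))
}

random_binary_mx <- function(n, density = 0.3) {
  mk <- function(tag) {
    # signed weights may run out of positives at high density; that warning
    # path has its own test, silence it here
    suppressWarnings(
      binarize_at_density(weighted_layer(random_symmetric(n), tag), density))
  }
  binary_multiplex(mk("gray_matter"), mk("amyloid"))
}

# Binary multiplex straight from two adjacency matrices (equal edge count
# not required by the oracles; pad to equal count by construction).
mx_from_adjacency <- function(a1, a2) {
  d <- sum(a1) / (nrow(a1) * (nrow(a1) - 1))
  binary_multiplex(binary_layer(a1, d, "gray_matter"),
                   binary_layer(a2, d, "amyloid"))
}

# Overlapping-strength oracle: explicit double loop over nodes and neighbours.
oracle_strength <- function(w1, w2) {
  n <- nrow(w1)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) s[i] <- s[i] + w1[i, j] + w2[i, j]
  }
  s
}

# Degree-overlap oracle: intersection of neighbour sets.
oracle_degree_overlap <- function(a1, a2) {
  n <- nrow(a1)
  vapply(seq_len(n), function(i) {
    length(intersect(which(a1[i, ] == 1), which(a2[i, ] == 1)))
  }, numeric(1))
}

# Participation-coefficient oracle: direct evaluation.
oracle_participation <- function(a1, a2) {
  n <- nrow(a1)
  vapply(seq_len(n), function(i) {
    k1 <- sum(a1[i, ]); k2 <- sum(a2[i, ]); o <- k1 + k2
    if (o == 0) return(0)
    2 * (1 - (k1 / o)^2 - (k2 / o)^2)
  }, numeric(1))
}

# Multiplex-clustering oracle: exhaustive enumeration over ordered layer pairs and
# ordered (j, m) node pairs.
oracle_clustering <- function(a1, a2) {
  n <- nrow(a1)
  layers <- list(a1, a2)
  vapply(seq_len(n), function(i) {
    num <- 0
    for (al in 1:2) for (be in 1:2) {
      if (be == al) next
      A <- layers[[al]]; B <- layers[[be]]
      for (j in seq_len(n)) for (m in seq_len(n)) {
        if (j == i || m == i || j == m) next
        num <- num + (A[i, j] * B[j, m] * A[m, i])^(1 / 3)
      }
    }
    k1 <- sum(a1[i, ]); k2 <- sum(a2[i, ])
    den <- k1 * (k1 - 1) + k2 * (k2 - 1)
    if (den == 0) 0 else num / den
  }, numeric(1))
}

# Normalized VI oracle from an explicit contingency table.
oracle_vi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  hx <- 0; hy <- 0; mi <- 0
  for (x in ua) {
    px <- sum(a == x) / n
    hx <- hx - px * log(px)
  }
  for (y in ub) {
    py <- sum(b == y) / n
    hy <- hy - py * log(py)
  }
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  (hx + hy - 2 * mi) / log(n)
}

# Benjamini-Hochberg step-up oracle: largest k with p_(k) <= k q / m.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(k)) mask[ord[seq_len(max(k))]] <- TRUE
  mask
}

# Tiny single-group cohort with random values for plumbing tests.
tiny_cohort <- function(n = 20, n_regions = 8, modality = "gray_matter",
                        group = "CN_Aneg", seed = 1) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n * n_regions, 10, 1), n)
  if (modality == "amyloid") vals <- abs(vals)
  regional_cohort(vals, modality,
                  paste0("r", seq_len(n_regions)),
                  sprintf("T%03d", seq_len(n)),
                  age = stats::runif(n, 60, 85),
                  sex = stats::rbinom(n, 1, 0.5),
                  tiv = if (modality == "gray_matter")
                    stats::runif(n, 1.3e6, 1.7e6) else NULL,
                  csf_abeta42 = stats::runif(n, 400, 1600),
                  group = rep(group, n))
}

# Two 6-node cliques joined by one edge; the classic planted two-community
# fixture used for Louvain ground truth.
two_clique_weights <- function() {
  w <- matrix(0, 12, 12)
  w[1:6, 1:6] <- 1
  w[7:12, 7:12] <- 1
  w[6, 7] <- w[7, 6] <- 1
  diag(w) <- 0
  w
}

# Index-subset of a regional_cohort (used to split one generated group into
# two exchangeable halves for null calibration).
cohort_subset_idx <- function(co, idx) {
  regional_cohort(co$values[idx, , drop = FALSE], co$modality,
                  co$region_names, co$subject_ids[idx], co$age[idx],
                  co$sex[idx],
                  tiv = if (is.null(co$tiv)) NULL else co$tiv[idx],
                  csf_abeta42 = co$csf_abeta42[idx],
                  group = co$group[idx])
}

# Two exchangeable pseudo-groups split from one generated group: the
# sharpest possible permutation null.
split_null_pair <- function(seed, n_half = 100L) {
  cfg <- synthetic_config(group_sizes = c(CN_Aneg = 2L * n_half),
                          effect_size = 0, seed = seed)
  syn <- generate_cohort(cfg)
  gm <- subset_group(syn$gray_matter, "CN_Aneg")
  amy <- subset_group(syn$amyloid, "CN_Aneg")
  i1 <- seq_len(n_half)
  i2 <- n_half + seq_len(n_half)
  list(a = list(gray_matter = cohort_subset_idx(gm, i1),
                amyloid = cohort_subset_idx(amy, i1)),
       b = list(gray_matter = cohort_subset_idx(gm, i2),
                amyloid = cohort_subset_idx(amy, i2)))
}
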