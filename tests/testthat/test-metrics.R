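test_that("overlapping strength matches the double-loop oracle and trivial cases", {
  set.seed(20)
  mx <- random_weighted_mx(6)
  s <- overlapping_strength(mx, weight_mode = "raw")
  expect_equal(unname(s), oracle_strength(mx$layers$gray_matter$weights,
                                          mx$layers$amyloid$weights),
               tolerance = 1e-12)
  # all-zero layers
  z <- weighted_layer(matrix(0, 5, 5), "gray_matter")
  z2 <- weighted_layer(matrix(0, 5, 5), "amyloid")
  expect_equal(unname(overlapping_strength(weighted_multiplex(z, z2))),
               rep(0, 5))
  # identical layers double the single-layer strength
  w <- abs(random_symmetric(7))
  mx2 <- weighted_multiplex(weighted_layer(w, "gray_matter"),
                            weighted_layer(w, "amyloid"))
  expect_equal(unname(overlapping_strength(mx2)), 2 * rowSums(w),
               tolerance = 1e-12)
})

test_that("weight handling modes treat negative correlations as configured", {
  w1 <- matrix(c(0, -0.5, -0.5, 0), 2)
  w2 <- matrix(c(0, 0.25, 0.25, 0), 2)
  mx <- weighted_multiplex(weighted_layer(w1, "gray_matter"),
                           weighted_layer(w2, "amyloid"))
  expect_equal(unname(overlapping_strength(mx, "positive")), c(0.25, 0.25))
  expect_equal(unname(overlapping_strength(mx, "absolute")), c(0.75, 0.75))
  expect_equal(unname(overlapping_strength(mx, "raw")), c(-0.25, -0.25))
})

test_that("degree overlap equals the neighbour-set-intersection oracle", {
  set.seed(21)
  for (rep in 1:20) {
    mx <- random_binary_mx(8, density = runif(1, 0.2, 0.5))
    a1 <- mx$layers$gray_matter$adjacency
    a2 <- mx$layers$amyloid$adjacency
    expect_equal(unname(degree_overlap(mx)), oracle_degree_overlap(a1, a2))
  }
  # identical layers: overlap = degree; disjoint layers: overlap = 0
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1
  b <- matrix(0, 4, 4); b[1, 3] <- b[3, 1] <- b[2, 4] <- b[4, 2] <- 1
  expect_equal(unname(degree_overlap(mx_from_adjacency(a, a))), rowSums(a))
  expect_equal(unname(degree_overlap(mx_from_adjacency(a, b))), rep(0, 4))
})

test_that("participation hits its analytic boundary values", {
  # equal nonzero degrees in both layers -> 1
  a <- matrix(0, 5, 5); a[1, 2:4] <- 1; a <- a + t(a)
  b <- matrix(0, 5, 5); b[1, c(2, 3, 5)] <- 1; b <- b + t(b)
  p <- multiplex_participation(mx_from_adjacency(a, b))
  expect_equal(unname(p[1]), 1)
  # density-matched 6-node fixture: node 1 has k1 = 1, k2 = 3 -> 0.75;
  # node 5 has degree in layer 1 only -> 0
  a2 <- matrix(0, 6, 6)
  a2[1, 2] <- a2[5, 6] <- a2[3, 4] <- 1
  a2 <- a2 + t(a2)
  b2 <- matrix(0, 6, 6)
  b2[1, 2:4] <- 1
  b2 <- b2 + t(b2)
  p2 <- multiplex_participation(mx_from_adjacency(a2, b2))
  expect_equal(unname(p2[1]), 0.75)
  expect_equal(unname(p2[5]), 0)
})

test_that("participation and clustering match oracles on many random multiplexes", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    mx <- random_binary_mx(n, density = runif(1, 0.2, 0.5))
    a1 <- mx$layers$gray_matter$adjacency
    a2 <- mx$layers$amyloid$adjacency
    expect_equal(as.numeric(multiplex_participation(mx)),
                 oracle_participation(a1, a2), tolerance = 1e-12)
    expect_equal(unname(multiplex_clustering(mx)),
                 oracle_clustering(a1, a2), tolerance = 1e-12)
  }
})

test_that("clustering is zero on trees and one on complete twin triangles", {
  # star (tree) in both layers: no triangles anywhere
  a <- matrix(0, 5, 5); a[1, 2:5] <- 1; a <- a + t(a)
  expect_equal(unname(multiplex_clustering(mx_from_adjacency(a, a))),
               rep(0, 5))
  # both layers complete on 3 nodes: every 2-triangle present
  k3 <- 1 - diag(3)
  expect_equal(unname(multiplex_clustering(mx_from_adjacency(k3, k3))),
               rep(1, 3))
})

test_that("multiplex measures are symmetric under layer swap and bounded", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    mx <- random_binary_mx(n, density = runif(1, 0.05, 0.5))
    sw <- binary_multiplex(
      binary_layer(mx$layers$amyloid$adjacency, mx$density, "gray_matter"),
      binary_layer(mx$layers$gray_matter$adjacency, mx$density, "amyloid"))
    expect_equal(unname(degree_overlap(mx)), unname(degree_overlap(sw)))
    expect_equal(as.numeric(multiplex_participation(mx)),
                 as.numeric(multiplex_participation(sw)), tolerance = 1e-12)
    expect_equal(unname(multiplex_clustering(mx)),
                 unname(multiplex_clustering(sw)), tolerance = 1e-12)
    p <- multiplex_participation(mx)
    cc <- multiplex_clustering(mx)
    k <- list(k1 = rowSums(mx$layers$gray_matter$adjacency),
              k2 = rowSums(mx$layers$amyloid$adjacency))
    expect_true(all(p >= 0 & p <= 1 + 1e-12))
    expect_true(all(cc >= 0 & cc <= 1 + 1e-12))
    expect_true(all(degree_overlap(mx) <= pmin(k$k1, k$k2)))
    # binary multiplex viewed as 0/1 weights: strength == overlapping degree
    wmx <- weighted_multiplex(
      weighted_layer(mx$layers$gray_matter$adjacency * 1, "gray_matter"),
      weighted_layer(mx$layers$amyloid$adjacency * 1, "amyloid"))
    expect_equal(overlapping_strength(wmx), k$k1 + k$k2, ignore_attr = TRUE)
  }
})

test_that("sweep metrics table is complete and consistent with direct calls", {
  syn <- generate_cohort(synthetic_config(group_sizes = c(AD_Apos = 30L),
                                          seed = 24))
  mx <- build_group_multiplex(syn$gray_matter, syn$amyloid, "AD_Apos")
  sweep <- density_sweep(mx, 0.05, 0.10, 0.01)
  tab <- metrics_over_sweep(sweep)
  expect_equal(length(unique(tab$density)), 6)
  expect_equal(nrow(tab), 6 * 4 * 72)
  # spot-check one density against individually called operations
  d <- sweep[["0.07"]]
  sub <- tab[tab$density == 0.07 & tab$measure == "participation", ]
  sub <- sub[match(colnames(d$layers$gray_matter$adjacency), sub$region), ]
  expect_equal(sub$value, as.numeric(multiplex_participation(d)),
               tolerance = 1e-12)
  # permuting sweep order re-sorts to the same table
  tab2 <- metrics_over_sweep(rev(sweep))
  expect_equal(tab, tab2)
})
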