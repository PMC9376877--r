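two_clique_mx <- function() {
  w <- two_clique_weights()
  weighted_multiplex(weighted_layer(w, "gray_matter"),
                     weighted_layer(w, "amyloid"))
}

test_that("single-community modularity reduces to the coupling term at gamma 1", {
  mx <- two_clique_mx()
  labels <- cbind(rep(1, 12), rep(1, 12))
  cfg <- modularity_config(gamma = 1, omega = 1)
  w <- two_clique_weights()
  two_mu <- 2 * sum(w) + 2 * 1 * 12
  expect_equal(multilayer_modularity(mx, labels, cfg), 2 * 12 / two_mu,
               tolerance = 1e-12)
})

test_that("decoupled modularity equals the sum of single-layer NG modularities", {
  # two disconnected cliques per layer, clique partition, omega = 0
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1; diag(w) <- 0
  mx <- weighted_multiplex(weighted_layer(w, "gray_matter"),
                           weighted_layer(w, "amyloid"))
  labels <- cbind(rep(1:2, each = 4), rep(3:4, each = 4))
  cfg <- modularity_config(gamma = 1, omega = 0)
  q <- multilayer_modularity(mx, labels, cfg)
  # independent single-layer oracle under the shared normalization
  ng_single <- function(w, g) {
    s <- rowSums(w); two_m <- sum(w)
    b <- w - outer(s, s) / two_m
    sum(b[outer(g, g, "==")])
  }
  oracle <- (ng_single(w, labels[, 1]) + ng_single(w, labels[, 2])) /
    (2 * sum(w))
  expect_equal(q, oracle, tolerance = 1e-12)
})

test_that("modularity is invariant under global relabeling", {
  set.seed(30)
  mx <- random_weighted_mx(10)
  mx <- weighted_multiplex(
    weighted_layer(abs(mx$layers$gray_matter$weights), "gray_matter"),
    weighted_layer(abs(mx$layers$amyloid$weights), "amyloid"))
  labels <- cbind(sample(1:3, 10, TRUE), sample(1:3, 10, TRUE))
  relab <- matrix(c(7L, 9L, 5L)[labels], ncol = 2)
  cfg <- modularity_config()
  expect_equal(multilayer_modularity(mx, labels, cfg),
               multilayer_modularity(mx, relab, cfg), tolerance = 1e-12)
})

test_that("Louvain recovers planted cliques with full persistence", {
  mx <- two_clique_mx()
  part <- louvain_multilayer(mx, modularity_config(n_restarts = 10, seed = 1))
  expect_equal(part$n_communities, 2)
  expect_equal(part$persistence, 1)
  expect_identical(part$labels[, 1], part$labels[, 2])
  expect_equal(length(unique(part$labels[1:6, 1])), 1)
  expect_equal(length(unique(part$labels[7:12, 1])), 1)
  expect_false(part$labels[1, 1] == part$labels[12, 1])
  # optimizer dominance: random partitions never beat the Louvain optimum
  set.seed(31)
  for (k in 1:20) {
    rnd <- matrix(sample(1:4, 24, TRUE), ncol = 2)
    expect_lte(multilayer_modularity(mx, rnd, part$config), part$Q + 1e-12)
  }
})

test_that("Louvain is deterministic given the seed", {
  mx <- two_clique_mx()
  a <- louvain_multilayer(mx, modularity_config(n_restarts = 5, seed = 9))
  b <- louvain_multilayer(mx, modularity_config(n_restarts = 5, seed = 9))
  expect_identical(a$labels, b$labels)
  expect_identical(a$Q, b$Q)
})

test_that("strong coupling forces identical labels across layers", {
  # layers with deliberately different clique structure
  set.seed(32)
  w1 <- two_clique_weights()
  w2 <- w1[c(7:12, 1:6), c(7:12, 1:6)]  # relabeled cliques
  noise <- abs(random_symmetric(12)) * 0.05
  mx <- weighted_multiplex(weighted_layer(pmin(w1 + noise, 1), "gray_matter"),
                           weighted_layer(pmin(w2 + noise, 1), "amyloid"))
  part <- louvain_multilayer(mx, modularity_config(omega = 10,
                                                   n_restarts = 10, seed = 2))
  expect_equal(part$persistence, 1)
})

test_that("coupling pulls discordant layers toward shared structure", {
  # planted partitions differ across layers; omega = 1 should persist more
  # than omega = 0 on average over seeds
  pers <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    set.seed(s + 100)
    base1 <- two_clique_weights()
    perm <- sample(12)
    base2 <- base1[perm, perm]
    n1 <- abs(random_symmetric(12)) * 0.2
    n2 <- abs(random_symmetric(12)) * 0.2
    mx <- weighted_multiplex(
      weighted_layer(pmin(base1 + n1, 1), "gray_matter"),
      weighted_layer(pmin(base2 + n2, 1), "amyloid"))
    p0 <- louvain_multilayer(mx, modularity_config(omega = 0.001,
                                                   n_restarts = 5, seed = s))
    p1 <- louvain_multilayer(mx, modularity_config(omega = 1,
                                                   n_restarts = 5, seed = s))
    pers[s, ] <- c(p0$persistence, p1$persistence)
  }
  expect_gt(mean(pers[, 2]), mean(pers[, 1]))
})

test_that("persistence counts label agreement across layers", {
  expect_equal(persistence(cbind(1:10, 1:10)), 1)
  expect_equal(persistence(cbind(rep(1, 10), rep(2, 10))), 0)
  expect_equal(persistence(cbind(c(1, 1, 2, 2), c(1, 1, 3, 3))), 0.5)
})

test_that("normalized VI matches the contingency-table oracle", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(5, 5, 9, 9)), 0)
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(variation_of_information(a, b), oracle_vi(a, b),
               tolerance = 1e-12)
  set.seed(33)
  for (k in 1:50) {
    n <- sample(4:40, 1)
    x <- sample(1:4, n, TRUE); y <- sample(1:4, n, TRUE)
    expect_equal(variation_of_information(x, y), oracle_vi(x, y),
                 tolerance = 1e-12)
  }
  expect_error(variation_of_information(1:3, 1:4), "length")
})

test_that("gamma/omega sweep returns the full grid with a symmetric VI matrix", {
  mx <- two_clique_mx()
  res <- sweep_gamma_omega(mx, gammas = c(0.8, 1, 1.5),
                           omegas = c(0.5, 1),
                           config = modularity_config(n_restarts = 5, seed = 4))
  expect_length(res$partitions, 6)
  expect_equal(dim(res$vi_matrix), c(6, 6))
  expect_equal(res$vi_matrix, t(res$vi_matrix))
  expect_equal(diag(res$vi_matrix), rep(0, 6))
  expect_equal(nrow(res$selected), 1)
  # resolution property: community count non-decreasing in gamma on average
  tab <- res$table
  mean_by_gamma <- tapply(tab$n_communities, tab$gamma, mean)
  expect_true(all(diff(mean_by_gamma) >= 0))
})

test_that("default grid has the study dimensions: 7 gammas x 4 omegas", {
  g <- eval(formals(sweep_gamma_omega)$gammas)
  o <- eval(formals(sweep_gamma_omega)$omegas)
  expect_equal(g, c(0.5, 0.8, 0.9, 1, 1.1, 1.2, 2))
  expect_equal(o, c(0.25, 0.5, 0.75, 1))
})

test_that("empty layers are rejected", {
  z <- weighted_layer(matrix(0, 4, 4), "gray_matter")
  p <- weighted_layer(1 - diag(4), "amyloid")
  mx <- weighted_multiplex(z, p)
  expect_error(louvain_multilayer(mx), "zero total weight")
})
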