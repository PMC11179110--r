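test_that("Fisher transform is applied elementwise with a zero diagonal", {
  r <- eqcorr(3, 0.5)
  z <- correlation_to_z(r)
  expect_equal(z[1, 2], 0.5 * log(3))
  expect_equal(diag(z), rep(0, 3))
  expect_equal(correlation_to_z(diag(2) + 0)[1, 2], 0)
  bad <- r
  bad[1, 2] <- 0.6 # asymmetric
  expect_error(correlation_to_z(bad), "symmetric")
  r[1, 2] <- r[2, 1] <- 1
  expect_error(correlation_to_z(r), ">= 1")
})

test_that("MST backbone is the maximum-weight spanning tree", {
  # chain-structured weights: strong (i, i+1) links
  n <- 5
  w <- matrix(0.05, n, n)
  for (i in 1:(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 0.9
  diag(w) <- 0
  bb <- mst_backbone(w)
  expect_equal(bb[order(bb[, 1]), ], cbind(1:4, 2:5), ignore_attr = TRUE)

  # brute force over all spanning trees at N = 6
  set.seed(7)
  w6 <- matrix(0, 6, 6)
  w6[upper.tri(w6)] <- runif(15)
  w6 <- w6 + t(w6)
  bb6 <- mst_backbone(w6)
  expect_equal(sum(w6[bb6]), bf_max_spanning_tree_weight(w6), tolerance = 1e-12)

  # uniform weights: deterministic spanning tree with N-1 edges
  u <- matrix(1, 6, 6); diag(u) <- 0
  b1 <- mst_backbone(u); b2 <- mst_backbone(u)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 5L)
  expect_error(mst_backbone(matrix(0, 1, 1)), "at least 2 nodes")
})

test_that("proportional thresholding keeps exact edge counts and connectivity", {
  z <- random_z_matrix(10, 2)
  tg <- threshold_at_density(z, 0.2)
  expect_equal(tg$n_edges, 9L) # round(0.2 * 45) = 9 = N - 1, MST only
  expect_equal(tg$adjacency[tg$backbone], pmax(z, 0)[tg$backbone])

  for (s in 1:20) {
    z <- random_z_matrix(25, s + 100)
    for (d in c(0.2, 0.3, 0.4)) {
      tg <- threshold_at_density(z, d)
      m <- 25 * 24 / 2
      expect_equal(tg$n_edges, round(d * m))
      a <- tg$adjacency
      expect_true(all(a[tg$backbone] > 0)) # backbone inside the edge set
      ig <- igraph::graph_from_adjacency_matrix((a > 0) * 1, mode = "undirected")
      expect_true(igraph::is_connected(ig))
    }
  }
  expect_error(threshold_at_density(random_z_matrix(10, 1), 0.05), "MST floor")
  tg_full <- threshold_at_density(abs(random_z_matrix(8, 3)), 1.0)
  expect_equal(tg_full$n_edges, 28L)
})

test_that("binary transitivity and efficiency match brute-force oracles", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(graph_transitivity(k3, "binary"), 1)
  s4 <- matrix(0, 5, 5); s4[1, 2:5] <- 1; s4 <- s4 + t(s4)
  expect_equal(graph_transitivity(s4, "binary"), 0)
  k4e <- matrix(1, 4, 4); diag(k4e) <- 0; k4e[1, 4] <- k4e[4, 1] <- 0
  expect_equal(graph_transitivity(k4e, "binary"), bf_transitivity(k4e))
  expect_equal(graph_efficiency(k3, "binary"), 1)
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  expect_equal(graph_efficiency(p3, "binary"), 5 / 6)

  for (s in 1:15) {
    n <- sample(4:7, 1)
    a <- random_connected_graph(n, 0.5, s + 500)
    expect_equal(graph_transitivity(a, "binary"), bf_transitivity(a),
                 tolerance = 1e-12)
    expect_equal(graph_efficiency(a, "binary"), bf_efficiency(a),
                 tolerance = 1e-12)
  }
  # adding an edge never decreases efficiency
  a <- random_connected_graph(7, 0.3, 9)
  miss <- which(a == 0 & upper.tri(a), arr.ind = TRUE)[1, ]
  a2 <- a; a2[miss[1], miss[2]] <- a2[miss[2], miss[1]] <- 1
  expect_gte(graph_efficiency(a2, "binary"), graph_efficiency(a, "binary"))
  expect_error(graph_transitivity(diag(0, 3), "binary"), "degree")
})

test_that("weighted metrics rescale weights and agree with binary on 0/1 graphs", {
  a <- random_connected_graph(7, 0.5, 11)
  expect_equal(graph_transitivity(a, "weighted"), graph_transitivity(a, "binary"))
  expect_equal(graph_efficiency(a, "weighted"), graph_efficiency(a, "binary"))
  # scale invariance of the weighted variants
  w <- a * 0.37
  expect_equal(graph_transitivity(w, "weighted"), graph_transitivity(a, "weighted"))
  expect_equal(graph_efficiency(w, "weighted"), graph_efficiency(a, "weighted"))
})

test_that("Louvain finds known partitions and never beats exhaustive search", {
  two_k4 <- matrix(0, 8, 8)
  two_k4[1:4, 1:4] <- 1; two_k4[5:8, 5:8] <- 1; diag(two_k4) <- 0
  out <- louvain_q(two_k4, n_restarts = 10, seed = 1)
  expect_equal(out$q, 0.5)
  expect_equal(length(unique(out$partition)), 2L)
  expect_true(all(out$partition[1:4] == out$partition[1]))
  expect_true(all(out$partition[5:8] == out$partition[5]))

  for (s in 1:3) {
    a <- random_connected_graph(8, 0.35, s + 900)
    q_louvain <- louvain_q(a, n_restarts = 20, seed = s)$q
    expect_lte(q_louvain, bf_max_modularity(a) + 1e-9)
  }
  # determinism under seed
  a <- random_connected_graph(12, 0.3, 77)
  expect_identical(louvain_q(a, 10, 5), louvain_q(a, 10, 5))
})

test_that("Louvain recovers planted blocks in noisy stochastic block graphs", {
  ari <- vapply(1:20, function(s) {
    set.seed(s + 300)
    n <- 40
    lab <- rep(1:4, each = 10)
    pmat <- ifelse(outer(lab, lab, "=="), 0.9, 0.05)
    a <- matrix(0, n, n)
    iu <- upper.tri(a)
    a[iu] <- rbinom(sum(iu), 1, pmat[iu])
    a <- a + t(a)
    part <- louvain_q(a, n_restarts = 10, seed = s)$partition
    adjusted_rand(part, lab)
  }, numeric(1))
  expect_gte(mean(ari >= 0.95), 0.95)
})

test_that("participation coefficient matches closed-form fixtures", {
  # node 1: one edge into each of two modules -> PC = 0.5
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[1, 3] <- 1
  a[4, 5] <- 1
  a[2, 3] <- 1
  a <- a + t(a)
  mods <- c("A", "A", "B", "B", "B")
  pc <- participation_coefficient(a, mods)
  expect_equal(pc[1], 0.5)
  # degree-4 node spread evenly over 4 modules -> 0.75
  b <- matrix(0, 9, 9)
  b[1, 2:5] <- 1
  for (i in 6:9) b[i - 4, i] <- 1 # keep others non-isolated
  b <- b + t(b)
  mods4 <- c("m1", "m1", "m2", "m3", "m4", "m1", "m2", "m3", "m4")
  expect_equal(participation_coefficient(b, mods4)[1], 0.75)
  # all edges inside own module -> 0
  c3 <- matrix(0, 6, 6)
  c3[1:3, 1:3] <- 1; c3[4:6, 4:6] <- 1; diag(c3) <- 0
  expect_equal(participation_coefficient(c3, rep(c("x", "y"), each = 3))[1], 0)
  expect_error(participation_coefficient(a, mods[1:3]), "every node")
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_error(participation_coefficient(iso, c("a", "a", "b")), "isolated")
})

test_that("degree-preserving null keeps degrees and weights, randomizes structure", {
  z <- abs(random_z_matrix(20, 5))
  tg <- threshold_at_density(z, 0.3)
  a <- tg$adjacency
  nl <- degree_preserving_null(tg, n_swaps_per_edge = 10, seed = 3)
  expect_equal(rowSums(nl > 0), rowSums(a > 0))
  expect_equal(sort(nl[upper.tri(nl) & nl > 0]), sort(a[upper.tri(a) & a > 0]))
  expect_gt(attr(nl, "accepted"), 0)
  # complete graph: no legal swaps
  kn <- matrix(1, 6, 6); diag(kn) <- 0
  expect_warning(out <- degree_preserving_null(kn, 10, 1), "saturation")
  expect_equal(out, kn, ignore_attr = TRUE)

  # ring lattice clustering collapses toward random level after rewiring
  n <- 20
  ring <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  t_ring <- graph_transitivity(ring, "binary")
  t_null <- vapply(1:20, function(s)
    graph_transitivity(degree_preserving_null(ring, 10, seed = s), "binary"),
    numeric(1))
  expect_lt(mean(t_null), t_ring)
})

test_that("null-normalized metrics are calibrated on random graphs", {
  # an ER-like graph is its own null class: ratios near 1
  a <- random_connected_graph(30, 0.3, 13) * 1
  nm <- normalized_metrics(a, k_nulls = 10, seed = 2, mode = "binary")
  expect_lt(abs(nm$transitivity_norm - 1), 3 * nm$null_sd["transitivity"] /
              nm$null_mean["transitivity"] + 0.05)
  expect_lt(abs(nm$efficiency_norm - 1), 0.1)
  # a modular graph has excess clustering
  spec <- network_spec(n_nodes = 40, module_sizes = rep(10, 4),
                       within_corr = 0.6, between_corr = 0.1,
                       subject_noise_sd = 0, group_delta = 0, seed = 1)
  coh <- simulate_connectomes(spec, c(1, 1))
  tg <- threshold_at_density(coh$z[[1]], 0.25)
  nm2 <- normalized_metrics(tg, k_nulls = 10, seed = 4)
  expect_gt(nm2$transitivity_norm, 1)
})

test_that("density sweep produces complete, consistent profiles", {
  spec <- network_spec(n_nodes = 45, module_sizes = c(18, 12, 9, 6),
                       within_corr = 0.5, between_corr = 0.1,
                       subject_noise_sd = 0.08, group_delta = 0.1, seed = 6)
  coh <- simulate_connectomes(spec, c(3, 3))
  prof <- density_sweep(coh, densities = c(0.2, 0.3, 0.4), k_nulls = 3,
                        seed = 9, louvain_restarts = 5)
  expect_equal(nrow(prof$global), 6 * 3)
  expect_equal(sort(unique(prof$global$density)), c(0.2, 0.3, 0.4))
  expect_equal(nrow(prof$parcel_pc), 6 * 3 * 4)
  # parcel PC profiles at nearby densities are strongly rank-correlated
  pp <- prof$parcel_pc
  wide <- reshape(pp, idvar = c("subject", "module"), timevar = "density",
                  direction = "wide")
  expect_gt(cor(wide$pc.0.2, wide$pc.0.3, method = "spearman"), 0.8)
  expect_gt(cor(wide$pc.0.3, wide$pc.0.4, method = "spearman"), 0.8)
  # empty sweep: no error, empty tables
  empty <- density_sweep(coh, densities = numeric(0), k_nulls = 2, seed = 1)
  expect_equal(nrow(empty$global), 0L)
  expect_equal(nrow(empty$parcel_pc), 0L)
  # invalid subject matrix aborts with the subject id
  coh$z[[2]][1, 2] <- coh$z[[2]][1, 2] + 1
  expect_error(density_sweep(coh, densities = 0.3, k_nulls = 2, seed = 1),
               "s002")
})

test_that("group metric tests and PC-g correlations flag planted structure", {
  spec <- network_spec(n_nodes = 45, module_sizes = rep(15, 3),
                       within_corr = 0.55, between_corr = 0.1,
                       subject_noise_sd = 0.05, group_delta = 0.15, seed = 2)
  coh <- simulate_connectomes(spec, c(12, 12))
  prof <- density_sweep(coh, densities = 0.3, k_nulls = 4, seed = 3,
                        louvain_restarts = 5)
  gt <- group_metric_tests(prof, alpha = 0.05, n_perm = 2000, seed = 1)
  q_row <- gt$global[gt$global$metric == "modularity_q", ]
  expect_lt(q_row$mean_patient, q_row$mean_control)
  expect_true(all(gt$parcel$mean_patient > gt$parcel$mean_control))
  expect_true(all(c("p", "p_adj", "significant") %in% names(gt$global)))

  # PC-g: a fake module equal to g correlates perfectly
  set.seed(4)
  g <- rnorm(24)
  pc_mat <- cbind(M1 = g, M2 = rnorm(24), M3 = rnorm(24))
  out <- pc_g_correlation(pc_mat, g, rep(0:1, each = 12))
  expect_equal(out$rho[out$module == "M1"], c(1, 1))
  expect_error(pc_g_correlation(pc_mat[1:7, ], g[1:7], c(rep(0, 4), rep(1, 3))),
               "n < 4")
})
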