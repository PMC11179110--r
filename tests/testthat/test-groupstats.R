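test_that("pooled Cohen's d reproduces the published effect-size table", {
  tab <- published_effect_sizes()
  d <- mapply(cohens_d, tab$mean_patient, tab$sd_patient, tab$n_patient,
              tab$mean_control, tab$sd_control, tab$n_control)
  expect_true(all(abs(d - tab$published_d) < 0.005))
  expect_equal(cohens_d(1, 1, 10, 1, 1, 10), 0)
  expect_error(cohens_d(1, 0, 10, 2, 0, 10), "pooled variance")
})

test_that("permutation test is exact on small samples", {
  expect_equal(permutation_test(c(1, 2, 3, 1, 2, 3),
                                c(0, 0, 0, 1, 1, 1))$p, 1)
  out <- permutation_test(c(10, 11, 12, 0, 1, 2), c(1, 1, 1, 0, 0, 0))
  expect_equal(out$method, "exact")
  expect_equal(out$p, 2 / 20)
  expect_warning(p0 <- permutation_test(rep(5, 8), rep(0:1, 4)), "constant")
  expect_equal(p0$p, 1)
})

test_that("sampled permutation p is stable across seeds", {
  set.seed(1)
  v <- c(rnorm(12, 0.8), rnorm(12))
  g <- rep(1:0, each = 12)
  p1 <- permutation_test(v, g, n_perm = 10000, seed = 1)
  p2 <- permutation_test(v, g, n_perm = 10000, seed = 2)
  expect_equal(p1$method, "sampled")
  expect_lt(abs(p1$p - p2$p), 0.01)
})

test_that("Fisher discriminant direction and separation are correct", {
  # strong covariance: w must depart from the mean-difference direction
  set.seed(42)
  n <- 4000
  sig <- matrix(c(1, 0.9, 0.9, 1), 2)
  ch <- chol(sig)
  x0 <- matrix(rnorm(2 * n), n) %*% ch
  x1 <- sweep(matrix(rnorm(2 * n), n) %*% ch, 2, c(1, 0), "+")
  x <- rbind(x0, x1)
  g <- rep(0:1, each = n)
  fit <- lda_fit(x, g)
  # hand-solved S^-1 (mu1 - mu0) for Sigma = [[1,.9],[.9,1]], dmu = (1,0):
  # direction prop to (5.263, -4.737); sign flipped so controls score higher
  dir <- fit$direction / fit$direction[1]
  expect_equal(unname(dir[2]), -4.737 / 5.263, tolerance = 0.1)
  # projected separation equals the empirical Mahalanobis distance
  s <- ((n - 1) * cov(x0) + (n - 1) * cov(x1)) / (2 * n - 2)
  dmu <- colMeans(x1) - colMeans(x0)
  expect_equal(unname(fit$mahalanobis), sqrt(drop(t(dmu) %*% solve(s) %*% dmu)),
               tolerance = 1e-8)
  # identical scores (up to sign/scale) as the reference implementation
  ml <- MASS::lda(x, grouping = g)
  ref <- as.numeric(predict(ml)$x)
  expect_equal(abs(cor(fit$scores, ref)), 1, tolerance = 1e-10)
})

test_that("the discriminant dominates every single input on training data", {
  wins <- vapply(1:50, function(s) {
    tab <- simulate_battery(battery_spec(n_per_group = 40, seed = s,
                                         loadings = rep(0.6, 5)))
    x <- as.matrix(tab[attr(tab, "tests")])
    fit <- lda_fit(x, tab$group)
    d_proj <- abs(diff(tapply(fit$scores, tab$group, mean))) /
      sqrt(((39) * var(fit$scores[tab$group == 0]) +
            (39) * var(fit$scores[tab$group == 1])) / 78)
    d_each <- apply(x, 2, function(v)
      cohens_d(mean(v[tab$group == 1]), sd(v[tab$group == 1]), 40,
               mean(v[tab$group == 0]), sd(v[tab$group == 0]), 40))
    d_proj >= max(d_each) - 1e-10
  }, logical(1))
  expect_true(all(wins))
})

test_that("LDA correlates with g more than any single test on shift-only batteries", {
  hits <- vapply(1:50, function(s) {
    tab <- simulate_battery(battery_spec(n_per_group = 200, seed = s))
    fit <- gfactor(tab)
    ld <- lda_fit(as.matrix(tab[attr(tab, "tests")]), tab$group)
    cmp <- lda_vs_g(ld, fit$g, tab[attr(tab, "tests")])
    cmp$g_beats_all_tests
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("g fed as the only LDA feature projects onto itself", {
  tab <- simulate_battery(battery_spec(n_per_group = 30, seed = 8))
  fit <- gfactor(tab)
  ld <- lda_fit(matrix(fit$g, ncol = 1), tab$group)
  expect_equal(abs(cor(ld$scores, fit$g)), 1, tolerance = 1e-12)
})

test_that("adjusting for g nulls a measure that is pure g", {
  tab <- simulate_battery(battery_spec(n_per_group = 25, seed = 4))
  g <- attr(tab, "latent")
  out <- adjust_for_g(2 * g, g, tab$group, n_perm = 500)
  expect_lt(max(abs(out$adjusted)), 1e-10)
  expect_equal(out$p_after, 1)
  # residual orthogonality to g for a generic measure
  v <- 0.5 * g + rnorm(length(g))
  out2 <- adjust_for_g(v, g, tab$group, n_perm = 500)
  expect_lt(abs(sum(out2$adjusted * g)), 1e-8)
})

test_that("g-adjustment keeps independent group effects and calibrates under the null", {
  reject <- matrix(NA, 30, 3,
                   dimnames = list(NULL, c("before", "after", "null_after")))
  for (s in 1:30) {
    set.seed(s + 1000)
    n <- 100
    grp <- rep(0:1, each = n)
    f <- rnorm(2 * n)
    delta <- 0.8
    v_effect <- 0.8 * f + delta * grp + rnorm(2 * n, sd = 0.6)
    v_null <- 0.8 * f + rnorm(2 * n, sd = 0.6)
    out <- adjust_for_g(v_effect, f, grp, n_perm = 400, seed = s)
    out_null <- adjust_for_g(v_null, f, grp, n_perm = 400, seed = s)
    reject[s, ] <- c(out$p_before < 0.05, out$p_after < 0.05,
                     out_null$p_after < 0.05)
  }
  expect_gte(mean(reject[, "before"]), 0.8)
  expect_gte(mean(reject[, "after"]), 0.8)
  expect_lte(mean(reject[, "null_after"]), 0.2) # approx alpha
})

test_that("associate dispatches on the declared covariate type", {
  set.seed(99)
  g <- rnorm(1000)
  self <- associate(g, g, "pearson")
  expect_equal(self$estimate, 1)
  expect_lt(self$p, 1e-10)
  indep <- associate(g, rnorm(1000), "pearson")
  expect_lt(abs(indep$estimate), 0.1)
  y <- g + rnorm(1000)
  expect_equal(associate(g, y, "spearman")$estimate,
               associate(g, exp(y), "spearman")$estimate)
  f <- factor(ifelse(g + rnorm(1000) > 0, "a", "b"))
  tt <- associate(g, f, "t")
  expect_lt(tt$p, 1e-6)
  x2 <- associate(factor(g > 0), f, "chi2")
  expect_lt(x2$p, 1e-6)
  expect_error(associate(1:2, 1:2, "pearson"), "3 complete pairs")
})

test_that("effect_size_table mirrors the per-measure summary layout", {
  tab <- simulate_battery(battery_spec(n_per_group = 40, seed = 10))
  fit <- gfactor(tab)
  tab$g <- fit$g
  eff <- effect_size_table(tab, c("g", "T01"), n_perm = 500, seed = 1)
  expect_equal(eff$measure, c("g", "T01"))
  expect_true(all(eff$cohens_d >= 0))
  expect_true(all(eff$perm_p >= 0 & eff$perm_p <= 1))
  expect_equal(eff$mean_diff[1],
               mean(fit$g[tab$group == 1]) - mean(fit$g[tab$group == 0]))
})
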