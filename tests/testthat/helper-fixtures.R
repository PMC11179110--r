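# shared fixtures and independent brute-force oracles

eqcorr <- function(p, rho) {
  r <- matrix(rho, p, p)
  diag(r) <- 1
  r
}

one_factor_corr <- function(loadings) {
  r <- outer(loadings, loadings)
  diag(r) <- 1
  r
}

random_pd_corr <- function(p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(p * (p + 5)), p + 5, p)
  cov2cor(crossprod(x))
}

random_z_matrix <- function(n, seed) {
  z <- correlation_to_z(random_pd_corr(n, seed))
  z
}

# random connected binary graph as adjacency matrix
random_connected_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    iu <- upper.tri(a)
    a[iu] <- rbinom(sum(iu), 1, p_edge)
    a <- a + t(a)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::is_connected(ig) && sum(a) > 0 && max(rowSums(a)) >= 2) return(a)
  }
}

# triplet-census transitivity oracle: closed / connected ordered triplets
bf_transitivity <- function(a) {
  n <- nrow(a)
  closed <- 0
  triplets <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i != j && j != k && i != k && a[i, j] && a[i, k]) {
      triplets <- triplets + 1
      if (a[j, k]) closed <- closed + 1
    }
  }
  closed / triplets
}

# Floyd-Warshall global-efficiency oracle (binary)
bf_efficiency <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# enumerate all spanning trees of a complete weighted graph (small N)
bf_max_spanning_tree_weight <- function(w) {
  n <- nrow(w)
  iu <- which(upper.tri(w))
  ii <- row(w)[iu]; jj <- col(w)[iu]
  best <- -Inf
  sets <- combn(length(iu), n - 1)
  for (c in seq_len(ncol(sets))) {
    sel <- sets[, c]
    parent <- 1:n
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ri <- find(ii[e]); rj <- find(jj[e])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- max(best, sum(w[iu[sel]]))
  }
  best
}

# all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rgs
      return()
    }
    for (v in 1:(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxv, v))
    }
  }
  recurse(1, 0)
  out
}

# exhaustive maximum modularity over all partitions
bf_max_modularity <- function(w) {
  k <- rowSums(w)
  two_m <- sum(k)
  b <- w - outer(k, k) / two_m
  best <- -Inf
  for (p in all_partitions(nrow(w))) {
    q <- sum(b[outer(p, p, "==")]) / two_m
    if (q > best) best <- q
  }
  best
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

published_effect_sizes <- function() {
  read.csv(system.file("extdata", "tle_cognitive_effect_sizes.csv",
                       package = "gconnect"))
}
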