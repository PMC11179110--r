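#' Fisher z-transform a correlation matrix into a connectivity matrix
#'
#' Applies `atanh` elementwise to a symmetric correlation matrix and zeroes
#' the diagonal, the variance-stabilized form in which functional
#' connectivity enters graph construction.
#'
#' @param corr Symmetric matrix with off-diagonal entries strictly inside
#'   (-1, 1).
#' @return Symmetric zero-diagonal matrix of Fisher-z values.
#' @export
#' @examples
#' correlation_to_z(matrix(c(1, .5, .5, 1), 2))[1, 2] # 0.5 * log(3)
correlation_to_z <- function(corr) {
  check_square_symmetric(corr, what = "correlation matrix")
  off <- corr
  diag(off) <- 0
  if (max(abs(off)) >= 1) stop("off-diagonal |r| >= 1 cannot be Fisher-transformed")
  z <- atanh(off)
  diag(z) <- 0
  z
}

# apply the negative-weight policy before graph construction
apply_negative_policy <- function(z, policy = c("zero", "abs", "error")) {
  policy <- match.arg(policy)
  if (any(z < 0)) {
    z <- switch(policy,
      zero = pmax(z, 0),
      abs = abs(z),
      error = stop("negative connectivity weights present (negative_policy = 'error')"))
  }
  z
}

as_adjacency <- function(g) {
  if (inherits(g, "thresholded_graph")) g$adjacency else g
}

as_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Maximum-weight spanning tree backbone
#'
#' Kruskal's algorithm on edges ordered by decreasing weight with
#' lexicographic (i, j) tie-breaking, so the backbone is deterministic. This
#' is the minimum spanning tree under lengths 1/weight; it is retained inside
#' every thresholded graph to guarantee connectedness.
#'
#' @param z Connectivity matrix (symmetric, zero diagonal).
#' @param negative_policy How to treat negative weights before construction.
#' @return An (N-1) x 2 integer matrix of backbone edges, `i < j`.
#' @export
mst_backbone <- function(z, negative_policy = "zero") {
  z <- as_adjacency(z)
  check_square_symmetric(z, what = "connectivity matrix")
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 nodes")
  w <- apply_negative_policy(z, negative_policy)
  iu <- which(upper.tri(w))
  ii <- row(w)[iu]; jj <- col(w)[iu]; ww <- w[iu]
  ord <- order(-ww, ii, jj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]] # path halving
      x <- parent[x]
    }
    x
  }
  sel <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (e in ord) {
    ri <- find(ii[e]); rj <- find(jj[e])
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      sel[k, ] <- c(ii[e], jj[e])
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) stop("graph is not connectable: fewer than N-1 usable edges")
  sel
}

#' Proportional thresholding with an MST backbone
#'
#' Keeps the `round(density * N(N-1)/2)` strongest edges subject to always
#' containing the maximum-weight spanning tree, so the thresholded graph is
#' connected at any admissible density. Weights are retained on surviving
#' edges; negative weights are handled by `negative_policy` first (default:
#' zeroed, i.e. treated as absent).
#'
#' @param z Connectivity matrix.
#' @param density Target edge density in (0, 1]; must be at least the MST
#'   floor `(N-1) / (N(N-1)/2)`.
#' @param negative_policy `"zero"`, `"abs"` or `"error"`.
#' @return Object of class `thresholded_graph`: `adjacency` (weighted),
#'   `density` (requested), `density_actual`, `n_edges`, `backbone`.
#' @export
threshold_at_density <- function(z, density, negative_policy = "zero") {
  z <- as_adjacency(z)
  check_square_symmetric(z, what = "connectivity matrix")
  n <- nrow(z)
  w <- apply_negative_policy(z, negative_policy)
  m_all <- n * (n - 1) / 2
  n_edges <- round(density * m_all)
  if (n_edges < n - 1L)
    stop(sprintf("density %.3f is below the MST floor %.3f", density,
                 (n - 1) / m_all))
  bb <- mst_backbone(w)
  bb_w <- w[bb]
  if (any(bb_w <= 0))
    stop("spanning-tree backbone requires zero-weight edges; positive-weight graph is disconnected")
  adj <- matrix(0, n, n)
  adj[bb] <- bb_w
  extra <- n_edges - (n - 1L)
  if (extra > 0L) {
    iu <- which(upper.tri(w))
    in_bb <- matrix(FALSE, n, n)
    in_bb[bb] <- TRUE
    cand <- iu[!in_bb[iu] & w[iu] > 0]
    ii <- row(w)[cand]; jj <- col(w)[cand]; ww <- w[cand]
    ord <- order(-ww, ii, jj)
    take <- utils::head(ord, extra)
    if (length(take) < extra)
      warning("only ", length(take) + n - 1L, " positive edges available for ",
              n_edges, " requested")
    adj[cand[take]] <- ww[take]
  }
  adj <- adj + t(adj)
  got <- sum(adj[upper.tri(adj)] > 0)
  structure(
    list(adjacency = adj, density = density, density_actual = got / m_all,
         n_edges = got, backbone = bb),
    class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("Thresholded graph: %d nodes, %d edges (density %.3f requested, %.3f actual), MST backbone retained\n",
              nrow(x$adjacency), x$n_edges, x$density, x$density_actual))
  invisible(x)
}

#' Network transitivity (global clustering)
#'
#' Fraction of closed triangles to connected triplets,
#' `sum_i 2 t_i / sum_i k_i (k_i - 1)`. In weighted mode the triangle count
#' uses geometric-mean triangle intensities on weights rescaled to a maximum
#' of 1 (degrees stay binary).
#'
#' @param graph Thresholded graph or adjacency matrix.
#' @param mode `"weighted"` or `"binary"`.
#' @return Scalar in `[0, 1]`.
#' @export
graph_transitivity <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  w <- as_adjacency(graph)
  a <- (w > 0) * 1
  k <- rowSums(a)
  denom <- sum(k * (k - 1))
  if (denom == 0) stop("no node with degree >= 2")
  if (mode == "binary") {
    num <- sum(diag(a %*% a %*% a))
  } else {
    ws <- (w / max(w))^(1 / 3)
    num <- sum(diag(ws %*% ws %*% ws))
  }
  num / denom
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E = 1/(N(N-1)) * sum_{i != j} 1 / d_ij`. Binary mode uses hop counts;
#' weighted mode uses path lengths 1/weight on weights rescaled to a maximum
#' of 1 (so weighted efficiency of a complete unit-weight graph is 1).
#'
#' @inheritParams graph_transitivity
#' @return Scalar; in `[0, 1]` for binary mode.
#' @export
graph_efficiency <- function(graph, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  w <- as_adjacency(graph)
  n <- nrow(w)
  if (mode == "weighted") {
    w <- w / max(w)
    ig <- as_igraph(w)
    d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  } else {
    ig <- as_igraph((w > 0) * 1)
    d <- igraph::distances(ig)
  }
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Louvain modularity with seeded restarts
#'
#' Runs the Louvain local-move/aggregation algorithm from `n_restarts` random
#' node orders (via vertex permutation) and keeps the best-Q partition.
#' `Q = 1/(2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`.
#'
#' @param graph Thresholded graph or (weighted) adjacency matrix.
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed.
#' @return List with `q` and `partition` (integer membership vector).
#' @export
louvain_q <- function(graph, n_restarts = 100L, seed = 1L) {
  w <- as_adjacency(graph)
  check_square_symmetric(w, what = "adjacency")
  n <- nrow(w)
  ig <- as_igraph(w)
  with_seed(derive_seed(seed, "louvain"), {
    best_q <- -Inf
    best_part <- NULL
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)
      igp <- igraph::permute(ig, perm)
      cl <- igraph::cluster_louvain(igp, weights = igraph::E(igp)$weight)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        best_part <- igraph::membership(cl)[perm]
      }
    }
    list(q = best_q, partition = as.integer(best_part))
  })
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2` where `k_is` is node i's (weighted)
#' strength into module s of the given parcellation. 0 means all of a node's
#' connections stay inside its own module; values near 1 mean connections are
#' spread evenly across modules.
#'
#' @param graph Thresholded graph or adjacency matrix.
#' @param modules Module label per node (length N).
#' @param mode `"weighted"` (strengths) or `"binary"` (degrees).
#' @return Numeric vector of length N.
#' @export
participation_coefficient <- function(graph, modules, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  w <- as_adjacency(graph)
  if (mode == "binary") w <- (w > 0) * 1
  n <- nrow(w)
  if (length(modules) != n) stop("modules must assign every node")
  f <- as.factor(modules)
  if (nlevels(f) < 2L) stop("need at least 2 modules")
  ind <- stats::model.matrix(~ f - 1)
  ks <- w %*% ind
  k <- rowSums(w)
  if (any(k == 0)) stop("isolated node encountered (node ",
                        which(k == 0)[1], ")")
  1 - rowSums((ks / k)^2)
}

#' Degree-preserving randomized null graph
#'
#' Repeated double-edge swaps (rejecting self-loops and multi-edges) preserve
#' the degree sequence exactly; the original weight multiset is then shuffled
#' onto the rewired edges. Connectivity is verified after rewiring and the
#' swap sequence is re-drawn under a derived sub-seed if it was lost (rare at
#' the densities used here). If no legal swap exists (e.g. a complete graph)
#' the graph is returned unchanged with a saturation warning.
#'
#' @param graph Thresholded graph or adjacency matrix.
#' @param n_swaps_per_edge Attempted swaps per edge.
#' @param seed Integer seed.
#' @param require_connected Re-try (up to 10 times) until the null is
#'   connected, provided the input was.
#' @return Adjacency matrix with attributes `accepted` and `attempted`.
#' @export
degree_preserving_null <- function(graph, n_swaps_per_edge = 10L, seed = 1L,
                                   require_connected = TRUE) {
  w <- as_adjacency(graph)
  n <- nrow(w)
  iu <- which(upper.tri(w) & w > 0)
  m <- length(iu)
  if (m < 2L) stop("need at least 2 edges")
  edges <- cbind(row(w)[iu], col(w)[iu])
  weights <- w[iu]
  was_connected <- igraph::is_connected(as_igraph((w > 0) * 1))
  attempts <- as.integer(n_swaps_per_edge * m)
  for (try in seq_len(10L)) {
    res <- with_seed(derive_seed(seed, paste0("rewire", try)), {
      out <- rewire_degseq_cpp(edges, n, attempts)
      out$weights <- sample(weights)
      out
    })
    new_edges <- res$edges
    if (res$accepted == 0L) {
      warning("swap saturation: no legal double-edge swap accepted (",
              res$attempted, " attempts); returning graph unchanged")
      out <- w
      attr(out, "accepted") <- 0L
      attr(out, "attempted") <- res$attempted
      return(out)
    }
    adj <- matrix(0, n, n)
    adj[new_edges] <- res$weights
    adj <- adj + t(adj)
    if (!require_connected || !was_connected ||
        igraph::is_connected(as_igraph((adj > 0) * 1)))
      break
    if (try == 10L)
      warning("could not preserve connectivity after 10 rewiring attempts")
  }
  if (res$accepted < 0.05 * res$attempted)
    warning("low swap acceptance rate (", res$accepted, "/", res$attempted, ")")
  attr(adj, "accepted") <- res$accepted
  attr(adj, "attempted") <- res$attempted
  adj
}

#' Null-normalized global metrics
#'
#' Divides transitivity and global efficiency by their means over an ensemble
#' of degree-preserving null graphs — the standard correction that expresses
#' clustering and integration relative to a random network with the same
#' degree distribution.
#'
#' @param graph Thresholded graph or adjacency matrix.
#' @param k_nulls Ensemble size (>= 1).
#' @param seed Integer seed.
#' @param mode Metric mode, see [graph_transitivity()].
#' @param n_swaps_per_edge Passed to [degree_preserving_null()].
#' @return List with raw metrics, normalized metrics and null-ensemble means
#'   and SDs.
#' @export
normalized_metrics <- function(graph, k_nulls = 20L, seed = 1L,
                               mode = c("weighted", "binary"),
                               n_swaps_per_edge = 10L) {
  mode <- match.arg(mode)
  stopifnot(k_nulls >= 1L)
  t_raw <- graph_transitivity(graph, mode)
  e_raw <- graph_efficiency(graph, mode)
  nulls <- vapply(seq_len(k_nulls), function(k) {
    nm <- degree_preserving_null(graph, n_swaps_per_edge,
                                 seed = derive_seed(seed, paste0("null", k)))
    c(graph_transitivity(nm, mode), graph_efficiency(nm, mode))
  }, numeric(2))
  t_null <- mean(nulls[1, ]); e_null <- mean(nulls[2, ])
  if (t_null == 0 || e_null == 0) stop("null metric is zero; cannot normalize")
  list(transitivity_raw = t_raw, efficiency_raw = e_raw,
       transitivity_norm = t_raw / t_null, efficiency_norm = e_raw / e_null,
       null_mean = c(transitivity = t_null, efficiency = e_null),
       null_sd = c(transitivity = stats::sd(nulls[1, ]),
                   efficiency = stats::sd(nulls[2, ])))
}

validate_connectivity_matrix <- function(z, subject = "?") {
  if (!is.matrix(z) || nrow(z) != ncol(z))
    stop("subject ", subject, ": matrix is not square")
  if (any(!is.finite(z))) stop("subject ", subject, ": non-finite entries")
  if (max(abs(z - t(z))) > 1e-10) {
    idx <- sort(which(abs(z - t(z)) == max(abs(z - t(z))), arr.ind = TRUE)[1, ])
    stop(sprintf("subject %s: asymmetry at (%d,%d)", subject, idx[1], idx[2]))
  }
  if (any(diag(z) != 0)) stop("subject ", subject, ": nonzero diagonal")
  invisible(TRUE)
}

#' Density sweep of graph metrics over a cohort
#'
#' For every subject and every density: threshold with the MST backbone,
#' compute raw and null-normalized transitivity and global efficiency, Louvain
#' modularity, and nodal participation coefficients aggregated to parcel
#' means. Deterministic given `seed` (each subject/density pair draws its own
#' sub-seed).
#'
#' @param subjects A `connectome_cohort` from [simulate_connectomes()] or
#'   [read_connectome_set()], or a plain list of connectivity matrices.
#' @param densities Numeric vector of target densities (may be empty).
#' @param parcellation Module label per node; defaults to the cohort's planted
#'   modules.
#' @param k_nulls Null-ensemble size for normalization.
#' @param seed Integer seed.
#' @param groups Group label per subject when `subjects` is a plain list.
#' @param mode `"weighted"` or `"binary"` metric variants.
#' @param negative_policy Negative-weight policy for thresholding.
#' @param louvain_restarts Restarts per Louvain run.
#' @param n_swaps_per_edge Swaps per edge for the null model.
#' @return Object of class `metric_profiles`: `global` (one row per subject x
#'   density with transitivity_raw/norm, efficiency_raw/norm, modularity_q),
#'   `parcel_pc` (long: subject, group, density, module, pc), `nodal_pc`
#'   (list by density of subject x node matrices).
#' @export
density_sweep <- function(subjects, densities = c(0.2, 0.3, 0.4),
                          parcellation = NULL, k_nulls = 20L, seed = 1L,
                          groups = NULL, mode = c("weighted", "binary"),
                          negative_policy = "zero", louvain_restarts = 100L,
                          n_swaps_per_edge = 10L) {
  mode <- match.arg(mode)
  if (inherits(subjects, "connectome_cohort")) {
    zs <- subjects$z
    ids <- subjects$subject
    groups <- groups %||% subjects$group
    parcellation <- parcellation %||% subjects$modules
  } else {
    zs <- subjects
    ids <- names(zs) %||% sprintf("s%03d", seq_along(zs))
  }
  if (is.null(parcellation)) stop("parcellation required")
  for (i in seq_along(zs)) validate_connectivity_matrix(zs[[i]], ids[i])
  if (!is.null(groups)) stopifnot(length(groups) == length(zs))
  glob <- list(); pc_rows <- list(); nodal <- list()
  for (d in densities) {
    dtag <- sprintf("%.6g", d)
    pc_mat <- matrix(NA_real_, length(zs), nrow(zs[[1]]),
                     dimnames = list(ids, NULL))
    for (i in seq_along(zs)) {
      sseed <- derive_seed(seed, paste0(ids[i], "@", dtag))
      tg <- threshold_at_density(zs[[i]], d, negative_policy)
      nm <- normalized_metrics(tg, k_nulls, seed = sseed, mode = mode,
                               n_swaps_per_edge = n_swaps_per_edge)
      lq <- louvain_q(tg, n_restarts = louvain_restarts, seed = sseed)
      pc <- participation_coefficient(tg, parcellation, mode = mode)
      pc_mat[i, ] <- pc
      glob[[length(glob) + 1L]] <- data.frame(
        subject = ids[i],
        group = if (is.null(groups)) NA_integer_ else groups[i],
        density = d,
        transitivity_raw = nm$transitivity_raw,
        transitivity_norm = nm$transitivity_norm,
        efficiency_raw = nm$efficiency_raw,
        efficiency_norm = nm$efficiency_norm,
        modularity_q = lq$q,
        row.names = NULL)
    }
    parcel_means <- t(apply(pc_mat, 1, function(v) tapply(v, parcellation, mean)))
    for (mod in colnames(parcel_means)) {
      pc_rows[[length(pc_rows) + 1L]] <- data.frame(
        subject = ids,
        group = if (is.null(groups)) NA_integer_ else groups,
        density = d, module = mod, pc = parcel_means[, mod],
        row.names = NULL)
    }
    nodal[[dtag]] <- pc_mat
  }
  empty_global <- data.frame(subject = character(), group = integer(),
                             density = numeric(), transitivity_raw = numeric(),
                             transitivity_norm = numeric(),
                             efficiency_raw = numeric(),
                             efficiency_norm = numeric(),
                             modularity_q = numeric())
  empty_pc <- data.frame(subject = character(), group = integer(),
                         density = numeric(), module = character(),
                         pc = numeric())
  structure(
    list(global = if (length(glob)) do.call(rbind, glob) else empty_global,
         parcel_pc = if (length(pc_rows)) do.call(rbind, pc_rows) else empty_pc,
         nodal_pc = nodal,
         densities = densities, mode = mode),
    class = "metric_profiles")
}

#' Group comparisons of graph metrics with multiplicity correction
#'
#' Global metrics (normalized transitivity, normalized efficiency, modularity
#' Q) are compared between groups at each density by permutation test with
#' Bonferroni correction across densities (within each metric family);
#' parcel-level participation coefficients are compared per module with
#' Benjamini-Hochberg FDR across modules at each density.
#'
#' @param profiles A `metric_profiles` object from [density_sweep()].
#' @param alpha Significance level after correction.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return List with data frames `global` (metric, density, group means, p,
#'   p_adj, significant) and `parcel` (density, module, group means, p, p_fdr,
#'   significant).
#' @export
group_metric_tests <- function(profiles, alpha = 0.05, n_perm = 10000L,
                               seed = 1L) {
  gl <- profiles$global
  if (length(unique(gl$group)) < 2L) stop("need two groups")
  metrics <- c("transitivity_norm", "efficiency_norm", "modularity_q")
  dens <- sort(unique(gl$density))
  rows <- list()
  for (met in metrics) {
    for (d in dens) {
      sub <- gl[gl$density == d, ]
      pt <- permutation_test(sub[[met]], sub$group, n_perm,
                             derive_seed(seed, paste0(met, d)))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, density = d,
        mean_control = mean(sub[[met]][sub$group == 0]),
        mean_patient = mean(sub[[met]][sub$group == 1]),
        p = pt$p, row.names = NULL)
    }
  }
  global <- do.call(rbind, rows)
  global$p_adj <- NA_real_
  for (met in metrics) {
    i <- global$metric == met
    global$p_adj[i] <- stats::p.adjust(global$p[i], method = "bonferroni")
  }
  global$significant <- global$p_adj < alpha

  pp <- profiles$parcel_pc
  prow <- list()
  for (d in sort(unique(pp$density))) {
    sub <- pp[pp$density == d, ]
    mods <- unique(sub$module)
    ps <- vapply(mods, function(mod) {
      s2 <- sub[sub$module == mod, ]
      permutation_test(s2$pc, s2$group, n_perm,
                       derive_seed(seed, paste0("pc", mod, d)))$p
    }, numeric(1))
    pf <- stats::p.adjust(ps, method = "BH")
    for (k in seq_along(mods)) {
      s2 <- sub[sub$module == mods[k], ]
      prow[[length(prow) + 1L]] <- data.frame(
        density = d, module = mods[k],
        mean_control = mean(s2$pc[s2$group == 0]),
        mean_patient = mean(s2$pc[s2$group == 1]),
        p = ps[k], p_fdr = pf[k], significant = pf[k] < alpha,
        row.names = NULL)
    }
  }
  list(global = global,
       parcel = if (length(prow)) do.call(rbind, prow) else NULL)
}

#' Correlate parcel participation coefficients with g, per group
#'
#' Within each group separately, Spearman-correlates every module's mean PC
#' with the subjects' g scores and applies Benjamini-Hochberg FDR across
#' modules, flagging survivors — the analysis asking which networks' loss of
#' segregation tracks general ability.
#'
#' @param parcel_pc Subject x module matrix of mean participation
#'   coefficients, or the long `parcel_pc` data frame from [density_sweep()]
#'   restricted to one density.
#' @param g Numeric g score per subject (matched order).
#' @param groups Group label per subject.
#' @param alpha FDR level.
#' @return `data.frame`: group, module, rho, p, p_fdr, significant.
#' @export
pc_g_correlation <- function(parcel_pc, g, groups, alpha = 0.05) {
  if (is.data.frame(parcel_pc)) {
    if (length(unique(parcel_pc$density)) > 1L)
      stop("restrict parcel_pc to a single density")
    subs <- unique(parcel_pc$subject)
    mods <- unique(parcel_pc$module)
    mat <- matrix(NA_real_, length(subs), length(mods),
                  dimnames = list(subs, mods))
    mat[cbind(match(parcel_pc$subject, subs),
              match(parcel_pc$module, mods))] <- parcel_pc$pc
    parcel_pc <- mat
  }
  stopifnot(nrow(parcel_pc) == length(g), length(groups) == length(g))
  rows <- list()
  for (grp in sort(unique(groups))) {
    i <- groups == grp
    if (sum(i) < 4L) stop("n < 4 in group ", grp)
    res <- lapply(colnames(parcel_pc), function(mod) {
      ct <- stats::cor.test(parcel_pc[i, mod], g[i], method = "spearman",
                            exact = FALSE)
      data.frame(group = grp, module = mod, rho = unname(ct$estimate),
                 p = ct$p.value, row.names = NULL)
    })
    tab <- do.call(rbind, res)
    tab$p_fdr <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- tab$p_fdr < alpha
    rows[[length(rows) + 1L]] <- tab
  }
  do.call(rbind, rows)
}
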