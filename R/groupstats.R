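#' Cohen's d from group summary statistics
#'
#' Pooled-SD standardized mean difference,
#' `d = |m1 - m0| / sqrt(((n1-1) s1^2 + (n0-1) s0^2) / (n1 + n0 - 2))`,
#' reported as a positive magnitude (the convention of effect-size tables);
#' retain the sign of `m1 - m0` separately if direction matters.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m0,s0,n0 Mean, SD and size of group 0.
#' @return The absolute standardized difference.
#' @export
#' @examples
#' cohens_d(-0.307, 0.876, 110, 0.427, 0.846, 79) # ~0.85
cohens_d <- function(m1, s1, n1, m0, s0, n0) {
  stopifnot(n1 >= 2, n0 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n0 - 1) * s0^2) / (n1 + n0 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  abs(m1 - m0) / sqrt(sp2)
}

#' Two-sample permutation test on the difference in means
#'
#' Two-sided test of the group mean difference by permutation of group labels.
#' When the number of distinct label assignments is at most `exact_max` the
#' null distribution is enumerated exhaustively and the p-value is the exact
#' proportion of assignments at least as extreme; otherwise `n_perm` random
#' permutations are drawn and the +1-corrected estimate
#' `(1 + #extreme) / (1 + n_perm)` is returned (never exactly zero).
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector, same length.
#' @param n_perm Random permutations when not exhaustive.
#' @param seed Integer seed for the sampled case.
#' @param exact_max Enumeration threshold on `choose(n, n1)`.
#' @return List with `p`, `statistic` (mean of second level minus mean of
#'   first), `method` (`"exact"`/`"sampled"`), `n_perm`.
#' @export
permutation_test <- function(values, groups, n_perm = 10000L, seed = 1L,
                             exact_max = 20000L) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  keep <- is.finite(values)
  values <- values[keep]; g <- g[keep]
  i1 <- which(g == levels(g)[2])
  obs <- mean(values[i1]) - mean(values[-i1])
  if (stats::sd(values) == 0) {
    warning("constant input; permutation p set to 1")
    return(list(p = 1, statistic = 0, method = "degenerate", n_perm = 0L))
  }
  n <- length(values)
  n1 <- length(i1)
  tot <- choose(n, n1)
  # statistic is a function of the group-1 sum only
  tot_sum <- sum(values)
  stat_from_sum <- function(s1) s1 / n1 - (tot_sum - s1) / (n - n1)
  eps <- 1e-12 * max(1, abs(obs))
  if (tot <= exact_max) {
    sums <- utils::combn(values, n1, sum)
    stats_all <- stat_from_sum(sums)
    p <- mean(abs(stats_all) >= abs(obs) - eps)
    method <- "exact"; n_used <- as.integer(tot)
  } else {
    stats_perm <- with_seed(derive_seed(seed, "perm"), {
      vapply(seq_len(n_perm),
             function(i) stat_from_sum(sum(values[sample.int(n, n1)])),
             numeric(1))
    })
    p <- (1 + sum(abs(stats_perm) >= abs(obs) - eps)) / (1 + n_perm)
    method <- "sampled"; n_used <- as.integer(n_perm)
  }
  list(p = p, statistic = obs, method = method, n_perm = n_used)
}

#' Two-class Fisher linear discriminant
#'
#' Builds the linear combination of input variables that optimally separates
#' two groups under a shared covariance assumption: direction
#' `w ~ S_pooled^-1 (mu1 - mu0)`, rescaled so the projected scores have unit
#' pooled within-group SD and sign-fixed so the control group (0) scores
#' higher. Scores are centred on the combined-sample mean. If the pooled
#' covariance is numerically singular a ridge of `1e-8 * trace/p` is added.
#'
#' @param x Numeric matrix or score table of predictor columns.
#' @param groups Binary group vector (0 = control, 1 = patient).
#' @param tests Optional predictor column names when `x` is a data frame.
#' @return Object of class `fisher_lda`: `direction`, `threshold` (midpoint of
#'   projected group means), `scores`, `means`, group means on the score.
#' @export
lda_fit <- function(x, groups = NULL, tests = NULL) {
  if (is.data.frame(x)) {
    if (is.null(groups)) groups <- x$group
    x <- extract_test_matrix(x, tests)
  }
  g <- as.integer(groups)
  stopifnot(length(g) == nrow(x), all(g %in% c(0L, 1L)))
  x0 <- x[g == 0L, , drop = FALSE]
  x1 <- x[g == 1L, , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1); p <- ncol(x)
  if (n0 < 2L || n1 < 2L) stop("each group needs at least 2 observations")
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  s <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) / (n0 + n1 - 2)
  w <- tryCatch(solve(s, mu1 - mu0), error = function(e) {
    if (min(n0, n1) <= p)
      warning("n <= p in a group; using ridge-regularized pooled covariance")
    solve(s + diag(1e-8 * sum(diag(s)) / p, p), mu1 - mu0)
  })
  sp <- sqrt(drop(t(w) %*% s %*% w)) # pooled SD of projection
  w <- w / sp
  proj0 <- mean(x0 %*% w); proj1 <- mean(x1 %*% w)
  if (proj0 < proj1) w <- -w # controls score higher
  raw <- drop(x %*% w)
  center <- mean(raw)
  scores <- raw - center
  gm <- tapply(scores, g, mean)
  structure(
    list(direction = stats::setNames(drop(w), colnames(x)),
         center = center,
         threshold = mean(gm),
         scores = scores,
         group_means = gm,
         mahalanobis = abs(diff(gm))),
    class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, digits = 3, ...) {
  cat("Two-class Fisher linear discriminant\n")
  cat("  projected group separation (Mahalanobis distance):",
      round(x$mahalanobis, digits), "\n")
  cat("  direction:\n")
  print(round(x$direction, digits))
  invisible(x)
}

#' @export
coef.fisher_lda <- function(object, ...) object$direction

#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata))
    as.matrix(newdata[names(object$direction)]) else as.matrix(newdata)
  score <- drop(x %*% object$direction) - object$center
  list(score = score,
       class = as.integer(score < object$threshold)) # patients score lower
}

#' Compare a discriminant score with g
#'
#' Reports the Pearson correlation of LDA scores with g, the correlation of
#' every input test with the LDA score (and with g), and a ranking of which
#' correlates most with the discriminant — the comparison used to argue that g
#' carries the discriminable group variance.
#'
#' @param lda_scores Numeric vector of discriminant scores (or a `fisher_lda`).
#' @param g Numeric vector of g scores, same subjects.
#' @param tests Optional matrix/data.frame of the input tests.
#' @return List with `r_lda_g` and a data frame `correlations`
#'   (test, r_with_lda, r_with_g) sorted by `|r_with_lda|`.
#' @export
lda_vs_g <- function(lda_scores, g, tests = NULL) {
  if (inherits(lda_scores, "fisher_lda")) lda_scores <- lda_scores$scores
  stopifnot(length(lda_scores) == length(g))
  out <- list(r_lda_g = stats::cor(lda_scores, g))
  if (!is.null(tests)) {
    x <- if (is.data.frame(tests)) extract_test_matrix(tests) else as.matrix(tests)
    tab <- data.frame(
      test = colnames(x) %||% paste0("V", seq_len(ncol(x))),
      r_with_lda = apply(x, 2, stats::cor, y = lda_scores),
      r_with_g = apply(x, 2, stats::cor, y = g),
      row.names = NULL)
    out$correlations <- tab[order(-abs(tab$r_with_lda)), ]
    out$g_beats_all_tests <- abs(out$r_lda_g) > max(abs(tab$r_with_lda))
  }
  out
}

#' Adjust a measure for g and re-test the group difference
#'
#' Residualizes `values` on `g` by ordinary least squares over the combined
#' sample and runs the permutation group test before and after adjustment —
#' the "unique variance beyond g" analysis for measures not used in
#' constructing g.
#'
#' @param values Numeric measure.
#' @param g Numeric g scores.
#' @param groups Two-level group labels.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return List with `adjusted` (residuals), `p_before`, `p_after`, `slope`.
#' @export
adjust_for_g <- function(values, g, groups, n_perm = 10000L, seed = 1L) {
  stopifnot(all(is.finite(g)))
  if (stats::sd(g) == 0) stop("constant g")
  fit <- stats::lm.fit(cbind(1, g), values)
  res <- fit$residuals
  before <- permutation_test(values, groups, n_perm, derive_seed(seed, "before"))
  after <- if (stats::sd(res) == 0) {
    list(p = 1, statistic = 0, method = "degenerate", n_perm = 0L)
  } else {
    permutation_test(res, groups, n_perm, derive_seed(seed, "after"))
  }
  list(adjusted = res, p_before = before$p, p_after = after$p,
       slope = fit$coefficients[2])
}

#' Association between two variables with a declared test type
#'
#' Continuous covariates are related by Pearson or Spearman correlation
#' (Spearman when declared non-normal); a two-level category against a
#' continuous variable by Student's t-test; two categories by chi-squared.
#'
#' @param x First variable (typically g).
#' @param y Second variable (covariate).
#' @param type One of `"pearson"`, `"spearman"`, `"t"`, `"chi2"`.
#' @param covariate Name used in the output row.
#' @return A one-row `data.frame`: covariate, method, statistic, estimate, p.
#' @export
associate <- function(x, y, type = c("pearson", "spearman", "t", "chi2"),
                      covariate = deparse(substitute(y))) {
  type <- match.arg(type)
  force(covariate) # before y is subset below
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  res <- switch(type,
    pearson = ,
    spearman = {
      ct <- stats::cor.test(x, y, method = type, exact = FALSE)
      c(statistic = unname(ct$statistic), estimate = unname(ct$estimate),
        p = ct$p.value)
    },
    t = {
      f <- as.factor(y)
      if (nlevels(f) != 2L) stop("t-test requires a two-level covariate")
      tt <- stats::t.test(x ~ f, var.equal = TRUE)
      c(statistic = unname(tt$statistic),
        estimate = unname(diff(rev(tt$estimate))), p = tt$p.value)
    },
    chi2 = {
      ct <- suppressWarnings(stats::chisq.test(table(x, y)))
      c(statistic = unname(ct$statistic), estimate = NA_real_, p = ct$p.value)
    })
  data.frame(covariate = covariate, method = type,
             statistic = res[["statistic"]], estimate = res[["estimate"]],
             p = res[["p"]], row.names = NULL)
}

#' Group effect-size table for a set of measures
#'
#' For each measure: group means and SDs, two-sided permutation p-value and
#' pooled-SD Cohen's d (absolute value, plus the signed mean difference).
#'
#' @param data Score table with a `group` column (0/1).
#' @param measures Character vector of measure column names.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return `data.frame` with one row per measure.
#' @export
effect_size_table <- function(data, measures, n_perm = 10000L, seed = 1L) {
  stopifnot("group" %in% names(data))
  g <- as.integer(data$group)
  rows <- lapply(measures, function(m) {
    v <- data[[m]]
    ok <- is.finite(v)
    v1 <- v[ok & g == 1L]; v0 <- v[ok & g == 0L]
    pt <- permutation_test(v[ok], g[ok], n_perm, derive_seed(seed, m))
    data.frame(
      measure = m,
      mean_patient = mean(v1), sd_patient = stats::sd(v1), n_patient = length(v1),
      mean_control = mean(v0), sd_control = stats::sd(v0), n_control = length(v0),
      mean_diff = mean(v1) - mean(v0),
      perm_p = pt$p,
      cohens_d = cohens_d(mean(v1), stats::sd(v1), length(v1),
                          mean(v0), stats::sd(v0), length(v0)),
      row.names = NULL)
  })
  do.call(rbind, rows)
}
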