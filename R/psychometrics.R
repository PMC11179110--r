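#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Ratio of squared correlations to squared correlations plus squared
#' anti-image partial correlations, overall and per item. Values above 0.8 are
#' conventionally "meritorious".
#'
#' @param corr A p x p correlation matrix (symmetric positive definite).
#' @return A list with `kmo_overall` and `msa_per_item`.
#' @export
#' @examples
#' r <- matrix(0.5, 3, 3); diag(r) <- 1
#' kmo(r)$kmo_overall # 1.5 / (1.5 + 2/3)
kmo <- function(corr) {
  check_correlation_matrix(corr)
  s <- solve(corr)
  q <- -s / sqrt(outer(diag(s), diag(s)))
  diag(q) <- 0
  r <- corr
  diag(r) <- 0
  r2 <- r^2
  q2 <- q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(msa) <- colnames(corr)
  list(kmo_overall = overall, msa_per_item = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix departs from identity, i.e. whether the
#' variables are correlated enough for factor analysis to be meaningful.
#' `chi2 = -(n - 1 - (2p + 5)/6) * log(det(corr))` with `p(p-1)/2` degrees of
#' freedom.
#'
#' @param corr Correlation matrix.
#' @param n Sample size used to estimate `corr` (must exceed p).
#' @return A list with `chi2`, `df` and `p`.
#' @export
bartlett_sphericity <- function(corr, n) {
  check_square_symmetric(corr, what = "correlation matrix")
  p <- ncol(corr)
  stopifnot(n > p)
  ld <- determinant(corr, logarithm = TRUE)
  if (ld$sign <= 0) stop("correlation matrix has non-positive determinant")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Velicer's minimum average partial (MAP) test for the number of factors
#'
#' For m = 0, ..., p-2 principal components partialled out of the correlation
#' matrix, averages the squared (1976 criterion) or fourth-power (2000
#' criterion) off-diagonal partial correlations; the optimal factor count
#' minimizes this average. The m = 0 term is the average over the raw
#' correlation matrix, so an identity-like matrix yields 0 factors.
#'
#' @param corr Correlation matrix (positive definite).
#' @param criterion `"1976"` (squares) or `"2000"` (fourth powers).
#' @return A list with `n_factors` (the argmin) and `map_values` (named vector
#'   indexed by m = 0, 1, ...).
#' @export
map_test <- function(corr, criterion = c("1976", "2000")) {
  criterion <- match.arg(criterion)
  check_correlation_matrix(corr)
  p <- ncol(corr)
  pw <- if (criterion == "1976") 2 else 4
  e <- eigen(corr, symmetric = TRUE)
  off <- upper.tri(corr)
  avg <- rep(NA_real_, p - 1)
  avg[1] <- mean(abs(corr[off])^pw)
  for (m in seq_len(p - 2)) {
    lam <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(m)]), m)
    cc <- corr - tcrossprod(lam)
    d <- diag(cc)
    if (any(d <= sqrt(.Machine$double.eps))) break # residual variance exhausted
    pr <- cc / sqrt(outer(d, d))
    avg[m + 1] <- mean(abs(pr[off])^pw)
  }
  avg <- avg[!is.na(avg)]
  names(avg) <- seq_along(avg) - 1L
  list(n_factors = as.integer(which.min(avg) - 1L), map_values = avg)
}

# quartimin criterion value and gradient for gradient-projection rotation
vgq_quartimin <- function(L) {
  m <- ncol(L)
  L2 <- L^2
  M <- matrix(1, m, m); diag(M) <- 0
  X <- L2 %*% M
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# oblique gradient-projection rotation (quartimin/oblimin gamma = 0)
gpa_oblimin <- function(A, t_mat = diag(ncol(A)), eps = 1e-6, maxit = 1000) {
  al <- 1
  Ti <- solve(t_mat)
  L <- A %*% t(Ti)
  vg <- vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  for (iter in seq_len(maxit)) {
    Gp <- G - t_mat %*% diag(colSums(t_mat * G), ncol(A))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:20) {
      X <- t_mat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(A))
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vgt <- vgq_quartimin(L)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    t_mat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
  }
  phi <- crossprod(t_mat)
  # fix column signs so each factor's loading sum is positive
  sg <- ifelse(colSums(L) < 0, -1, 1)
  L <- L %*% diag(sg, ncol(A))
  phi <- diag(sg, ncol(A)) %*% phi %*% diag(sg, ncol(A))
  list(loadings = L, phi = phi)
}

#' Exploratory factor analysis by minimum residual (ULS) estimation
#'
#' Minimizes the sum of squared off-diagonal residuals between the observed
#' correlation matrix and the model-implied `Lambda Lambda' + Psi`, over the
#' uniquenesses (bounded below at 0.005; hitting the floor raises a Heywood
#' warning). For a single factor the solution is sign-fixed so the loading sum
#' is positive; for m > 1 an oblique quartimin rotation via the
#' gradient-projection algorithm is applied when requested.
#'
#' @param corr Correlation matrix.
#' @param n_factors Number of factors (>= 1).
#' @param rotation `"none"`, `"oblimin"` or its alias `"oblique-GPA"`.
#' @param n_obs Optional sample size; enables the ULS-proxy chi-square and the
#'   Tucker-Lewis index.
#' @param max_iter Maximum optimizer iterations.
#' @return An object of class `factor_model`: loadings, uniquenesses,
#'   `factor_corr` (Phi), `rmsr`, `tli`, `dof`, plus the input correlation
#'   matrix for downstream scoring.
#' @export
efa <- function(corr, n_factors = 1L, rotation = c("oblimin", "none", "oblique-GPA"),
                n_obs = NULL, max_iter = 1000L) {
  rotation <- match.arg(rotation)
  check_correlation_matrix(corr)
  p <- ncol(corr)
  m <- as.integer(n_factors)
  stopifnot(m >= 1L, m < p)
  floor_psi <- 0.005

  loadings_from_psi <- function(psi) {
    s <- corr
    diag(s) <- 1 - psi
    e <- eigen(s, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(m)], 0)
    e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(ev), m)
  }
  objective <- function(psi) {
    lam <- loadings_from_psi(psi)
    res <- corr - tcrossprod(lam)
    diag(res) <- 0
    sum(res^2) / 2
  }
  start <- 1 / diag(solve(corr)) # 1 - SMC
  start <- pmin(pmax(start, floor_psi), 1)
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = floor_psi, upper = 1,
                      control = list(maxit = max_iter, factr = 1e4))
  if (opt$convergence != 0 && opt$value > 1e-10)
    stop("minres estimation did not converge (last objective ", signif(opt$value, 6),
         "): ", opt$message)
  psi <- opt$par
  if (any(psi <= floor_psi + 1e-12))
    warning("Heywood case: ", sum(psi <= floor_psi + 1e-12),
            " uniqueness(es) floored at ", floor_psi)
  lam <- loadings_from_psi(psi)
  phi <- diag(m)
  if (m == 1L) {
    if (sum(lam) < 0) lam <- -lam
  } else if (rotation != "none") {
    rot <- gpa_oblimin(lam)
    lam <- rot$loadings
    phi <- rot$phi
  } else {
    sg <- ifelse(colSums(lam) < 0, -1, 1)
    lam <- lam %*% diag(sg, m)
  }
  implied <- lam %*% phi %*% t(lam)
  res <- corr - implied
  diag(res) <- 0
  n_off <- p * (p - 1) / 2
  rmsr <- sqrt(sum(res[upper.tri(res)]^2) / n_off)
  dof <- ((p - m)^2 - p - m) / 2
  tli <- chi2 <- NA_real_
  if (!is.null(n_obs)) {
    f_model <- sum(res[upper.tri(res)]^2)
    r0 <- corr; diag(r0) <- 0
    f_null <- sum(r0[upper.tri(r0)]^2)
    c_model <- n_obs - 1 - (2 * p + 5) / 6 - 2 * m / 3
    c_null <- n_obs - 1 - (2 * p + 5) / 6
    chi2 <- f_model * c_model
    chi2_null <- f_null * c_null
    df_null <- n_off
    if (dof > 0 && chi2_null > df_null) {
      r_null <- chi2_null / df_null
      r_mod <- chi2 / dof
      tli <- (r_null - r_mod) / (r_null - 1)
    }
  }
  structure(
    list(n_factors = m, loadings = lam, uniquenesses = psi, factor_corr = phi,
         rmsr = rmsr, tli = tli, chi2 = chi2, dof = dof, corr = corr,
         objective = opt$value, n_obs = n_obs),
    class = "factor_model")
}

#' Thurstone regression factor scores
#'
#' Computes regression score weights `W = R^-1 Lambda Phi`, applies them to the
#' standardized score columns and restandardizes. Score validity per factor is
#' `sqrt(diag(Phi Lambda' R^-1 Lambda Phi))` and the multiple R-squared of
#' scores with factors is its square (the two are reported together because the
#' identity `R2 = validity^2` is itself a check on the computation).
#'
#' @param model A `factor_model` from [efa()].
#' @param table Score table (`data.frame`) containing the test columns the
#'   model was fitted on, or a numeric matrix with matching columns.
#' @param tests Character vector of test column names; defaults to the
#'   dimnames of the model's correlation matrix or all numeric columns.
#' @return A list of class `factor_scores`: `g` (first-factor standardized
#'   scores), `scores` (all factors), `weights`, `validity`, `r2`,
#'   `method = "regression"`.
#' @export
factor_scores <- function(model, table, tests = NULL) {
  stopifnot(inherits(model, "factor_model"))
  x <- extract_test_matrix(table, tests, expected = colnames(model$corr),
                           p = ncol(model$corr))
  w <- solve(model$corr, model$loadings %*% model$factor_corr)
  r2 <- diag(t(w) %*% model$corr %*% w)
  validity <- sqrt(r2)
  z <- scale(x)
  raw <- z %*% w
  sc <- scale(raw)
  colnames(sc) <- paste0("F", seq_len(ncol(sc)))
  structure(
    list(g = as.numeric(sc[, 1]), scores = sc[, , drop = TRUE],
         weights = w, validity = as.numeric(validity), r2 = as.numeric(r2),
         center = attr(z, "scaled:center"), scale = attr(z, "scaled:scale"),
         raw_center = attr(sc, "scaled:center"), raw_scale = attr(sc, "scaled:scale"),
         method = "regression"),
    class = "factor_scores")
}

extract_test_matrix <- function(table, tests = NULL, expected = NULL, p = NULL) {
  if (is.matrix(table)) return(table)
  if (is.null(tests)) tests <- attr(table, "tests")
  if (is.null(tests) && !is.null(expected) && all(expected %in% names(table)))
    tests <- expected
  if (is.null(tests)) {
    drop <- c("subject", "group")
    tests <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], drop)
  }
  missing <- setdiff(tests, names(table))
  if (length(missing))
    stop("tests missing from table: ", paste(missing, collapse = ", "))
  x <- as.matrix(table[tests])
  if (!is.null(p) && ncol(x) != p)
    stop("table provides ", ncol(x), " tests but the model was fitted on ", p)
  x
}

#' Fit a general cognitive factor (g) model to a score table
#'
#' The central fitting function: computes sampling-adequacy diagnostics (KMO,
#' Bartlett sphericity), selects the number of factors by Velicer's MAP test
#' (both the 1976 and 2000 criteria; the 1976 answer is used unless
#' `n_factors` overrides it), fits a minres factor model with oblique rotation
#' where more than one factor is retained, and derives Thurstone regression
#' scores standardized on the combined sample. The first factor score is the
#' subject-level g estimate.
#'
#' Pearson correlations on complete cases (listwise deletion) are used
#' throughout.
#'
#' @param data A score table `data.frame` (e.g. from [simulate_battery()] or
#'   [read_score_table()]) with a `group` column and numeric test columns.
#' @param tests Optional character vector naming the test columns.
#' @param n_factors Optional override of the MAP-selected factor count.
#' @param rotation Rotation passed to [efa()].
#' @return An object of class `gfactor` with components `adequacy`, `map`
#'   (both criteria), `model`, `scores`, `g`, `data` (the table with a `g`
#'   column appended), `tests`, `n_complete`.
#' @seealso [efa()], [factor_scores()], [map_test()]
#' @export
#' @examples
#' tab <- simulate_battery(battery_spec(n_per_group = 60, seed = 42))
#' fit <- gfactor(tab)
#' fit
#' head(coef(fit))
gfactor <- function(data, tests = NULL, n_factors = NULL,
                    rotation = c("oblimin", "none")) {
  rotation <- match.arg(rotation)
  x <- extract_test_matrix(data, tests)
  tests <- colnames(x)
  cc <- stats::complete.cases(x)
  if (sum(cc) <= ncol(x))
    stop("need more complete cases (", sum(cc), ") than tests (", ncol(x), ")")
  xc <- x[cc, , drop = FALSE]
  r <- stats::cor(xc)
  adequacy <- kmo(r)
  adequacy <- c(adequacy, bartlett_sphericity(r, nrow(xc)))
  map <- list(`1976` = map_test(r, "1976"), `2000` = map_test(r, "2000"))
  m <- n_factors %||% max(1L, map[["1976"]]$n_factors)
  model <- efa(r, n_factors = m, rotation = if (m > 1) rotation else "none",
               n_obs = nrow(xc))
  scores <- factor_scores(model, xc)
  g <- rep(NA_real_, nrow(x))
  g[cc] <- scores$g
  out_data <- if (is.data.frame(data)) data else as.data.frame(x)
  out_data$g <- g
  structure(
    list(adequacy = adequacy, map = map, model = model, scores = scores,
         g = g, data = out_data, tests = tests, n_complete = sum(cc),
         call = match.call()),
    class = "gfactor")
}

#' @export
print.gfactor <- function(x, digits = 3, ...) {
  cat("General-factor model (", x$model$n_factors, " factor",
      if (x$model$n_factors > 1) "s", ", minres)\n", sep = "")
  cat(sprintf("  tests: %d, complete cases: %d\n", length(x$tests), x$n_complete))
  cat(sprintf("  KMO overall MSA: %.2f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$adequacy$kmo_overall, x$adequacy$df, x$adequacy$chi2, x$adequacy$p))
  cat(sprintf("  MAP factor count: %d (1976), %d (2000)\n",
              x$map[["1976"]]$n_factors, x$map[["2000"]]$n_factors))
  cat(sprintf("  RMSR: %.3f; TLI: %s\n", x$model$rmsr,
              ifelse(is.na(x$model$tli), "NA", sprintf("%.2f", x$model$tli))))
  cat(sprintf("  score validity: %s; score R2: %s\n",
              paste(round(x$scores$validity, digits), collapse = ", "),
              paste(round(x$scores$r2, digits), collapse = ", ")))
  invisible(x)
}

#' @export
summary.gfactor <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  cat("\nLoadings:\n")
  l <- object$model$loadings
  rownames(l) <- object$tests
  colnames(l) <- paste0("F", seq_len(ncol(l)))
  print(round(l, digits))
  cat("\nUniquenesses:\n")
  print(round(stats::setNames(object$model$uniquenesses, object$tests), digits))
  if (object$model$n_factors > 1) {
    cat("\nFactor correlations:\n")
    print(round(object$model$factor_corr, digits))
  }
  invisible(object)
}

#' @export
coef.gfactor <- function(object, ...) {
  l <- object$model$loadings
  rownames(l) <- object$tests
  colnames(l) <- paste0("F", seq_len(ncol(l)))
  l
}

#' Predict factor scores for new subjects
#'
#' Applies the training-sample standardization and score weights to new data,
#' so scores are on the scale of the estimation sample.
#'
#' @param object A `gfactor` fit.
#' @param newdata Score table or matrix with the same test columns.
#' @param ... Unused.
#' @return Numeric vector (one factor) or matrix of factor scores.
#' @export
predict.gfactor <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$g)
  x <- extract_test_matrix(newdata, object$tests, p = length(object$tests))
  s <- object$scores
  z <- sweep(sweep(x, 2, s$center), 2, s$scale, "/")
  raw <- z %*% s$weights
  out <- sweep(sweep(raw, 2, s$raw_center), 2, s$raw_scale, "/")
  if (ncol(out) == 1L) as.numeric(out) else out
}

#' @export
residuals.gfactor <- function(object, ...) {
  m <- object$model
  res <- m$corr - m$loadings %*% m$factor_corr %*% t(m$loadings)
  diag(res) <- 0
  dimnames(res) <- list(object$tests, object$tests)
  res
}

#' @export
plot.gfactor <- function(x, ...) {
  l <- coef(x)
  graphics::barplot(t(l), beside = ncol(l) > 1, las = 2,
                    ylab = "loading", main = "Factor loadings", ...)
  invisible(x)
}

#' Simulate score tables from a fitted g-factor model
#'
#' Draws new subjects from the fitted one-factor population
#' (`x = lambda * f + e` with uniqueness variances from the fit), on the
#' standardized test scale.
#'
#' @param object A `gfactor` fit (single factor).
#' @param nsim Number of replicate tables.
#' @param seed Integer seed.
#' @param n Subjects per table (default: size of the estimation sample).
#' @param ... Unused.
#' @return A list of `data.frame`s with the fitted test columns.
#' @export
simulate.gfactor <- function(object, nsim = 1, seed = 1L, n = NULL, ...) {
  m <- object$model
  if (m$n_factors != 1L) stop("simulate() supports single-factor fits")
  n <- n %||% object$n_complete
  lam <- as.numeric(m$loadings)
  psi <- m$uniquenesses
  with_seed(derive_seed(seed, "simulate-gfactor"), {
    lapply(seq_len(nsim), function(i) {
      f <- stats::rnorm(n)
      x <- outer(f, lam) + matrix(stats::rnorm(n * length(lam)), n) %*%
        diag(sqrt(psi), length(lam))
      colnames(x) <- object$tests
      d <- as.data.frame(x)
      attr(d, "latent") <- f
      d
    })
  })
}
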