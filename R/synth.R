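#' Specify a synthetic single-factor cognitive battery
#'
#' Defines the population model for a simulated neuropsychological battery:
#' every test loads on one latent general ability factor ("positive manifold"),
#' and the patient group (coded 1) is shifted on the latent factor by
#' `group_shift` standard deviations. Defaults emulate a comprehensive
#' 11-test battery administered to a patient/control cohort of 110/79, with
#' heterogeneous loadings whose implied single-factor score validity is in the
#' low 0.9s, as typical for such batteries.
#'
#' @param n_per_group Subjects per group; scalar or length-2 `c(control, patient)`.
#' @param loadings Vector of factor loadings, each strictly in (0, 1).
#' @param group_shift Standardized mean shift of the latent factor for group 1
#'   (negative = patients lower).
#' @param noise_sd Residual SD per test; default `sqrt(1 - loadings^2)` so each
#'   test has unit population variance and the implied correlations are
#'   `loadings %o% loadings` off the diagonal.
#' @param seed Integer seed.
#' @return An object of class `battery_spec`.
#' @export
battery_spec <- function(n_per_group = c(79L, 110L),
                         loadings = c(0.70, 0.67, 0.52, 0.62, 0.55, 0.48,
                                      0.50, 0.68, 0.64, 0.58, 0.55),
                         group_shift = -0.85,
                         noise_sd = NULL,
                         seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 3L))
  if (any(loadings <= 0 | loadings >= 1))
    stop("loadings must be strictly between 0 and 1")
  p <- length(loadings)
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - loadings^2)
  noise_sd <- rep_len(noise_sd, p)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  spec <- structure(
    list(n_per_group = as.integer(n_per_group), loadings = loadings,
         group_shift = group_shift, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "battery_spec")
  imp <- implied_battery_corr(spec)
  if (min(eigen(imp, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
    stop("implied population correlation matrix is not positive definite; ",
         "reduce loadings or increase noise_sd")
  spec
}

# population correlation matrix implied by the one-factor model
implied_battery_corr <- function(spec) {
  lam <- spec$loadings
  v <- lam^2 + spec$noise_sd^2
  s <- outer(lam, lam)
  diag(s) <- v
  stats::cov2cor(s)
}

#' Simulate a cognitive score table from a one-factor battery model
#'
#' Draws `f ~ N(0, 1)` per subject (shifted by `group_shift` for group 1) and
#' scores `x_ij = loading_j * f_i + e_ij` with `e_ij ~ N(0, noise_sd_j)`.
#' The true latent factor is attached as attribute `"latent"` so recovery can
#' be tested directly.
#'
#' @param spec A [battery_spec()].
#' @return A `data.frame` with columns `subject`, `group` (0 = control,
#'   1 = patient) and one column per test (`T01`, `T02`, ...); attributes
#'   `latent` (true factor values) and `tests` (test column names).
#' @export
simulate_battery <- function(spec) {
  stopifnot(inherits(spec, "battery_spec"))
  n0 <- spec$n_per_group[1]; n1 <- spec$n_per_group[2]
  n <- n0 + n1
  p <- length(spec$loadings)
  tests <- sprintf("T%02d", seq_len(p))
  out <- with_seed(derive_seed(spec$seed, "battery"), {
    f <- stats::rnorm(n) + rep(c(0, spec$group_shift), c(n0, n1))
    eps <- matrix(stats::rnorm(n * p), n, p) %*% diag(spec$noise_sd, p)
    x <- outer(f, spec$loadings) + eps
    list(f = f, x = x)
  })
  tab <- data.frame(subject = sprintf("s%03d", seq_len(n)),
                    group = rep(c(0L, 1L), c(n0, n1)))
  tab[tests] <- as.data.frame(out$x)
  attr(tab, "latent") <- out$f
  attr(tab, "tests") <- tests
  tab
}

#' Specify a synthetic modular connectome population
#'
#' Block-structured correlation matrices: node pairs within a module correlate
#' at `within_corr` (reduced by `group_delta` for the patient group, emulating
#' weaker modular segregation), pairs across modules at `between_corr`.
#' Per-subject noise perturbs the off-diagonal entries, followed by a
#' positive-semidefinite repair (eigenvalue clipping at 1e-8 and
#' re-normalization to unit diagonal).
#'
#' @param n_nodes Number of nodes.
#' @param module_sizes Integer vector summing to `n_nodes`.
#' @param within_corr,between_corr Target correlations, `0 <= between < within < 1`.
#' @param subject_noise_sd SD of per-subject off-diagonal perturbation.
#' @param group_delta Reduction of `within_corr` for group 1 (patients).
#' @param seed Integer seed.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_nodes = 90L,
                         module_sizes = rep(15L, 6L),
                         within_corr = 0.5,
                         between_corr = 0.1,
                         subject_noise_sd = 0.06,
                         group_delta = 0.1,
                         seed = 1L) {
  if (sum(module_sizes) != n_nodes)
    stop("module_sizes must sum to n_nodes (", sum(module_sizes), " != ", n_nodes, ")")
  if (!(between_corr >= 0 && between_corr < within_corr && within_corr < 1))
    stop("require 0 <= between_corr < within_corr < 1")
  if (within_corr - group_delta <= between_corr)
    stop("within_corr - group_delta must stay above between_corr")
  structure(
    list(n_nodes = as.integer(n_nodes), module_sizes = as.integer(module_sizes),
         within_corr = within_corr, between_corr = between_corr,
         subject_noise_sd = subject_noise_sd, group_delta = group_delta,
         seed = as.integer(seed)),
    class = "network_spec")
}

block_template <- function(spec, patient = FALSE) {
  w <- spec$within_corr - if (patient) spec$group_delta else 0
  labs <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  same <- outer(labs, labs, "==")
  r <- ifelse(same, w, spec$between_corr)
  diag(r) <- 1
  r
}

psd_repair <- function(r, floor = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= floor) return(r)
  v <- pmax(e$values, floor)
  m <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(m)
}

#' Simulate a cohort of subject connectivity matrices
#'
#' Each subject's matrix is the group block template plus symmetric Gaussian
#' off-diagonal noise, PSD-repaired, re-normalized to unit diagonal, Fisher
#' z-transformed and zero-diagonal.
#'
#' @param spec A [network_spec()].
#' @param n_subjects_per_group Subjects per group; scalar or length-2
#'   `c(control, patient)`.
#' @return A list of class `connectome_cohort` with elements `z` (list of
#'   N x N Fisher-z matrices), `subject`, `group` (0/1), `modules` (planted
#'   module label per node, `M1`, `M2`, ...), `template` (the two noise-free
#'   correlation templates).
#' @export
simulate_connectomes <- function(spec, n_subjects_per_group = c(50L, 50L)) {
  stopifnot(inherits(spec, "network_spec"))
  if (length(n_subjects_per_group) == 1L)
    n_subjects_per_group <- rep(n_subjects_per_group, 2L)
  n0 <- n_subjects_per_group[1]; n1 <- n_subjects_per_group[2]
  n <- n0 + n1
  N <- spec$n_nodes
  tmpl <- list(control = block_template(spec, FALSE),
               patient = block_template(spec, TRUE))
  group <- rep(c(0L, 1L), c(n0, n1))
  iu <- upper.tri(tmpl$control)
  zs <- with_seed(derive_seed(spec$seed, "connectomes"), {
    lapply(seq_len(n), function(i) {
      r <- tmpl[[group[i] + 1L]]
      if (spec$subject_noise_sd > 0) {
        e <- matrix(0, N, N)
        e[iu] <- stats::rnorm(sum(iu), sd = spec$subject_noise_sd)
        r <- r + e + t(e)
        diag(r) <- 1
        r <- psd_repair(r)
      }
      r <- pmin(pmax(r, -0.9999), 0.9999)
      diag(r) <- 1
      correlation_to_z(r)
    })
  })
  structure(
    list(z = zs,
         subject = sprintf("s%03d", seq_len(n)),
         group = group,
         modules = paste0("M", rep(seq_along(spec$module_sizes), spec$module_sizes)),
         template = tmpl,
         spec = spec),
    class = "connectome_cohort")
}

#' Simulate clinical and sociodemographic covariates tied to a latent ability
#'
#' Continuous covariates are generated as `slope * g_true + noise`. A covariate
#' named `"adi"` is emitted as a two-level neighbourhood-deprivation category
#' (`"advantaged"`/`"disadvantaged"`, median split of its latent value), the
#' form in which an Area Deprivation Index grouping enters the analysis.
#'
#' @param g_true Numeric vector of true latent ability values.
#' @param coeffs Named numeric vector or list of slopes, e.g.
#'   `c(education = 0.5, onset_age = 0.4, duration = -0.4, n_asm = -0.4, adi = 0.5)`.
#' @param seed Integer seed.
#' @param noise_sd Residual SD of each covariate (default 1).
#' @return A `data.frame` of covariates, one row per subject.
#' @export
simulate_covariates <- function(g_true, coeffs, seed = 1L, noise_sd = 1) {
  coeffs <- unlist(coeffs)
  stopifnot(is.numeric(g_true), all(is.finite(coeffs)))
  n <- length(g_true)
  out <- with_seed(derive_seed(seed, "covariates"), {
    cols <- lapply(names(coeffs), function(nm) {
      v <- coeffs[[nm]] * g_true + stats::rnorm(n, sd = noise_sd)
      if (identical(nm, "adi"))
        factor(ifelse(v >= stats::median(v), "advantaged", "disadvantaged"),
               levels = c("advantaged", "disadvantaged"))
      else v
    })
    names(cols) <- names(coeffs)
    cols
  })
  as.data.frame(out, optional = TRUE)
}
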