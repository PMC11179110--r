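#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every stochastic stage of the pipeline draws its own RNG stream from one
#' user-supplied integer seed, so that stages can be re-run independently
#' without cross-contaminating each other's draws.
#'
#' @param seed Integer master seed.
#' @param tag Character label naming the consuming stage.
#' @return An integer in `[0, 2^31)`, deterministic in `(seed, tag)`.
#' @export
#' @examples
#' derive_seed(1, "battery")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629 # large prime below 2^31
  h <- abs(as.numeric(seed)) %% m
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# run expr with a temporarily-set RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_square_symmetric <- function(x, tol = 1e-10, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (nrow(x) != ncol(x)) stop(what, " must be square")
  if (any(!is.finite(x))) stop(what, " contains non-finite entries")
  d <- max(abs(x - t(x)))
  if (d > tol) {
    idx <- sort(which(abs(x - t(x)) == max(abs(x - t(x))), arr.ind = TRUE)[1, ])
    stop(sprintf("%s is not symmetric: asymmetry at (%d,%d), |diff| = %.3g",
                 what, idx[1], idx[2], d))
  }
  invisible(TRUE)
}

check_correlation_matrix <- function(r, tol = 1e-8) {
  check_square_symmetric(r, what = "correlation matrix")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("correlation matrix must have unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) {
    # point at the most collinear pair for the error message
    off <- r; diag(off) <- 0
    idx <- sort(which(abs(off) == max(abs(off)), arr.ind = TRUE)[1, ])
    stop(sprintf(
      "correlation matrix is singular or not positive definite (min eigenvalue %.3g); most collinear pair: (%d,%d) r = %.4f",
      min(ev), idx[1], idx[2], off[idx[1], idx[2]]))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
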