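## Internal numerical helpers shared across the package.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG state is restored afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

## n draws from N(mean, sigma) via the upper Cholesky factor; rows are draws.
rmvn <- function(n, mean, sigma) {
  L <- chol(sigma)  # upper triangular, sigma = t(L) %*% L
  z <- matrix(stats::rnorm(n * length(mean)), n, length(mean))
  sweep(z %*% L, 2L, mean, `+`, check.margin = FALSE)
}

## Multivariate normal log-density of the rows of x, constant covariance.
dmvn_log <- function(x, mean, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  m <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("covariance matrix is not positive definite (condition estimate ",
         format(kappa(sigma)), ")", call. = FALSE))
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * m * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

## Symmetrize and clip negative eigenvalues to zero. Small negative
## eigenvalues are expected Monte-Carlo noise in near-degenerate directions
## (amplified by ratio Jacobians at extreme grid points) and are clipped;
## gross indefiniteness (beyond `hard_tol` relative to the largest
## eigenvalue) signals a real inconsistency and errors.
psd_project <- function(a, hard_tol = 0.25, label = "matrix", ref = NULL) {
  a <- (a + t(a)) / 2
  e <- eigen(a, symmetric = TRUE)
  lmax <- max(abs(e$values), ref, .Machine$double.eps)
  if (min(e$values) < -hard_tol * lmax)
    stop(label, " is indefinite beyond tolerance (min eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (vals * t(e$vectors))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 1
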