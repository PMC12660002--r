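#' Pointwise z-statistic for a single residual
#'
#' Standardizes one (transformed) residual by its estimated asymptotic
#' standard error: `z = sqrt(n) r / sqrt(omega)`, which is asymptotically
#' standard normal under correct specification; `|z| > 1.96` flags misfit at
#' the 5% level.
#'
#' @param r Residual component.
#' @param omega Corresponding diagonal entry of the residual ACM.
#' @param n Sample size.
#' @param var_floor Diagonal entries below this are treated as numerically
#'   zero and the statistic is marked unusable.
#' @return Object of class `"z_result"`: `z`, `se` (`sqrt(omega/n)`), `p`
#'   (two-sided), `usable`.
#' @export
z_statistic <- function(r, omega, n, var_floor = 1e-12) {
  if (!is.finite(omega) || omega < -1e-8)
    stop("negative residual variance beyond tolerance: internal ",
         "inconsistency in the ACM", call. = FALSE)
  if (omega < var_floor)
    return(structure(list(z = NA_real_, se = NA_real_, p = NA_real_,
                          usable = FALSE), class = "z_result"))
  z <- sqrt(n) * r / sqrt(omega)
  structure(list(z = z, se = sqrt(omega / n),
                 p = 2 * stats::pnorm(-abs(z)), usable = TRUE),
            class = "z_result")
}

#' Truncated-eigendecomposition weight matrix
#'
#' Eigendecomposes the residual ACM `Omega = U D U'` (eigenvalues descending,
#' ties kept in stable order) and inverts only the `s` largest eigenvalues:
#' `W = U D~ U'`. `W` is a generalized inverse on the retained subspace
#' (`W Omega W = W`), and coincides with the Moore-Penrose pseudoinverse when
#' `s` equals the numerical rank. Fixing `s` small avoids the numerical-rank
#' tolerance that makes pseudoinverse-weighted statistics unstable.
#'
#' @param acm Symmetric PSD matrix.
#' @param s Number of retained eigenvalues (reference chi-square degrees of
#'   freedom).
#' @return Weight matrix with attributes `eigvals` (descending), `kept`
#'   (indices retained), `s`.
#' @export
weight_matrix <- function(acm, s) {
  stopifnot(is_count(s))
  e <- eigen((acm + t(acm)) / 2, symmetric = TRUE)
  rank_tol <- 1e-10 * max(e$values, .Machine$double.eps)
  n_pos <- sum(e$values > rank_tol)
  if (s > n_pos)
    stop("s = ", s, " exceeds the number of eigenvalues above the rank ",
         "tolerance (", n_pos, "); choose a smaller s", call. = FALSE)
  dtil <- numeric(length(e$values))
  dtil[seq_len(s)] <- 1 / e$values[seq_len(s)]
  W <- e$vectors %*% (dtil * t(e$vectors))
  W <- (W + t(W)) / 2
  structure(W, eigvals = e$values, kept = seq_len(s), s = as.integer(s))
}

#' Overall chi-square statistic from multiple residuals
#'
#' Quadratic form `T = n r' W r` with `W` from [weight_matrix()]; under
#' correct specification `T` is asymptotically chi-square with `s` degrees of
#' freedom, for any admissible `s`.
#'
#' @param r Residual vector.
#' @param W Weight matrix from [weight_matrix()] built from the same ACM.
#' @param n Sample size.
#' @param s Degrees of freedom; defaults to the `s` recorded on `W`.
#' @return Object of class `"t_result"`: `T`, `s`, `p` (upper tail),
#'   `eigvals`, `kept`.
#' @export
t_statistic <- function(r, W, n, s = attr(W, "s")) {
  stopifnot(length(r) == nrow(W))
  T <- n * as.numeric(crossprod(r, W %*% r))
  if (T < -1e-8)
    stop("negative quadratic form: weight matrix not PSD on the retained ",
         "subspace", call. = FALSE)
  T <- max(T, 0)
  structure(list(T = T, s = s, p = stats::pchisq(T, df = s,
                                                 lower.tail = FALSE),
                 eigvals = attr(W, "eigvals"), kept = attr(W, "kept")),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat("Overall chi-square test: T =", format(x$T, digits = 4),
      " df =", x$s, " p =", format.pval(x$p, digits = 3), "\n")
  invisible(x)
}
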