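#' Specify a confirmatory factor model
#'
#' Defines the structure of a linear normal common factor model: the number of
#' manifest variables (MVs), the latent dimension, which loadings are free, and
#' how the latent scale is identified.
#'
#' Two identification schemes are supported. Under `"unit_factor_variance"` the
#' diagonal of the factor covariance `Phi` is fixed at 1 and the off-diagonal
#' correlations are free. Under `"anchor_loading"` the first free loading of
#' each factor is fixed at 1 and `Phi` is fully free.
#'
#' @param m Number of manifest variables.
#' @param d Latent dimension.
#' @param pattern `m x d` 0/1 matrix marking free loadings (1 = free). Defaults
#'   to all free for `d = 1` and must be given otherwise. Every factor needs at
#'   least one free loading, and every MV must load on at least one factor.
#' @param identification `"unit_factor_variance"` (default) or
#'   `"anchor_loading"`.
#' @param mean_structure Logical; if `TRUE` (default) the `m` intercepts are
#'   free parameters.
#'
#' @return An object of class `"fa_model_spec"` with elements `m`, `d`,
#'   `pattern`, `identification`, `mean_structure`, `anchor` (row index of the
#'   anchored loading per factor, or `NULL`), and `npar`.
#' @export
#' @examples
#' ## two-factor independent-cluster model for 6 MVs
#' pat <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
#' fa_model_spec(6, 2, pat)
fa_model_spec <- function(m, d, pattern = NULL,
                          identification = c("unit_factor_variance",
                                             "anchor_loading"),
                          mean_structure = TRUE) {
  stopifnot(is_count(m), is_count(d))
  identification <- match.arg(identification)
  if (is.null(pattern)) {
    if (d == 1L) pattern <- matrix(1, m, 1)
    else stop("'pattern' must be supplied when d > 1", call. = FALSE)
  }
  pattern <- as.matrix(pattern)
  if (!all(dim(pattern) == c(m, d)))
    stop("'pattern' must be an m x d matrix", call. = FALSE)
  if (!all(pattern %in% c(0, 1)))
    stop("'pattern' entries must be 0 or 1", call. = FALSE)
  if (any(colSums(pattern) < 1))
    stop("every factor needs at least one free loading", call. = FALSE)
  if (any(rowSums(pattern) < 1))
    stop("every manifest variable must load on at least one factor",
         call. = FALSE)
  anchor <- NULL
  free_pattern <- pattern
  if (identification == "anchor_loading") {
    anchor <- apply(pattern, 2L, function(col) which(col == 1)[1L])
    for (k in seq_len(d)) free_pattern[anchor[k], k] <- 0
  }
  n_lambda <- sum(free_pattern)
  n_phi <- if (identification == "unit_factor_variance") d * (d - 1L) / 2L
           else d * (d + 1L) / 2L
  npar <- (if (mean_structure) m else 0L) + n_lambda + n_phi + m
  structure(list(m = as.integer(m), d = as.integer(d), pattern = pattern,
                 free_pattern = free_pattern, identification = identification,
                 mean_structure = isTRUE(mean_structure), anchor = anchor,
                 npar = as.integer(npar)),
            class = "fa_model_spec")
}

#' @export
print.fa_model_spec <- function(x, ...) {
  cat("Linear normal factor model specification\n")
  cat("  manifest variables:", x$m, " latent dimension:", x$d, "\n")
  cat("  identification:", x$identification,
      " mean structure:", x$mean_structure, "\n")
  cat("  free parameters:", x$npar, "\n")
  invisible(x)
}

## Index bookkeeping for the packed parameter vector theta. Fixed ordering:
## (nu, free Lambda entries column-major, free lower-triangle Phi column-major,
## Psi). Scores, the information matrix, and the ACM all depend on it.
theta_index <- function(spec) {
  m <- spec$m; d <- spec$d
  n_nu <- if (spec$mean_structure) m else 0L
  lam_idx <- which(spec$free_pattern == 1)       # column-major positions
  n_lam <- length(lam_idx)
  if (spec$identification == "unit_factor_variance") {
    phi_pos <- which(lower.tri(diag(d)))
  } else {
    phi_pos <- which(lower.tri(diag(d), diag = TRUE))
  }
  n_phi <- length(phi_pos)
  list(nu = seq_len(n_nu),
       lambda = n_nu + seq_len(n_lam),
       phi = n_nu + n_lam + seq_len(n_phi),
       psi = n_nu + n_lam + n_phi + seq_len(m),
       lam_pos = lam_idx, phi_pos = phi_pos,
       p = n_nu + n_lam + n_phi + m)
}
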