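#' Singular value soft-thresholding
#'
#' The proximal operator of the nuclear norm: each singular value of `X` is
#' replaced by `max(sigma - tau, 0)` while the singular vectors are kept.
#'
#' @param X numeric matrix.
#' @param tau nonnegative threshold.
#' @return Matrix of the same shape.
#' @export
svt <- function(X, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  sv <- svd(X)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(X), ncol(X)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Elementwise soft-thresholding (shrinkage)
#'
#' `sgn(x) * max(|x| - tau, 0)`, the proximal operator of the l1 norm.
#'
#' @param X numeric matrix or vector.
#' @param tau nonnegative threshold.
#' @return Object of the same shape.
#' @export
shrink <- function(X, tau) {
  if (tau < 0) stop("tau must be nonnegative")
  sign(X) * pmax(abs(X) - tau, 0)
}

#' Robust PCA by principal component pursuit
#'
#' Splits `M = L + S` with `L` low-rank and `S` sparse by solving
#' `min ||L||_* + lambda ||S||_1 s.t. M = L + S` with the augmented
#' Lagrange multiplier iteration: `L <- svt(M - S + Y/mu, 1/mu)`,
#' `S <- shrink(M - L + Y/mu, lambda/mu)`, `Y <- Y + mu (M - L - S)` until
#' the relative feasibility residual `||M - L - S||_F / ||M||_F` falls
#' below `tol`. `lambda` defaults to `1/sqrt(P)` with `P` the larger matrix
#' dimension, and `mu` to the classic `n1 n2 / (4 ||M||_1)`.
#'
#' In the heart-rate pipeline `L` is the "background" signal carrying the
#' pulse and `S` absorbs sparse outliers from abrupt motion or tracking
#' glitches; only `L` proceeds to source separation.
#'
#' @param M numeric matrix (or [channel_series()], whose values are used).
#' @param lam sparsity weight `lambda`; `NULL` for the `P^(-1/2)` default.
#' @param mu penalty parameter; `NULL` for the default above.
#' @param tol relative feasibility tolerance.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   flagged `converged = FALSE` with a warning.
#' @return An object of class `rpca_decomposition`: `L`, `S`, `Y`, `mu`,
#'   `lam`, `iters`, `residual`, `converged`.
#' @export
#' @examples
#' M <- tcrossprod(rnorm(3), rnorm(50))
#' dec <- pcp(M)
#' dec$residual
pcp <- function(M, lam = NULL, mu = NULL, tol = 1e-7, max_iter = 500L) {
  if (inherits(M, "channel_series")) M <- M$values
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("pcp input must be finite")
  n1 <- nrow(M); n2 <- ncol(M)
  if (is.null(lam)) lam <- 1 / sqrt(max(n1, n2))
  if (lam <= 0) stop("lam must be positive")
  normM <- sqrt(sum(M^2))
  L <- matrix(0, n1, n2); S <- L; Y <- L
  if (normM == 0) {
    return(structure(list(L = L, S = S, Y = Y, mu = Inf, lam = lam,
                          iters = 1L, residual = 0, converged = TRUE),
                     class = "rpca_decomposition"))
  }
  if (is.null(mu)) mu <- n1 * n2 / (4 * sum(abs(M)))
  converged <- FALSE
  res <- Inf
  for (it in seq_len(max_iter)) {
    L <- svt(M - S + Y / mu, 1 / mu)
    S <- shrink(M - L + Y / mu, lam / mu)
    R <- M - L - S
    Y <- Y + mu * R
    res <- sqrt(sum(R^2)) / normM
    if (res <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("pcp did not converge in %d iterations (residual %.3g)",
                    max_iter, res))
  structure(list(L = L, S = S, Y = Y, mu = mu, lam = lam,
                 iters = it, residual = res, converged = converged),
            class = "rpca_decomposition")
}

#' @export
print.rpca_decomposition <- function(x, ...) {
  cat(sprintf(
    "<rpca_decomposition> %dx%d  lambda=%.4g  iters=%d  residual=%.3g%s\n",
    nrow(x$L), ncol(x$L), x$lam, x$iters, x$residual,
    if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}
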