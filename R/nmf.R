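#' Non-negative matrix factorization by multiplicative updates
#'
#' Classical Lee–Seung multiplicative updates for the Frobenius objective
#' `||X - W H||_F^2` with `W >= 0`, `H >= 0`. Used throughout as the linear
#' baseline against the non-linear joint factorization. Denominators carry a
#' small epsilon guard so zero rows/columns decay to zero instead of
#' producing NaNs; the residual trace is non-increasing (the classical
#' monotonicity guarantee of these updates).
#'
#' @param X Non-negative numeric matrix (m x n).
#' @param k Rank, `k < min(m, n)`.
#' @param max_iter Number of update sweeps.
#' @param seed Seed for random initialization.
#' @param init `"svd"` (NNDSVD-style non-negative projection of the
#'   truncated SVD, deterministic) or `"random"` (`|N(0,1)|` entries).
#' @param eps Denominator guard.
#' @return An object of class `nmf_result`: list with `W` (m x k), `H`
#'   (k x n) and `residual_trace` (squared Frobenius residual per
#'   iteration, including the initial residual).
#' @examples
#' X <- tcrossprod(runif(10), runif(8))
#' res <- nmf_multiplicative(X, k = 1, max_iter = 200, seed = 1)
#' tail(res$residual_trace, 1)
#' @export
nmf_multiplicative <- function(X, k, max_iter = 200L, seed = 1L,
                               init = c("svd", "random"), eps = 1e-10) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative for NMF", call. = FALSE)
  m <- nrow(X); n <- ncol(X)
  if (k >= min(m, n)) stop("rank k must be smaller than min(dim(X))", call. = FALSE)

  if (init == "random") {
    set.seed(seed)
    W <- abs(matrix(stats::rnorm(m * k), m, k))
    H <- abs(matrix(stats::rnorm(k * n), k, n))
  } else {
    f <- truncated_svd(X, k)
    # NNDSVD-style: keep the dominant non-negative part of each rank-1 term
    W <- pmax(f$left, 0)
    H <- pmax(f$right, 0)
    W[W == 0] <- eps
    H[H == 0] <- eps
  }

  trace <- numeric(max_iter + 1L)
  trace[1L] <- sum((X - W %*% H)^2)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    trace[it + 1L] <- sum((X - W %*% H)^2)
  }
  structure(list(W = W, H = H, residual_trace = trace),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> %d x %d, rank %d, final residual %.6g\n",
              nrow(x$W), ncol(x$H), ncol(x$W),
              utils::tail(x$residual_trace, 1)))
  invisible(x)
}

#' @rdname nmf_multiplicative
#' @param x An `nmf_result`.
#' @param ... Unused.
#' @export
glance.nmf_result <- function(x, ...) {
  tibble::tibble(
    rank = ncol(x$W),
    iterations = length(x$residual_trace) - 1L,
    residual = utils::tail(x$residual_trace, 1),
    monotone = all(diff(x$residual_trace) <=
                     1e-12 * pmax(utils::head(x$residual_trace, -1), 1))
  )
}

#' Shift a mixed-sign matrix into the non-negative orthant
#'
#' Subtracts each column's (negative) minimum so all entries are >= 0;
#' used to feed mixed-sign data such as the Gaussian simulated views to
#' the NMF baseline, which requires non-negative input.
#'
#' @param X Numeric matrix.
#' @return A matrix with the same shape, all entries non-negative.
#' @export
shift_nonneg <- function(X) {
  mins <- apply(X, 2L, min)
  sweep(X, 2L, pmin(mins, 0), "-")
}
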