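#' Truncated randomized SVD of a (sparse) matrix
#'
#' Approximates the top-`t` singular triplets of `A` with the randomized
#' range-finder scheme: project onto `t + oversample` Gaussian probe
#' vectors, refine the basis with `power_iters` subspace iterations
#' (re-orthonormalizing each half-step for numerical stability), then take
#' an exact SVD of the small projected matrix and truncate to rank `t`.
#' Only matrix-vector products with `A` and `t(A)` are used, so `A` may be
#' large and sparse.
#'
#' Signs are fixed so the largest-magnitude entry of each left singular
#' vector is positive; the reconstruction `U diag(d) t(V)` is invariant to
#' this choice.
#'
#' @param A numeric matrix (dense or `Matrix` sparse), m x n.
#' @param t retained rank, `1 <= t <= min(m, n)`.
#' @param oversample extra probe vectors (default 10).
#' @param power_iters subspace (power) iterations (default 4).
#' @param seed integer seed for the Gaussian probes.
#' @return object of class `"svd_view"`: list with `u` (m x t), `d` (length-t
#'   non-increasing singular values), `v` (n x t), and `t`.
#' @examples
#' A <- matrix(rnorm(48), 8, 6)
#' sv <- randomized_svd(A, t = 3, seed = 1)
#' sv$d
#' @export
randomized_svd <- function(A, t, oversample = 10, power_iters = 4, seed = 1) {
  m <- nrow(A); n <- ncol(A)
  if (t < 1 || t > min(m, n)) {
    stop("rank t must lie in [1, ", min(m, n), "], got ", t)
  }
  r <- min(t + oversample, min(m, n))
  with_seed(seed, {
    omega <- matrix(stats::rnorm(n * r), n, r)
    Y <- as.matrix(A %*% omega)
    Q <- qr.Q(qr(Y))
    for (it in seq_len(power_iters)) {
      Z <- as.matrix(Matrix::crossprod(A, Q)) # t(A) %*% Q
      Z <- qr.Q(qr(Z))
      Y <- as.matrix(A %*% Z)
      Q <- qr.Q(qr(Y))
    }
    B <- as.matrix(Matrix::crossprod(Q, A)) # r x n
    sv <- svd(B, nu = t, nv = t)
    u <- Q %*% sv$u
    v <- sv$v
    d <- sv$d[seq_len(t)]
    # sign convention: dominant entry of each u column positive
    for (kcol in seq_len(t)) {
      s <- sign(u[which.max(abs(u[, kcol])), kcol])
      if (s < 0) {
        u[, kcol] <- -u[, kcol]
        v[, kcol] <- -v[, kcol]
      }
    }
    structure(list(u = u, d = d, v = v, t = t), class = "svd_view")
  })
}

#' @exportS3Method base::print
print.svd_view <- function(x, ...) {
  cat(sprintf("Truncated SVD view: rank %d, %d x %d, singular values [%s]\n",
              x$t, nrow(x$u), nrow(x$v),
              paste(signif(x$d, 4), collapse = ", ")))
  invisible(x)
}

#' Reconstruct the low-rank matrix of an SVD view
#'
#' `U diag(d) t(V)`, materialized. Only intended for small matrices
#' (tests, inspection); propagation always stays in factored form.
#'
#' @param view an `svd_view`.
#' @return dense m x n matrix.
#' @export
svd_reconstruct <- function(view) {
  view$u %*% (view$d * t(view$v))
}
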