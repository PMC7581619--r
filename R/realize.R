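#' Impulse responses of the identified input-output model
#'
#' Per-channel unit-impulse simulation of the difference equation. Row `k+1`
#' holds `H(k) = (h_n(k), h_s(k))` for `k = 0..N`; `H(0) = 0` because the
#' model has a one-sample input delay, and `H(1) = (b1, b3)`.
#'
#' @param poly An [io_poly()].
#' @param N Horizon (number of non-zero-lag samples). Default 48.
#' @return An `(N+1) x 2` matrix with columns `h_n`, `h_s` and attribute
#'   `"lags" = 0:N`.
#' @export
impulse_response <- function(poly, N = 48) {
  stopifnot(N >= 1)
  rho <- max(Mod(polyroot(c(poly$a2, poly$a1, 1))))
  if (rho >= 1)
    warning(sprintf("denominator has root magnitude %.4g >= 1: impulse response does not decay", rho))
  imp <- c(1, numeric(N))
  zero <- numeric(N + 1)
  H <- cbind(h_n = simulate_io(poly, imp, zero),
             h_s = simulate_io(poly, zero, imp))
  attr(H, "lags") <- 0:N
  H
}

#' Block-Hankel matrix of impulse responses
#'
#' Lays out the `1 x 2` impulse-response blocks so block `(i, j)` is
#' `H(i + j - 1)`, padding with zero blocks past the last available lag.
#' The padding is only harmless when the impulse-response tail is
#' negligible; [ho_kalman()] avoids it by using an unpadded rectangle.
#'
#' @param H Impulse-response matrix from [impulse_response()] (rows are
#'   lags `0..N`).
#' @param rows Number of block rows.
#' @return A `rows x (2*rows)`-ish numeric matrix (`rows` block rows and
#'   `rows` block columns of width 2).
#' @export
build_hankel <- function(H, rows) {
  N <- nrow(H) - 1L
  stopifnot(rows >= 1, rows <= N)
  blk <- function(k) if (k <= N) H[k + 1L, , drop = FALSE] else matrix(0, 1, 2)
  do.call(rbind, lapply(seq_len(rows), function(i)
    do.call(cbind, lapply(seq_len(rows), function(j) blk(i + j - 1L)))))
}

#' Singular value decomposition by Gram-Schmidt QR iteration
#'
#' Pedagogical alternative to the standard SVD backend: the eigenvalue
#' problem of `X'X` is solved by plain QR iteration, with each QR step
#' computed by classical Gram-Schmidt orthogonalization (with one
#' re-orthogonalization pass for stability). Singular values are the square
#' roots of the eigenvalues; left vectors are recovered as `X v / sigma`.
#' Intended as an independent cross-check of the library SVD on
#' well-conditioned problems, not as a replacement.
#'
#' @param X Numeric matrix.
#' @param iter Number of QR iterations. Default 300.
#' @param tol Relative cutoff below which singular directions are dropped
#'   from the left-vector recovery. Default 1e-12.
#' @return A list with `d`, `u`, `v` like [base::svd()] (thin form,
#'   `min(dim(X))` columns).
#' @export
svd_gram_schmidt <- function(X, iter = 300, tol = 1e-12) {
  wide <- nrow(X) < ncol(X)
  A <- if (wide) X %*% t(X) else crossprod(X)   # symmetric PSD
  n <- nrow(A)
  gs_qr <- function(M) {
    Q <- matrix(0, nrow(M), ncol(M)); R <- matrix(0, ncol(M), ncol(M))
    for (j in seq_len(ncol(M))) {
      v <- M[, j]
      for (pass in 1:2) for (i in seq_len(j - 1L)) {
        pr <- sum(Q[, i] * v); R[i, j] <- R[i, j] + pr; v <- v - pr * Q[, i]
      }
      R[j, j] <- sqrt(sum(v^2))
      Q[, j] <- if (R[j, j] > 0) v / R[j, j] else 0
    }
    list(Q = Q, R = R)
  }
  V <- diag(n); M <- A
  for (k in seq_len(iter)) {
    f <- gs_qr(M)
    M <- f$R %*% f$Q
    V <- V %*% f$Q
  }
  ev <- diag(M)
  ord <- order(ev, decreasing = TRUE)
  d <- sqrt(pmax(ev[ord], 0))
  V <- V[, ord, drop = FALSE]
  # recover the other factor through X, guarding rank-deficient directions
  other <- matrix(0, if (wide) ncol(X) else nrow(X), n)
  keep <- d > tol * max(d, .Machine$double.xmin)
  if (wide) other[, keep] <- crossprod(X, V[, keep]) %*% diag(1 / d[keep], sum(keep))
  else other[, keep] <- X %*% V[, keep] %*% diag(1 / d[keep], sum(keep))
  if (wide) list(d = d, u = V, v = other) else list(d = d, u = other, v = V)
}

# unpadded r x c block Hankel (r + c - 1 <= N)
hankel_rect <- function(H, r, c) {
  do.call(rbind, lapply(seq_len(r), function(i)
    do.call(cbind, lapply(seq_len(c), function(j) H[i + j, , drop = FALSE]))))
}

#' Select the model order from Hankel singular values
#'
#' Smallest `r` whose next singular value falls below `tol` relative to the
#' largest; `force` overrides (the digestion model is second order by
#' construction).
#'
#' @param sigma Singular values, sorted non-increasing.
#' @param tol Relative cutoff `sigma(r+1)/sigma(1)` (default 1e-3).
#' @param force Optional fixed order to return regardless of `sigma`.
#' @return Integer order.
#' @export
order_select <- function(sigma, tol = 1e-3, force = NULL) {
  if (!is.null(force)) return(as.integer(force))
  if (length(sigma) == 0L) stop("no singular values supplied")
  if (any(diff(sigma) > 1e-12)) stop("singular values must be sorted non-increasing")
  rel <- sigma / sigma[1]
  below <- which(rel < tol)
  if (length(below)) as.integer(min(below) - 1L) else length(sigma)
}

#' Minimal state-space realization from impulse responses (Ho-Kalman)
#'
#' Assembles an unpadded rectangular block-Hankel matrix from the impulse
#' responses, takes its SVD, splits it into balanced observability and
#' reachability factors `Omega = U sqrt(Sigma)`, `Gamma = sqrt(Sigma) V'`
#' (truncated to `order`), and recovers
#' `A = pinv(Omega[1:r-1]) Omega[2:r]` (block-shift), `B` as the first
#' block column of `Gamma`, and `C` as the first block row of `Omega`.
#' The realization is unique up to state-space similarity, so it is
#' validated by its Markov parameters, not its matrices.
#'
#' @param H Impulse-response matrix from [impulse_response()].
#' @param order Model order; must not exceed the numerical rank of the
#'   Hankel matrix.
#' @param rows Number of block rows of the internal Hankel rectangle
#'   (default `floor((N+1)/2)`, the most square unpadded choice).
#' @param dt Sampling interval to stamp on the model (default 1 h).
#' @param svd_method `"base"` (library SVD, default) or `"gram_schmidt"`
#'   (QR-iteration path, see [svd_gram_schmidt()]).
#' @return A discrete [state_space()] model with attribute
#'   `"singular_values"`.
#' @export
ho_kalman <- function(H, order, rows = NULL, dt = 1,
                      svd_method = c("base", "gram_schmidt")) {
  svd_method <- match.arg(svd_method)
  N <- nrow(H) - 1L
  if (is.null(rows)) rows <- max(2L, (N + 1L) %/% 2L)
  rows <- min(rows, N - 1L)
  cols <- N - rows            # rows + cols <= N, all blocks from data
  Hn <- hankel_rect(H, rows, cols)
  sv <- if (svd_method == "base") svd(Hn) else svd_gram_schmidt(Hn)
  tol_rank <- max(dim(Hn)) * .Machine$double.eps * sv$d[1]
  num_rank <- sum(sv$d > max(tol_rank, 1e-12 * sv$d[1]))
  if (is.na(num_rank) || num_rank == 0L)
    stop("Hankel matrix is numerically zero: no realizable dynamics")
  if (order > num_rank)
    stop(sprintf("requested order %d exceeds numerical rank %d (singular values: %s)",
                 order, num_rank,
                 paste(sprintf("%.3g", utils::head(sv$d, 8)), collapse = ", ")))
  sq <- sqrt(sv$d[seq_len(order)])
  Omega <- sv$u[, seq_len(order), drop = FALSE] %*% diag(sq, order)
  Gamma <- diag(sq, order) %*% t(sv$v[, seq_len(order), drop = FALSE])
  up <- Omega[seq_len(rows - 1L), , drop = FALSE]
  dn <- Omega[1L + seq_len(rows - 1L), , drop = FALSE]
  A <- qr.solve(up, dn)       # pinv(Omega_1:r-1) Omega_2:r via least squares
  B <- Gamma[, 1:2, drop = FALSE]
  C <- Omega[1, , drop = FALSE]
  ss <- state_space(A, B, C, dt = dt, domain = "discrete")
  attr(ss, "singular_values") <- sv$d
  ss
}

#' Markov parameters of a discrete state-space model
#'
#' `H(0) = 0`, `H(k) = C A^(k-1) B` for `k >= 1`, stacked like
#' [impulse_response()].
#'
#' @param ss A discrete [state_space()] model.
#' @param N Horizon.
#' @return An `(N+1) x 2` matrix.
#' @export
markov_parameters <- function(ss, N = 48) {
  out <- matrix(0, N + 1L, ncol(ss$B),
                dimnames = list(NULL, c("h_n", "h_s")[seq_len(ncol(ss$B))]))
  Ak <- diag(nrow(ss$A))
  for (k in seq_len(N)) {
    out[k + 1L, ] <- as.numeric(ss$C %*% Ak %*% ss$B)
    Ak <- Ak %*% ss$A
  }
  out
}
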