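#' Adaptive-identifier configuration
#'
#' Tunables of the parameter-estimation system. The regressor filter is the
#' monic second-order polynomial `Lambda(q) = (q + l)^2` built from the
#' control-system design constant `l`; the two input channels are multiplied
#' by scaling coefficients `m_n` and `m_s` before filtering to balance their
#' contributions in the regressor Gram matrix (the substrate channel's gas
#' contribution is orders of magnitude larger per unit input than the
#' bacteria channel's).
#'
#' @param l Control-system design constant; `|l| < 1` so the filter
#'   `1/(q+l)^2` is stable. Default 0.1.
#' @param m_n Scaling coefficient, bacteria channel (> 0). Default 1.
#' @param m_s Scaling coefficient, substrate channel (> 0). Default 1e-4.
#' @param h_filter Output filter `h(q^-1)` coefficients applied to the
#'   predicted output; default `1` (identity pass-through).
#' @param window Maximum number of most-recent samples retained by windowed
#'   estimation (default `Inf`, i.e. growing window; 144 h is a practical
#'   choice to track slowly drifting operating conditions).
#' @param switch_holdover How many samples after the latest substrate
#'   feeding the substrate switch stays closed. Substrate responses ring on
#'   long after an impulsive feeding, so the default `Inf` keeps the switch
#'   closed permanently once feeding has commenced (it is open only during
#'   an unfed lead-in term); a finite value re-opens it between feedings.
#' @return An `identifier_config` object.
#' @export
identifier_config <- function(l = 0.1, m_n = 1, m_s = 1e-4, h_filter = 1,
                              window = Inf, switch_holdover = Inf) {
  if (abs(l) >= 1) stop("|l| must be < 1 for a stable regressor filter")
  if (m_n <= 0 || m_s <= 0) stop("scaling coefficients must be positive")
  if (window < 6) stop("window must be at least 6 samples")
  structure(list(l = l, m_n = m_n, m_s = m_s, h_filter = as.numeric(h_filter),
                 window = window, switch_holdover = switch_holdover),
            class = "identifier_config")
}

# second-order all-pole filters used on every regressor channel:
#   q / (q + l)^2 :  x(k) = -2l x(k-1) - l^2 x(k-2) + u(k-1)
#   1 / (q + l)^2 :  x(k) = -2l x(k-1) - l^2 x(k-2) + u(k-2)
# zero initial conditions throughout.
lambda_filter <- function(u, l, delay) {
  N <- length(u)
  x <- numeric(N)
  for (k in seq_len(N)) {
    x1 <- if (k >= 2) x[k - 1] else 0
    x2 <- if (k >= 3) x[k - 2] else 0
    ud <- if (k > delay) u[k - delay] else 0
    x[k] <- -2 * l * x1 - l^2 * x2 + ud
  }
  x
}

#' Build the filtered regressor matrix
#'
#' Generates the six control signals of the adaptive identifier from an
#' hourly operation record. With `Lambda(q) = (q + l)^2`:
#' `xi11, xi21` are `q/Lambda` and `1/Lambda` applied to `m_n * u_n`;
#' `xi12, xi22` the same applied to `m_s * u_s`; and `xi3, xi4` the same
#' applied to the (scaled) measured output. The linear-in-parameters output
#' model is then `y(k) = theta' xi(k)` with
#' `theta = (b1, b3, b2, b4, 2l - a1, l^2 - a2)` — see [pack_parameters()].
#'
#' @param series An [operation_series()] (or any data frame with columns
#'   `u_n`, `u_s`, `y` sampled at a fixed interval).
#' @param cfg An [identifier_config()].
#' @return An `N x 6` matrix with columns
#'   `xi11, xi12, xi21, xi22, xi3, xi4`.
#' @export
build_regressors <- function(series, cfg) {
  if (!is.null(series$time_h)) {
    dt <- diff(series$time_h)
    if (length(dt) && any(abs(dt - dt[1]) > 1e-9))
      stop("operation series must be uniformly sampled")
  }
  un <- cfg$m_n * series$u_n
  us <- cfg$m_s * series$u_s
  ym <- series$y
  l <- cfg$l
  Xi <- cbind(
    xi11 = lambda_filter(un, l, 1L),
    xi12 = lambda_filter(us, l, 1L),
    xi21 = lambda_filter(un, l, 2L),
    xi22 = lambda_filter(us, l, 2L),
    xi3  = lambda_filter(ym, l, 1L),
    xi4  = lambda_filter(ym, l, 2L)
  )
  Xi
}

#' Predicted (scaled) output from a parameter vector
#'
#' `y_hat(k) = h(q^-1) theta' xi(k)`; with the default identity filter this
#' is the plain inner product.
#'
#' @param theta Length-6 parameter vector.
#' @param xi A length-6 regressor vector, or an `N x 6` matrix.
#' @param cfg An [identifier_config()].
#' @return Predicted output (scalar or length-`N` vector).
#' @export
predict_output <- function(theta, xi, cfg = identifier_config()) {
  if (is.matrix(xi)) raw <- as.numeric(xi %*% theta)
  else raw <- sum(theta * xi)
  h <- cfg$h_filter
  if (length(h) == 1L && h == 1) return(raw)
  as.numeric(stats::filter(raw, h, method = "convolution", sides = 1)) |>
    (\(z) { z[is.na(z)] <- 0; z })()
}

#' Output error
#'
#' @param y Measured output.
#' @param y_hat Predicted output.
#' @return `y - y_hat`.
#' @export
output_error <- function(y, y_hat) y - y_hat

#' Batch least-squares parameter estimate
#'
#' Solves the normal equations `(Xi' Xi) theta = Xi' y` by QR factorization
#' (no explicit inverse). An optional Gaussian prior `(theta0, P0)` adds the
#' ridge term `P0^-1` — exactly the implicit prior of recursive least
#' squares started from `(theta0, P0)`, so the two estimators can be
#' compared sample for sample.
#'
#' @param Xi `N x 6` regressor matrix (rows are samples).
#' @param y Length-`N` output vector.
#' @param prior Optional list with elements `theta0` (length 6) and `P0`
#'   (6x6 or scalar variance); `NULL` for plain least squares.
#' @return Length-6 estimate `theta_hat`.
#' @export
batch_ls <- function(Xi, y, prior = NULL) {
  Xi <- as.matrix(Xi)
  stopifnot(nrow(Xi) == length(y))
  if (is.null(prior)) {
    if (nrow(Xi) < ncol(Xi))
      stop("insufficient excitation: fewer samples than parameters")
    qrX <- qr(Xi)
    if (qrX$rank < ncol(Xi)) {
      null_dir <- qr.Q(qrX, complete = TRUE)[, ncol(Xi), drop = TRUE]
      stop(sprintf(
        "insufficient excitation: regressor matrix rank %d < %d (null direction ~ [%s])",
        qrX$rank, ncol(Xi), paste(sprintf("%.3g", null_dir), collapse = ", ")))
    }
    return(as.numeric(qr.coef(qrX, y)))
  }
  P0 <- prior$P0
  if (length(P0) == 1L) P0 <- diag(as.numeric(P0), ncol(Xi))
  theta0 <- prior$theta0
  if (is.null(theta0)) theta0 <- numeric(ncol(Xi))
  # augmented least squares: stack chol(P0^-1) rows anchoring theta0
  Rp <- chol(solve(P0))
  Xa <- rbind(Xi, Rp)
  ya <- c(y, as.numeric(Rp %*% theta0))
  as.numeric(qr.coef(qr(Xa), ya))
}

#' Initialize the recursive least-squares estimator
#'
#' @param cfg An [identifier_config()].
#' @param P0 Initial covariance scale (default `1e6`, i.e. a diffuse prior
#'   `P = 1e6 * I`); may also be a full 6x6 matrix.
#' @param theta0 Initial estimate (default all zero).
#' @return An `rls_state` list with fields `theta`, `P`, `K`, `count`,
#'   `theta_history` and the configuration.
#' @export
rls_init <- function(cfg = identifier_config(), P0 = 1e6, theta0 = numeric(6)) {
  P <- if (length(P0) == 1L) diag(as.numeric(P0), 6) else as.matrix(P0)
  structure(list(theta = theta0, P = P, K = numeric(6), count = 0L,
                 cfg = cfg, theta_history = NULL, hold = Inf),
            class = "rls_state")
}

#' One recursive least-squares update
#'
#' Standard covariance-form RLS without forgetting:
#' `K = P xi / (1 + xi' P xi)`, `theta <- theta + K (y - xi' theta)`,
#' `P <- P - K xi' P` (kept symmetric). When the substrate switch is open
#' (no substrate feeding active) the substrate-channel regressor entries
#' `xi12` and `xi22` are zeroed so only the bacteria-channel and output
#' parameters move — the identifier treats the plant as two
#' single-input subsystems sharing one output.
#'
#' @param st An `rls_state` from [rls_init()] or a previous update.
#' @param xi Length-6 regressor vector.
#' @param y Measured (scaled) output at this sample.
#' @param switch_open Logical; `TRUE` when no substrate feeding is active.
#' @param forgetting Exponential forgetting factor in (0, 1]; default 1
#'   (growing window).
#' @return The updated `rls_state`; `theta_history` gains one row.
#' @export
rls_update <- function(st, xi, y, switch_open = FALSE, forgetting = 1) {
  xi <- as.numeric(xi)
  stopifnot(length(xi) == 6L)
  if (switch_open) xi[c(2, 4)] <- 0
  P <- st$P
  denom <- forgetting + sum(xi * (P %*% xi))
  K <- as.numeric(P %*% xi) / denom
  eps <- y - sum(st$theta * xi)
  theta <- st$theta + K * eps
  P <- (P - tcrossprod(K, as.numeric(crossprod(xi, P)))) / forgetting
  P <- (P + t(P)) / 2
  st$theta <- theta; st$P <- P; st$K <- K
  st$count <- st$count + 1L
  st$theta_history <- rbind(st$theta_history, theta)
  st
}

#' Pack an input-output model into the identifier parameter vector
#'
#' `theta = (b1*m-scaled, b3*m-scaled, b2, b4, 2l - a1, l^2 - a2)` in the
#' identifier's ordering and channel scaling (`b`'s divided by the channel
#' scaling coefficient because the regressors carry the scaled inputs).
#'
#' @param poly An [io_poly()] in physical (unscaled) coefficients.
#' @param cfg An [identifier_config()].
#' @return Length-6 theta vector.
#' @export
pack_parameters <- function(poly, cfg = identifier_config()) {
  l <- cfg$l
  c(poly$b1 / cfg$m_n, poly$b3 / cfg$m_s,
    poly$b2 / cfg$m_n, poly$b4 / cfg$m_s,
    2 * l - poly$a1, l^2 - poly$a2)
}

#' Unpack an identifier parameter vector into an input-output model
#'
#' Inverse of [pack_parameters()]: `a1 = 2l - theta5`, `a2 = l^2 - theta6`,
#' and the numerator coefficients are returned to physical scale by undoing
#' the input-channel scaling.
#'
#' @param theta Length-6 parameter vector as estimated.
#' @param cfg The [identifier_config()] used to build the regressors.
#' @return An [io_poly()].
#' @export
unpack_parameters <- function(theta, cfg = identifier_config()) {
  l <- cfg$l
  io_poly(a1 = 2 * l - theta[5], a2 = l^2 - theta[6],
          b1 = theta[1] * cfg$m_n, b2 = theta[3] * cfg$m_n,
          b3 = theta[2] * cfg$m_s, b4 = theta[4] * cfg$m_s)
}

#' Run the adaptive identifier over an operation record
#'
#' Convenience driver: builds the regressors, runs the recursive estimator
#' sample by sample with the substrate switch driven by `u_s` (open when no
#' substrate feeding is active, with the configured hold-over), and unpacks
#' the final estimate.
#'
#' @param series An [operation_series()].
#' @param cfg An [identifier_config()].
#' @param st Optional estimator state to continue from (default fresh
#'   [rls_init()]); pass the state returned by a previous call to identify
#'   across several operation terms.
#' @return A list with `state` (final `rls_state`), `theta` (final
#'   estimate), `poly` (unpacked [io_poly()]), `theta_history`
#'   (`N x 6` matrix) and `residuals` (one-step output errors).
#' @export
identify_series <- function(series, cfg = identifier_config(), st = NULL) {
  Xi <- build_regressors(series, cfg)
  if (is.null(st)) st <- rls_init(cfg)
  res <- numeric(nrow(Xi))
  since_feed <- st$hold   # samples since the latest substrate feeding (Inf: never fed)
  for (k in seq_len(nrow(Xi))) {
    if (series$u_s[k] > 0) since_feed <- 0
    else if (is.finite(since_feed)) since_feed <- since_feed + 1
    switch_open <- since_feed > cfg$switch_holdover
    res[k] <- series$y[k] - sum(st$theta * Xi[k, ])
    st <- rls_update(st, Xi[k, ], series$y[k], switch_open = switch_open)
  }
  st$hold <- since_feed
  list(state = st, theta = st$theta, poly = unpack_parameters(st$theta, cfg),
       theta_history = st$theta_history, residuals = res)
}
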