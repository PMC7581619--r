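#' Kinetic parameters of the anaerobic-digestion process model
#'
#' Bundles the biological rate constants of the lumped two-state digestion
#' model: logistic bacterial growth with Monod-Haldane substrate-inhibited
#' specific growth rate, first-order autolysis, yield-coupled substrate
#' decomposition, and biogas generation proportional to the active biomass.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param k_s Dissociation (half-saturation) constant (kg/m^3).
#' @param k_i Substrate-inhibition coefficient (m^3/kg); 0 recovers plain
#'   Monod kinetics.
#' @param b Autolysis (decay) rate of the bacterial population (1/h).
#' @param n_max Maximum (carrying-capacity) bacterial concentration (kg/m^3).
#' @param Y Bacterial cell yield, kg biomass per kg substrate (dimensionless).
#' @param k_g1,k_g2 Biogas generation coefficients (m^3 gas per kg), weighting
#'   the autolysis-driven and growth-driven contributions respectively.
#' @param m Sludge volume in the reactor (m^3); constant for the semi-batch,
#'   completely mixed reactor assumed here.
#' @param output_form Either `"canonical"` (gas rate
#'   `(k_g1*b + k_g2*mu/Y)*m*n`) or `"swapped"`
#'   (`(k_g1*mu/Y + k_g2*b)*m*n`), exchanging the roles of the two gas
#'   coefficients.
#'
#' @return An object of class `kinetic_params` (a validated list).
#' @export
kinetic_params <- function(mu_max, k_s, k_i, b, n_max, Y,
                           k_g1, k_g2, m = 0.2,
                           output_form = c("canonical", "swapped")) {
  output_form <- match.arg(output_form)
  p <- list(mu_max = mu_max, k_s = k_s, k_i = k_i, b = b, n_max = n_max,
            Y = Y, k_g1 = k_g1, k_g2 = k_g2, m = m, output_form = output_form)
  num <- p[setdiff(names(p), "output_form")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all kinetic parameters must be finite scalars")
  if (p$k_i < 0) stop("k_i must be >= 0")
  pos <- c("mu_max", "k_s", "b", "n_max", "Y", "k_g1", "k_g2", "m")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    stop("kinetic parameters must be strictly positive: ", paste(bad, collapse = ", "))
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Anaerobic-digestion kinetic parameters\n")
  cat(sprintf("  mu_max %.4g 1/h, k_s %.4g kg/m^3, k_i %.4g m^3/kg, b %.4g 1/h\n",
              x$mu_max, x$k_s, x$k_i, x$b))
  cat(sprintf("  n_max %.4g kg/m^3, Y %.4g, k_g1 %.4g, k_g2 %.4g m^3/kg, m %.4g m^3\n",
              x$n_max, x$Y, x$k_g1, x$k_g2, x$m))
  cat(sprintf("  gas output form: %s\n", x$output_form))
  invisible(x)
}

#' Monod-Haldane specific growth rate
#'
#' `mu(s) = mu_max * s / (k_s + s + k_i * s^2)`: saturating in substrate with
#' inhibition at high concentration. For `k_i > 0` the rate is unimodal with
#' its maximum at `s* = sqrt(k_s / k_i)`, where it equals
#' `mu_max / (1 + 2 * sqrt(k_s * k_i))`.
#'
#' @param s Substrate concentration (kg/m^3); vectorized. Negative values are
#'   evaluated as written (the linear model may report them).
#' @param p A [kinetic_params()] object.
#' @return Specific growth rate (1/h), same length as `s`.
#' @export
specific_growth_rate <- function(s, p) {
  p$mu_max * s / (p$k_s + s + p$k_i * s^2)
}

# d mu / d s, used by the analytic Jacobian
growth_rate_slope <- function(s, p) {
  den <- p$k_s + s + p$k_i * s^2
  p$mu_max * (p$k_s - p$k_i * s^2) / den^2
}

#' Time derivatives of the fermentation state
#'
#' Right-hand side of the two-state mass-balance model:
#' `dn/dt = (mu(s) - b) * n * (1 - n/n_max) + u_n` and
#' `ds/dt = -(1/Y) * mu(s) * n + u_s`.
#'
#' @param x Numeric state `c(n, s)` (kg/m^3).
#' @param u Numeric feed rates `c(u_n, u_s)` (kg/m^3/h).
#' @param p A [kinetic_params()] object.
#' @return Numeric `c(dn_dt, ds_dt)` (kg/m^3/h).
#' @export
ad_derivatives <- function(x, u, p) {
  n <- x[[1]]; s <- x[[2]]
  mu <- specific_growth_rate(s, p)
  c((mu - p$b) * n * (1 - n / p$n_max) + u[[1]],
    -mu * n / p$Y + u[[2]])
}

#' Biogas generation rate
#'
#' Gas production proportional to the active biomass, with an autolysis-driven
#' and a growth-driven contribution:
#' `v = (k_g1*b + k_g2*mu(s)/Y) * m * n` (canonical form; see
#' [kinetic_params()] for the swapped alternative).
#'
#' @param n Bacterial concentration (kg/m^3); vectorized.
#' @param s Substrate concentration (kg/m^3); vectorized.
#' @param p A [kinetic_params()] object.
#' @return Biogas flow (m^3/h).
#' @export
biogas_rate <- function(n, s, p) {
  mu <- specific_growth_rate(s, p)
  if (p$output_form == "canonical")
    (p$k_g1 * p$b + p$k_g2 * mu / p$Y) * p$m * n
  else
    (p$k_g1 * mu / p$Y + p$k_g2 * p$b) * p$m * n
}

#' Feed schedule with zero-order-held rates
#'
#' @param t_start Strictly increasing event times (h); the rates in row `i`
#'   hold from `t_start[i]` until the next event (or forever for the last).
#'   Before the first event both rates are zero.
#' @param u_n,u_s Non-negative bacteria / substrate feed rates (kg/m^3/h).
#' @return A `feed_schedule` data frame.
#' @export
feed_schedule <- function(t_start, u_n, u_s) {
  stopifnot(length(t_start) == length(u_n), length(u_n) == length(u_s))
  if (length(t_start) && any(diff(t_start) <= 0))
    stop("feed schedule times must be strictly increasing")
  if (any(u_n < 0) || any(u_s < 0))
    stop("feed rates must be non-negative")
  structure(data.frame(t_start = as.numeric(t_start),
                       u_n = as.numeric(u_n), u_s = as.numeric(u_s)),
            class = c("feed_schedule", "data.frame"))
}

#' Turn an hourly input series into a feed schedule
#'
#' Hour `k` of `u_n`/`u_s` (1-based) is held over `[k-1, k)` h.
#' @param u_n,u_s Hourly feed-rate vectors (kg/m^3/h).
#' @return A [feed_schedule()].
#' @export
hourly_feeds <- function(u_n, u_s) {
  stopifnot(length(u_n) == length(u_s))
  feed_schedule(seq_along(u_n) - 1, u_n, u_s)
}

# rates held at time t (zero before the first event)
feed_rates_at <- function(feeds, t) {
  if (is.null(feeds) || nrow(feeds) == 0L) return(c(0, 0))
  # guard well above float roundoff of the step times, well below any step
  i <- findInterval(t + 1e-7, feeds$t_start)
  if (i == 0L) c(0, 0) else c(feeds$u_n[i], feeds$u_s[i])
}

#' Simulate the nonlinear digestion model
#'
#' Fixed-step fourth-order Runge-Kutta integration of the two-state model
#' with zero-order-held feed rates. The state and the biogas flow are
#' recorded every `record_dt` hours. A first excursion into negative
#' substrate is reported as a warning ("deficient state") rather than
#' clamped: the lumped model interprets `s < 0` as the methanogens running
#' out of accessible substrate.
#'
#' @param p A [kinetic_params()] object.
#' @param x0 Initial state `c(n, s)` (kg/m^3), `n >= 0`.
#' @param feeds A [feed_schedule()] (or `NULL` for no feeding).
#' @param duration Simulation length (h), > 0.
#' @param step RK4 step (h); must divide `record_dt` sensibly (it is snapped
#'   to an integer number of sub-steps per record).
#' @param record_dt Recording interval (h), default 1 (hourly records).
#' @return A data frame with columns `time_h`, `n`, `s`, `v` (gas flow,
#'   m^3/h), of class `ad_trajectory`.
#' @export
simulate_ad <- function(p, x0, feeds = NULL, duration, step = 0.05,
                        record_dt = 1) {
  stopifnot(duration > 0, step > 0, step <= record_dt)
  n_rec <- ceiling(duration / record_dt)
  n_sub <- max(1L, round(record_dt / step))
  h <- record_dt / n_sub
  times <- numeric(n_rec + 1L); nn <- numeric(n_rec + 1L)
  ss <- numeric(n_rec + 1L); vv <- numeric(n_rec + 1L)
  x <- c(x0[[1]], x0[[2]])
  times[1] <- 0; nn[1] <- x[1]; ss[1] <- x[2]
  vv[1] <- biogas_rate(x[1], x[2], p)
  warned_deficient <- FALSE
  t <- 0
  for (r in seq_len(n_rec)) {
    for (j in seq_len(n_sub)) {
      # sub-step time from integer counters, not accumulation, so the
      # zero-order-hold feed lookup lands on schedule boundaries exactly
      t0 <- ((r - 1) * n_sub + (j - 1)) * h
      u <- feed_rates_at(feeds, t0)
      k1 <- ad_derivatives(x, u, p)
      k2 <- ad_derivatives(x + h / 2 * k1, u, p)
      k3 <- ad_derivatives(x + h / 2 * k2, u, p)
      k4 <- ad_derivatives(x + h * k3, u, p)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t0 + h
      if (!all(is.finite(x)))
        stop(sprintf("non-finite state at t = %.4f h; aborting simulation", t))
      if (!warned_deficient && x[2] < 0) {
        warning(sprintf(
          "substrate concentration negative from t = %.2f h (deficient state)", t))
        warned_deficient <- TRUE
      }
    }
    times[r + 1L] <- t; nn[r + 1L] <- x[1]; ss[r + 1L] <- x[2]
    vv[r + 1L] <- biogas_rate(x[1], x[2], p)
  }
  structure(data.frame(time_h = times, n = nn, s = ss, v = vv),
            class = c("ad_trajectory", "data.frame"))
}

#' Discrete or continuous linear state-space model
#'
#' Container for the two-state, two-input, one-output linear model
#' `dX/dt = A X + B U, y = C X` (continuous) or
#' `X(k+1) = A X(k) + B U(k), y(k) = C X(k)` (discrete).
#'
#' @param A 2x2 (or n x n) state matrix.
#' @param B n x 2 input matrix.
#' @param C 1 x n output matrix (a numeric vector is accepted).
#' @param dt Sampling interval (h); `NA` for continuous models.
#' @param domain `"continuous"` or `"discrete"`.
#' @return A `state_space` object.
#' @export
state_space <- function(A, B, C, dt = NA_real_,
                        domain = c("continuous", "discrete")) {
  domain <- match.arg(domain)
  A <- as.matrix(A); B <- as.matrix(B)
  C <- matrix(as.numeric(C), nrow = 1)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (nrow(B) != nrow(A)) stop("B must have as many rows as A")
  if (ncol(C) != nrow(A)) stop("C must have as many columns as A has rows")
  if (!all(is.finite(A)) || !all(is.finite(B)) || !all(is.finite(C)))
    stop("state-space matrices must be finite")
  if (domain == "discrete" && (is.na(dt) || dt <= 0))
    stop("discrete models need a positive sampling interval dt")
  structure(list(A = A, B = B, C = C, dt = dt, domain = domain),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("%s state-space model (%d states, %d inputs)",
              x$domain, nrow(x$A), ncol(x$B)))
  if (x$domain == "discrete") cat(sprintf(", dt = %g h", x$dt))
  cat("\nA:\n"); print(x$A)
  cat("B:\n"); print(x$B)
  cat("C:\n"); print(x$C)
  invisible(x)
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Linearize the digestion model around an operating point
#'
#' Analytic Jacobians of the state equations and the gas-output map,
#' evaluated at `(x_eq, u_eq)`. The inputs enter additively, so the input
#' Jacobian is exactly the identity. The operating point need not be an
#' exact equilibrium: the residual `F(x_eq, u_eq)` is attached as attribute
#' `"residual"` for the caller to inspect.
#'
#' @param p A [kinetic_params()] object.
#' @param x_eq State `c(n, s)` at the operating point (kg/m^3).
#' @param u_eq Feed rates `c(u_n, u_s)` at the operating point (kg/m^3/h).
#' @return A continuous [state_space()] model with attribute `"residual"`.
#' @export
linearize_ad <- function(p, x_eq, u_eq = c(0, 0)) {
  n <- x_eq[[1]]; s <- x_eq[[2]]
  mu <- specific_growth_rate(s, p)
  dmu <- growth_rate_slope(s, p)
  A <- matrix(c(
    (mu - p$b) * (1 - 2 * n / p$n_max), dmu * n * (1 - n / p$n_max),
    -mu / p$Y,                          -dmu * n / p$Y
  ), nrow = 2, byrow = TRUE)
  B <- diag(2)
  if (p$output_form == "canonical") {
    C <- c((p$k_g1 * p$b + p$k_g2 * mu / p$Y) * p$m,
           p$k_g2 * dmu * n * p$m / p$Y)
  } else {
    C <- c((p$k_g1 * mu / p$Y + p$k_g2 * p$b) * p$m,
           p$k_g1 * dmu * n * p$m / p$Y)
  }
  ss <- state_space(A, B, C, domain = "continuous")
  attr(ss, "residual") <- ad_derivatives(x_eq, u_eq, p)
  ss
}

#' Exact zero-order-hold discretization
#'
#' `A_d = expm(A dt)` and `B_d = (integral_0^dt expm(A tau) dtau) B`,
#' computed in one shot from the matrix exponential of the augmented
#' `[A B; 0 0]` system. `C` is unchanged.
#'
#' @param ss A continuous [state_space()] model.
#' @param dt Sampling interval (h).
#' @return A discrete [state_space()] model.
#' @export
discretize_ss <- function(ss, dt) {
  if (ss$domain != "continuous")
    stop("discretize_ss expects a continuous-domain model")
  stopifnot(dt > 0)
  n <- nrow(ss$A); m <- ncol(ss$B)
  aug <- rbind(cbind(ss$A, ss$B), matrix(0, m, n + m))
  E <- as.matrix(Matrix::expm(aug * dt))
  state_space(E[1:n, 1:n, drop = FALSE], E[1:n, n + 1:m, drop = FALSE],
              ss$C, dt = dt, domain = "discrete")
}

#' Discrete input-output polynomial model
#'
#' Second-order two-input one-output difference-equation model
#' `y(k) = -a1 y(k-1) - a2 y(k-2) + b1 u_n(k-1) + b2 u_n(k-2)
#'        + b3 u_s(k-1) + b4 u_s(k-2)`,
#' i.e. transfer functions `(b1 q + b2) / (q^2 + a1 q + a2)` for the
#' bacteria channel and `(b3 q + b4) / (q^2 + a1 q + a2)` for the substrate
#' channel.
#'
#' @param a1,a2 Output-side (denominator) coefficients.
#' @param b1,b2 Bacteria-channel numerator coefficients.
#' @param b3,b4 Substrate-channel numerator coefficients.
#' @return An `io_poly` object.
#' @export
io_poly <- function(a1, a2, b1, b2, b3, b4) {
  v <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, b3 = b3, b4 = b4)
  if (!all(is.finite(v))) stop("io_poly coefficients must be finite")
  structure(as.list(v), class = "io_poly")
}

#' @export
print.io_poly <- function(x, ...) {
  cat("Discrete input-output model (order 2, 2 inputs / 1 output)\n")
  cat(sprintf("  denominator: q^2 + (%.5g) q + (%.5g)\n", x$a1, x$a2))
  cat(sprintf("  bacteria channel:  (%.5g) q + (%.5g)\n", x$b1, x$b2))
  cat(sprintf("  substrate channel: (%.5g) q + (%.5g)\n", x$b3, x$b4))
  invisible(x)
}

#' Input-output polynomial of a discrete 2-state model
#'
#' Denominator from the characteristic polynomial (`a1 = -trace(A)`,
#' `a2 = det(A)`); per-channel numerators from `C adj(qI - A) B[,j]`, so
#' the leading numerator coefficient of channel `j` is `C B[,j]`.
#'
#' @param ss A discrete 2-state [state_space()] model.
#' @return An [io_poly()].
#' @export
io_polynomial <- function(ss) {
  if (ss$domain != "discrete")
    stop("io_polynomial expects a discrete-domain model")
  A <- ss$A; B <- ss$B; C <- ss$C
  if (nrow(A) != 2L) stop("io_polynomial is defined for 2-state models")
  adjA <- matrix(c(A[2, 2], -A[1, 2], -A[2, 1], A[1, 1]), 2, 2, byrow = TRUE)
  lead <- as.numeric(C %*% B)          # coefficient of q, per channel
  const <- as.numeric(-C %*% adjA %*% B) # constant coefficient, per channel
  io_poly(a1 = -sum(diag(A)), a2 = det(A),
          b1 = lead[1], b2 = const[1], b3 = lead[2], b4 = const[2])
}

#' Simulate the input-output polynomial model
#'
#' Runs the difference equation from rest (zero initial conditions).
#'
#' @param poly An [io_poly()].
#' @param u_n,u_s Input sequences (equal length).
#' @return Output sequence `y`, same length.
#' @export
simulate_io <- function(poly, u_n, u_s) {
  stopifnot(length(u_n) == length(u_s))
  N <- length(u_n)
  y <- numeric(N)
  for (k in seq_len(N)) {
    y1 <- if (k >= 2) y[k - 1] else 0
    y2 <- if (k >= 3) y[k - 2] else 0
    un1 <- if (k >= 2) u_n[k - 1] else 0
    un2 <- if (k >= 3) u_n[k - 2] else 0
    us1 <- if (k >= 2) u_s[k - 1] else 0
    us2 <- if (k >= 3) u_s[k - 2] else 0
    y[k] <- -poly$a1 * y1 - poly$a2 * y2 +
      poly$b1 * un1 + poly$b2 * un2 + poly$b3 * us1 + poly$b4 * us2
  }
  y
}
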