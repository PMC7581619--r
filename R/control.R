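#' Reference-trajectory specification
#'
#' A piecewise-constant set-point for the biogas production rate together
#' with a ramp rate. The derived reference trajectory moves from its current
#' level toward the active set-point at no more than `ramp_rate` per sample
#' and is clamped below at zero, giving the ideal ramp-plateau-ramp
#' transition the controller tracks.
#'
#' @param times Sample indices (h) at which each set-point level starts.
#' @param values Set-point levels (L/h), same length as `times`.
#' @param ramp_rate Maximum reference change per sample (L/h per h).
#'   Default 0.46.
#' @param r0 Reference level at sample 0. Default 0.
#' @return A `trajectory_spec` object.
#' @export
trajectory_spec <- function(times = c(0, 121), values = c(22, 0),
                            ramp_rate = 0.46, r0 = 0) {
  stopifnot(length(times) == length(values), ramp_rate > 0,
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, values = values, ramp_rate = ramp_rate,
                 r0 = r0), class = "trajectory_spec")
}

setpoint_at <- function(spec, k) {
  i <- findInterval(k, spec$times)
  ifelse(i == 0L, spec$r0, spec$values[pmax(i, 1L)])
}

#' Build the reference trajectory
#'
#' @param spec A [trajectory_spec()].
#' @param k Sample indices (non-negative integers; any order).
#' @return Reference values `r(k)`, clamped to `[0, max set-point]`.
#' @export
build_reference <- function(spec, k) {
  stopifnot(all(k >= 0))
  kmax <- max(k)
  r <- numeric(kmax + 1L)
  r[1] <- spec$r0
  if (kmax >= 1) for (i in seq_len(kmax)) {
    s <- setpoint_at(spec, i)
    step <- max(-spec$ramp_rate, min(spec$ramp_rate, s - r[i]))
    r[i + 1L] <- max(0, r[i] + step)
  }
  r[k + 1L]
}

#' MPC configuration
#'
#' Horizons and weights of the feedstock-determination controller. Outputs
#' are costed over samples `k + H_w .. k + H_p`; input moves are free over
#' the first `H_u` samples and zero afterwards (input held constant beyond
#' the control horizon).
#'
#' @param H_w Window parameter: first costed prediction step (>= 1).
#' @param H_p Prediction horizon. Default 48 (one full reference ramp).
#' @param H_u Control horizon (`1 <= H_u <= H_p`). Default 24.
#' @param Q Per-step scalar output weight (>= 0). Default 1.
#' @param R Per-step 2x2 input-change weight, positive definite; default
#'   `diag(c(100, 10))` — bacteria moves penalized 10x harder than
#'   substrate moves so the controller feeds substrate, not seed biomass.
#' @param u_floor Elementwise lower bound on the applied feed rates
#'   (default 0: feeds cannot be withdrawn).
#' @return An `mpc_config` object.
#' @export
mpc_config <- function(H_w = 1, H_p = 48, H_u = 24, Q = 1,
                       R = diag(c(100, 10)), u_floor = 0) {
  stopifnot(H_w >= 1, H_w <= H_p, H_u >= 1, H_u <= H_p, Q >= 0)
  R <- as.matrix(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("R must be positive definite")
  structure(list(H_w = as.integer(H_w), H_p = as.integer(H_p),
                 H_u = as.integer(H_u), Q = Q, R = R, u_floor = u_floor),
            class = "mpc_config")
}

#' Stacked prediction matrices for the Delta-u form MPC
#'
#' With model `x(k+1) = A x(k) + B u(k)`, `z(k) = C x(k)`, input moves
#' `u(k+t) = u(k-1) + sum of Delta-u up to t`, and the stacked prediction
#' `Z = Psi x(k) + Upsilon u(k-1) + T DeltaU` over steps `H_w .. H_p`,
#' where `DeltaU` stacks the `H_u` free moves at offsets `0 .. H_u - 1`.
#'
#' @param ss A discrete [state_space()] model.
#' @param cfg An [mpc_config()].
#' @return A list with matrices `Psi` (`nz x n`), `Upsilon` (`nz x 2`),
#'   `T` (`nz x 2*H_u`) and the model/config, class `prediction_matrices`.
#' @export
build_prediction_matrices <- function(ss, cfg) {
  if (ss$domain != "discrete") stop("MPC needs a discrete model")
  A <- ss$A; B <- ss$B; C <- ss$C
  n <- nrow(A); m <- ncol(B)
  steps <- cfg$H_w:cfg$H_p
  nz <- length(steps)
  # powers of A and cumulative Markov sums S_i = C (I + A + ... + A^(i-1)) B
  Apow <- vector("list", cfg$H_p + 1L); Apow[[1]] <- diag(n)
  for (i in seq_len(cfg$H_p)) Apow[[i + 1L]] <- Apow[[i]] %*% A
  CS <- vector("list", cfg$H_p + 1L)    # CS[[i+1]] = C * sum_{d=0}^{i-1} A^d * B
  acc <- matrix(0, n, m)
  CS[[1]] <- matrix(0, 1, m)
  for (i in seq_len(cfg$H_p)) {
    acc <- acc + Apow[[i]] %*% B
    CS[[i + 1L]] <- C %*% acc
  }
  Psi <- do.call(rbind, lapply(steps, function(i) ss$C %*% Apow[[i + 1L]]))
  Upsilon <- do.call(rbind, lapply(steps, function(i) CS[[i + 1L]]))
  Tm <- matrix(0, nz, m * cfg$H_u)
  for (ri in seq_len(nz)) {
    i <- steps[ri]
    for (t in seq_len(cfg$H_u)) {      # move at offset t-1
      if (t - 1L <= i - 1L)
        Tm[ri, (t - 1L) * m + seq_len(m)] <- CS[[i - t + 2L]]
    }
  }
  structure(list(Psi = Psi, Upsilon = Upsilon, T = Tm, ss = ss, cfg = cfg),
            class = "prediction_matrices")
}

#' Tracking error of the free response
#'
#' `E = Gamma_ref - Psi x - Upsilon u_prev`: what remains for the input
#' moves to correct after letting the model coast on the previous input.
#'
#' @param ref Stacked reference vector over steps `H_w .. H_p`.
#' @param M A [build_prediction_matrices()] result.
#' @param x Current model state.
#' @param u_prev Previously applied input (length 2).
#' @return Tracking-error vector.
#' @export
tracking_error <- function(ref, M, x, u_prev) {
  as.numeric(ref - M$Psi %*% x - M$Upsilon %*% u_prev)
}

#' Solve the unconstrained MPC least-squares problem
#'
#' Minimizes `V = ||T dU - E||^2_Q + ||dU||^2_R` via the normal equations
#' `(T' Qbar T + Rbar) dU = T' Qbar E` (solved by Cholesky; `Rbar` positive
#' definite guarantees a unique minimizer). If the implied input trajectory
#' falls below the floor, the violated entries are pinned to the floor and
#' the remaining free moves are re-solved once (single-pass active set).
#'
#' @param M A [build_prediction_matrices()] result.
#' @param E Tracking-error vector from [tracking_error()].
#' @param u_prev Previously applied input (length 2), needed to locate
#'   floor violations.
#' @return A list with `dU` (`H_u x 2` move matrix), `U` (`H_u x 2` implied
#'   input trajectory, floored), `Z` (contribution `T dU` of the moves to
#'   the predicted outputs; the predicted output is the free response plus
#'   `Z`), `V` (cost at the solution) and `E`.
#' @export
solve_mpc <- function(M, E, u_prev = c(0, 0)) {
  cfg <- M$cfg
  m <- ncol(M$ss$B); Hu <- cfg$H_u
  Tm <- M$T
  Rbar <- kronecker(diag(Hu), cfg$R)
  G <- cfg$Q * crossprod(Tm) + Rbar
  f <- cfg$Q * as.numeric(crossprod(Tm, E))
  dU <- as.numeric(solve(G, f))
  u_traj <- function(dU) {
    d <- matrix(dU, ncol = m, byrow = TRUE)
    sweep(apply(d, 2, cumsum), 2, u_prev, "+")
  }
  U <- u_traj(dU)
  viol <- which(U < cfg$u_floor - 1e-12, arr.ind = TRUE)
  if (nrow(viol)) {
    # pin violated inputs to the floor: sum of moves up to step j equals
    # floor - u_prev for each violated (step, channel); KKT solve, one pass
    S <- matrix(0, nrow(viol), m * Hu)
    d <- numeric(nrow(viol))
    for (v in seq_len(nrow(viol))) {
      j <- viol[v, 1]; ch <- viol[v, 2]
      S[v, (seq_len(j) - 1L) * m + ch] <- 1
      d[v] <- cfg$u_floor - u_prev[ch]
    }
    KKT <- rbind(cbind(G, t(S)), cbind(S, matrix(0, nrow(S), nrow(S))))
    sol <- solve(KKT, c(f, d))
    dU <- sol[seq_len(m * Hu)]
    U <- u_traj(dU)
  }
  U <- pmax(U, cfg$u_floor)
  resid <- as.numeric(Tm %*% dU) - E
  V <- cfg$Q * sum(resid^2) + as.numeric(t(dU) %*% Rbar %*% dU)
  list(dU = matrix(dU, ncol = m, byrow = TRUE), U = U,
       Z = as.numeric(Tm %*% dU), V = V, E = E)
}

#' Hourly stepping hook for the nonlinear plant
#'
#' Wraps the nonlinear simulator as a closure advancing one hour per call,
#' for use as the `plant` argument of [receding_horizon()]. Inputs arrive
#' in g/L/h (numerically equal to kg/m^3/h); the returned output is in L/h.
#'
#' @param p A [kinetic_params()] object.
#' @param x0 Initial state `c(n, s)` (kg/m^3).
#' @param step RK4 sub-step (h).
#' @return A function `f(u)` returning the biogas flow (L/h) after one hour
#'   under the zero-order-held feed rates `u`.
#' @export
nonlinear_plant_hook <- function(p, x0, step = 0.05) {
  x <- c(x0[[1]], x0[[2]])
  function(u) {
    traj <- simulate_ad(p, x, feed_schedule(0, u[1], u[2]),
                        duration = 1, step = step)
    x <<- c(traj$n[nrow(traj)], traj$s[nrow(traj)])
    1000 * traj$v[nrow(traj)]
  }
}

#' Closed-loop receding-horizon simulation
#'
#' At every sample the controller builds the tracking error from the
#' current model state and reference preview, solves the MPC least-squares
#' problem, applies the first input move to the plant, and advances the
#' internal model state with the open-loop predictor
#' `x <- A x + B u` (optionally corrected by an output-error innovation
#' gain).
#'
#' @param plant Either a discrete [state_space()] model (simulated
#'   internally) or a closure `f(u) -> y` advancing the true plant one
#'   sample (see [nonlinear_plant_hook()]).
#' @param model The discrete [state_space()] prediction model used by the
#'   controller.
#' @param cfg An [mpc_config()].
#' @param spec A [trajectory_spec()].
#' @param duration Number of closed-loop samples (h).
#' @param x0_model,x0_plant Initial states (default zero; `x0_plant` is
#'   ignored when `plant` is a closure).
#' @param innovation_gain Optional length-`n` gain `L` for the correction
#'   `x <- x + L (y_plant - C x)` after the predictor step; `NULL` (default)
#'   for pure open-loop prediction.
#' @return A data frame log (class `mpc_run`) with columns `time_h`, `u_n`,
#'   `u_s`, `y_model`, `y_plant`, `r`, plus attribute `"cost"` (per-step
#'   optimal cost).
#' @export
receding_horizon <- function(plant, model, cfg, spec, duration,
                             x0_model = NULL, x0_plant = NULL,
                             innovation_gain = NULL) {
  M <- build_prediction_matrices(model, cfg)
  n <- nrow(model$A)
  x_m <- if (is.null(x0_model)) numeric(n) else x0_model
  plant_is_ss <- inherits(plant, "state_space")
  if (plant_is_ss) {
    if (!is.null(plant$dt) && !is.na(plant$dt) && !is.na(model$dt) &&
        abs(plant$dt - model$dt) > 1e-12)
      stop("plant and model must share the sampling interval")
    x_p <- if (is.null(x0_plant)) numeric(nrow(plant$A)) else x0_plant
  }
  u_prev <- c(0, 0)
  out <- data.frame(time_h = seq_len(duration), u_n = NA_real_,
                    u_s = NA_real_, y_model = NA_real_, y_plant = NA_real_,
                    r = build_reference(spec, seq_len(duration)))
  cost <- numeric(duration)
  for (k in seq_len(duration)) {
    ref <- build_reference(spec, (k - 1) + cfg$H_w:cfg$H_p)
    E <- tracking_error(ref, M, x_m, u_prev)
    sol <- solve_mpc(M, E, u_prev)
    u <- pmax(sol$U[1, ], cfg$u_floor)
    x_m <- as.numeric(model$A %*% x_m + model$B %*% u)
    if (plant_is_ss) {
      x_p <- as.numeric(plant$A %*% x_p + plant$B %*% u)
      y_p <- as.numeric(plant$C %*% x_p)
    } else {
      y_p <- plant(u)
    }
    if (!is.finite(y_p))
      stop(sprintf("non-finite plant output at step %d; aborting", k))
    if (!is.null(innovation_gain))
      x_m <- x_m + innovation_gain * (y_p - as.numeric(model$C %*% x_m))
    out$u_n[k] <- u[1]; out$u_s[k] <- u[2]
    out$y_model[k] <- as.numeric(model$C %*% x_m)
    out$y_plant[k] <- y_p
    cost[k] <- sol$V
    u_prev <- u
  }
  attr(out, "cost") <- cost
  class(out) <- c("mpc_run", "data.frame")
  out
}

#' Integrate the optimal input into feasible discrete feedings
#'
#' Converts the continuous hourly optimal feed-rate series into a sparse
#' schedule of one-hour feeding events by a greedy accumulate-and-release
#' forward pass: the hourly optimal feed mass accumulates, and the whole
#' accumulated amount is released at the latest hour such that the
#' model-predicted output deviation from the continuous-input prediction
#' stays within `bound` at every sample inside the constraint `window`.
#' Any remainder is flushed at the final hour, so the total released mass
#' equals the total optimal mass exactly.
#'
#' @param u_opt `K x 2` matrix of hourly optimal feed rates (columns
#'   `u_n`, `u_s`), all `>= 0`.
#' @param ss The discrete [state_space()] model used for the deviation
#'   prediction.
#' @param bound Maximum allowed output deviation (L/h) inside the window.
#'   Default 5.
#' @param window `c(first, last)` output sample (h) over which the bound is
#'   enforced. Default `c(48, 120)`.
#' @param lookahead Deviation-prediction depth (samples) of the feasibility
#'   check. Default 48.
#' @return A list with `u` (`K x 2` discrete hourly feed rates), `events`
#'   (data frame `hour`, `u_n`, `u_s` of release events), `y` (model output
#'   under the discrete feeds), `y_cont` (under the continuous feeds) and
#'   `deviation` (`y - y_cont`).
#' @export
discretize_feeding <- function(u_opt, ss, bound = 5, window = c(48, 120),
                               lookahead = 48) {
  u_opt <- as.matrix(u_opt)
  stopifnot(ncol(u_opt) == 2, all(u_opt >= -1e-12))
  u_opt[u_opt < 0] <- 0
  K <- nrow(u_opt)
  A <- ss$A; B <- ss$B; C <- ss$C
  n <- nrow(A)
  # deviation state d = x_discrete - x_continuous; y deviation = C d
  dev_ok <- function(d, feeds, k0) {
    # feeds: list of input differences applied at steps k0, k0+1, ...;
    # afterwards the discrete plan returns to the optimal rates (zero diff)
    L <- min(lookahead, K - k0 + length(feeds))
    for (j in seq_len(L)) {
      df <- if (j <= length(feeds)) feeds[[j]] else c(0, 0)
      d <- as.numeric(A %*% d + B %*% df)
      tj <- k0 + j - 1L   # output sample index of this step
      if (tj >= window[1] && tj <= window[2] &&
          abs(sum(C * d)) > bound) return(FALSE)
    }
    TRUE
  }
  d <- numeric(n)
  acc <- c(0, 0)
  u_disc <- matrix(0, K, 2, dimnames = list(NULL, c("u_n", "u_s")))
  events <- data.frame(hour = integer(), u_n = numeric(), u_s = numeric())
  for (k in seq_len(K)) {
    acc <- acc + u_opt[k, ]
    # hold: zero feed now, release everything (incl. next hour's mass) next
    # hour; input diffs vs the optimal plan are -u_opt[k] now, +acc next
    hold_feasible <- k < K && dev_ok(d, list(-u_opt[k, ], acc), k)
    if (hold_feasible || all(acc == 0)) {
      d <- as.numeric(A %*% d + B %*% (-u_opt[k, ]))
    } else {
      if (!dev_ok(d, list(acc - u_opt[k, ]), k) && k >= window[1] && k <= window[2])
        stop(sprintf("feeding bound %.3g infeasible at hour %d even with immediate release",
                     bound, k))
      u_disc[k, ] <- acc
      events <- rbind(events,
                      data.frame(hour = k, u_n = acc[1], u_s = acc[2]))
      d <- as.numeric(A %*% d + B %*% (acc - u_opt[k, ]))
      acc <- c(0, 0)
    }
  }
  sim_lin <- function(u) {
    x <- numeric(n); y <- numeric(K)
    for (k in seq_len(K)) {
      x <- as.numeric(A %*% x + B %*% u[k, ])
      y[k] <- sum(C * x)
    }
    y
  }
  y_disc <- sim_lin(u_disc)
  y_cont <- sim_lin(u_opt)
  list(u = u_disc, events = events, y = y_disc, y_cont = y_cont,
       deviation = y_disc - y_cont)
}
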