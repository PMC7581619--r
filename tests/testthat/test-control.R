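test_that("reference trajectory ramps, plateaus, ramps down clamped at zero", {
  spec <- trajectory_spec()
  expect_equal(build_reference(spec, 10), 4.6)
  expect_equal(build_reference(spec, 100), 22)
  expect_equal(build_reference(spec, 130), 22 - 0.46 * 10, tolerance = 1e-12)
  r <- build_reference(spec, 0:200)
  expect_true(all(r >= 0 & r <= 22))
  expect_true(all(abs(diff(r)) <= 0.46 + 1e-12))
  expect_equal(r[201], 0)   # fully ramped down
})

test_that("prediction matrices reproduce explicit step-by-step simulation", {
  ss <- rand_stable_ss(51)
  cfg <- mpc_config(H_w = 1, H_p = 12, H_u = 5, R = diag(c(1, 1)))
  M <- build_prediction_matrices(ss, cfg)
  set.seed(51)
  x0 <- rnorm(2); u_prev <- rnorm(2); dU <- matrix(rnorm(10), 5, 2)
  # oracle: run the recursion with held inputs
  x <- x0; u <- u_prev; z <- numeric(cfg$H_p)
  for (i in 1:cfg$H_p) {
    if (i <= cfg$H_u) u <- u + dU[i, ]
    x <- as.numeric(ss$A %*% x + ss$B %*% u)
    z[i] <- as.numeric(ss$C %*% x)
  }
  pred <- as.numeric(M$Psi %*% x0 + M$Upsilon %*% u_prev +
                     M$T %*% as.numeric(t(dU)))
  expect_equal(pred, z[cfg$H_w:cfg$H_p], tolerance = 1e-10)
  # all-zero arguments predict zero
  expect_equal(as.numeric(M$Psi %*% c(0, 0)), numeric(12))

  # H_u = 1: single block column of cumulative Markov sums
  cfg1 <- mpc_config(H_w = 1, H_p = 6, H_u = 1, R = diag(c(1, 1)))
  M1 <- build_prediction_matrices(ss, cfg1)
  cs <- t(vapply(1:6, function(i)
    as.numeric(ss$C %*% Reduce(`+`, lapply(0:(i - 1), function(d)
      matpow(ss$A, d))) %*% ss$B), numeric(2)))
  expect_equal(unname(M1$T), unname(cs), tolerance = 1e-10)
})

test_that("tracking error is reference minus free response", {
  ss <- rand_stable_ss(52)
  cfg <- mpc_config(H_p = 8, H_u = 3, R = diag(c(1, 1)))
  M <- build_prediction_matrices(ss, cfg)
  set.seed(52)
  x <- rnorm(2); u_prev <- rnorm(2); ref <- rnorm(8)
  free <- as.numeric(M$Psi %*% x + M$Upsilon %*% u_prev)
  expect_equal(tracking_error(ref, M, x, u_prev), ref - free)
  expect_equal(tracking_error(free, M, x, u_prev), numeric(8))
  expect_equal(tracking_error(ref, M, c(0, 0), c(0, 0)), ref)
})

test_that("the MPC solve matches a brute-force quadratic oracle and is a true minimum", {
  n_agree <- 0
  for (seed in 1:25) {
    ss <- rand_stable_ss(seed)
    cfg <- mpc_config(H_w = 1, H_p = 6, H_u = 3, Q = 1,
                      R = diag(c(0.5, 0.2)), u_floor = -Inf)
    M <- build_prediction_matrices(ss, cfg)
    set.seed(seed + 500)
    E <- rnorm(6, 0, 2)
    sol <- solve_mpc(M, E, u_prev = c(0, 0))
    # oracle: cost by explicit closed-loop simulation, quadratic rebuilt by
    # exact finite differences (step 1 is exact for a quadratic)
    cost <- function(dU) {
      d <- matrix(dU, ncol = 2, byrow = TRUE)
      x <- c(0, 0); u <- c(0, 0); z <- numeric(cfg$H_p)
      for (i in 1:cfg$H_p) {
        if (i <= cfg$H_u) u <- u + d[i, ]
        x <- as.numeric(ss$A %*% x + ss$B %*% u)
        z[i] <- as.numeric(ss$C %*% x)
      }
      dd <- as.numeric(t(d))
      sum((z - E)^2) + sum(dd * as.numeric(kronecker(diag(3), cfg$R) %*% dd))
    }
    m <- 6
    G <- matrix(0, m, m); f <- numeric(m); c0 <- cost(numeric(m))
    for (i in 1:m) {
      ei <- numeric(m); ei[i] <- 1
      f[i] <- (cost(-ei) - cost(ei)) / 2
      G[i, i] <- cost(ei) + cost(-ei) - 2 * c0
      for (j in seq_len(i - 1)) {
        ej <- numeric(m); ej[j] <- 1
        G[i, j] <- G[j, i] <-
          (cost(ei + ej) - cost(ei) - cost(ej) + c0)
      }
    }
    dU_oracle <- solve(G, f)
    dU_pkg <- as.numeric(t(sol$dU))
    if (max(abs(dU_pkg - dU_oracle)) < 1e-8) n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 25)
})

test_that("zero tracking error yields exactly zero moves; heavier R never increases them", {
  ss <- rand_stable_ss(53)
  cfg <- mpc_config(H_p = 10, H_u = 4, R = diag(c(1, 1)))
  M <- build_prediction_matrices(ss, cfg)
  sol0 <- solve_mpc(M, numeric(10))
  expect_identical(as.numeric(sol0$dU), numeric(8))
  expect_identical(sol0$V, 0)

  set.seed(53)
  E <- rnorm(10, 0, 3)
  norms <- vapply(c(1, 10, 100, 1000), function(s) {
    cfgs <- mpc_config(H_p = 10, H_u = 4, R = s * diag(c(1, 1)), u_floor = -Inf)
    Ms <- build_prediction_matrices(ss, cfgs)
    sqrt(sum(solve_mpc(Ms, E)$dU^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("the unconstrained solution satisfies the normal equations and beats 1000 perturbations", {
  ss <- rand_stable_ss(54)
  cfg <- mpc_config(H_p = 12, H_u = 5, R = diag(c(2, 1)), u_floor = -Inf)
  M <- build_prediction_matrices(ss, cfg)
  set.seed(54)
  E <- rnorm(12, 0, 2)
  sol <- solve_mpc(M, E)
  dU <- as.numeric(t(sol$dU))
  Rbar <- kronecker(diag(5), cfg$R)
  G <- crossprod(M$T) + Rbar
  expect_lt(max(abs(G %*% dU - crossprod(M$T, E))), 1e-10)
  qcost <- function(v) sum((as.numeric(M$T %*% v) - E)^2) + sum(v * (Rbar %*% v))
  base <- qcost(dU)
  worse <- vapply(1:1000, function(i) qcost(dU + rnorm(10, 0, 0.05)), numeric(1))
  expect_true(all(worse >= base - 1e-12))
})

test_that("floor clipping pins violated inputs and keeps applied feeds non-negative", {
  ss <- example_identified_model()
  cfg <- mpc_config(H_p = 12, H_u = 6)
  M <- build_prediction_matrices(ss, cfg)
  # negative tracking error demands withdrawal: floor must bind at 0
  sol <- solve_mpc(M, rep(-5, 12), u_prev = c(0, 0))
  expect_true(all(sol$U >= -1e-12))
})

test_that("receding horizon: trivial regulation, exact setpoint tracking, non-negative feeds", {
  ss <- example_identified_model()
  cfg <- mpc_config(H_p = 24, H_u = 8)
  null_spec <- trajectory_spec(times = 0, values = 0)
  run0 <- receding_horizon(ss, ss, cfg, null_spec, 30)
  expect_true(all(run0$u_n == 0 & run0$u_s == 0 & run0$y_model == 0))

  # reachable constant set-point: steady-state tracking error vanishes
  step_spec <- trajectory_spec(times = 0, values = 10, ramp_rate = 0.5)
  run1 <- receding_horizon(ss, ss, cfg, step_spec, 120)
  expect_lt(max(abs(run1$y_model - run1$r)[80:120]), 1e-6)
  expect_true(all(run1$u_n >= 0 & run1$u_s >= 0))
  # identical call is bit-identical (determinism)
  run2 <- receding_horizon(ss, ss, cfg, step_spec, 120)
  expect_identical(run1, run2)
})

test_that("receding horizon stays bounded on the nonlinear plant with a matched linearized model", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- kinetic_params(mu_max = 0.4 * runif(1, 0.9, 1.1),
                        k_s = 85 * runif(1, 0.9, 1.1), k_i = 0.001,
                        b = 2e-4, n_max = 5, Y = 0.1,
                        k_g1 = 0.1, k_g2 = 0.5, m = 0.2)
    x_op <- c(5, 0.3)
    lin <- linearize_ad(p, x_op)
    lin$C <- lin$C * 1000                   # model output in L/h
    model <- discretize_ss(lin, 1)
    plant <- nonlinear_plant_hook(p, x_op)
    spec <- trajectory_spec(times = 0, values = 15, ramp_rate = 0.5)
    run <- receding_horizon(plant, model, mpc_config(H_p = 24, H_u = 8),
                            spec, 100)
    expect_true(all(is.finite(run$y_plant)))
    expect_true(all(run$y_plant >= 0 & run$y_plant < 200))
    expect_lt(max(abs(run$y_plant - run$r)[60:100]), 5)
  }
})

test_that("feasible-feeding integration conserves mass and honours the deviation bound", {
  ss <- example_identified_model()
  # zero input: empty schedule
  out0 <- discretize_feeding(matrix(0, 50, 2), ss)
  expect_equal(nrow(out0$events), 0L)
  expect_true(all(out0$u == 0))

  run <- receding_horizon(ss, ss, mpc_config(H_p = 36, H_u = 24),
                          trajectory_spec(), 168)
  u_opt <- cbind(run$u_n, run$u_s)
  fea <- discretize_feeding(u_opt, ss, bound = 5, window = c(48, 120))
  expect_equal(colSums(fea$u), colSums(u_opt), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(fea$deviation[48:120])), 5 + 1e-9)
  # events are sparse one-hour releases
  expect_lt(nrow(fea$events), 30)
  expect_true(all(fea$u[fea$u > 0] > 0))
})
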