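test_that("Monod-Haldane growth rate is zero at s = 0, peaks at sqrt(k_s/k_i), unimodal", {
  p <- test_kinetics()
  expect_identical(specific_growth_rate(0, p), 0)

  s_star <- sqrt(p$k_s / p$k_i)
  mu_star <- p$mu_max / (1 + 2 * sqrt(p$k_s * p$k_i))
  expect_equal(specific_growth_rate(s_star, p), mu_star, tolerance = 1e-12)
  # k_s = 1, k_i = 0.25, mu_max = 0.1: peak at s = 2 with value 0.05
  expect_equal(specific_growth_rate(2, p), 0.05, tolerance = 1e-12)

  s <- seq(0.01, 4 * s_star, by = 0.01)
  mu <- specific_growth_rate(s, p)
  rising <- s < s_star - 0.01
  falling <- s > s_star + 0.01
  expect_true(all(diff(mu)[rising[-1]] > 0))
  expect_true(all(diff(mu)[falling[-1]] < 0))
  expect_true(all(mu <= mu_star + 1e-12))
})

test_that("state derivatives have the washout and logistic-ceiling fixed points", {
  p <- test_kinetics()
  expect_equal(ad_derivatives(c(0, 0), c(0, 0), p), c(0, 0))
  # at n = n_max with no bacterial feed, growth stalls but substrate still moves
  d <- ad_derivatives(c(p$n_max, 2), c(0, 0.3), p)
  expect_equal(d[1], 0)
  expect_equal(d[2], -specific_growth_rate(2, p) * p$n_max / p$Y + 0.3)
})

test_that("derivatives agree with central differences of a simulated trajectory", {
  p <- test_kinetics()
  feeds <- feed_schedule(0, 0.05, 0.4)
  tr <- simulate_ad(p, c(1, 0.5), feeds, duration = 2, step = 0.01,
                    record_dt = 0.01)
  k <- 100  # interior record
  h <- 0.01
  fd <- c((tr$n[k + 1] - tr$n[k - 1]) / (2 * h),
          (tr$s[k + 1] - tr$s[k - 1]) / (2 * h))
  an <- ad_derivatives(c(tr$n[k], tr$s[k]), c(0.05, 0.4), p)
  expect_equal(fd, an, tolerance = 1e-4)
})

test_that("biogas rate vanishes without biomass and reduces to autolysis gas at s = 0", {
  p <- test_kinetics()
  expect_equal(biogas_rate(0, 3, p), 0)
  expect_equal(biogas_rate(2, 0, p), p$k_g1 * p$b * p$m * 2)
  # hand expansion at a generic point
  mu <- specific_growth_rate(1.5, p)
  expect_equal(biogas_rate(3, 1.5, p),
               (p$k_g1 * p$b + p$k_g2 * mu / p$Y) * p$m * 3, tolerance = 1e-14)
  # swapped output form exchanges the coefficient roles
  ps <- test_kinetics(); ps$output_form <- "swapped"
  expect_equal(biogas_rate(3, 1.5, ps),
               (p$k_g1 * mu / p$Y + p$k_g2 * p$b) * p$m * 3, tolerance = 1e-14)
})

test_that("simulator: empty reactor stays empty; substrate balances the fed mass when unconsumed", {
  p <- test_kinetics()
  tr <- simulate_ad(p, c(0, 0), NULL, duration = 10)
  expect_true(all(tr$n == 0 & tr$s == 0 & tr$v == 0))

  # with n = 0 nothing consumes substrate: ds/dt = u_s exactly
  feeds <- feed_schedule(c(0, 2, 5), c(0, 0, 0), c(0.3, 0, 0.1))
  tr2 <- simulate_ad(p, c(0, 0), feeds, duration = 10)
  expect_equal(tr2$s[nrow(tr2)], 0.3 * 2 + 0.1 * 5, tolerance = 1e-10)
})

test_that("simulator converges to the fed steady state and flags substrate deficiency", {
  p <- kinetic_params(mu_max = 0.5, k_s = 1, k_i = 0.1, b = 0.05,
                      n_max = 10, Y = 0.2, k_g1 = 0.3, k_g2 = 0.6, m = 0.2)
  feeds <- feed_schedule(0, 0.02, 0.5)
  tr <- simulate_ad(p, c(1, 0.5), feeds, duration = 2000, step = 0.05)
  xT <- c(tr$n[nrow(tr)], tr$s[nrow(tr)])
  expect_lt(max(abs(ad_derivatives(xT, c(0.02, 0.5), p))), 1e-6)

  # vigorous consumption against a coarse step overshoots s past zero:
  # reported as a deficient state, not clamped
  fast <- kinetic_params(mu_max = 1, k_s = 0.5, k_i = 0.01, b = 0.01,
                         n_max = 10, Y = 0.1, k_g1 = 0.3, k_g2 = 0.6, m = 0.2)
  expect_warning(tr3 <- simulate_ad(fast, c(5, 1), NULL, duration = 5,
                                    step = 0.5),
                 "deficient")
  expect_true(any(tr3$s < 0))
})

test_that("RK4 step-halving shows at least fourth-order-like convergence", {
  p <- test_kinetics()
  feeds <- feed_schedule(0, 0.05, 0.4)
  run <- function(h) {
    tr <- simulate_ad(p, c(1, 0.5), feeds, duration = 10, step = h)
    c(tr$n[nrow(tr)], tr$s[nrow(tr)])
  }
  x1 <- run(0.2); x2 <- run(0.1); x4 <- run(0.05)
  e1 <- sqrt(sum((x1 - x2)^2)); e2 <- sqrt(sum((x2 - x4)^2))
  expect_gt(log2(e1 / e2), 3.5)
  # and successive refinements agree tightly in relative terms
  expect_lt(sqrt(sum((x2 - x4)^2)) / sqrt(sum(x4^2)), 1e-6)
})

test_that("RK4 trajectories agree with an independent adaptive ODE solver", {
  p <- test_kinetics()
  u <- c(0.05, 0.4)
  tr <- simulate_ad(p, c(1, 0.5), feed_schedule(0, u[1], u[2]), duration = 20)
  ref <- deSolve::ode(y = c(n = 1, s = 0.5), times = seq(0, 20, by = 1),
                      func = function(t, y, parms) list(ad_derivatives(y, u, p)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$n, unname(ref[, "n"]), tolerance = 1e-7)
  expect_equal(tr$s, unname(ref[, "s"]), tolerance = 1e-7)
})

test_that("analytic Jacobians match finite differences; inputs enter with identity Jacobian", {
  p <- test_kinetics()
  x0 <- c(2.5, 1.2); u0 <- c(0.05, 0.3)
  lin <- linearize_ad(p, x0, u0)
  h <- 1e-6
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    fd_A <- (ad_derivatives(x0 + e, u0, p) - ad_derivatives(x0 - e, u0, p)) / (2 * h)
    expect_equal(lin$A[, j], fd_A, tolerance = 1e-6)
    fd_C <- (biogas_rate(x0[1] + e[1], x0[2] + e[2], p) -
             biogas_rate(x0[1] - e[1], x0[2] - e[2], p)) / (2 * h)
    expect_equal(lin$C[1, j], fd_C, tolerance = 1e-6)
  }
  expect_identical(lin$B, diag(2))
  # output Jacobian w.r.t. substrate vanishes without biomass
  expect_equal(linearize_ad(p, c(0, 1.2))$C[1, 2], 0)
  expect_equal(attr(lin, "residual"), ad_derivatives(x0, u0, p))
})

test_that("nonlinear and linearized trajectories diverge quadratically in the perturbation", {
  p <- test_kinetics()
  # exact equilibrium by back-solving the feed rates; s_eq chosen so that
  # mu < b and the balancing bacterial feed is non-negative
  x_eq <- c(3, 0.05)
  mu <- specific_growth_rate(x_eq[2], p)
  u_eq <- c(-(mu - p$b) * x_eq[1] * (1 - x_eq[1] / p$n_max),
            mu * x_eq[1] / p$Y)
  expect_lt(max(abs(ad_derivatives(x_eq, u_eq, p))), 1e-14)
  lin <- linearize_ad(p, x_eq, u_eq)
  Phi <- as.matrix(Matrix::expm(lin$A * 5))   # 5 h propagator
  feeds <- feed_schedule(0, u_eq[1], u_eq[2])
  dev_err <- function(eps) {
    d0 <- eps * c(1, 0.5)
    tr <- simulate_ad(p, x_eq + d0, feeds, duration = 5, step = 0.01)
    xT <- c(tr$n[nrow(tr)], tr$s[nrow(tr)])
    sqrt(sum((xT - x_eq - as.numeric(Phi %*% d0))^2))
  }
  e1 <- dev_err(0.04); e2 <- dev_err(0.02); e3 <- dev_err(0.01)
  expect_gt(log2(e1 / e2), 1.8)
  expect_gt(log2(e2 / e3), 1.8)
})

test_that("zero-order-hold discretization matches closed forms and a series oracle", {
  # A = 0: pure integrator of the input
  ss0 <- state_space(matrix(0, 2, 2), diag(2), c(1, 0))
  d0 <- discretize_ss(ss0, 0.5)
  expect_equal(d0$A, diag(2))
  expect_equal(d0$B, 0.5 * diag(2))

  # scalar: A_d = exp(a dt)
  ss1 <- state_space(matrix(-0.3), matrix(c(1, 2), 1, 2), 1.5)
  d1 <- discretize_ss(ss1, 2)
  expect_equal(d1$A[1, 1], exp(-0.6), tolerance = 1e-12)

  # random stable 2x2 vs truncated series for expm and its integral
  set.seed(7)
  A <- matrix(rnorm(4), 2, 2); A <- A - diag(2) * (max(Re(eigen(A)$values)) + 0.5)
  B <- matrix(rnorm(4), 2, 2)
  ssr <- state_space(A, B, c(1, 1))
  dt <- 0.7
  Ad_ser <- diag(2); intA <- diag(2) * dt; term <- diag(2)
  for (k in 1:40) {
    term <- term %*% (A * dt) / k
    Ad_ser <- Ad_ser + term
    intA <- intA + term %*% diag(2) * dt / (k + 1)
  }
  dr <- discretize_ss(ssr, dt)
  expect_equal(dr$A, Ad_ser, tolerance = 1e-10)
  expect_equal(dr$B, intA %*% B, tolerance = 1e-10)
})

test_that("input-output polynomial carries the characteristic polynomial and Markov parameters", {
  ss <- example_identified_model()
  pl <- io_polynomial(ss)
  expect_equal(pl$a1, -(0.9691 + 0.8443), tolerance = 1e-12)          # -trace
  expect_equal(pl$a2, 0.9691 * 0.8443 + 0.1481 * 0.02027, tolerance = 1e-12) # det
  expect_equal(pl$a2, 0.82121, tolerance = 1e-4)

  # transfer-function equivalence: polynomial impulse response == C A^(k-1) B
  for (seed in 1:3) {
    ssr <- rand_stable_ss(seed)
    plr <- io_polynomial(ssr)
    expect_equal(impulse_response(plr, 50), markov_parameters(ssr, 50),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})
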