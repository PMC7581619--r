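# shared fixtures: random stable discrete systems and reference kinetics

rand_stable_ss <- function(seed, rho = 0.85, dt = 1) {
  set.seed(seed)
  A <- matrix(rnorm(4), 2, 2)
  A <- A * (rho / max(Mod(eigen(A, only.values = TRUE)$values)))
  state_space(A, matrix(rnorm(4), 2, 2), rnorm(2), dt = dt,
              domain = "discrete")
}

rand_stable_poly <- function(seed, rho = 0.85) io_polynomial(rand_stable_ss(seed, rho))

# small, fast test kinetics (not the workbench defaults): strong Haldane
test_kinetics <- function() {
  kinetic_params(mu_max = 0.1, k_s = 1, k_i = 0.25, b = 0.01,
                 n_max = 10, Y = 0.2, k_g1 = 0.3, k_g2 = 0.6, m = 0.2)
}

# persistently exciting hourly input series
pe_inputs <- function(n, seed = 1) {
  set.seed(seed)
  list(u_n = abs(rnorm(n)), u_s = abs(rnorm(n)))
}

matpow <- function(A, k) {
  if (k == 0) return(diag(nrow(A)))
  Reduce(`%*%`, rep(list(A), k))
}

# operation series from an io polynomial run from rest (noiseless)
series_from_poly <- function(poly, u_n, u_s) {
  operation_series(seq_along(u_n) - 1, u_n, u_s, simulate_io(poly, u_n, u_s))
}
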