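# Shared test oracles, independent of the code paths they validate.

# Plant realizing relative speed S at a given delay through the
# zero-stiffness path (or the critical-stiffness path for S = 0).
plant_for_S <- function(S, tau_delay = 0.14) {
  if (S > 0) {
    plant_params(tau_m0 = tau_delay / S, k_frac = 0, tau_delay = tau_delay)
  } else {
    plant_params(k_frac = 1, tau_delay = tau_delay)
  }
}

# Long-horizon decay-vs-growth oracle for stability of dimensionless PD
# gains. Returns "stable", "unstable" or "indeterminate" (late/early
# amplitude ratio not conclusive).
stability_sim_oracle <- function(P, D, S, tau_delay = 0.14) {
  plant <- plant_for_S(S, tau_delay)
  g <- dimensional_gains(P = P, D = D, tau_delay = tau_delay)
  sim <- simulate_balance(plant, g, dt = tau_delay / 100,
                          horizon = 60 * tau_delay)
  if (sim$diverged) return("unstable")
  tmax <- max(sim$t)
  a_early <- max(abs(sim$theta[sim$t <= 2 * tau_delay]))
  a_end <- max(abs(sim$theta[sim$t >= tmax - 2 * tau_delay]))
  if (a_end < 0.2 * a_early) "stable"
  else if (a_end > 5 * a_early) "unstable"
  else "indeterminate"
}

# Root-based multiple-root oracle: build the characteristic-polynomial
# coefficients directly from the printed Pade forms and check via
# polyroot() that every root sits at -omega0.
char_poly_coefs <- function(kind, S, P, D, A = 0, I = 0, D_M = 0) {
  switch(kind,
    PD = c(1, 2 - D, 2 * D - P - S^2, 2 * (P - S^2)),
    PD_damped = c(1, 2 - D + D_M, 2 * D + 2 * D_M - P - S^2,
                  2 * (P - S^2)),
    PDA = c(1 + A, 4 + D - 4 * A, 8 - S^2 + P - 4 * D + 8 * A,
            -4 * S^2 - 4 * P + 8 * D, 8 * (P - S^2)),
    PID = c(1, 2 - D, 2 * D - S^2 - P, 2 * P - 2 * S^2 - I, 2 * I))
}

# Root clustering of an n-fold root is conditioned like residual^(1/n)
# (~1e-3 for a quartic at coefficient residual 1e-12), so the tolerance
# is far looser than the coefficient residual itself.
expect_multiple_root <- function(sol, tol = 5e-4) {
  co <- char_poly_coefs(sol$controller_kind, sol$S, sol$P, sol$D,
                        A = sol$A, I = sol$I, D_M = sol$D_M)
  roots <- polyroot(rev(co))
  expect_true(all(Mod(roots + sol$omega0) < tol),
              label = sprintf("%s roots clustered at -omega0 (S = %.3g)",
                              sol$controller_kind, sol$S))
}

# The published tables print peak excursions truncated toward zero at two
# decimals (every cell, and the percent-change cells, are consistent with
# truncation of the converged values; plain rounding disagrees on one cell).
trunc2 <- function(x) trunc(x * 100) / 100

# Random well-conditioned diagonalizable matrix with prescribed positive
# eigenvalues (pendulum-like modes).
random_diagonalizable <- function(n, s_range = c(0.1, 1.0)) {
  s <- sort(runif(n, s_range[1], s_range[2]), decreasing = TRUE)
  repeat {
    E <- matrix(rnorm(n * n), n)
    if (rcond(E) > 0.1) break
  }
  # eigenvalues of t(M) (= those of M) are s with eigenvectors E
  M <- t(E %*% diag(s, n) %*% solve(E))
  list(M = M, s = s)
}
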