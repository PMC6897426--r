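reference_plant <- plant_params(k_frac = 0.5, tau_delay = 0.14)
reference_gains <- pd_critical(reference_plant$S, 0.14)$gains

test_that("uncontrolled fall matches the hyperbolic closed form", {
  p0 <- plant_params(k_frac = 0)
  sim <- simulate_balance(p0, controller_gains(), horizon = 2)
  expect_lt(max(abs(sim$theta - cosh(sim$t / p0$tau_m0))), 1e-8)
  # monotone pure fall
  expect_true(all(diff(sim$theta) > 0))
  # and the first delay interval of any run reproduces free_fall
  sim_fb <- simulate_balance(reference_plant, reference_gains)
  idx <- sim_fb$t <= reference_plant$tau_delay
  ff <- free_fall(reference_plant, 1, 0, sim_fb$t[idx])
  expect_lt(max(abs(sim_fb$theta[idx] - ff$theta)), 1e-10)
})

test_that("reference simulation reproduces the printed peak excursions", {
  sim <- simulate_balance(reference_plant, reference_gains)
  expect_equal(round(sim$peak_com, 2), 1.11)
  expect_equal(round(sim$peak_cop, 2), 1.67)
})

test_that("torque decomposition honours its identities", {
  sim <- simulate_balance(reference_plant, reference_gains)
  expect_identical(sim$torque_weight, sim$theta)
  expect_equal(sim$torque_stiffness, 0.5 * sim$theta, tolerance = 1e-14)
  expect_equal(sim$cop, sim$torque_stiffness + sim$torque_contraction,
               tolerance = 1e-14)
  # contraction is exactly zero before the first feedback arrival,
  # so the CoP torque is purely elastic there
  pre <- sim$t < reference_plant$tau_delay
  expect_true(all(sim$torque_contraction[pre] == 0))
  expect_equal(sim$cop[pre], 0.5 * sim$theta[pre], tolerance = 1e-14)
})

test_that("at critical stiffness the CoM stays immobile during the delay", {
  p1 <- plant_params(k_frac = 1)
  cs <- pd_critical(p1$S, p1$tau_delay)
  sim <- simulate_balance(p1, cs$gains)
  during <- sim$t <= p1$tau_delay
  expect_true(all(sim$theta[during] == 1))
})

test_that("simulations are invariant under the dimensionless rescaling", {
  # same (S, P, D) at twice the delay: identical normalized traces
  p2 <- plant_params(tau_m0 = 2 * reference_plant$tau_m0, k_frac = 0.5,
                     tau_delay = 0.28)
  expect_equal(p2$S, reference_plant$S, tolerance = 1e-15)
  cs2 <- pd_critical(p2$S, 0.28)
  s1 <- simulate_balance(reference_plant, reference_gains, horizon = 6)
  s2 <- simulate_balance(p2, cs2$gains, horizon = 12)
  n <- length(s1$theta)
  expect_lt(max(abs(s1$theta - s2$theta[seq_len(n)])), 1e-9)
  expect_lt(abs(s1$peak_com - s2$peak_com), 1e-9)
})

test_that("divergent runs are flagged, not raised", {
  # gains tuned for critical stiffness applied without any stiffness
  p1 <- plant_params(k_frac = 1)
  g1 <- pd_critical(p1$S, p1$tau_delay)$gains
  p0 <- plant_params(k_frac = 0)
  sim <- expect_no_error(simulate_balance(p0, g1, horizon = 8))
  expect_true(sim$diverged || max(abs(sim$theta)) > 10)
  expect_identical(classify_response(sim), "unstable")
})

test_that("response classification separates the canonical regimes", {
  sim_crit <- simulate_balance(reference_plant, reference_gains)
  expect_identical(classify_response(sim_crit), "critical-like")
  expect_lte(sim_crit$n_sign_changes, 1)

  # proportional gain well above critical oscillates (zero stiffness case)
  p0 <- plant_params(k_frac = 0)
  cs0 <- pd_critical(p0$S, p0$tau_delay)
  g_hi <- controller_gains(p = 1.5 * cs0$gains$p, d = cs0$gains$d)
  expect_identical(classify_response(simulate_balance(p0, g_hi)),
                   "oscillatory")

  # proportional gain well below critical settles slowly (critical
  # stiffness case, where the static stability line sits at P = 0)
  p1 <- plant_params(k_frac = 1)
  cs1 <- pd_critical(p1$S, p1$tau_delay)
  g_lo <- controller_gains(p = 0.4 * cs1$gains$p, d = cs1$gains$d)
  sim_lo <- simulate_balance(p1, g_lo, horizon = 12)
  expect_identical(classify_response(sim_lo), "sluggish")
})

test_that("the integrator self-converges at 4th order on smooth segments", {
  cc <- convergence_check(reference_plant, reference_gains)
  expect_lt(cc$error, 1e-6)
  expect_lt(cc$error_refined, cc$error)

  # PDA controller with recorded-acceleration history also refines
  csa <- pda_critical(reference_plant$S, 0.14)
  cca <- convergence_check(reference_plant, csa$gains)
  expect_lt(cca$error, 1e-6)
  expect_lt(cca$error_refined, cca$error)

  # PID controller (integral state)
  csi <- pid_critical(reference_plant$S, 0.14)
  cci <- convergence_check(reference_plant, csi$gains)
  expect_lt(cci$error, 1e-6)
})

test_that("simulation config constraints are enforced", {
  expect_error(simulate_balance(reference_plant, reference_gains,
                                dt = 0.14 / 50), "tau_delay/100")
  expect_error(simulate_balance(reference_plant, reference_gains,
                                horizon = 1), "10 \\* tau_delay")
})

test_that("PID integral feedback modifies the trace as expected", {
  csi <- pid_critical(reference_plant$S, 0.14)
  sim <- simulate_balance(reference_plant, csi$gains)
  expect_false(sim$diverged)
  # integral term contributes: trace differs from the pure-PD run with
  # the same P, D
  g_pd <- controller_gains(p = csi$gains$p, d = csi$gains$d)
  sim_pd <- simulate_balance(reference_plant, g_pd)
  expect_gt(max(abs(sim$theta - sim_pd$theta)), 1e-3)
})
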