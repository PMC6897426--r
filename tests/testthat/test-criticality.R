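reference_S <- plant_params(k_frac = 0.5, tau_delay = 0.14)$S

test_that("closed-form PD critical gains reproduce the reference systems", {
  # k_frac = 0.5, tau_delay = 0.14 s
  cs <- pd_critical(reference_S, 0.14)
  expect_equal(round(cs$gains$p, 2), 8.08)
  expect_equal(round(cs$gains$d, 2), 3.58)
  # 20% longer delay, same stiffness
  S2 <- plant_params(k_frac = 0.5, tau_delay = 0.168)$S
  cs2 <- pd_critical(S2, 0.168)
  expect_equal(round(cs2$gains$p, 2), 6.99)
  expect_equal(round(cs2$gains$d, 2), 3.15)
  # domain edge
  expect_error(pd_critical(sqrt(2), 0.14), "no critically damped")
})

test_that("every critical solution is a true multiple root of its polynomial", {
  for (S in c(0, 0.31, 0.7, 1.0, 1.3)) {
    sols <- list(pd_critical(S, 0.14),
                 pd_damped_critical(S, D_M = 0.2, tau_delay = 0.14),
                 pda_critical(S, 0.14),
                 pid_critical(S, 0.14))
    for (sol in sols) {
      expect_lt(sol$residual, 1e-10)
      expect_gt(sol$omega0, 0)
      expect_multiple_root(sol)
    }
  }
})

test_that("S = 0 PD solution matches the analytic cube-root expression", {
  cs <- pd_critical(0, 0.14)
  expect_equal(cs$omega0, 16^(1 / 3) - 2, tolerance = 1e-14)
  expect_equal(cs$tau_balance, 0.14 / (16^(1 / 3) - 2), tolerance = 1e-14)
})

test_that("mechanical damping reduces to PD at zero and speeds recovery", {
  cs0 <- pd_damped_critical(0.31, D_M = 0, tau_delay = 0.14)
  cs <- pd_critical(0.31, 0.14)
  expect_equal(cs0$omega0, cs$omega0, tolerance = 1e-12)
  expect_equal(cs0$P, cs$P, tolerance = 1e-12)
  expect_equal(cs0$D, cs$D, tolerance = 1e-12)
  csd <- pd_damped_critical(0.31, D_M = 0.2, tau_delay = 0.14)
  expect_lt(csd$tau_balance, cs$tau_balance)
})

test_that("acceleration feedback speeds recovery and raises PD gains; integral slows it", {
  for (S in c(0, 0.5, 1)) {
    pd <- pd_critical(S, 0.14)
    pda <- pda_critical(S, 0.14)
    pid <- pid_critical(S, 0.14)
    expect_lt(pda$tau_balance, pd$tau_balance)
    expect_gt(pid$tau_balance, pd$tau_balance)
    expect_gt(pda$P, pd$P)
    expect_gt(pda$D, pd$D)
    expect_equal(pid$I, pid$omega0^4 / 2, tolerance = 1e-12)
    expect_gte(pid$I, 0)
  }
})

test_that("critical gains sit inside the PD stable region", {
  for (S in seq(0, 1.3, by = 0.1)) {
    cs <- pd_critical(S, 0.14)
    memb <- is_stable(cs$P, cs$D, S)
    expect_true(memb$stable, label = sprintf("S = %.1f", S))
  }
})

test_that("critical gains and recovery time are monotone in stiffness and delay", {
  # at fixed delay, p_crit, d_crit and tau_balance all fall with stiffness
  ks <- seq(0, 1, length.out = 21)
  sols <- lapply(ks, function(k) {
    p <- plant_params(k_frac = k, tau_delay = 0.14)
    pd_critical(p$S, 0.14)
  })
  expect_true(all(diff(vapply(sols, function(s) s$gains$p, 1)) < 0))
  expect_true(all(diff(vapply(sols, function(s) s$gains$d, 1)) < 0))
  expect_true(all(diff(vapply(sols, function(s) s$tau_balance, 1)) < 0))
  # at fixed stiffness, p_crit and d_crit fall and tau_balance grows with delay
  tds <- seq(0.14, 0.28, length.out = 15)
  sols <- lapply(tds, function(td) {
    p <- plant_params(k_frac = 0.5, tau_delay = td)
    pd_critical(p$S, td)
  })
  expect_true(all(diff(vapply(sols, function(s) s$gains$p, 1)) < 0))
  expect_true(all(diff(vapply(sols, function(s) s$gains$d, 1)) < 0))
  expect_true(all(diff(vapply(sols, function(s) s$tau_balance, 1)) > 0))
})

test_that("dimensionless critical gains depend on S only", {
  cs1 <- pd_critical(0.31, 0.14)
  cs2 <- pd_critical(0.31, 0.28)
  expect_identical(cs1$P, cs2$P)
  expect_identical(cs1$D, cs2$D)
  expect_equal(cs2$gains$p, cs1$gains$p / 4, tolerance = 1e-12)
  expect_equal(cs2$gains$d, cs1$gains$d / 2, tolerance = 1e-12)
})

test_that("stiffness solver inverts the critical proportional gain", {
  p_ref <- pd_critical(reference_S, 0.14)$gains$p
  # fixed point
  expect_equal(stiffness_for_critical_p(p_ref, 0.14), 0.5, tolerance = 1e-8)
  # 15% reduced gain calls for ~63.4% of critical stiffness
  k <- stiffness_for_critical_p(0.85 * p_ref, 0.14)
  expect_equal(round(100 * k, 1), 63.4)
  # Table-2 co-adaptation solved through the gain route
  k2 <- stiffness_for_critical_p(5.613914, 0.168)
  expect_equal(round(100 * k2, 1), 65.3)
  expect_error(stiffness_for_critical_p(100, 0.14), "achievable")
})

test_that("constant-S stiffness adaptation matches its closed form", {
  S_ref <- plant_params(k_frac = 0.5, tau_delay = 0.14)$S
  k <- stiffness_for_constant_S(0.168, S_ref)
  expect_equal(round(100 * k, 1), 65.3)
  # verify: the new plant really has the old S
  expect_equal(plant_params(k_frac = k, tau_delay = 0.168)$S, S_ref,
               tolerance = 1e-12)
  # unchanged delay is a fixed point
  expect_equal(stiffness_for_constant_S(0.14, S_ref), 0.5,
               tolerance = 1e-12)
  # S = 0 is realized exactly at the critical-stiffness boundary
  expect_identical(stiffness_for_constant_S(0.168, 0), 1)
  # infeasible: would need tau_mech below tau_m0
  expect_error(stiffness_for_constant_S(0.1, 1.5), "negative stiffness")
})
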