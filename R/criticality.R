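#' @title Generalized critical damping for delayed feedback
#' @description
#' In a second-order system critical damping is the gain setting at which
#' the characteristic polynomial has a unique double negative root: the
#' fastest return to equilibrium without oscillation. Replacing the pure
#' delay `exp(-X)` by a Pade rational approximation turns the transcendental
#' characteristic equation of the delayed feedback loop into a polynomial
#' (cubic with the first-order approximant, quartic with the second-order
#' one), and criticality generalizes to a unique negative root `-omega0`
#' of full multiplicity. The functions below compute the critical gain set
#' and the recovery time `tau_balance = tau_delay / omega0` for four
#' controller variants.
#' @name criticality
NULL

new_critical_solution <- function(kind, S, tau_delay, omega0, P, D,
                                  A = 0, I = 0, D_M = 0, residual) {
  gains <- dimensional_gains(P = P, D = D, A = A, I = I,
                             tau_delay = tau_delay)
  structure(
    list(controller_kind = kind, S = S, tau_delay = tau_delay,
         omega0 = omega0, P = P, D = D, A = A, I = I, D_M = D_M,
         gains = gains, tau_balance = tau_delay / omega0,
         residual = residual),
    class = "critical_solution"
  )
}

#' @export
print.critical_solution <- function(x, ...) {
  cat(sprintf("Critical %s solution (S = %.6g, tau_delay = %.6g s)\n",
              x$controller_kind, x$S, x$tau_delay))
  cat(sprintf("  omega0      = %.6g (multiple root magnitude)\n", x$omega0))
  cat(sprintf("  P, D        = %.6g, %.6g (dimensionless)\n", x$P, x$D))
  if (x$controller_kind == "PDA") cat(sprintf("  A           = %.6g\n", x$A))
  if (x$controller_kind == "PID") cat(sprintf("  I           = %.6g\n", x$I))
  if (x$controller_kind == "PD_damped")
    cat(sprintf("  D_M         = %.6g\n", x$D_M))
  cat(sprintf("  p, d        = %.6g 1/s^2, %.6g 1/s (per inertia)\n",
              x$gains$p, x$gains$d))
  cat(sprintf("  tau_balance = %.6g s\n", x$tau_balance))
  cat(sprintf("  residual    = %.3g\n", x$residual))
  invisible(x)
}

# Characteristic-polynomial coefficients (descending powers of X) for each
# controller variant under its Pade approximation, and the matching
# multiple-root target. Residual = max abs coefficient mismatch.
critical_residual <- function(kind, S, omega0, P, D, A = 0, I = 0, D_M = 0) {
  coefs <- switch(kind,
    PD = c(1, 2 - D, 2 * D - P - S^2, 2 * (P - S^2)),
    PD_damped = c(1, 2 - D + D_M, 2 * D + 2 * D_M - P - S^2, 2 * (P - S^2)),
    PDA = c(1 + A, 4 + D - 4 * A, 8 - S^2 + P - 4 * D + 8 * A,
            -4 * S^2 - 4 * P + 8 * D, 8 * (P - S^2)),
    PID = c(1, 2 - D, 2 * D - S^2 - P, 2 * P - 2 * S^2 - I, 2 * I),
    stop("unknown controller kind ", kind)
  )
  n <- length(coefs) - 1L
  lead <- if (kind == "PDA") 1 + A else 1
  target <- lead * choose(n, 0:n) * omega0^(0:n)
  max(abs(coefs - target))
}

# Damped Newton with central-difference Jacobian for the small
# coefficient-matching systems.
damped_newton <- function(fn, x0, tol = 1e-12, maxit = 200) {
  x <- x0
  f <- fn(x)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol)
      return(list(x = x, residual = max(abs(f)), converged = TRUE, iter = it))
    m <- length(f); n <- length(x)
    J <- matrix(0, m, n)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- h[j]
      J[, j] <- (fn(x + e) - fn(x - e)) / (2 * h[j])
    }
    dx <- tryCatch(qr.solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) break
    lam <- 1
    repeat {
      xn <- x + lam * dx
      fn_new <- fn(xn)
      if (max(abs(fn_new)) < max(abs(f)) || lam < 1e-10) break
      lam <- lam / 2
    }
    x <- xn
    f <- fn_new
  }
  list(x = x, residual = max(abs(f)), converged = max(abs(f)) < tol,
       iter = maxit)
}

check_S_range <- function(S) {
  stopifnot(is.numeric(S), length(S) == 1L, is.finite(S))
  if (S < 0) stop("S must be >= 0", call. = FALSE)
  if (S >= sqrt(2))
    stop("omega0 <= 0: no critically damped solution for S >= sqrt(2)",
         call. = FALSE)
}

#' Critical PD gains (closed form)
#'
#' With the first-order Pade approximant the closed-loop characteristic
#' polynomial is the cubic
#' `X^3 + X^2 (2 - D) + X (2D - P - S^2) + 2 (P - S^2)`; requiring it to
#' equal `(X + omega0)^3` gives the closed-form critical solution
#' `omega0 = -2 + (16 - 4 S^2)^(1/3)`,
#' `D_crit = 8 - 3 (16 - 4 S^2)^(1/3)`,
#' `P_crit = 4 - S^2 + 6 (16 - 4 S^2)^(1/3) - 3 (16 - 4 S^2)^(2/3)`
#' (the unique real branch of the cube root). The per-inertia gains are
#' `p = P_crit / tau_delay^2`, `d = D_crit / tau_delay`, and the recovery
#' time is `tau_balance = tau_delay / omega0`.
#'
#' @param S relative speed `tau_delay/tau_mech`, in `[0, sqrt(2))`.
#' @param tau_delay feedback delay in seconds.
#' @return A `critical_solution` object with fields `omega0`, dimensionless
#'   `P`, `D`, per-inertia `gains`, `tau_balance`, and the
#'   coefficient-matching `residual`.
#' @examples
#' p <- plant_params(k_frac = 0.5, tau_delay = 0.14)
#' pd_critical(p$S, p$tau_delay)   # p = 8.08, d = 3.58
#' @export
pd_critical <- function(S, tau_delay = 0.14) {
  check_S_range(S)
  r <- (16 - 4 * S^2)^(1 / 3)
  omega0 <- -2 + r
  D <- 8 - 3 * r
  P <- 4 - S^2 + 6 * r - 3 * r^2
  res <- critical_residual("PD", S, omega0, P, D)
  new_critical_solution("PD", S, tau_delay, omega0, P, D, residual = res)
}

#' Critical PD gains with mechanical damping
#'
#' Adds a dimensionless undelayed mechanical damping `D_M` to the plant;
#' the Pade cubic becomes
#' `X^3 + X^2 (2 - D + D_M) + X (2D + 2 D_M - P - S^2) + 2 (P - S^2)`.
#' The triple-root conditions are solved numerically by damped Newton
#' iteration seeded from the undamped closed form.
#'
#' @inheritParams pd_critical
#' @param D_M dimensionless mechanical damping, `>= 0`.
#' @return A `critical_solution` (kind `"PD_damped"`).
#' @export
pd_damped_critical <- function(S, D_M = 0, tau_delay = 0.14) {
  check_S_range(S)
  stopifnot(is.numeric(D_M), length(D_M) == 1L, D_M >= 0)
  seed <- pd_critical(S, tau_delay)
  fn <- function(v) {
    w <- v[1]; P <- v[2]; D <- v[3]
    c(w^3 - 2 * (P - S^2),
      3 * w^2 - (2 * D + 2 * D_M - P - S^2),
      3 * w - (2 - D + D_M))
  }
  sol <- damped_newton(fn, c(seed$omega0, seed$P, seed$D))
  if (!sol$converged)
    stop("PD_damped critical solve did not converge (residual ",
         format(sol$residual), ")", call. = FALSE)
  if (sol$x[1] <= 0)
    stop("no positive-omega0 critically damped solution for S = ", S,
         ", D_M = ", D_M, call. = FALSE)
  res <- critical_residual("PD_damped", S, sol$x[1], sol$x[2], sol$x[3],
                           D_M = D_M)
  new_critical_solution("PD_damped", S, tau_delay, sol$x[1], sol$x[2],
                        sol$x[3], D_M = D_M, residual = res)
}

#' Critical PDA gains (delayed acceleration feedback)
#'
#' With delayed acceleration feedback the loop order rises and the
#' second-order Pade approximant
#' `exp(-X) ~ (X^2 - 4X + 8)/(X^2 + 4X + 8)` is required; the
#' characteristic polynomial is the quartic
#' `X^4 (1+A) + X^3 (4 + D - 4A) + X^2 (8 - S^2 + P - 4D + 8A) +
#' X (-4 S^2 - 4P + 8D) + 8 (P - S^2)`, matched against
#' `(1+A) (X + omega0)^4`. Solved by damped Newton seeded from the PD
#' closed form with `A = 0`.
#'
#' @inheritParams pd_critical
#' @return A `critical_solution` (kind `"PDA"`) including the acceleration
#'   gain `A`.
#' @export
pda_critical <- function(S, tau_delay = 0.14) {
  check_S_range(S)
  seed <- pd_critical(S, tau_delay)
  fn <- function(v) {
    w <- v[1]; P <- v[2]; D <- v[3]; A <- v[4]
    c((1 + A) * 4 * w - (4 + D - 4 * A),
      (1 + A) * 6 * w^2 - (8 - S^2 + P - 4 * D + 8 * A),
      (1 + A) * 4 * w^3 - (-4 * S^2 - 4 * P + 8 * D),
      (1 + A) * w^4 - 8 * (P - S^2))
  }
  sol <- damped_newton(fn, c(seed$omega0, seed$P, seed$D, 0))
  if (!sol$converged)
    stop("PDA critical solve did not converge (residual ",
         format(sol$residual), ")", call. = FALSE)
  res <- critical_residual("PDA", S, sol$x[1], sol$x[2], sol$x[3],
                           A = sol$x[4])
  new_critical_solution("PDA", S, tau_delay, sol$x[1], sol$x[2], sol$x[3],
                        A = sol$x[4], residual = res)
}

#' Critical PID gains (delayed integral feedback)
#'
#' With delayed integral feedback (integral of the delayed angle starting
#' at the perturbation) and the first-order Pade approximant, the
#' characteristic polynomial (scaled by 2) is
#' `X^4 + X^3 (2 - D) + X^2 (2D - S^2 - P) + X (2P - 2 S^2 - I) + 2 I`,
#' matched against `(X + omega0)^4`; in particular `I = omega0^4 / 2`.
#' Solved by damped Newton seeded from the PD closed form with
#' `I = omega0^4 / 2`; the branch continuously connected to the PD
#' solution as `I -> 0` is returned and must have `I >= 0`.
#'
#' @inheritParams pd_critical
#' @return A `critical_solution` (kind `"PID"`) including the integral
#'   gain `I`.
#' @export
pid_critical <- function(S, tau_delay = 0.14) {
  check_S_range(S)
  seed <- pd_critical(S, tau_delay)
  fn <- function(v) {
    w <- v[1]; P <- v[2]; D <- v[3]; I <- v[4]
    c(4 * w - (2 - D),
      6 * w^2 - (2 * D - S^2 - P),
      4 * w^3 - (2 * P - 2 * S^2 - I),
      w^4 - 2 * I)
  }
  sol <- damped_newton(fn, c(seed$omega0, seed$P, seed$D, seed$omega0^4 / 2))
  if (!sol$converged)
    stop("PID critical solve did not converge (residual ",
         format(sol$residual), ")", call. = FALSE)
  if (sol$x[1] <= 0 || sol$x[4] < 0)
    stop("PID solve left the physical branch (omega0 > 0, I >= 0)",
         call. = FALSE)
  res <- critical_residual("PID", S, sol$x[1], sol$x[2], sol$x[3],
                           I = sol$x[4])
  new_critical_solution("PID", S, tau_delay, sol$x[1], sol$x[2], sol$x[3],
                        I = sol$x[4], residual = res)
}

#' Dispatch to a critical-gain solver by controller kind
#'
#' @param kind one of `"PD"`, `"PD_damped"`, `"PDA"`, `"PID"`.
#' @inheritParams pd_critical
#' @param D_M dimensionless mechanical damping (used by `"PD_damped"`).
#' @return A `critical_solution`.
#' @export
critical_gains <- function(kind = c("PD", "PD_damped", "PDA", "PID"), S,
                           tau_delay = 0.14, D_M = 0) {
  kind <- match.arg(kind)
  switch(kind,
         PD = pd_critical(S, tau_delay),
         PD_damped = pd_damped_critical(S, D_M, tau_delay),
         PDA = pda_critical(S, tau_delay),
         PID = pid_critical(S, tau_delay))
}

#' Stiffness fraction at which a given proportional gain is critical
#'
#' Inverse co-adaptation solve: find the ankle stiffness fraction `k_frac`
#' at which the critical per-inertia proportional gain
#' `p_crit(k_frac) = P_crit(S(k_frac)) / tau_delay^2` equals `p_target`.
#' Because `P_crit` increases with S and S decreases with stiffness,
#' `p_crit` is strictly decreasing in `k_frac`, so the root is bracketed
#' and solved with [stats::uniroot()].
#'
#' @param p_target target per-inertia proportional gain (1/s^2 per rad).
#' @param tau_delay feedback delay in seconds.
#' @param tau_m0 base mechanical time constant in seconds.
#' @return The stiffness fraction `k_frac` in `[0, 1)`.
#' @examples
#' # a 15% gain reduction from the reference requires ~63.4% stiffness
#' p_ref <- pd_critical(plant_params()$S, 0.14)$gains$p
#' stiffness_for_critical_p(0.85 * p_ref, 0.14)
#' @export
stiffness_for_critical_p <- function(p_target, tau_delay = 0.14,
                                     tau_m0 = 1 / sqrt(9.81)) {
  stopifnot(is.numeric(p_target), length(p_target) == 1L, is.finite(p_target),
            tau_delay > 0, tau_m0 > 0)
  p_at <- function(k_frac) {
    S <- plant_params(tau_m0 = tau_m0, k_frac = k_frac,
                      tau_delay = tau_delay)$S
    pd_critical(S, tau_delay)$gains$p
  }
  S_max_k0 <- tau_delay / tau_m0
  k_lo <- if (S_max_k0 < sqrt(2)) 0 else 1 - (tau_delay / (tau_m0 * sqrt(2)))^2 + 1e-9
  p_hi <- p_at(k_lo)           # largest achievable critical p
  p_lo <- p_at(1)              # S = 0 floor
  if (p_target > p_hi || p_target < p_lo)
    stop(sprintf(
      "p_target = %.4g outside achievable critical range [%.4g, %.4g] at tau_delay = %.4g s",
      p_target, p_lo, p_hi, tau_delay), call. = FALSE)
  stats::uniroot(function(k) p_at(k) - p_target, c(k_lo, 1),
                 tol = 1e-12)$root
}

#' Stiffness fraction preserving the relative speed S under a new delay
#'
#' Co-adaptation to an increased delay: ankle stiffness is raised so that
#' `S = tau_delay / tau_mech` keeps its old value, leaving all
#' dimensionless quantities (and hence the normalized response shape)
#' unchanged. Closed form:
#' `k_frac = 1 - (tau_m0 * S_target / tau_delay_new)^2`.
#'
#' @param tau_delay_new new feedback delay in seconds.
#' @param S_target relative speed to preserve, `>= 0`. `S_target = 0` is
#'   the exact critical-stiffness boundary and returns `k_frac = 1`.
#' @param tau_m0 base mechanical time constant in seconds.
#' @return The stiffness fraction `k_frac` in `[0, 1]`.
#' @examples
#' S_ref <- plant_params(k_frac = 0.5, tau_delay = 0.14)$S
#' stiffness_for_constant_S(0.168, S_ref)   # ~0.653
#' @export
stiffness_for_constant_S <- function(tau_delay_new, S_target,
                                     tau_m0 = 1 / sqrt(9.81)) {
  stopifnot(tau_delay_new > 0, is.numeric(S_target), S_target >= 0,
            tau_m0 > 0)
  if (S_target == 0) return(1)
  k_frac <- 1 - (tau_m0 * S_target / tau_delay_new)^2
  if (k_frac < 0)
    stop("would need negative stiffness: required tau_mech = ",
         format(tau_delay_new / S_target), " s < tau_m0 = ",
         format(tau_m0), " s", call. = FALSE)
  k_frac
}
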