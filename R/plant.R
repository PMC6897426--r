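#' Normalized plant parameters for the inverted-pendulum stance model
#'
#' Bundles the mechanical description of the linearized single inverted
#' pendulum in normalized units: the base mechanical time constant
#' `tau_m0` (value of the falling time constant at zero ankle stiffness),
#' the stiffness fraction `k_frac` = k / K_crit where
#' K_crit = m g L cos(theta_eq) is the critical ankle stiffness that exactly
#' cancels the destabilizing torque of weight, an optional dimensionless
#' mechanical damping, and the neural feedback delay `tau_delay`.
#'
#' Two derived quantities drive everything else:
#' * `tau_mech = tau_m0 / sqrt(1 - k_frac)`, the e-folding time of
#'   uncontrolled falling (infinite at critical stiffness), and
#' * `S = tau_delay / tau_mech`, the relative speed of the plant with
#'   respect to the feedback loop. At critical stiffness `S = 0` with a
#'   finite delay; all downstream formulas are continuous in `S` at 0, so
#'   the `k_frac = 1` case is always handled through the `S = 0` path and
#'   never through a literal infinity.
#'
#' @param tau_m0 base mechanical time constant in seconds (stiffness-free
#'   falling). Default `1/sqrt(9.81)`, the value for a person modelled as a
#'   point mass at 1 m height with J = m L^2.
#' @param k_frac ankle stiffness as a fraction of the critical stiffness,
#'   in `[0, 1]`.
#' @param d_mech dimensionless mechanical damping (`tau_delay` times the
#'   per-inertia damping coefficient), `>= 0`.
#' @param tau_delay neural response delay in seconds, `> 0`.
#'
#' @return An object of class `plant_params`: a list with fields `tau_m0`,
#'   `k_frac`, `d_mech`, `tau_delay`, and derived `tau_mech` (`Inf` when
#'   `k_frac = 1`) and `S`.
#' @examples
#' plant_params()                      # the reference plant (50% stiffness)
#' plant_params(k_frac = 1)$S          # 0: critical stiffness
#' @export
plant_params <- function(tau_m0 = 1 / sqrt(9.81), k_frac = 0.5, d_mech = 0,
                         tau_delay = 0.14) {
  stopifnot(is.numeric(tau_m0), length(tau_m0) == 1L, is.finite(tau_m0),
            is.numeric(k_frac), length(k_frac) == 1L, is.finite(k_frac),
            is.numeric(d_mech), length(d_mech) == 1L, is.finite(d_mech),
            is.numeric(tau_delay), length(tau_delay) == 1L, is.finite(tau_delay))
  if (tau_m0 <= 0) stop("tau_m0 must be positive", call. = FALSE)
  if (tau_delay <= 0) stop("tau_delay must be positive", call. = FALSE)
  if (k_frac < 0 || k_frac > 1)
    stop("k_frac must lie in [0, 1]; over-critical stiffness is not modelled",
         call. = FALSE)
  if (d_mech < 0) stop("d_mech must be >= 0", call. = FALSE)
  tau_mech <- if (k_frac == 1) Inf else tau_m0 / sqrt(1 - k_frac)
  S <- if (k_frac == 1) 0 else tau_delay / tau_mech
  structure(
    list(tau_m0 = tau_m0, k_frac = k_frac, d_mech = d_mech,
         tau_delay = tau_delay, tau_mech = tau_mech, S = S),
    class = "plant_params"
  )
}

#' Plant parameters from dimensional anthropometrics
#'
#' Converts dimensional body parameters into the normalized plant
#' description. The critical ankle stiffness is
#' `K_crit = m * g * L * cos(theta_eq)`; the mechanical time constant at
#' stiffness `k` is `sqrt(J / (m g L cos(theta_eq) - k))`, so the
#' zero-stiffness base value is `tau_m0 = sqrt(J / (m g L cos(theta_eq)))`.
#'
#' @param m body mass (kg), `> 0`.
#' @param g gravitational acceleration (m/s^2), `> 0`.
#' @param L height of the centre of mass above the ankles (m), `> 0`.
#' @param J rotational inertia around the ankles (kg m^2), `> 0`.
#' @param theta_eq equilibrium lean angle (radians); `cos(theta_eq)` must be
#'   positive.
#' @param k ankle stiffness (N m / rad), `0 <= k <= K_crit`.
#' @param tau_delay neural response delay in seconds.
#' @param d_mech dimensionless mechanical damping, passed through.
#'
#' @return A [plant_params] object.
#' @examples
#' # point mass at 1 m: tau_m0 = 1/sqrt(9.81) ~ 0.32 s
#' from_anthropometrics(m = 70, g = 9.81, L = 1, J = 70, theta_eq = 0, k = 0)
#' @export
from_anthropometrics <- function(m, g, L, J, theta_eq = 0, k = 0,
                                 tau_delay = 0.14, d_mech = 0) {
  stopifnot(is.numeric(m), is.numeric(g), is.numeric(L), is.numeric(J),
            is.numeric(theta_eq), is.numeric(k))
  if (m <= 0 || g <= 0 || L <= 0 || J <= 0)
    stop("m, g, L and J must all be positive", call. = FALSE)
  K_crit <- m * g * L * cos(theta_eq)
  if (K_crit <= 0)
    stop("m*g*L*cos(theta_eq) must be positive for an inverted pendulum",
         call. = FALSE)
  if (k < 0) stop("stiffness k must be >= 0", call. = FALSE)
  if (k > K_crit)
    stop("over-critical stiffness not modelled (k > K_crit = ",
         format(K_crit), ")", call. = FALSE)
  plant_params(tau_m0 = sqrt(J / K_crit), k_frac = k / K_crit,
               d_mech = d_mech, tau_delay = tau_delay)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Inverted-pendulum plant (normalized)\n")
  cat(sprintf("  tau_m0    = %.6g s\n", x$tau_m0))
  cat(sprintf("  k_frac    = %.6g (stiffness / K_crit)\n", x$k_frac))
  cat(sprintf("  d_mech    = %.6g (dimensionless)\n", x$d_mech))
  cat(sprintf("  tau_delay = %.6g s\n", x$tau_delay))
  cat(sprintf("  tau_mech  = %.6g s\n", x$tau_mech))
  cat(sprintf("  S         = %.6g (relative speed)\n", x$S))
  invisible(x)
}

#' Free fall of the pendulum during the response delay
#'
#' Closed-form trajectory of the uncontrolled linearized pendulum released
#' at angle `theta0` with angular velocity `thetadot0`:
#' `theta(t) = (theta0 + tau_mech*thetadot0)/2 * exp(t/tau_mech) +
#' (theta0 - tau_mech*thetadot0)/2 * exp(-t/tau_mech)`.
#' This is the trajectory the body follows between a perturbation and the
#' first delayed feedback correction. At critical stiffness (`k_frac = 1`)
#' the dynamics degenerate to a double integrator and the limit
#' `theta(t) = theta0 + thetadot0 * t` is returned.
#'
#' @param params a [plant_params] object.
#' @param theta0 initial angle (normalized units, default 1).
#' @param thetadot0 initial angular velocity (1/s, default 0).
#' @param t time(s) since the perturbation, `>= 0` (vectorized).
#'
#' @return A list with numeric vectors `theta` and `thetadot` evaluated
#'   at `t`.
#' @examples
#' p <- plant_params(k_frac = 0.5)
#' free_fall(p, t = p$tau_delay)   # amplified by cosh(tau_delay/tau_mech)
#' @export
free_fall <- function(params, theta0 = 1, thetadot0 = 0, t) {
  stopifnot(inherits(params, "plant_params"),
            is.finite(theta0), is.finite(thetadot0), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (params$k_frac == 1) {
    return(list(theta = theta0 + thetadot0 * t,
                thetadot = rep(thetadot0, length(t))))
  }
  tm <- params$tau_mech
  cg <- (theta0 + tm * thetadot0) / 2  # growing mode
  cd <- (theta0 - tm * thetadot0) / 2  # decaying mode
  list(theta = cg * exp(t / tm) + cd * exp(-t / tm),
       thetadot = (cg * exp(t / tm) - cd * exp(-t / tm)) / tm)
}

#' Perturbation amplification over the response delay
#'
#' A perturbation aligned with the growing mode is amplified by
#' `exp(S) = exp(tau_delay / tau_mech)` by the time feedback can first act.
#' Equals 1 at critical stiffness (`S = 0`) or zero delay.
#'
#' @param params a [plant_params] object.
#' @return The dimensionless amplification factor `exp(S)`.
#' @examples
#' amplification_factor(plant_params(k_frac = 0.5))
#' amplification_factor(plant_params(k_frac = 1))  # 1
#' @export
amplification_factor <- function(params) {
  stopifnot(inherits(params, "plant_params"))
  exp(params$S)
}
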