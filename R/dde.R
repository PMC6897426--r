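#' Simulate the delayed-feedback balance loop
#'
#' Integrates the closed-loop delay differential equation
#' `thetaddot = theta/tau_mech^2 - d_M*thetadot
#'  - p*theta(t - tau_delay) - d*thetadot(t - tau_delay)
#'  - a*thetaddot(t - tau_delay) - i*integral_0^t theta(u - tau_delay) du`
#' for a unit (or user-chosen) angle perturbation at `t = 0` with
#' identically zero pre-perturbation history, so the feedback contraction
#' is exactly zero on `[0, tau_delay)`.
#'
#' Integration uses the method of steps: the grid is aligned so that all
#' multiples of the delay are grid nodes (`dt` is snapped to
#' `tau_delay / round(tau_delay/dt)`), classical 4th-order Runge-Kutta
#' advances the solution inside each delay interval, and delayed-state
#' lookups use cubic Hermite interpolation of the stored history (angle
#' from stored angle + velocity, velocity from stored velocity +
#' acceleration; delayed acceleration, needed for PDA control, is taken
#' from the recorded right-hand-side history). At the solution kinks
#' (multiples of the delay) one-sided history limits are used so that no
#' Runge-Kutta stage ever evaluates across a discontinuity.
#'
#' All torques are normalized to the torque of weight per radian
#' (`m g L cos(theta_eq)`): the weight/CoM torque equals `theta` itself,
#' the stiffness torque is `k_frac * theta`, the feedback contraction
#' torque is `tau_m0^2` times the per-inertia feedback law, and the
#' CoP/ground-reaction torque is their sum.
#'
#' @param params a [plant_params] object (`d_mech` is the dimensionless
#'   mechanical damping acting without delay).
#' @param gains a [controller_gains] object (per-inertia gains).
#' @param dt integration step in seconds; snapped to an integer divisor of
#'   the delay and required to be at most `tau_delay/100`.
#' @param horizon total simulated time in seconds, at least
#'   `10 * tau_delay`.
#' @param theta0 perturbation amplitude (normalized angle) applied at
#'   `t = 0`.
#' @param thetadot0 initial angular velocity (1/s).
#'
#' @return An object of class `balance_sim`: a list with the time grid `t`,
#'   traces `theta`, `thetadot`, `torque_weight` (identical to `theta`),
#'   `torque_stiffness`, `torque_contraction`, `cop`, scalar summaries
#'   `peak_com`, `peak_cop`, `overshoot` (most negative angle),
#'   `n_sign_changes`, a `diverged` flag (set instead of an error when an
#'   unstable run overflows; peaks then cover the pre-divergence span),
#'   and the `params`, `gains`, `dt` used.
#' @examples
#' p <- plant_params(k_frac = 0.5, tau_delay = 0.14)
#' cs <- pd_critical(p$S, p$tau_delay)
#' sim <- simulate_balance(p, cs$gains)
#' round(c(sim$peak_com, sim$peak_cop), 2)   # 1.11, 1.67
#' @export
simulate_balance <- function(params, gains, dt = params$tau_delay / 200,
                             horizon = 6, theta0 = 1, thetadot0 = 0) {
  stopifnot(inherits(params, "plant_params"),
            inherits(gains, "controller_gains"),
            is.finite(theta0), is.finite(thetadot0), horizon > 0, dt > 0)
  td <- params$tau_delay
  n <- as.integer(round(td / dt))
  if (n < 100L)
    stop("dt must be at most tau_delay/100 (got tau_delay/", n, ")",
         call. = FALSE)
  dt <- td / n
  if (horizon < 10 * td)
    stop("horizon must be at least 10 * tau_delay", call. = FALSE)
  # whole number of delay intervals, so refined grids nest exactly
  N <- as.integer(ceiling(horizon / td)) * n

  invtm2 <- (1 - params$k_frac) / params$tau_m0^2  # 1/tau_mech^2
  dM <- params$d_mech / td                          # per-second damping
  p <- gains$p; d <- gains$d; a <- gains$a; i_g <- gains$i

  th <- numeric(N + 1L); thd <- numeric(N + 1L); thdd <- numeric(N + 1L)
  zz <- numeric(N + 1L)
  thdd_left <- numeric(N + 1L)  # left-limit acceleration at kink nodes

  # Delayed lookup in grid-index units. `idx` is the (0-based, possibly
  # half-integer) index of the current evaluation time; the delayed index
  # is idx - n. `m` is the delay-interval index of the current step, so the
  # delayed index lies in [(m-1)*n, m*n]: at the left endpoint the stored
  # (right-limit) values apply, at the right endpoint the left-limit
  # acceleration applies.
  lag_state <- function(idx, m) {
    if (m == 0L) return(c(0, 0, 0))
    didx <- idx - n
    lo <- (m - 1L) * n
    hi <- m * n
    if (didx <= lo) {
      j <- lo + 1L
      return(c(th[j], thd[j], thdd[j]))
    }
    if (didx >= hi) {
      j <- hi + 1L
      return(c(th[j], thd[j], thdd_left[j]))
    }
    j <- floor(didx)
    u <- didx - j
    j1 <- as.integer(j) + 1L
    if (u == 0) return(c(th[j1], thd[j1], thdd[j1]))
    j2 <- j1 + 1L
    # right node of the bracketing subinterval may be the kink node hi
    a2 <- if (j2 == hi + 1L) thdd_left[j2] else thdd[j2]
    h00 <- (1 + 2 * u) * (1 - u)^2; h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u); h11 <- u^2 * (u - 1)
    thv <- h00 * th[j1] + h10 * thd[j1] * dt + h01 * th[j2] +
      h11 * thd[j2] * dt
    thdv <- h00 * thd[j1] + h10 * thdd[j1] * dt + h01 * thd[j2] +
      h11 * a2 * dt
    thddv <- (1 - u) * thdd[j1] + u * a2
    c(thv, thdv, thddv)
  }

  rhs <- function(idx, y, m) {
    lg <- lag_state(idx, m)
    acc <- y[1] * invtm2 - dM * y[2] -
      p * lg[1] - d * lg[2] - a * lg[3] - i_g * y[3]
    c(y[2], acc, lg[1])
  }

  y <- c(theta0, thetadot0, 0)
  th[1] <- theta0; thd[1] <- thetadot0
  thdd[1] <- rhs(0, y, 0L)[2]
  diverged <- FALSE
  last <- N + 1L
  for (istep in seq_len(N)) {
    idx0 <- istep - 1L
    m <- idx0 %/% n
    k1 <- rhs(idx0, y, m)
    k2 <- rhs(idx0 + 0.5, y + (dt / 2) * k1, m)
    k3 <- rhs(idx0 + 0.5, y + (dt / 2) * k2, m)
    k4 <- rhs(idx0 + 1, y + dt * k3, m)
    y <- y + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    j <- istep + 1L
    if (!all(is.finite(y)) || abs(y[1]) > 1e8) {
      diverged <- TRUE
      last <- istep
      break
    }
    th[j] <- y[1]; thd[j] <- y[2]; zz[j] <- y[3]
    if (istep %% n == 0L) {
      # kink node: store both one-sided accelerations
      thdd_left[j] <- rhs(istep, y, m)[2]
      thdd[j] <- rhs(istep, y, m + 1L)[2]
    } else {
      thdd[j] <- rhs(istep, y, m)[2]
    }
  }

  keep <- seq_len(last)
  th <- th[keep]; thd <- thd[keep]; thdd <- thdd[keep]; zz <- zz[keep]
  t_grid <- (keep - 1L) * dt

  # contraction trace from the stored (right-limit) delayed history
  lag_idx <- keep - 1L - n
  lth <- ifelse(lag_idx >= 0L, th[pmax(lag_idx, 0L) + 1L], 0)
  lthd <- ifelse(lag_idx >= 0L, thd[pmax(lag_idx, 0L) + 1L], 0)
  lthdd <- ifelse(lag_idx >= 0L, thdd[pmax(lag_idx, 0L) + 1L], 0)
  contraction <- params$tau_m0^2 *
    (p * lth + d * lthd + a * lthdd + i_g * zz)
  stiff <- params$k_frac * th
  cop <- stiff + contraction

  sgn <- sign(th[th != 0])
  n_cross <- if (length(sgn) > 1L) sum(diff(sgn) != 0) else 0L

  structure(
    list(t = t_grid, theta = th, thetadot = thd,
         torque_weight = th, torque_stiffness = stiff,
         torque_contraction = contraction, cop = cop,
         peak_com = max(th), peak_cop = max(cop),
         overshoot = min(th), n_sign_changes = n_cross,
         diverged = diverged, params = params, gains = gains, dt = dt),
    class = "balance_sim"
  )
}

#' @export
print.balance_sim <- function(x, ...) {
  cat(sprintf("Balance simulation: %d steps of %.5g s%s\n",
              length(x$t) - 1L, x$dt,
              if (x$diverged) " (DIVERGED)" else ""))
  cat(sprintf("  peak CoM = %.4f, peak CoP = %.4f, overshoot = %.4f, zero crossings = %d\n",
              x$peak_com, x$peak_cop, x$overshoot, x$n_sign_changes))
  invisible(x)
}

#' Classify the character of a simulated response
#'
#' Labels a completed simulation as one of `"unstable"` (diverged or angle
#' grew beyond 10 times the perturbation), `"oscillatory"` (the angle
#' crosses zero more than once with excursions beyond `tol`),
#' `"sluggish"` (settling time more than 3 times that of the critically
#' damped PD run for the same plant), or `"critical-like"` otherwise.
#' Gains below critical produce sluggish responses; gains above critical
#' produce oscillatory ones.
#'
#' @param result a `balance_sim` object from [simulate_balance()].
#' @param tol amplitude below which the response counts as settled
#'   (normalized units).
#' @return A single character string.
#' @export
classify_response <- function(result, tol = 1e-3) {
  stopifnot(inherits(result, "balance_sim"))
  amp0 <- max(abs(result$theta[1]), tol)
  if (result$diverged || max(abs(result$theta)) > 10 * amp0)
    return("unstable")
  th <- result$theta
  big <- abs(th) > tol
  sgn <- sign(th[big & th != 0])
  crossings <- if (length(sgn) > 1L) sum(diff(sgn) != 0) else 0L
  if (crossings > 1L) return("oscillatory")
  settle <- function(sim) {
    over <- abs(sim$theta) > tol
    if (!any(over)) sim$t[1] else sim$t[max(which(over))]
  }
  p <- result$params
  crit <- pd_critical(p$S, p$tau_delay)
  ref <- simulate_balance(p, crit$gains, dt = result$dt,
                          horizon = max(result$t),
                          theta0 = result$theta[1])
  if (settle(result) > 3 * settle(ref)) return("sluggish")
  "critical-like"
}

#' Self-convergence check of the integrator
#'
#' Reruns a simulation at `dt/2` and `dt/4` and reports the maximum
#' absolute difference in the angle trace between successive refinements
#' on the shared grid. With the 4th-order stepping the refined difference
#' must shrink; if it does not, an error is raised.
#'
#' @inheritParams simulate_balance
#' @return A list with `error` (dt vs dt/2), `error_refined` (dt/2 vs
#'   dt/4) and the observed convergence `order`
#'   (`log2(error/error_refined)`).
#' @export
convergence_check <- function(params, gains, dt = params$tau_delay / 200,
                              horizon = 6, theta0 = 1, thetadot0 = 0) {
  s1 <- simulate_balance(params, gains, dt, horizon, theta0, thetadot0)
  s2 <- simulate_balance(params, gains, dt / 2, horizon, theta0, thetadot0)
  s4 <- simulate_balance(params, gains, dt / 4, horizon, theta0, thetadot0)
  n1 <- length(s1$theta)
  e1 <- max(abs(s1$theta - s2$theta[seq(1, by = 2, length.out = n1)]))
  n2 <- length(s2$theta)
  e2 <- max(abs(s2$theta - s4$theta[seq(1, by = 2, length.out = n2)]))
  if (e2 >= e1 && e1 > .Machine$double.eps * 100)
    stop("non-convergent refinement: error ", format(e1), " -> ",
         format(e2), call. = FALSE)
  list(error = e1, error_refined = e2,
       order = if (e2 > 0) log2(e1 / e2) else Inf)
}
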