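#' Feedback controller gains
#'
#' Holds the per-inertia feedback gains of the delayed controller:
#' proportional `p` (1/s^2 per rad), derivative `d` (1/s per rad),
#' acceleration `a` (dimensionless) and integral `i` (1/s^3 per rad).
#' "Per inertia" means the torque produced by the controller is
#' `J * (p*theta_d + d*thetadot_d + a*thetaddot_d + i*integral(theta_d))`
#' with `theta_d` the delayed angle; dividing gains by the inertia J makes
#' them directly comparable across body sizes.
#'
#' The natural dimensionless counterparts at delay `tau_delay` are
#' `P = p * tau_delay^2`, `D = d * tau_delay`, `A = a`,
#' `I = i * tau_delay^3`; use [dimensionless_gains()] and
#' [dimensional_gains()] to convert. Unused gains default to 0.
#'
#' @param p proportional gain (1/s^2 per rad).
#' @param d derivative gain (1/s per rad).
#' @param a acceleration gain (dimensionless).
#' @param i integral gain (1/s^3 per rad).
#' @return An object of class `controller_gains`.
#' @examples
#' controller_gains(p = 8.08, d = 3.58)
#' @export
controller_gains <- function(p = 0, d = 0, a = 0, i = 0) {
  vals <- c(p = p, d = d, a = a, i = i)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  structure(list(p = p, d = d, a = a, i = i), class = "controller_gains")
}

#' @export
print.controller_gains <- function(x, ...) {
  cat("Controller gains (per unit inertia)\n")
  cat(sprintf("  p = %.6g 1/s^2, d = %.6g 1/s, a = %.6g, i = %.6g 1/s^3\n",
              x$p, x$d, x$a, x$i))
  invisible(x)
}

#' Convert per-inertia gains to dimensionless gains
#'
#' @param gains a [controller_gains] object.
#' @param tau_delay feedback delay in seconds.
#' @return A named list with `P = p*tau_delay^2`, `D = d*tau_delay`,
#'   `A = a`, `I = i*tau_delay^3`.
#' @seealso [dimensional_gains()]
#' @export
dimensionless_gains <- function(gains, tau_delay) {
  stopifnot(inherits(gains, "controller_gains"), tau_delay > 0)
  list(P = gains$p * tau_delay^2, D = gains$d * tau_delay,
       A = gains$a, I = gains$i * tau_delay^3)
}

#' Build per-inertia gains from dimensionless gains
#'
#' Inverse of [dimensionless_gains()]; the round trip is exact to machine
#' precision.
#'
#' @param P,D,A,I dimensionless proportional, derivative, acceleration and
#'   integral gains.
#' @param tau_delay feedback delay in seconds.
#' @return A [controller_gains] object.
#' @export
dimensional_gains <- function(P = 0, D = 0, A = 0, I = 0, tau_delay) {
  stopifnot(tau_delay > 0)
  controller_gains(p = P / tau_delay^2, d = D / tau_delay, a = A,
                   i = I / tau_delay^3)
}
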