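#' Parametric stability boundary of the delayed PD controller
#'
#' In the dimensionless gain plane (P, D) at relative speed S, the boundary
#' of the stable region consists of the static line `P = S^2` and the
#' oscillatory (Hopf) curve parametrised by the dimensionless frequency
#' `x = omega * tau_delay > 0`:
#' `P(x) = (x^2 + S^2) * cos(x)`, `D(x) = (x^2 + S^2) * sin(x) / x`.
#'
#' @param S relative speed `tau_delay / tau_mech`, `>= 0`.
#' @param x numeric vector of dimensionless frequencies, all `> 0`. For the
#'   `x -> 0+` limit use [boundary_limit()].
#' @return A data frame with columns `x`, `P`, `D`, and attribute `S`.
#' @examples
#' boundary_curve(0.31, seq(0.01, pi, length.out = 200))
#' @export
boundary_curve <- function(S, x) {
  stopifnot(is.numeric(S), length(S) == 1L, S >= 0, is.numeric(x))
  if (any(x <= 0))
    stop("x must be > 0; the x -> 0 limit is boundary_limit(S)", call. = FALSE)
  out <- data.frame(x = x,
                    P = (x^2 + S^2) * cos(x),
                    D = (x^2 + S^2) * sin(x) / x)
  attr(out, "S") <- S
  out
}

#' Limit of the oscillatory boundary at zero frequency
#'
#' As `x -> 0+`, `cos(x) -> 1` and `sin(x)/x -> 1`, so the parametric
#' boundary approaches the corner point `(P, D) = (S^2, S^2)` where it
#' meets the static boundary line.
#'
#' @inheritParams boundary_curve
#' @return Named numeric vector `c(P = S^2, D = S^2)`.
#' @export
boundary_limit <- function(S) {
  stopifnot(is.numeric(S), length(S) == 1L, S >= 0)
  c(P = S^2, D = S^2)
}

#' Static stability boundary
#'
#' Gains with `P < S^2` (dimensional `p < 1/tau_mech^2`) are unstable for
#' any derivative gain: the total proportional restoring action is then
#' weaker than the destabilizing torque of weight.
#'
#' @inheritParams boundary_curve
#' @return The dimensionless threshold `S^2`.
#' @export
static_boundary <- function(S) {
  stopifnot(is.numeric(S), S >= 0)
  S^2
}

# Sampled first arc of the oscillatory boundary: x on (0, pi], prefixed by
# the x -> 0 corner (S^2, S^2). The first arc together with the static line
# encloses the entire stable region for S in [0, sqrt(2)).
stable_region_polygon <- function(S, n = 2000) {
  x <- seq(pi / n, pi, length.out = n)
  bc <- boundary_curve(S, x)
  lim <- boundary_limit(S)
  list(P = c(lim[["P"]], bc$P), D = c(lim[["D"]], bc$D))
}

# Even-odd ray casting; vertices implicitly closed.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xcross <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Stability of delayed PD gains
#'
#' Tests whether dimensionless PD gains lie inside the stable region at
#' relative speed S. The region is bounded on the left by the static line
#' `P = S^2` and everywhere else by the first arc of the oscillatory
#' boundary ([boundary_curve()], `x` in `(0, pi]`). Membership is decided
#' geometrically by ray casting against the densely sampled arc closed back
#' to its `x -> 0` corner, intersected with the half plane `P > S^2`.
#'
#' For `S >= sqrt(2)` no PD gains stabilize the plant (the critically
#' damped solution ceases to exist there) and an error is raised.
#'
#' @param P,D dimensionless proportional and derivative gains (vectors of
#'   equal length are accepted).
#' @param S relative speed, in `[0, sqrt(2))`.
#' @param tol points closer than `tol` to a boundary are reported with
#'   `on_boundary = TRUE`; membership there is numerically unreliable.
#' @param n number of arc samples.
#' @return A data frame with columns `P`, `D`, `stable` (logical), `margin`
#'   (Euclidean distance in the (P, D) plane to the nearest boundary) and
#'   `on_boundary` (`margin <= tol`).
#' @examples
#' is_stable(P = 0.16, D = 0.50, S = 0.31)   # near-critical gains: stable
#' is_stable(P = 0, D = 0, S = 0.31)         # uncontrolled: unstable
#' @export
is_stable <- function(P, D, S, tol = 1e-6, n = 2000) {
  stopifnot(is.numeric(P), is.numeric(D), length(P) == length(D),
            is.numeric(S), length(S) == 1L, S >= 0)
  if (S >= sqrt(2))
    stop("no stabilizing PD gains exist for S >= sqrt(2)", call. = FALSE)
  poly <- stable_region_polygon(S, n)
  S2 <- static_boundary(S)
  stable <- logical(length(P))
  margin <- numeric(length(P))
  for (k in seq_along(P)) {
    inside <- P[k] > S2 && point_in_polygon(P[k], D[k], poly$P, poly$D)
    d_arc <- min(sqrt((poly$P - P[k])^2 + (poly$D - D[k])^2))
    margin[k] <- min(d_arc, abs(P[k] - S2))
    stable[k] <- inside
  }
  data.frame(P = P, D = D, stable = stable, margin = margin,
             on_boundary = margin <= tol)
}
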