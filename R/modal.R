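#' Decompose a multi-joint delayed-feedback system into independent modes
#'
#' For a multi-joint linearized stance model
#' `tau_delay^2 * thetaddot = M theta - C` (state vector `theta`,
#' dimensionless dynamics matrix `M` scaled by `tau_delay^2`, delayed
#' feedback `C`), the generic assumption that the transpose of `M` is
#' diagonalizable with real eigenvalues yields mode vectors `e_i`
#' (`t(M) e_i = s_i e_i`) whose projections `alpha_i = e_i' theta` each
#' follow independent single-joint dynamics with relative speed
#' `S_i = sqrt(s_i)` (for `s_i > 0`; `s_i = tau_delay^2 / tau_i^2` with
#' `tau_i` the modal mechanical time constant). All single-pendulum
#' machinery then applies per mode.
#'
#' Modes are ordered by descending `s_i` (fastest first) and mode vectors
#' are normalized to unit length with their first nonzero component
#' positive, so the decomposition is deterministic. Matrices with complex
#' eigenvalues, or whose eigenbasis is ill-conditioned (reciprocal
#' condition below `tol`), are rejected.
#'
#' @param M square real dynamics matrix (dimensionless, scaled by
#'   `tau_delay^2`).
#' @param tau_delay shared feedback delay in seconds.
#' @param tol conditioning tolerance for declaring the matrix defective.
#' @return An object of class `modal_system`: a list with the input
#'   `matrix` and `tau_delay`, `values` (the `s_i`), `vectors` (matrix of
#'   mode vectors, one per column), `S` (per-mode relative speeds, 0 for
#'   non-pendulum-like modes with `s_i <= 0`), `tau_i` (modal time
#'   constants, `NA` for `s_i <= 0`), `pendulum_like` (logical), and the
#'   eigenbasis reciprocal condition number `rcond`.
#' @examples
#' ms <- modal_decompose(matrix(c(2, 1, 1, 2), 2), tau_delay = 0.14)
#' ms$values   # 3, 1
#' @export
modal_decompose <- function(M, tau_delay, tol = 1e-8) {
  stopifnot(is.matrix(M), is.numeric(M), nrow(M) == ncol(M),
            all(is.finite(M)), tau_delay > 0)
  eg <- eigen(t(M))
  if (is.complex(eg$values) &&
      any(abs(Im(eg$values)) > 1e-10 * max(1, abs(eg$values))))
    stop("dynamics matrix has complex eigenvalues; only the real ",
         "diagonalizable case is supported", call. = FALSE)
  values <- Re(eg$values)
  vectors <- Re(eg$vectors)
  rc <- rcond(vectors)
  if (rc < tol)
    stop("dynamics matrix is defective within tolerance (eigenbasis ",
         "rcond = ", format(rc), "); modal decomposition requires a ",
         "diagonalizable matrix", call. = FALSE)
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j] / sqrt(sum(vectors[, j]^2))
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) v <- -v
    vectors[, j] <- v
  }
  pend <- values > 0
  structure(
    list(matrix = M, tau_delay = tau_delay, values = values,
         vectors = vectors,
         S = ifelse(pend, sqrt(pmax(values, 0)), 0),
         tau_i = ifelse(pend, tau_delay / sqrt(pmax(values, 1e-300)), NA_real_),
         pendulum_like = pend, rcond = rc),
    class = "modal_system"
  )
}

#' @export
print.modal_system <- function(x, ...) {
  cat(sprintf("Modal system: %d modes, tau_delay = %.6g s (eigenbasis rcond %.3g)\n",
              length(x$values), x$tau_delay, x$rcond))
  for (i in seq_along(x$values)) {
    cat(sprintf("  mode %d: s = %.6g, S = %.6g%s\n", i, x$values[i], x$S[i],
                if (x$pendulum_like[i]) "" else " (non-pendulum-like)"))
  }
  invisible(x)
}

#' Critical PD gains per mode, recombined into physical coordinates
#'
#' Applies [pd_critical()] to each mode of a [modal_decompose()] system
#' and recombines the per-mode gains into physical-coordinate gain
#' matrices `K_p`, `K_d` (per unit inertia, units 1/s^2 and 1/s) such
#' that the feedback torque `tau_delay^2 (K_p theta_d + K_d thetadot_d)`
#' closes each modal loop at its critical gains. Modes with `s_i <= 0`
#' (already stable without feedback, like an over-critically-stiff joint)
#' are handled through the `S = 0` path and flagged.
#'
#' @param system a `modal_system` object.
#' @return A list with `solutions` (one `critical_solution` per mode,
#'   fastest first), gain matrices `K_p` and `K_d`, and the per-mode
#'   `pendulum_like` flags.
#' @export
modal_critical_gains <- function(system) {
  stopifnot(inherits(system, "modal_system"))
  if (any(system$S >= sqrt(2)))
    stop("mode ", which(system$S >= sqrt(2))[1],
         " has S >= sqrt(2): no stabilizing PD gains exist for it",
         call. = FALSE)
  sols <- lapply(system$S, pd_critical, tau_delay = system$tau_delay)
  E <- system$vectors
  p_modal <- vapply(sols, function(s) s$gains$p, numeric(1))
  d_modal <- vapply(sols, function(s) s$gains$d, numeric(1))
  # e_i' K = p_i e_i'  =>  K' E = E diag(p)  =>  K = t(E diag(p) solve(E))
  K_p <- t(E %*% diag(p_modal, length(p_modal)) %*% solve(E))
  K_d <- t(E %*% diag(d_modal, length(d_modal)) %*% solve(E))
  list(solutions = sols, K_p = K_p, K_d = K_d,
       pendulum_like = system$pendulum_like)
}

#' Simulate a multi-joint system mode by mode
#'
#' Projects the initial physical state onto the modes, runs the
#' single-joint delay-differential simulation per mode with that mode's
#' gains, and recombines the modal traces into physical coordinates.
#' For a diagonalizable system this reproduces the fully coupled
#' simulation exactly (up to integrator tolerance).
#'
#' @param system a `modal_system` object.
#' @param gains list of [controller_gains] (one per mode), or the result
#'   of [modal_critical_gains()] to use the per-mode critical gains.
#' @param theta0,thetadot0 initial physical state vectors.
#' @param dt,horizon integrator settings, as in [simulate_balance()].
#' @return A list with the time grid `t`, the physical angle matrix
#'   `theta` (one column per joint), and the per-mode `balance_sim`
#'   objects in `modes`.
#' @export
simulate_modal <- function(system, gains = modal_critical_gains(system),
                           theta0, thetadot0 = rep(0, length(theta0)),
                           dt = system$tau_delay / 200, horizon = 6) {
  stopifnot(inherits(system, "modal_system"),
            length(theta0) == length(system$values),
            length(thetadot0) == length(theta0))
  if (!is.null(gains$solutions))
    gains <- lapply(gains$solutions, function(s) s$gains)
  stopifnot(is.list(gains), length(gains) == length(system$values))
  if (any(system$values < 0))
    stop("simulate_modal supports pendulum-like modes (s_i >= 0) only; ",
         "mode ", which(system$values < 0)[1], " has s = ",
         format(system$values[which(system$values < 0)[1]]), call. = FALSE)
  E <- system$vectors
  a0 <- drop(crossprod(E, theta0))      # alpha_i = e_i' theta
  ad0 <- drop(crossprod(E, thetadot0))
  sims <- vector("list", length(a0))
  for (i in seq_along(a0)) {
    # modal plant: S_i at the shared delay; tau_m0 chosen to realize S_i
    # through the k_frac = 0 path (s_i > 0) or the critical path (s_i <= 0)
    plant <- if (system$S[i] > 0) {
      plant_params(tau_m0 = system$tau_delay / system$S[i], k_frac = 0,
                   tau_delay = system$tau_delay)
    } else {
      plant_params(k_frac = 1, tau_delay = system$tau_delay)
    }
    sims[[i]] <- simulate_balance(plant, gains[[i]], dt = dt,
                                  horizon = horizon, theta0 = a0[i],
                                  thetadot0 = ad0[i])
  }
  alpha <- vapply(sims, function(s) s$theta, numeric(length(sims[[1]]$t)))
  theta <- t(solve(t(E), t(alpha)))     # theta = solve(E') alpha
  list(t = sims[[1]]$t, theta = theta, modes = sims)
}
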