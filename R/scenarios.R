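#' @title Named balance strategies and parameter sweeps
#' @description
#' Composes the named adaptation strategies — changing ankle stiffness,
#' sensorimotor gains, or both, in response to challenging balance
#' conditions or to an increased neural delay — into summary tables of
#' stiffness, delay, gains and simulated peak CoM/CoP excursions, and
#' sweeps the critical-gain machinery over stiffness-delay grids.
#' @name scenarios
NULL

scenario_row <- function(name, k_frac, tau_delay, tau_m0, p, d,
                         dt_frac = 200, horizon = 6) {
  plant <- plant_params(tau_m0 = tau_m0, k_frac = k_frac,
                        tau_delay = tau_delay)
  sim <- simulate_balance(plant, controller_gains(p = p, d = d),
                          dt = tau_delay / dt_frac, horizon = horizon)
  data.frame(name = name, stiffness_pct = 100 * k_frac,
             tau_delay = tau_delay, p = p, d = d,
             peak_com = sim$peak_com, peak_cop = sim$peak_cop)
}

finish_table <- function(rows, reference_name = "Reference") {
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  class(tbl) <- c("scenario_table", "data.frame")
  attr(tbl, "reference") <- reference_name
  tbl
}

#' Percent changes of each strategy relative to the reference row
#'
#' Gains and peak excursions are expressed as percent of the reference
#' value; the stiffness change is expressed in percentage points of the
#' critical stiffness; the delay change as percent of the reference delay.
#' Changes are always recomputed from the raw values.
#'
#' @param tbl a `scenario_table` from [build_table1()] or [build_table2()].
#' @return A data frame of changes, one row per non-reference strategy.
#' @export
scenario_changes <- function(tbl) {
  stopifnot(inherits(tbl, "scenario_table"))
  ref <- tbl[tbl$name == attr(tbl, "reference"), ]
  rel <- function(x, r) 100 * (x - r) / r
  out <- tbl[tbl$name != attr(tbl, "reference"), ]
  data.frame(
    name = out$name,
    stiffness_pct_Kcrit = out$stiffness_pct - ref$stiffness_pct,
    tau_delay_pct = rel(out$tau_delay, ref$tau_delay),
    p_pct = rel(out$p, ref$p),
    d_pct = rel(out$d, ref$d),
    peak_com_pct = rel(out$peak_com, ref$peak_com),
    peak_cop_pct = rel(out$peak_cop, ref$peak_cop)
  )
}

#' Strategies for standing in challenging balance conditions
#'
#' Builds the three-strategy comparison at a fixed 0.14 s delay:
#' * **Reference** — 50% of critical stiffness with the corresponding
#'   critical PD gains;
#' * **Gain decrease** — the proportional gain is cut by
#'   `gain_decrease_pct` percent and the derivative gain set to the
#'   critical derivative gain of the co-adapted system, with stiffness
#'   left unchanged (the reduced gain pair applied at the old stiffness);
#' * **Co-adaptation** — stiffness is raised (via
#'   [stiffness_for_critical_p()]) to the value at which the reduced
#'   proportional gain is exactly critical, and both gains take their
#'   critical values there.
#'
#' Peak CoM and CoP excursions come from [simulate_balance()] under a unit
#' angle perturbation.
#'
#' @param gain_decrease_pct percent reduction of the proportional gain
#'   (default 15). With 0 all rows collapse onto the reference.
#' @param k_frac_ref,tau_delay,tau_m0 reference plant definition.
#' @param dt_frac integration resolution, steps per delay interval.
#' @param horizon simulation horizon in seconds.
#' @return A `scenario_table` data frame with columns `name`,
#'   `stiffness_pct`, `tau_delay`, `p`, `d`, `peak_com`, `peak_cop`.
#' @examples
#' \donttest{
#' t1 <- build_table1()
#' print(t1)
#' scenario_changes(t1)
#' }
#' @export
build_table1 <- function(gain_decrease_pct = 15, k_frac_ref = 0.5,
                         tau_delay = 0.14, tau_m0 = 1 / sqrt(9.81),
                         dt_frac = 200, horizon = 6) {
  stopifnot(gain_decrease_pct >= 0, gain_decrease_pct < 100)
  S_ref <- plant_params(tau_m0 = tau_m0, k_frac = k_frac_ref,
                        tau_delay = tau_delay)$S
  ref <- pd_critical(S_ref, tau_delay)
  p_target <- (1 - gain_decrease_pct / 100) * ref$gains$p
  k_co <- stiffness_for_critical_p(p_target, tau_delay, tau_m0)
  S_co <- plant_params(tau_m0 = tau_m0, k_frac = k_co,
                       tau_delay = tau_delay)$S
  co <- pd_critical(S_co, tau_delay)
  finish_table(list(
    scenario_row("Reference", k_frac_ref, tau_delay, tau_m0,
                 ref$gains$p, ref$gains$d, dt_frac, horizon),
    scenario_row("Gain decrease", k_frac_ref, tau_delay, tau_m0,
                 co$gains$p, co$gains$d, dt_frac, horizon),
    scenario_row("Co-adaptation", k_co, tau_delay, tau_m0,
                 co$gains$p, co$gains$d, dt_frac, horizon)
  ))
}

#' Strategies for compensating an increased neural delay
#'
#' Builds the comparison between the reference system (50% stiffness,
#' 0.14 s delay, critical PD gains) and three responses to a delay
#' increased by `delay_increase_pct` percent:
#' * **No adaptation** — old stiffness and old gains at the new delay;
#' * **Gain adaptation** — old stiffness, gains recomputed to be critical
#'   at the new delay;
#' * **Co-adaptation** — stiffness raised to keep the relative speed S
#'   constant (via [stiffness_for_constant_S()]), gains critical for the
#'   co-adapted system. Because S (and hence all dimensionless quantities)
#'   is unchanged, the normalized CoM trace is the reference trace with
#'   time rescaled, and the peak CoM excursion is identical.
#'
#' @param delay_increase_pct percent increase of the delay (default 20).
#'   With 0 the "No adaptation" row equals the reference.
#' @inheritParams build_table1
#' @return A `scenario_table` data frame (first row `Reference`).
#' @examples
#' \donttest{
#' t2 <- build_table2()
#' print(t2)
#' }
#' @export
build_table2 <- function(delay_increase_pct = 20, k_frac_ref = 0.5,
                         tau_delay = 0.14, tau_m0 = 1 / sqrt(9.81),
                         dt_frac = 200, horizon = 6) {
  stopifnot(delay_increase_pct >= 0)
  td_new <- tau_delay * (1 + delay_increase_pct / 100)
  S_ref <- plant_params(tau_m0 = tau_m0, k_frac = k_frac_ref,
                        tau_delay = tau_delay)$S
  ref <- pd_critical(S_ref, tau_delay)
  S_new <- plant_params(tau_m0 = tau_m0, k_frac = k_frac_ref,
                        tau_delay = td_new)$S
  adapt <- pd_critical(S_new, td_new)
  k_co <- stiffness_for_constant_S(td_new, S_ref, tau_m0)
  co <- pd_critical(S_ref, td_new)
  finish_table(list(
    scenario_row("Reference", k_frac_ref, tau_delay, tau_m0,
                 ref$gains$p, ref$gains$d, dt_frac, horizon),
    scenario_row("No adaptation", k_frac_ref, td_new, tau_m0,
                 ref$gains$p, ref$gains$d, dt_frac, horizon),
    scenario_row("Gain adaptation", k_frac_ref, td_new, tau_m0,
                 adapt$gains$p, adapt$gains$d, dt_frac, horizon),
    scenario_row("Co-adaptation", k_co, td_new, tau_m0,
                 co$gains$p, co$gains$d, dt_frac, horizon)
  ))
}

#' Sweep critical feedback over a stiffness-delay grid
#'
#' Evaluates, for every combination of stiffness fraction and delay, the
#' recovery time `tau_balance` and critical gains of the requested
#' controller variant, and optionally the simulated peak CoM and CoP
#' excursions under the critical gains. Grid cells where the relative
#' speed reaches `sqrt(2)` (no critically damped solution) are returned
#' as `NA`.
#'
#' @param k_frac_grid numeric vector of stiffness fractions in `[0, 1]`.
#' @param tau_delay_grid numeric vector of delays in seconds.
#' @param controller_kind one of `"PD"`, `"PD_damped"`, `"PDA"`, `"PID"`.
#' @param tau_m0 base mechanical time constant in seconds.
#' @param D_M dimensionless mechanical damping for `"PD_damped"`.
#' @param peaks if `TRUE` (default) also simulate each cell for the peak
#'   excursion surfaces (the expensive part).
#' @param dt_frac,horizon simulation resolution and horizon.
#' @return An object of class `balance_sweep`: a list with the two axes
#'   and matrices (`k_frac` by `tau_delay`) `tau_balance`, `p_crit`,
#'   `d_crit`, and if requested `peak_com`, `peak_cop`.
#' @export
sweep_critical <- function(k_frac_grid, tau_delay_grid,
                           controller_kind = "PD",
                           tau_m0 = 1 / sqrt(9.81), D_M = 0,
                           peaks = TRUE, dt_frac = 200, horizon = 6) {
  nk <- length(k_frac_grid); nd <- length(tau_delay_grid)
  mk <- function() matrix(NA_real_, nk, nd,
                          dimnames = list(k_frac = NULL, tau_delay = NULL))
  tau_balance <- mk(); p_crit <- mk(); d_crit <- mk()
  peak_com <- mk(); peak_cop <- mk()
  for (ik in seq_len(nk)) for (id in seq_len(nd)) {
    plant <- plant_params(tau_m0 = tau_m0, k_frac = k_frac_grid[ik],
                          d_mech = D_M, tau_delay = tau_delay_grid[id])
    if (plant$S >= sqrt(2)) next
    cs <- critical_gains(controller_kind, plant$S, plant$tau_delay,
                         D_M = D_M)
    tau_balance[ik, id] <- cs$tau_balance
    p_crit[ik, id] <- cs$gains$p
    d_crit[ik, id] <- cs$gains$d
    if (peaks) {
      sim <- simulate_balance(plant, cs$gains,
                              dt = plant$tau_delay / dt_frac,
                              horizon = horizon)
      peak_com[ik, id] <- sim$peak_com
      peak_cop[ik, id] <- sim$peak_cop
    }
  }
  out <- list(k_frac = k_frac_grid, tau_delay = tau_delay_grid,
              controller_kind = controller_kind,
              tau_balance = tau_balance, p_crit = p_crit, d_crit = d_crit)
  if (peaks) {
    out$peak_com <- peak_com
    out$peak_cop <- peak_cop
  }
  structure(out, class = "balance_sweep")
}

#' @export
print.balance_sweep <- function(x, ...) {
  cat(sprintf("Critical-%s sweep over %d stiffness x %d delay values\n",
              x$controller_kind, length(x$k_frac), length(x$tau_delay)))
  cat(sprintf("  tau_balance range: [%.4g, %.4g] s\n",
              min(x$tau_balance, na.rm = TRUE),
              max(x$tau_balance, na.rm = TRUE)))
  invisible(x)
}
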