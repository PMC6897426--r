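#' Load a run configuration from a YAML file
#'
#' Reads a structured plain-text configuration describing a plant, a
#' controller and simulation settings, validates it against the package's
#' constructors, and fills defaults (the reference plant:
#' `tau_m0 = 1/sqrt(9.81)` s, `k_frac = 0.5`, `d_mech = 0`,
#' `tau_delay = 0.14` s; critical PD gains; `dt = tau_delay/200`,
#' `horizon = 6` s, unit perturbation). An empty file therefore describes
#' the reference system. Unknown keys are rejected.
#'
#' Recognized blocks and keys:
#' * `plant`: either `tau_m0`, `k_frac`, `d_mech`, `tau_delay`, or a
#'   dimensional block `m`, `g`, `L`, `J`, `theta_eq_deg`, `k`
#'   (plus `tau_delay`).
#' * `controller`: `kind` (PD, PD_damped, PDA, PID), `critical`
#'   (logical; compute critical gains for the plant), or explicit
#'   `p`, `d`, `a`, `i`.
#' * `simulation`: `dt`, `horizon`, `theta0`, `thetadot0`.
#' * top-level: `seed`, `verbosity`, `out`.
#'
#' @param path path to a YAML file.
#' @return A list of class `run_config` with elements `plant`
#'   ([plant_params]), `gains` ([controller_gains]), `controller_kind`,
#'   `simulation` (list of dt, horizon, theta0, thetadot0), `seed`,
#'   `verbosity`, `out`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known_top <- c("plant", "controller", "simulation", "seed", "verbosity",
                 "out")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)

  pl <- cfg$plant
  if (is.null(pl)) pl <- list()
  dim_keys <- c("m", "g", "L", "J", "theta_eq_deg", "k")
  norm_keys <- c("tau_m0", "k_frac", "d_mech", "tau_delay")
  bad <- setdiff(names(pl), c(dim_keys, norm_keys))
  if (length(bad))
    stop("unknown plant keys: ", paste(bad, collapse = ", "), call. = FALSE)
  plant <- if (any(dim_keys %in% names(pl))) {
    need <- setdiff(c("m", "g", "L", "J"), names(pl))
    if (length(need))
      stop("dimensional plant block missing keys: ",
           paste(need, collapse = ", "), call. = FALSE)
    from_anthropometrics(
      m = pl$m, g = pl$g, L = pl$L, J = pl$J,
      theta_eq = if (is.null(pl$theta_eq_deg)) 0 else pl$theta_eq_deg * pi / 180,
      k = if (is.null(pl$k)) 0 else pl$k,
      tau_delay = if (is.null(pl$tau_delay)) 0.14 else pl$tau_delay,
      d_mech = if (is.null(pl$d_mech)) 0 else pl$d_mech)
  } else {
    plant_params(
      tau_m0 = if (is.null(pl$tau_m0)) 1 / sqrt(9.81) else pl$tau_m0,
      k_frac = if (is.null(pl$k_frac)) 0.5 else pl$k_frac,
      d_mech = if (is.null(pl$d_mech)) 0 else pl$d_mech,
      tau_delay = if (is.null(pl$tau_delay)) 0.14 else pl$tau_delay)
  }

  ct <- cfg$controller
  if (is.null(ct)) ct <- list(critical = TRUE)
  bad <- setdiff(names(ct), c("kind", "critical", "p", "d", "a", "i"))
  if (length(bad))
    stop("unknown controller keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  kind <- if (is.null(ct$kind)) "PD" else ct$kind
  critical <- isTRUE(ct$critical) ||
    (is.null(ct$p) && is.null(ct$d) && is.null(ct$a) && is.null(ct$i))
  gains <- if (critical) {
    critical_gains(kind, plant$S, plant$tau_delay, D_M = plant$d_mech)$gains
  } else {
    controller_gains(p = if (is.null(ct$p)) 0 else ct$p,
                     d = if (is.null(ct$d)) 0 else ct$d,
                     a = if (is.null(ct$a)) 0 else ct$a,
                     i = if (is.null(ct$i)) 0 else ct$i)
  }

  sm <- cfg$simulation
  if (is.null(sm)) sm <- list()
  bad <- setdiff(names(sm), c("dt", "horizon", "theta0", "thetadot0"))
  if (length(bad))
    stop("unknown simulation keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  simulation <- list(
    dt = if (is.null(sm$dt)) plant$tau_delay / 200 else sm$dt,
    horizon = if (is.null(sm$horizon)) 6 else sm$horizon,
    theta0 = if (is.null(sm$theta0)) 1 else sm$theta0,
    thetadot0 = if (is.null(sm$thetadot0)) 0 else sm$thetadot0)

  structure(list(plant = plant, gains = gains, controller_kind = kind,
                 simulation = simulation, seed = cfg$seed,
                 verbosity = if (is.null(cfg$verbosity)) "info" else cfg$verbosity,
                 out = cfg$out),
            class = "run_config")
}

#' Write a simulation trace to disk
#'
#' Writes the time series of a [simulate_balance()] result as an
#' RFC-4180-style CSV with columns `t`, `theta`, `thetadot`,
#' `torque_weight`, `torque_stiffness`, `torque_contraction`, `cop`
#' (15 significant digits), or as JSON. A JSON sidecar
#' (`<path>.summary.json`) carries the peak statistics.
#'
#' @param result a `balance_sim` object.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param sidecar write the JSON summary sidecar next to the trace.
#' @return The path, invisibly.
#' @export
write_trace <- function(result, path, format = c("csv", "json"),
                        sidecar = TRUE) {
  stopifnot(inherits(result, "balance_sim"))
  format <- match.arg(format)
  df <- data.frame(t = result$t, theta = result$theta,
                   thetadot = result$thetadot,
                   torque_weight = result$torque_weight,
                   torque_stiffness = result$torque_stiffness,
                   torque_contraction = result$torque_contraction,
                   cop = result$cop)
  if (format == "csv") {
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "columns")
  }
  if (sidecar) {
    summ <- list(peak_com = result$peak_com, peak_cop = result$peak_cop,
                 overshoot = result$overshoot,
                 n_sign_changes = result$n_sign_changes,
                 diverged = result$diverged, dt = result$dt)
    jsonlite::write_json(summ, paste0(path, ".summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a scenario table to disk
#'
#' @param tbl a `scenario_table` (from [build_table1()]/[build_table2()])
#'   or any data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"` keep full precision (>= 10
#'   significant digits); `"markdown"` renders at the conventional printed
#'   precision (2 decimals for gains and peaks, 1 decimal for stiffness
#'   percent, 3 for the delay).
#' @return The path, invisibly.
#' @export
write_table <- function(tbl, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(format(as.data.frame(tbl), digits = 15, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(as.data.frame(tbl), path, digits = NA)
  } else {
    writeLines(format_markdown_table(tbl), path)
  }
  invisible(path)
}

#' Render a scenario table as markdown at printed precision
#'
#' @inheritParams write_table
#' @return A character vector of markdown lines.
#' @export
format_markdown_table <- function(tbl) {
  df <- as.data.frame(tbl)
  fmt <- function(col, x) {
    switch(col,
           name = as.character(x),
           stiffness_pct = sprintf("%.1f", x),
           tau_delay = sprintf("%.3f", x),
           sprintf("%.2f", x))
  }
  header <- c("Strategy", "Stiffness (% K_crit)", "Delay (s)",
              "p (1/s^2)", "d (1/s)", "Peak CoM", "Peak CoP")
  cells <- vapply(seq_along(df), function(j) fmt(names(df)[j], df[[j]]),
                  character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(header, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Generate fixture files for exploratory runs and property testing
#'
#' Writes a deterministic set of plain-text fixtures into a directory:
#' a stiffness-delay parameter grid (`param_grid.csv`), a set of random
#' dimensionless PD gain probes around the stable region
#' (`gain_probes.csv`, seeded), and ready-made scenario configuration
#' files for the reference system and both co-adaptation scenarios.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed for the random gain probes.
#' @param n_probes number of random gain probes.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, n_probes = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  grid <- expand.grid(k_frac = seq(0, 1, by = 0.25),
                      tau_delay = seq(0.1, 0.3, by = 0.05))
  grid$S <- mapply(function(k, td) plant_params(k_frac = k, tau_delay = td)$S,
                   grid$k_frac, grid$tau_delay)
  f1 <- file.path(dir, "param_grid.csv")
  utils::write.csv(grid, f1, row.names = FALSE, quote = FALSE)
  probes <- data.frame(S = stats::runif(n_probes, 0, 1.3),
                       P = stats::runif(n_probes, -0.5, 3),
                       D = stats::runif(n_probes, -0.5, 3))
  f2 <- file.path(dir, "gain_probes.csv")
  utils::write.csv(probes, f2, row.names = FALSE, quote = FALSE)
  f3 <- file.path(dir, "reference.yaml")
  writeLines(c("plant:", "  k_frac: 0.5", "  tau_delay: 0.14",
               "controller:", "  kind: PD", "  critical: true"), f3)
  f4 <- file.path(dir, "increased_delay.yaml")
  writeLines(c("plant:", "  k_frac: 0.5", "  tau_delay: 0.168",
               "controller:", "  kind: PD", "  critical: true"), f4)
  invisible(c(f1, f2, f3, f4))
}
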