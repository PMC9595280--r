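#' Quasi-steady orifice flow across a valve or septal defect
#'
#' Bernoulli orifice relation `dp = rho/2 * (Q/A)^2` (plus an optional
#' linear series resistance term `r_lin * Q`), solved for the volumetric
#' flow.  The flow sign follows the pressure gradient and a zero area gives
#' zero flow.
#'
#' @param p_upstream,p_downstream Pressures (mmHg).
#' @param effective_area Instantaneous open area (cm^2), `>= 0`.
#' @param r_lin Linear series resistance (mmHg s/mL); default 0 gives the
#'   pure orifice law, under which flow is exactly proportional to area at
#'   fixed gradient.
#' @return Volumetric flow (mL/s), positive from upstream to downstream.
#' @export
valve_flow <- function(p_upstream, p_downstream, effective_area, r_lin = 0) {
  stopifnot(all(effective_area >= 0), r_lin >= 0)
  dp <- p_upstream - p_downstream
  a_m2 <- effective_area * 1e-4
  k <- ifelse(a_m2 > 0, 1050 / (2 * a_m2^2) * 1e-12 / 133.322, Inf)
  q <- ifelse(is.finite(k) & k > 0,
              (sqrt(r_lin^2 + 4 * k * abs(dp)) - r_lin) / (2 * k),
              0)
  sign(dp) * q
}

run_core <- function(params, hr, state, max_beats, tol, record, dt_int) {
  core <- build_core_pars(params, hr)
  cpp_simulate(core, as.numeric(state), as.integer(max_beats), tol,
               record, dt_int)
}

#' Simulate one steady-state cardiac cycle
#'
#' Integrates the closed-loop circulation beat by beat from `state` until
#' the beat-to-beat change of all compartment volumes falls below `tol`
#' (relative), then records one full cycle at 1 ms resolution.
#'
#' @param config A [condition_config()]; only its heart rate is used here
#'   (disease parameters are applied beforehand with [apply_condition()]).
#' @param params A `heart_params` parameter set, e.g. [reference_params()].
#' @param state Named vector of the eight compartment volumes to start
#'   from; defaults to [initial_state()].
#' @param max_beats Beat cap for the steady-state search.
#' @param tol Relative beat-to-beat convergence tolerance.
#' @param dt_int Internal integration step (s); must divide 1 ms.
#' @return A data frame of class `hemo_series`, one row per millisecond,
#'   with chamber/arterial pressures (mmHg), compartment volumes (mL),
#'   valve and shunt flows (mL/s) and instantaneous effective valve open
#'   areas (cm^2).  Attributes: `hr`, `cycle_ms`, `e_window` (the search
#'   window for the early-diastolic inflow peak, ms), `params`, `state`
#'   (volumes at the recorded cycle start), `beats`, `converged`.
#' @export
simulate_beat <- function(config, params = reference_params(),
                          state = initial_state(), max_beats = 200,
                          tol = 1e-4, dt_int = 2.5e-4) {
  res <- run_core(params, config$hr, state, max_beats, tol,
                  record = TRUE, dt_int = dt_int)
  if (res$failed)
    stop("integration failure: compartment volume became non-positive ",
         "or non-finite")
  if (!res$converged)
    warning(sprintf(
      "beat not at steady state after %d beats (relative change %.2e)",
      res$beats, res$delta))
  rec <- as.data.frame(res$record)
  cycle_ms <- round(60000 / config$hr)
  lv <- params$chambers$lv
  la <- params$chambers$la
  e_window <- c(start = lv[["tp"]] * cycle_ms, end = la[["onset"]] * cycle_ms)
  structure(rec,
            hr = config$hr, cycle_ms = cycle_ms, e_window = e_window,
            params = params, state = res$state, beats = res$beats,
            converged = res$converged,
            class = c("hemo_series", "data.frame"))
}

#' Cycle-averaged hemodynamic summaries
#'
#' @param series A `hemo_series` from [simulate_beat()].
#' @return A list with mean arterial (aortic) pressure `map` (mmHg),
#'   cardiac output `co` (L/min, forward aortic valve flow), stroke volume
#'   `sv` (mL), and mean left atrial pressure `p_la` (mmHg).
#' @export
hemo_summary <- function(series) {
  map <- mean(series$p_ao)
  sv <- sum(series$q_av) * 1e-3              # mL (1 ms samples)
  co <- sv * attr(series, "hr") / 1000       # L/min
  list(map = map, co = co, sv = sv, p_la = mean(series$p_la))
}

#' Homeostatic pressure-flow regulation
#'
#' Adapts the systemic peripheral resistance and the total circulating
#' blood volume so that the steady-state beat has mean arterial pressure at
#' the target (91 mmHg) and cardiac output at the condition's target.
#' Multiplicative proportional updates are applied between steady-state
#' runs: resistance targets pressure, volume targets output.  Only these
#' two quantities are modified.
#'
#' @inheritParams simulate_beat
#' @param max_iter Cap on controller iterations.
#' @param map_tol Absolute MAP tolerance used internally (mmHg); stricter
#'   than the 0.5 mmHg contract.
#' @param co_tol Relative CO tolerance used internally; stricter than the
#'   1 % contract.
#' @return A list of class `adapted_run`: `params` (adapted set), `state`,
#'   `series` (the adapted steady-state beat), `map`, `co`, `iterations`,
#'   `converged`.
#' @export
homeostatic_adapt <- function(config, params = reference_params(),
                              state = initial_state(), max_iter = 100,
                              map_tol = 0.35, co_tol = 0.007) {
  map <- co <- NA_real_
  series <- NULL
  for (it in seq_len(max_iter)) {
    series <- simulate_beat(config, params, state)
    state <- attr(series, "state")
    hs <- hemo_summary(series)
    map <- hs$map; co <- hs$co
    ok_map <- abs(map - config$map_target) <= map_tol
    ok_co <- abs(co - config$co_target) / config$co_target <= co_tol
    if (ok_map && ok_co)
      return(structure(list(params = params, state = state, series = series,
                            map = map, co = co, iterations = it,
                            converged = TRUE),
                       class = "adapted_run"))
    # resistance targets pressure
    r <- params$beds[["r_sys"]] * (config$map_target / map)^0.7
    params$beds[["r_sys"]] <- min(max(r, 0.1), 15)
    # circulating volume targets output
    f <- (config$co_target / co)^0.5
    f <- min(max(f, 0.85), 1.18)
    dv <- (f - 1) * sum(state[1:8])  # volumes only, not the flow states
    if (state[["sv"]] + dv < 200)
      stop("regulation failure: venous reservoir exhausted")
    state[["sv"]] <- state[["sv"]] + dv
  }
  stop(sprintf(paste0("regulation failure: no convergence after %d ",
                      "iterations (MAP %.2f mmHg, CO %.3f L/min)"),
               max_iter, map, co))
}

#' Apply a cardiac condition to a baseline parameter set
#'
#' Implements the condition protocol sweeps: `exercise` changes only the
#' operating point (CO target and heart rate, held in the config);
#' `aging` scales ventricular passive stiffness and relaxation time by
#' `1 + 0.02 * step` (steps 1..6); `MR`/`TR` set the corresponding valve
#' leak fraction to 8-14 % in 2 % steps; `MS`/`TS` narrow the valve by
#' 50-80 % in 10 % steps; `ASD`/`VSD` open a 6-12 mm septal orifice in 2 mm
#' steps; `HFpEF` applies the graded diastolic abnormality to the left
#' ventricle (relaxation time +80 % in all grades; passive stiffness +0 %,
#' +75 %, +130 % for grades I-III).
#'
#' Exercise additionally engages sympathetic drive: above the resting
#' heart rate, the active elastance of every chamber is scaled by
#' `1 + (hr - 70) / 60` and all relaxation time constants by its
#' inverse (inotropy and lusitropy rise with heart rate), which is what
#' makes the 14 L/min operating point reachable at physiological filling
#' pressures.  The same scaling applies when a disease condition is run
#' at an exercise operating point.
#'
#' @param config A [condition_config()].
#' @param params Baseline `heart_params`, e.g. [reference_params()].
#' @return The modified parameter set.
#' @export
apply_condition <- function(config, params = reference_params()) {
  s <- config$severity_index
  cond <- config$condition
  scale_chamber <- function(ch, eed_mult = 1, tau_mult = 1) {
    ch[["eed"]] <- ch[["eed"]] * eed_mult
    ch[["tau"]] <- ch[["tau"]] * tau_mult
    ch
  }
  params <- switch(cond,
    reference = params,
    exercise = params,
    aging = {
      f <- 1 + 0.02 * s
      params$chambers$lv <- scale_chamber(params$chambers$lv, f, f)
      params$chambers$rv <- scale_chamber(params$chambers$rv, f, f)
      params
    },
    MR = { params$valves$mv[["leak"]] <- 0.06 + 0.02 * s; params },
    TR = { params$valves$tv[["leak"]] <- 0.06 + 0.02 * s; params },
    MS = { params$valves$mv[["sten"]] <- 0.40 + 0.10 * s; params },
    TS = { params$valves$tv[["sten"]] <- 0.40 + 0.10 * s; params },
    ASD = { params$shunt <- shunt_spec("atrial", 4 + 2 * s); params },
    VSD = { params$shunt <- shunt_spec("ventricular", 4 + 2 * s); params },
    HFpEF = {
      eed_mult <- c(1.00, 1.75, 2.30)[s]
      params$chambers$lv <- scale_chamber(params$chambers$lv,
                                          eed_mult, 1.80)
      params
    },
    stop("unknown condition: ", cond))
  if (config$hr > 70) {
    f <- 1 + 1.0 * (config$hr - 70) / 60
    params$chambers <- lapply(params$chambers, function(ch) {
      ch[["emax"]] <- ch[["emax"]] * f
      ch[["tau"]] <- ch[["tau"]] / f
      ch
    })
  }
  params
}

#' Total modelled blood volume at each sample of a beat
#'
#' @param series A `hemo_series`.
#' @return Numeric vector (mL), the sum over all eight compartments.
#' @export
total_volume <- function(series) {
  cols <- c("v_la", "v_lv", "v_ra", "v_rv", "v_ao", "v_sv", "v_pa", "v_pvn")
  rowSums(series[, cols])
}

#' Export a hemodynamic beat as CSV
#'
#' One row per millisecond with the canonical column set
#' `t_ms, p_la, p_lv, p_ra, p_rv, p_ao, p_pu, v_la, v_lv, v_ra, v_rv,
#' q_mv, q_tv, q_av, q_pv, q_shunt, a_mv, a_tv, a_av, a_pv`.
#'
#' @param series A `hemo_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_hemo_csv <- function(series, path) {
  cols <- c("t_ms", "p_la", "p_lv", "p_ra", "p_rv", "p_ao", "p_pu",
            "v_la", "v_lv", "v_ra", "v_rv",
            "q_mv", "q_tv", "q_av", "q_pv", "q_shunt",
            "a_mv", "a_tv", "a_av", "a_pv")
  utils::write.csv(as.data.frame(series)[, cols], path, row.names = FALSE)
  invisible(path)
}
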