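# One-degree-of-freedom cardiohemic vibration model of S3 generation.
#
# At the peak of early-diastolic atrioventricular inflow (where the
# transvalvular pressure gradient crosses zero) the momentum of the blood
# entering over one 1-ms snapshot is transferred, by perfectly inelastic
# collision, to the cardiohemic mass (ventricular free wall + cavity
# blood).  The system then vibrates freely as a damped mass-spring-dashpot
# whose displacement is the single-sided S3.

#' Physical constants of the cardiohemic model
#'
#' Myocardial density 1055 kg/m^3 and blood density 1050 kg/m^3.
#' @format Named numeric vector.
#' @export
s3_densities <- c(rho_myo = 1055, rho_bld = 1050)

#' Cardiohemic mass of one ventricle
#'
#' `m_myo` is the ventricular free-wall volume times myocardial density;
#' `m_bld` the cavity blood volume times blood density; the cardiohemic
#' mass is their sum.
#'
#' @param wall_volume Ventricular wall volume (mL), `> 0`.
#' @param cavity_volume Ventricular cavity blood volume (mL), `> 0`.
#' @return A list of class `cardiohemic_params`: `m_myo`, `m_bld`, `M_ch`
#'   (kg) and the densities used.
#' @export
compute_cardiohemic_mass <- function(wall_volume, cavity_volume) {
  if (!is.finite(wall_volume) || wall_volume <= 0)
    stop("invalid geometry: wall volume must be positive")
  if (!is.finite(cavity_volume) || cavity_volume <= 0)
    stop("invalid geometry: cavity volume must be positive")
  m_myo <- wall_volume * 1e-6 * s3_densities[["rho_myo"]]
  m_bld <- cavity_volume * 1e-6 * s3_densities[["rho_bld"]]
  structure(list(m_myo = m_myo, m_bld = m_bld, M_ch = m_myo + m_bld,
                 rho_myo = s3_densities[["rho_myo"]],
                 rho_bld = s3_densities[["rho_bld"]]),
            class = "cardiohemic_params")
}

side_columns <- function(side) {
  switch(side,
         LV = list(q = "q_mv", a = "a_mv", v = "v_lv", chamber = "lv"),
         RV = list(q = "q_tv", a = "a_tv", v = "v_rv", chamber = "rv"),
         stop("side must be 'LV' or 'RV'"))
}

#' Detect the S3 trigger instant (peak early-diastolic inflow)
#'
#' The vibration model is triggered at the peak of the E wave: the maximum
#' atrioventricular inflow within the diastolic window that ends at atrial
#' activation onset (excluding the A wave).  Because the AV valves carry
#' blood-column inertance, peak inflow is where the net transvalvular
#' driving pressure crosses zero and deceleration begins -- the
#' free-vibration moment.
#'
#' @param series A `hemo_series` from [simulate_beat()].
#' @param side `"LV"` (mitral inflow) or `"RV"` (tricuspid inflow).
#' @param min_flow Minimum peak flow (mL/s) for a trigger to exist.
#' @return Trigger time within the cycle (ms).
#' @export
detect_impact <- function(series, side = c("LV", "RV"), min_flow = 1) {
  side <- match.arg(side)
  cols <- side_columns(side)
  w <- attr(series, "e_window")
  idx <- which(series$t_ms >= w[["start"]] & series$t_ms <= w[["end"]])
  q <- series[[cols$q]][idx]
  if (!length(idx) || max(q) < min_flow)
    stop("no S3 trigger for ", side,
         ": no early-diastolic inflow peak found")
  i <- idx[which.max(q)]
  if (i == idx[1] || i == idx[length(idx)])
    warning("E-wave peak lies at the edge of the diastolic search window")
  series$t_ms[i]
}

#' Inflowing blood mass over one 1-ms snapshot
#'
#' The valve flow rate at the trigger instant integrated over the fixed
#' 1 ms sample interval and converted to mass with blood density.
#'
#' @inheritParams detect_impact
#' @param t_impact Trigger time (ms) from [detect_impact()].
#' @return Mass (kg).
#' @export
inflow_mass <- function(series, t_impact, side = c("LV", "RV")) {
  side <- match.arg(side)
  q <- series_at(series, t_impact, side_columns(side)$q)
  if (q < 0)
    stop("inconsistent trigger: negative inflow at t_impact")
  q * 1e-6 * 1e-3 * s3_densities[["rho_bld"]]  # mL/s -> m^3/s, over 1 ms
}

#' Mean inflow velocity before impact
#'
#' Valve flow rate divided by the instantaneous effective open area of the
#' valve, in SI units.
#'
#' @inheritParams inflow_mass
#' @return Velocity (m/s).
#' @export
inflow_velocity <- function(series, t_impact, side = c("LV", "RV")) {
  side <- match.arg(side)
  cols <- side_columns(side)
  q <- series_at(series, t_impact, cols$q)
  a <- series_at(series, t_impact, cols$a)
  if (a <= 0) {
    if (q != 0) stop("inconsistent series: flow through zero-area valve")
    return(0)
  }
  (q * 1e-6) / (a * 1e-4)
}

series_at <- function(series, t_ms, col) {
  i <- match(round(t_ms), round(series$t_ms))
  if (is.na(i)) stop("time ", t_ms, " ms not on the series grid")
  series[[col]][i]
}

#' Post-impact velocity of the cardiohemic mass
#'
#' Perfectly inelastic momentum transfer with the cardiohemic mass at rest
#' before impact: `V_a = m * v / (M_ch + m)`, so that
#' `(M_ch + m) * V_a == m * v` exactly.
#'
#' @param m Inflowing blood mass (kg), `>= 0`.
#' @param v Inflow velocity (m/s).
#' @param M_ch Cardiohemic mass (kg), `> 0`.
#' @return Velocity `V_a` (m/s).
#' @export
impact_velocity <- function(m, v, M_ch) {
  stopifnot(M_ch > 0, m >= 0)
  m * v / (M_ch + m)
}

#' Sphere-equivalent endocardial area of a cavity volume
#'
#' @param volume_ml Cavity volume (mL).
#' @return Area (m^2) of the sphere with that volume.
#' @export
sphere_area <- function(volume_ml) {
  stopifnot(volume_ml > 0)
  (36 * pi)^(1 / 3) * (volume_ml * 1e-6)^(2 / 3)
}

#' Spring and damping factors of the cardiohemic oscillator
#'
#' The spring factor is derived from the end-diastolic myocardial
#' stiffness at the ventricle's operating point:
#' `k = kappa * S(V_ed) * A_eff^2`, where
#' `S(V_ed) = eed * exp((V_ed - v0p)/vs)` is the slope of the passive
#' pressure-volume relation at the end-diastolic (maximum) cavity volume
#' of the beat (converted to Pa/m^3), and `A_eff` the sphere-equivalent
#' endocardial area of the cavity volume at the impact instant.
#' Evaluating the stiffness at the operating end-diastolic volume makes a
#' preload-dilated ventricle stiffer -- the mechanism that raises the S3
#' frequency in volume-overload conditions -- while the `eed` parameter
#' still scales the whole curve, so diastolic-stiffening diseases raise
#' `k` directly.  `kappa` is a single dimensionless scale calibrated once
#' at the reference condition ([s3_kappa()]) and then held fixed.  The
#' damping factor is a fixed fraction of critical damping:
#' `c = damping_ratio * 2 * sqrt(k * mass)`.
#'
#' @param chamber A [chamber_params()] (uses `eed`, `v0p`, `vs`).
#' @param cavity_volume Cavity volume at the impact instant (mL).
#' @param total_mass Vibrating mass `M_ch + m` (kg).
#' @param kappa Stiffness calibration scale; default [s3_kappa()].
#' @param damping_ratio Fraction of critical damping; default 0.1.
#' @param edv End-diastolic (maximum) cavity volume (mL) at which the
#'   passive stiffness is evaluated; defaults to `cavity_volume`.
#' @return A list with `k` (N/m), `c` (N s/m), the effective area `a_eff`
#'   (m^2) and the stiffness `s_ed` (mmHg/mL) used.
#' @export
estimate_spring_damper <- function(chamber, cavity_volume, total_mass,
                                   kappa = s3_kappa(), damping_ratio = 0.1,
                                   edv = cavity_volume) {
  stopifnot(total_mass > 0, kappa > 0, damping_ratio >= 0)
  a_eff <- sphere_area(cavity_volume)
  s_ed <- chamber[["eed"]] *
    exp((edv - chamber[["v0p"]]) / chamber[["vs"]])
  s_si <- s_ed * 133.322 / 1e-6            # mmHg/mL -> Pa/m^3
  k <- kappa * s_si * a_eff^2
  cc <- damping_ratio * 2 * sqrt(k * total_mass)
  list(k = k, c = cc, a_eff = a_eff, s_ed = s_ed)
}

#' Vibration parameters of the damped oscillator
#'
#' @param k Spring factor (N/m).
#' @param c Damping factor (N s/m).
#' @param total_mass Vibrating mass `M_ch + m` (kg).
#' @return A list of class `vibration_params`: `k`, `c`, `zeta`,
#'   `omega_n`, `omega_d` (rad/s).  `omega_d` is `NA` when `zeta >= 1`
#'   (non-oscillatory); a warning is raised in that case.
#' @export
vibration_params <- function(k, c, total_mass) {
  stopifnot(k > 0, c >= 0, total_mass > 0)
  zeta <- c / (2 * sqrt(k * total_mass))
  omega_n <- sqrt(k / total_mass)
  omega_d <- if (zeta < 1) omega_n * sqrt(1 - zeta^2) else NA_real_
  if (zeta >= 1)
    warning("zeta >= 1: non-oscillatory configuration")
  structure(list(k = k, c = c, zeta = zeta, omega_n = omega_n,
                 omega_d = omega_d, mass = total_mass),
            class = "vibration_params")
}

#' Build the full impact event for one ventricle
#'
#' Convenience wrapper running trigger detection, mass and velocity
#' estimation and the momentum transfer for one side of a simulated beat.
#'
#' @inheritParams detect_impact
#' @return A list of class `impact_event`: `side`, `t_impact` (ms), `m`
#'   (kg), `v` (m/s), `V_b` (0), `V_a` (m/s), `M_ch`, `m_myo`, `m_bld`
#'   (kg), `cavity_volume` (mL), `eed` (mmHg/mL).
#' @export
impact_event <- function(series, side = c("LV", "RV")) {
  side <- match.arg(side)
  cols <- side_columns(side)
  params <- attr(series, "params")
  chamber <- params$chambers[[cols$chamber]]
  t_imp <- detect_impact(series, side)
  cavity <- series_at(series, t_imp, cols$v)
  chm <- compute_cardiohemic_mass(chamber[["wall"]], cavity)
  m <- inflow_mass(series, t_imp, side)
  v <- inflow_velocity(series, t_imp, side)
  structure(list(side = side, t_impact = t_imp, m = m, v = v,
                 V_b = 0, V_a = impact_velocity(m, v, chm$M_ch),
                 M_ch = chm$M_ch, m_myo = chm$m_myo, m_bld = chm$m_bld,
                 cavity_volume = cavity, edv = max(series[[cols$v]]),
                 eed = chamber[["eed"]], chamber = chamber),
            class = "impact_event")
}

#' Sample the analytic free-vibration S3 waveform
#'
#' Analytic underdamped solution with initial displacement zero and
#' initial velocity `V_a`:
#' `x(t) = V_a / omega_d * exp(-zeta * omega_n * t) * sin(omega_d * t)`.
#' The waveform is sampled at `fs` from the impact instant until its
#' envelope falls below 1 % of the peak or `max_duration_ms`, whichever
#' comes first.
#'
#' @param event An `impact_event` (or any list with `V_a` and `t_impact`).
#' @param vib A `vibration_params`.
#' @param fs Sample rate (Hz).
#' @param max_duration_ms Duration cap (ms).
#' @param allow_overdamped If `TRUE`, returns the non-oscillatory closed
#'   form when `zeta >= 1` instead of failing.
#' @return A list of class `s3_waveform`: `side`, `fs`, `t_onset_ms`,
#'   `duration_ms`, `x` (displacement samples, m, starting at `x(0) = 0`).
#' @export
s3_waveform <- function(event, vib, fs = 1000, max_duration_ms = 200,
                        allow_overdamped = FALSE) {
  zeta <- vib$zeta; wn <- vib$omega_n
  if (zeta >= 1 && !allow_overdamped)
    stop("zeta >= 1: non-oscillatory regime (set allow_overdamped = TRUE ",
         "for the aperiodic closed form)")
  va <- event$V_a
  decay <- zeta * wn
  dur_ms <- if (decay > 0) min(max_duration_ms, ceiling(log(100) / decay * 1000))
            else max_duration_ms
  t <- seq(0, dur_ms / 1000, by = 1 / fs)
  x <- if (zeta < 1) {
    wd <- vib$omega_d
    va / wd * exp(-decay * t) * sin(wd * t)
  } else if (zeta == 1) {
    va * t * exp(-wn * t)
  } else {
    s <- wn * sqrt(zeta^2 - 1)
    va / (2 * s) * (exp((-decay + s) * t) - exp((-decay - s) * t))
  }
  structure(list(side = event$side %||% "LV", fs = fs,
                 t_onset_ms = event$t_impact %||% 0,
                 duration_ms = dur_ms, x = x),
            class = "s3_waveform")
}

#' Sum the left- and right-sided S3 on the common cycle axis
#'
#' Each single-sided waveform is placed at its own impact time and the two
#' are added sample-wise without rescaling.
#'
#' @param s3_lv,s3_rv `s3_waveform` objects on the same sample rate.
#' @param cycle_ms Length of the common cycle axis (ms); defaults to the
#'   smallest cycle containing both waveforms.
#' @return An `s3_waveform` with `side = "combined"`, spanning the full
#'   cycle from `t = 0`.
#' @export
combine_sides <- function(s3_lv, s3_rv, cycle_ms = NULL) {
  if (s3_lv$fs != s3_rv$fs)
    stop("mismatched sample rates: resample before combining")
  fs <- s3_lv$fs
  ends <- vapply(list(s3_lv, s3_rv),
                 function(w) w$t_onset_ms + (length(w$x) - 1) * 1000 / fs,
                 numeric(1))
  if (is.null(cycle_ms)) cycle_ms <- ceiling(max(ends))
  n <- round(cycle_ms * fs / 1000) + 1
  x <- numeric(n)
  for (w in list(s3_lv, s3_rv)) {
    i0 <- round(w$t_onset_ms * fs / 1000) + 1
    idx <- i0:min(n, i0 + length(w$x) - 1)
    x[idx] <- x[idx] + w$x[seq_along(idx)]
  }
  structure(list(side = "combined", fs = fs, t_onset_ms = 0,
                 duration_ms = cycle_ms, x = x),
            class = "s3_waveform")
}

#' Calibrate the stiffness scale at the reference condition
#'
#' Solves for the single dimensionless scale `kappa` that places the
#' damped resonance frequency of the left-ventricular S3 at `target_freq`
#' for a given reference beat.  `kappa` is calibrated once and then held
#' fixed across all conditions, so condition-to-condition frequency shifts
#' are driven purely by stiffness, geometry and inflow.
#'
#' @param series The reference `hemo_series`.
#' @param target_freq Target damped resonance frequency (Hz); default 27.
#' @param damping_ratio Fraction of critical damping; default 0.1.
#' @return The calibrated `kappa` (dimensionless).
#' @export
calibrate_stiffness_scale <- function(series, target_freq = 27,
                                      damping_ratio = 0.1) {
  ev <- impact_event(series, "LV")
  total_mass <- ev$M_ch + ev$m
  omega_d <- 2 * pi * target_freq
  omega_n <- omega_d / sqrt(1 - damping_ratio^2)
  k <- total_mass * omega_n^2
  base <- estimate_spring_damper(ev$chamber, ev$cavity_volume, total_mass,
                                 kappa = 1, damping_ratio = damping_ratio,
                                 edv = ev$edv)
  k / base$k
}

#' Frozen stiffness calibration scale
#'
#' The dimensionless spring-factor scale `kappa` obtained by a single
#' calibration of the reference simulation so that the left-ventricular S3
#' damped resonance frequency falls at 27 Hz (see
#' [calibrate_stiffness_scale()]).  Held fixed for all conditions.
#'
#' @return A single numeric value.
#' @export
s3_kappa <- function() 1.983217410480971

#' Export impact events and vibration parameters as CSV
#'
#' @param events List of `impact_event` objects.
#' @param vibs List of matching `vibration_params` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_events_csv <- function(events, vibs, path) {
  rows <- mapply(function(ev, vb) {
    data.frame(side = ev$side, t_impact_ms = ev$t_impact, m_kg = ev$m,
               v_mps = ev$v, Va_mps = ev$V_a, k = vb$k, c = vb$c,
               zeta = vb$zeta, omega_n = vb$omega_n, omega_d = vb$omega_d)
  }, events, vibs, SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
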