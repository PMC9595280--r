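#' Chamber parameters for the time-varying elastance model
#'
#' A cardiac chamber is modelled as a time-varying elastance: pressure is the
#' sum of an active term `act(t) * emax * (V - v0a)` and a passive
#' end-diastolic pressure-volume relation
#' `eed * vs * (exp((V - v0p)/vs) - 1)`, whose slope at the unstressed
#' volume `v0p` equals `eed`.  Activation rises as a raised cosine over
#' `tp` (fraction of the cycle) and relaxes exponentially with time
#' constant `tau`.
#'
#' @param emax Active elastance amplitude (mmHg/mL); `>= 0` (zero means a
#'   non-contracting chamber).
#' @param eed End-diastolic (passive) elastance scale (mmHg/mL); `> 0`.
#' @param v0a Active unstressed volume (mL).
#' @param v0p Passive unstressed volume (mL).
#' @param vs Passive curvature volume (mL); smaller values give a stiffer
#'   exponential EDPVR.
#' @param tau Isovolumic relaxation time constant (s).
#' @param onset Activation onset as a fraction of the cardiac cycle.
#' @param tp Time from onset to peak activation, fraction of the cycle.
#' @param wall_volume Wall (myocardial) volume of the chamber (mL); used for
#'   the cardiohemic mass.
#' @return A named numeric vector of class `chamber_params`.
#' @export
chamber_params <- function(emax, eed, v0a, v0p, vs, tau, onset, tp,
                           wall_volume) {
  stopifnot(emax >= 0, eed > 0, vs > 0, tau > 0, tp > 0, tp < 1,
            onset >= 0, onset < 1, wall_volume > 0)
  structure(c(emax = emax, eed = eed, v0a = v0a, v0p = v0p, vs = vs,
              tau = tau, onset = onset, tp = tp, wall = wall_volume),
            class = "chamber_params")
}

#' Valve specification
#'
#' @param area_open Anatomical open cross-sectional area (cm^2).
#' @param leak_fraction Fraction of `area_open` left open against the
#'   pressure gradient (regurgitation), in `[0, 1)`.
#' @param stenosis_fraction Fractional narrowing of the forward open area,
#'   in `[0, 1)`.
#' @param r_lin Linear series resistance (mmHg s/mL) acting as a
#'   characteristic impedance in the orifice law.
#' @param inertance_length Effective blood-column length (cm) giving the
#'   valve flow an inertance `rho * length / area`; 0 makes the valve
#'   quasi-steady.  The atrioventricular valves carry inertance so that
#'   peak inflow coincides with the zero crossing of the transvalvular
#'   gradient (the free-vibration trigger moment); the semilunar valves
#'   are quasi-steady.
#' @return A named numeric vector of class `valve_spec`.
#' @export
valve_spec <- function(area_open, leak_fraction = 0, stenosis_fraction = 0,
                       r_lin = 0.01, inertance_length = 0) {
  stopifnot(area_open > 0,
            leak_fraction >= 0, leak_fraction < 1,
            stenosis_fraction >= 0, stenosis_fraction < 1,
            r_lin >= 0, inertance_length >= 0)
  structure(c(area = area_open, leak = leak_fraction,
              sten = stenosis_fraction, rlin = r_lin,
              len = inertance_length),
            class = "valve_spec")
}

#' Septal shunt specification
#'
#' @param location `"none"`, `"atrial"` (LA-RA orifice) or `"ventricular"`
#'   (LV-RV orifice).
#' @param diameter Orifice diameter (mm); must be `> 0` unless
#'   `location == "none"`.
#' @return A named numeric vector of class `shunt_spec` with the orifice
#'   area in cm^2.
#' @export
shunt_spec <- function(location = c("none", "atrial", "ventricular"),
                       diameter = 0) {
  location <- match.arg(location)
  stopifnot(diameter >= 0)
  if (location != "none" && diameter <= 0)
    stop("shunt diameter must be > 0 when a shunt location is given")
  if (location == "none" && diameter > 0)
    stop("shunt diameter given without a location")
  loc <- match(location, c("none", "atrial", "ventricular")) - 1L
  area <- pi * (diameter / 20)^2  # mm diameter -> cm^2
  structure(c(loc = loc, area = area, rlin = 0.005),
            class = "shunt_spec")
}

#' Condition configuration
#'
#' Describes one simulated cardiac condition: the named disease (or
#' reference), the severity step within its protocol sweep, and the
#' regulated operating point (heart rate, cardiac output target, mean
#' arterial pressure target).
#'
#' Severity sweeps: aging steps 1..6 (stiffness/relaxation +2% per step),
#' MR/TR steps 1..4 (leak fraction 8, 10, 12, 14%), MS/TS steps 1..4
#' (area narrowing 50, 60, 70, 80%), ASD/VSD steps 1..4 (orifice 6, 8, 10,
#' 12 mm), HFpEF grades 1..3.  `exercise` uses `co_target`/`hr` instead of
#' a severity step.
#'
#' @param condition One of `"reference"`, `"exercise"`, `"aging"`, `"MR"`,
#'   `"TR"`, `"MS"`, `"TS"`, `"ASD"`, `"VSD"`, `"HFpEF"`.
#' @param severity_index Integer severity step (see Details); ignored for
#'   `reference` and `exercise`.
#' @param co_target Cardiac output target (L/min), 5 at rest.  When given
#'   above 5 the heart rate is interpolated linearly between (5 L/min,
#'   70 bpm) and (14 L/min, 130 bpm) unless `hr` is supplied.
#' @param hr Heart rate (beats/min); defaults to the exercise
#'   interpolation of `co_target`.
#' @param map_target Mean arterial pressure target (mmHg); 91 for all
#'   simulations.
#' @return A list of class `condition_config`.
#' @export
condition_config <- function(condition = "reference", severity_index = 1L,
                             co_target = 5, hr = NULL, map_target = 91) {
  conditions <- c("reference", "exercise", "aging", "MR", "TR", "MS", "TS",
                  "ASD", "VSD", "HFpEF")
  if (!condition %in% conditions)
    stop("unknown condition: ", condition)
  max_step <- c(reference = 1L, exercise = 4L, aging = 6L, MR = 4L, TR = 4L,
                MS = 4L, TS = 4L, ASD = 4L, VSD = 4L, HFpEF = 3L)
  severity_index <- as.integer(severity_index)
  if (severity_index < 1L || severity_index > max_step[[condition]])
    stop("severity_index ", severity_index, " out of range for ", condition)
  if (is.null(hr)) hr <- exercise_hr(co_target)
  stopifnot(hr >= 70, hr <= 130, co_target >= 5, co_target <= 14)
  structure(list(condition = condition, severity_index = severity_index,
                 co_target = co_target, hr = hr, map_target = map_target),
            class = "condition_config")
}

#' Heart rate at a given exercise cardiac output
#'
#' Linear interpolation between the rest (5 L/min, 70 bpm) and peak
#' exercise (14 L/min, 130 bpm) operating points.
#'
#' @param co_target Cardiac output (L/min) in `[5, 14]`.
#' @return Heart rate (beats/min).
#' @export
exercise_hr <- function(co_target) {
  stopifnot(co_target >= 5, co_target <= 14)
  70 + (130 - 70) * (co_target - 5) / (14 - 5)
}

#' @export
print.condition_config <- function(x, ...) {
  cat(sprintf("<condition_config> %s (severity %d), CO %.1f L/min, HR %.1f bpm, MAP %g mmHg\n",
              x$condition, x$severity_index, x$co_target, x$hr,
              x$map_target))
  invisible(x)
}

#' Reference parameter set for the closed-loop circulation
#'
#' Returns the full reference (healthy adult at rest) parameter set:
#' four elastance chambers, four valves, systemic and pulmonary windkessel
#' beds and an absent shunt.  Values are generic-adult: systolic/diastolic
#' aortic pressure near 120/75 mmHg, stroke volume near 71 mL at 70 bpm,
#' left ventricular wall volume 140 mL, right 60 mL.
#'
#' @return A list with elements `chambers`, `valves`, `beds`, `shunt`, of
#'   class `heart_params`.
#' @export
reference_params <- function() {
  chambers <- list(
    la = chamber_params(emax = 0.25, eed = 0.12, v0a = 5, v0p = 15, vs = 25,
                        tau = 0.040, onset = 0.85, tp = 0.10,
                        wall_volume = 25),
    lv = chamber_params(emax = 3.0, eed = 0.04, v0a = 5, v0p = 40, vs = 35,
                        tau = 0.045, onset = 0.0, tp = 0.30,
                        wall_volume = 140),
    ra = chamber_params(emax = 0.20, eed = 0.10, v0a = 5, v0p = 15, vs = 25,
                        tau = 0.040, onset = 0.85, tp = 0.10,
                        wall_volume = 20),
    rv = chamber_params(emax = 0.70, eed = 0.03, v0a = 5, v0p = 40, vs = 35,
                        tau = 0.045, onset = 0.0, tp = 0.30,
                        wall_volume = 60))
  valves <- list(
    mv = valve_spec(5.0, inertance_length = 1.5), av = valve_spec(3.0),
    tv = valve_spec(6.0, inertance_length = 1.5), pv = valve_spec(3.5))
  beds <- c(c_ao = 1.3, v0_ao = 80, c_sv = 70, v0_sv = 2500,
            c_pa = 4.0, v0_pa = 50, c_pv = 15, v0_pv = 120,
            r_sys = 1.05, r_vs = 0.03, r_pul = 0.08, r_vp = 0.025)
  structure(list(chambers = chambers, valves = valves, beds = beds,
                 shunt = shunt_spec("none")),
            class = "heart_params")
}

#' Default initial model state
#'
#' Starting point for the transient to the steady-state beat: the eight
#' compartment volumes (mL) plus the two inertial atrioventricular valve
#' flows (mL/s).  The homeostatic controller subsequently sets the total
#' circulating volume.
#'
#' @return Named numeric vector of length 10.
#' @export
initial_state <- function() {
  c(la = 60, lv = 120, ra = 55, rv = 120,
    ao = 200, sv = 2990, pa = 105, pvn = 255,
    q_mv = 0, q_tv = 0)
}

# Assemble the list handed to the compiled core.
build_core_pars <- function(params, hr) {
  n_ms <- round(60000 / hr)
  list(T = n_ms / 1000,
       chambers = lapply(params$chambers, function(ch) unclass(ch)),
       valves = lapply(params$valves, function(v) unclass(v)),
       beds = params$beds,
       shunt = unclass(params$shunt))
}

#' Read a condition configuration from a YAML or JSON file
#'
#' The file holds the keys `condition`, `severity_index`, `co_target` and
#' optionally `hr`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [condition_config()].
#' @export
read_condition_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    x <- yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  condition_config(condition = x$condition,
                   severity_index = x$severity_index %||% 1L,
                   co_target = x$co_target %||% 5,
                   hr = x$hr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
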