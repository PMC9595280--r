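# Experiment protocol: run one condition end-to-end, or the full grid of
# conditions x exercise levels, and collect per-condition S3 features.

#' Fixed physical-to-digital gain for loudness comparisons
#'
#' The S3 displacement is a physical quantity of order 1e-5 m.  Loudness
#' in LUFS is gain-dependent, so all conditions are converted to digital
#' full-scale units with one common, fixed gain before measurement; only
#' then are loudness values comparable across conditions and exercise
#' levels.
#'
#' @return A single numeric gain (digital units per metre).
#' @export
s3_gain <- function() 2e4

#' Run the full S3 pipeline for one cardiac condition
#'
#' Pipeline: [apply_condition()] -> [homeostatic_adapt()] (steady-state
#' beat) -> per-ventricle [impact_event()], [estimate_spring_damper()],
#' [s3_waveform()] -> [combine_sides()] -> acoustic features (peak
#' amplitude, dominant frequency, onset, integrated loudness at the fixed
#' common gain).  The pipeline has no stochastic stage: identical
#' configurations give identical results.
#'
#' @param config A [condition_config()].
#' @param params Baseline parameter set; default [reference_params()].
#' @param kappa Stiffness calibration scale; default the frozen
#'   [s3_kappa()].
#' @param gain Physical-to-digital gain for loudness; default [s3_gain()].
#' @return A list of class `condition_result`: `config`, `series`, `map`,
#'   `co`, per-side `events`, `vibration`, `waveforms`, `combined`
#'   waveform, and `features` (data frame with one row per side plus the
#'   combined signal).
#' @export
run_condition <- function(config, params = reference_params(),
                          kappa = s3_kappa(), gain = s3_gain()) {
  pars <- apply_condition(config, params)
  ad <- homeostatic_adapt(config, pars)
  series <- ad$series
  cycle_ms <- attr(series, "cycle_ms")

  events <- list(); vibs <- list(); wfs <- list()
  for (side in c("LV", "RV")) {
    ev <- tryCatch(impact_event(series, side), error = function(e) {
      warning(sprintf("[%s %s] %s", config$condition, side,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(ev)) next
    sd <- estimate_spring_damper(ev$chamber, ev$cavity_volume,
                                 ev$M_ch + ev$m, kappa = kappa,
                                 edv = ev$edv)
    vib <- vibration_params(sd$k, sd$c, ev$M_ch + ev$m)
    events[[side]] <- ev
    vibs[[side]] <- vib
    wfs[[side]] <- s3_waveform(ev, vib)
  }
  if (!length(wfs))
    stop("no S3 trigger on either side for condition ", config$condition)

  combined <- if (length(wfs) == 2) {
    combine_sides(wfs$LV, wfs$RV, cycle_ms = cycle_ms)
  } else {
    combine_sides(wfs[[1]], zero_waveform(wfs[[1]]), cycle_ms = cycle_ms)
  }
  track <- audio_signal(numeric(cycle_ms + 1), fs = 1000)
  audio <- superpose(track, combined, t_onset_ms = 0)
  loud <- integrated_loudness(audio, gain = gain)

  feat <- lapply(names(wfs), function(side) {
    sp <- band_energy_spectrum(wfs[[side]])
    data.frame(side = side,
               peak_amp = max(abs(wfs[[side]]$x)),
               dominant_freq = sp$dominant_freq,
               onset_ms = events[[side]]$t_impact,
               loudness = integrated_loudness(
                 place_in_cycle(wfs[[side]], cycle_ms), gain = gain)$lufs)
  })
  spc <- band_energy_spectrum(combined)
  feat <- rbind(do.call(rbind, feat),
                data.frame(side = "combined",
                           peak_amp = max(abs(combined$x)),
                           dominant_freq = spc$dominant_freq,
                           onset_ms = min(vapply(events, `[[`, 0,
                                                 "t_impact")),
                           loudness = loud$lufs))
  structure(list(config = config, params = ad$params, series = series,
                 map = ad$map, co = ad$co, iterations = ad$iterations,
                 events = events, vibration = vibs, waveforms = wfs,
                 combined = combined, features = feat),
            class = "condition_result")
}

zero_waveform <- function(template) {
  structure(list(side = "none", fs = template$fs, t_onset_ms = 0,
                 duration_ms = 1, x = numeric(2)),
            class = "s3_waveform")
}

place_in_cycle <- function(wf, cycle_ms) {
  track <- audio_signal(numeric(cycle_ms + 1), fs = wf$fs)
  superpose(track, wf)
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %s (severity %d): MAP %.1f mmHg, CO %.2f L/min\n",
              x$config$condition, x$config$severity_index, x$map, x$co))
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Run a grid of conditions across exercise levels
#'
#' Crosses the requested conditions (each over its full severity sweep)
#' with the requested cardiac-output levels and returns a long-format
#' feature table.  Cells that fail (non-convergence, no trigger) are
#' recorded with an error message and the grid continues.
#'
#' @param conditions Character vector of condition names; defaults to the
#'   full protocol (reference plus every disease).
#' @param co_levels Cardiac-output levels (L/min); default `c(5, 8, 11,
#'   14)` with heart rate interpolated 70-130 bpm.
#' @param params Baseline parameter set.
#' @param kappa,gain Passed to [run_condition()].
#' @param progress Print one line per cell.
#' @return A data frame with one row per condition cell and side
#'   (LV/RV/combined): severity, CO/HR operating point, achieved MAP and
#'   CO, peak amplitude, dominant frequency, onset and loudness.
#' @export
run_grid <- function(conditions = c("reference", "MR", "TR", "MS", "TS",
                                    "ASD", "VSD", "aging", "HFpEF"),
                     co_levels = c(5, 8, 11, 14),
                     params = reference_params(), kappa = s3_kappa(),
                     gain = s3_gain(), progress = FALSE) {
  n_sev <- c(reference = 1L, exercise = 1L, aging = 6L, MR = 4L, TR = 4L,
             MS = 4L, TS = 4L, ASD = 4L, VSD = 4L, HFpEF = 3L)
  rows <- list()
  for (cond in conditions) {
    for (sev in seq_len(n_sev[[cond]])) {
      for (co in co_levels) {
        cfg <- condition_config(cond, sev, co_target = co)
        if (progress)
          message(sprintf("grid: %s sev %d CO %g", cond, sev, co))
        res <- tryCatch(run_condition(cfg, params, kappa, gain),
                        error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1]] <- data.frame(
            condition = cond, severity = sev, co_target = co,
            hr = cfg$hr, map = NA_real_, co = NA_real_, side = NA_character_,
            peak_amp = NA_real_, dominant_freq = NA_real_,
            onset_ms = NA_real_, loudness = NA_real_,
            error = conditionMessage(res))
          next
        }
        f <- res$features
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, severity = sev, co_target = co, hr = cfg$hr,
          map = res$map, co = res$co, side = f$side,
          peak_amp = f$peak_amp, dominant_freq = f$dominant_freq,
          onset_ms = f$onset_ms, loudness = f$loudness,
          error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a condition result to a directory
#'
#' Writes the hemodynamic beat, the impact-event/vibration table, the
#' combined S3 as WAV (unit-peak normalized) and the feature table.
#'
#' @param result A `condition_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_condition <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_hemo_csv(result$series, file.path(dir, "hemodynamics.csv"))
  export_events_csv(result$events, result$vibration,
                    file.path(dir, "impact_events.csv"))
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  x <- result$combined$x
  if (max(abs(x)) > 0) x <- x / max(abs(x)) * 0.9
  write_wav(audio_signal(x, result$combined$fs),
            file.path(dir, "s3_combined.wav"))
  invisible(dir)
}
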