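# Shared fixtures.  The expensive pipeline runs (homeostatic adaptation,
# condition grid) are deterministic, so they are computed once per test
# session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

ref_result <- function() cached("ref", run_condition(condition_config()))

cond_result <- function(condition, severity = 1L, co = 5) {
  cached(paste("cond", condition, severity, co, sep = "_"),
         run_condition(condition_config(condition, severity,
                                        co_target = co)))
}

rest_grid <- function() cached("rest_grid", run_grid(co_levels = 5))

full_grid <- function() cached("full_grid", suppressWarnings(run_grid()))

# Synthetic single-beat series with prescribed mitral/tricuspid flow,
# for trigger-detection unit tests.
synthetic_series <- function(q_mv, q_tv = q_mv, a_mv = 5, a_tv = 6,
                             v_lv = 100, v_rv = 100,
                             e_window = c(start = 250, end = 700)) {
  n <- length(q_mv)
  df <- data.frame(t_ms = 0:(n - 1), q_mv = q_mv, q_tv = q_tv,
                   a_mv = a_mv, a_tv = a_tv, v_lv = v_lv, v_rv = v_rv)
  structure(df, e_window = e_window, cycle_ms = n - 1, hr = 70,
            params = reference_params(),
            class = c("hemo_series", "data.frame"))
}

# Analytic underdamped free vibration, used as the expected value against
# the package's waveform sampler.
analytic_vibration <- function(t, va, zeta, omega_n) {
  omega_d <- omega_n * sqrt(1 - zeta^2)
  va / omega_d * exp(-zeta * omega_n * t) * sin(omega_d * t)
}
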