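test_that("cardiohemic mass combines wall and blood with the fixed densities", {
  chm <- compute_cardiohemic_mass(150, 120)
  expect_equal(chm$m_myo, 0.15825)
  expect_equal(chm$m_bld, 0.1260)
  expect_equal(chm$M_ch, 0.28425)
  # linearity
  chm2 <- compute_cardiohemic_mass(300, 240)
  expect_equal(chm2$M_ch, 2 * chm$M_ch)
  expect_error(compute_cardiohemic_mass(150, 0), "invalid geometry")
  expect_error(compute_cardiohemic_mass(-1, 120), "invalid geometry")
})

test_that("impact detection finds the early-diastolic inflow peak", {
  # triangular pulse peaking at 400 ms
  q <- pmax(0, 200 - abs(0:857 - 400))
  s <- synthetic_series(q)
  expect_equal(detect_impact(s, "LV"), 400)
  expect_equal(detect_impact(s, "RV"), 400)
  # flat zero diastolic flow: no trigger
  expect_error(detect_impact(synthetic_series(rep(0, 858)), "LV"),
               "no S3 trigger")
})

test_that("inflow mass integrates the 1 ms flow snapshot with blood density", {
  q <- rep(0, 858); q[401] <- 500  # t_ms = 400
  s <- synthetic_series(q)
  expect_equal(inflow_mass(s, 400, "LV"), 5.25e-4)
  q[401] <- 1000
  expect_equal(inflow_mass(synthetic_series(q), 400, "LV"), 1.05e-3)
  expect_equal(inflow_mass(synthetic_series(rep(0, 858)), 400, "LV"), 0)
})

test_that("inflow velocity is flow over effective valve area in SI units", {
  q <- rep(0, 858); q[401] <- 500
  s <- synthetic_series(q, a_mv = 5)
  expect_equal(inflow_velocity(s, 400, "LV"), 1.0)
  s2 <- synthetic_series(q, a_mv = 2.5)
  expect_equal(inflow_velocity(s2, 400, "LV"), 2.0)
  expect_equal(inflow_velocity(synthetic_series(rep(0, 858)), 400, "LV"), 0)
  s3 <- synthetic_series(q, a_mv = 0)
  expect_error(inflow_velocity(s3, 400, "LV"), "zero-area valve")
})

test_that("post-impact velocity follows inelastic momentum transfer", {
  expect_equal(impact_velocity(5.25e-4, 1.0, 0.28425),
               5.25e-4 / (0.28425 + 5.25e-4))
  expect_equal(impact_velocity(5.25e-4, 1.0, 0.28425), 1.8436e-3,
               tolerance = 1e-4)
  expect_equal(impact_velocity(1e-3, 0, 0.3), 0)
  # large-mass limit approaches the inflow velocity
  expect_equal(impact_velocity(1e6, 0.7, 0.3), 0.7, tolerance = 1e-6)
})

test_that("momentum is conserved exactly for every impact event", {
  set.seed(42)
  for (i in 1:200) {
    m <- runif(1, 1e-5, 1e-2)
    v <- runif(1, 0, 3)
    M <- runif(1, 0.05, 0.6)
    va <- impact_velocity(m, v, M)
    expect_lt(abs((M + m) * va - m * v), 1e-15)
  }
})

test_that("spring factor scales with passive stiffness; damping with its policy", {
  ch <- chamber_params(emax = 3, eed = 0.04, v0a = 5, v0p = 40, vs = 35,
                       tau = 0.045, onset = 0, tp = 0.3, wall_volume = 140)
  ch2 <- ch; ch2[["eed"]] <- 2 * ch[["eed"]]
  sd1 <- estimate_spring_damper(ch, 100, 0.25, kappa = 2)
  sd2 <- estimate_spring_damper(ch2, 100, 0.25, kappa = 2)
  expect_equal(sd2$k, 2 * sd1$k)
  # damping is the stated fraction of critical damping
  expect_equal(sd1$c, 0.1 * 2 * sqrt(sd1$k * 0.25))
  vib <- vibration_params(sd1$k, sd1$c, 0.25)
  expect_equal(vib$zeta, 0.1, tolerance = 1e-12)
})

test_that("vibration parameters satisfy the oscillator identities", {
  vib <- vibration_params(k = 7800, c = 0, total_mass = 0.305)
  expect_equal(vib$omega_n, sqrt(7800 / 0.305))
  expect_equal(vib$omega_n, 159.92, tolerance = 1e-4)
  expect_equal(vib$omega_d, vib$omega_n)  # zeta = 0
  vib2 <- vibration_params(7800, 10, 0.305)
  expect_equal(vib2$zeta, 10 / (2 * sqrt(7800 * 0.305)))
  expect_equal(vib2$omega_d, vib2$omega_n * sqrt(1 - vib2$zeta^2))
  expect_warning(vibration_params(100, 1e4, 0.3), "non-oscillatory")
})

test_that("the sampled waveform matches the analytic free vibration", {
  ev <- list(side = "LV", t_impact = 400, V_a = 2e-3)
  vib <- vibration_params(6000, 0.1 * 2 * sqrt(6000 * 0.25), 0.25)
  wf <- s3_waveform(ev, vib, fs = 1000)
  expect_equal(wf$x[1], 0)
  t <- seq_along(wf$x - 1); t <- (t - 1) / 1000
  expect_equal(wf$x, analytic_vibration(t, 2e-3, vib$zeta, vib$omega_n),
               tolerance = 1e-12)
  # initial slope equals the post-impact velocity (finite differences)
  fs_hi <- 1e6
  wf_hi <- s3_waveform(ev, vib, fs = fs_hi, max_duration_ms = 1)
  expect_equal(wf_hi$x[2] * fs_hi, ev$V_a, tolerance = 1e-3)
})

test_that("the undamped limit oscillates at omega_n with amplitude V_a/omega_n", {
  ev <- list(side = "LV", t_impact = 0, V_a = 1e-3)
  vib <- vibration_params(6000, 0, 0.25)
  wf <- s3_waveform(ev, vib, fs = 5000)
  expect_equal(max(abs(wf$x)), ev$V_a / vib$omega_n, tolerance = 1e-4)
})

test_that("overdamped configurations are refused unless requested", {
  ev <- list(side = "LV", t_impact = 0, V_a = 1e-3)
  vib <- suppressWarnings(vibration_params(100, 1e4, 0.3))
  expect_error(s3_waveform(ev, vib), "non-oscillatory")
  wf <- s3_waveform(ev, vib, allow_overdamped = TRUE)
  expect_equal(wf$x[1], 0)
  expect_true(all(is.finite(wf$x)))
})

test_that("analytic solution agrees with numerical integration of the oscillator", {
  # independent RK4 oracle on M x'' + c x' + k x = 0, x(0)=0, x'(0)=V_a
  rk4_oscillator <- function(va, zeta, omega_n, t_end, dt) {
    n <- round(t_end / dt)
    x <- 0; u <- va
    out <- numeric(n)
    f <- function(x, u) c(u, -2 * zeta * omega_n * u - omega_n^2 * x)
    for (i in seq_len(n)) {
      k1 <- f(x, u)
      k2 <- f(x + dt / 2 * k1[1], u + dt / 2 * k1[2])
      k3 <- f(x + dt / 2 * k2[1], u + dt / 2 * k2[2])
      k4 <- f(x + dt * k3[1], u + dt * k3[2])
      x <- x + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      u <- u + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      out[i] <- x
    }
    out
  }
  cases <- expand.grid(zeta = c(0.05, 0.3), omega_n = c(120, 250),
                       va = c(5e-4, 2e-3))
  for (i in seq_len(nrow(cases))) {
    z <- cases$zeta[i]; wn <- cases$omega_n[i]; va <- cases$va[i]
    dt <- 1e-5
    num <- rk4_oscillator(va, z, wn, t_end = 0.3, dt = dt)
    t <- dt * seq_len(length(num))
    ana <- analytic_vibration(t, va, z, wn)
    expect_lt(max(abs(num - ana)), 1e-9 * max(abs(ana)))
  }
})

test_that("combining sides is additive, commutative and onset-aware", {
  ev_lv <- list(side = "LV", t_impact = 420, V_a = 2e-3)
  ev_rv <- list(side = "RV", t_impact = 370, V_a = 1.5e-3)
  vib <- vibration_params(6000, 0.1 * 2 * sqrt(6000 * 0.25), 0.25)
  lv <- s3_waveform(ev_lv, vib)
  rv <- s3_waveform(ev_rv, vib)
  comb <- combine_sides(lv, rv, cycle_ms = 857)
  expect_equal(comb$side, "combined")
  # commutative
  comb2 <- combine_sides(rv, lv, cycle_ms = 857)
  expect_identical(comb$x, comb2$x)
  # additive identity: a zero RV leaves the LV waveform placed at onset
  rv0 <- rv; rv0$x <- rv$x * 0
  comb3 <- combine_sides(lv, rv0, cycle_ms = 857)
  expect_equal(comb3$x[421:(420 + length(lv$x))], lv$x)
  expect_true(all(comb3$x[1:420] == 0))
  # sample-rate mismatch refused
  rv_fast <- s3_waveform(ev_rv, vib, fs = 2000)
  expect_error(combine_sides(lv, rv_fast), "sample rate")
})

test_that("the trigger coincides with the transvalvular gradient crossing", {
  s <- ref_result()$series
  t_imp <- detect_impact(s, "LV")
  i <- match(t_imp, round(s$t_ms))
  dp <- s$p_la - s$p_lv
  # at peak inflow the gradient has decayed to the small resistive residue
  expect_lt(abs(dp[i]), 6)
  # and the gradient is falling through it (inertial deceleration begins)
  expect_gt(dp[i - 20], dp[i + 20])
})
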