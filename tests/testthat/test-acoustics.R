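test_that("phonocardiogram preprocessing rejects the stop band, keeps the pass band", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  lo <- audio_signal(sin(2 * pi * 15 * t), fs)
  mid <- audio_signal(sin(2 * pi * 100 * t), fs)
  out_lo <- preprocess_pcg(lo)
  out_mid <- preprocess_pcg(mid)
  # measure on the central portion, away from filter edge effects
  core <- function(x) {
    n <- length(x$samples)
    x$samples[round(n / 4):round(3 * n / 4)]
  }
  a_lo <- max(abs(core(out_lo)))
  a_mid <- max(abs(core(out_mid)))
  expect_equal(out_lo$fs, 1000)
  expect_gt(20 * log10(a_mid / a_lo), 20)   # >= 20 dB relative attenuation
  expect_lt(abs(20 * log10(a_mid / 1)), 1)  # pass band within 1 dB
})

test_that("preprocessing removes isolated spikes and passes silence through", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- 0.3 * sin(2 * pi * 60 * t)
  x_spiked <- x
  x_spiked[c(500, 1200)] <- 10
  clean <- preprocess_pcg(audio_signal(x_spiked, fs))
  no_despike <- preprocess_pcg(audio_signal(x_spiked, fs),
                               despike_mads = Inf)
  # clipping attenuates the spike energy left after filtering
  expect_lt(max(abs(clean$samples)), max(abs(no_despike$samples)))
  expect_lt(max(abs(clean$samples)), 3)
  zeros <- preprocess_pcg(audio_signal(numeric(2000), fs))
  expect_true(all(zeros$samples == 0))
  expect_error(preprocess_pcg(audio_signal(numeric(1000), 500)),
               ">= 1000")
})

test_that("band energies are normalized and locate a pure tone", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  sp <- band_energy_spectrum(audio_signal(sin(2 * pi * 30 * t), fs))
  expect_equal(sum(sp$band_energy), 1, tolerance = 1e-9)
  top <- which.max(sp$band_energy)
  expect_true(sp$band_edges[top] <= 30 && 30 <= sp$band_edges[top + 1])
  expect_error(band_energy_spectrum(numeric(100), fs = 1000), "all-zero")
})

test_that("the damped vibration spectrum peaks at the damped resonance", {
  for (fd in c(20, 27, 45)) {
    for (zeta in c(0.05, 0.1, 0.2)) {
      omega_d <- 2 * pi * fd
      omega_n <- omega_d / sqrt(1 - zeta^2)
      t <- seq(0, 0.5, by = 1e-3)
      x <- exp(-zeta * omega_n * t) * sin(omega_d * t)
      sp <- band_energy_spectrum(x, fs = 1000)
      expect_lt(abs(sp$dominant_freq - fd), 15)
    }
  }
  # a lightly damped 27 Hz line keeps most spectral mass below 60 Hz
  t <- seq(0, 0.5, by = 1e-3)
  x <- exp(-0.1 * 2 * pi * 27 * t) * sin(2 * pi * 27 * t)
  sp <- band_energy_spectrum(x, fs = 1000)
  lo <- sp$band_edges[-length(sp$band_edges)]
  expect_gt(sum(sp$band_energy[lo < 60]), 0.5)
})

test_that("integrated loudness is BS.1770-compliant on the calibration tone", {
  fs <- 48000
  t <- seq(0, 2, by = 1 / fs)
  sine <- sin(2 * pi * 1000 * t)
  l <- integrated_loudness(sine, fs = fs)
  expect_lt(abs(l$lufs - (-3.01)), 0.1)
})

test_that("silence gates out; gain shifts loudness by its decibel value", {
  expect_identical(integrated_loudness(numeric(48000), fs = 48000)$lufs,
                   -Inf)
  fs <- 48000
  t <- seq(0, 1.5, by = 1 / fs)
  x <- 0.5 * sin(2 * pi * 250 * t)
  l1 <- integrated_loudness(x, fs = fs)$lufs
  l2 <- integrated_loudness(0.5 * x, fs = fs)$lufs
  expect_equal(l1 - l2, 6.0206, tolerance = 0.1)
  # monotone in gain
  l3 <- integrated_loudness(2 * x, fs = fs)$lufs
  expect_gt(l3, l1)
})

test_that("superposition is additive and respects occurrence times", {
  track <- audio_signal(numeric(858), 1000)
  wf <- structure(list(side = "LV", fs = 1000, t_onset_ms = 420,
                       duration_ms = 100, x = sin(2 * pi * 27 * (0:100) / 1000)),
                  class = "s3_waveform")
  out <- superpose(track, wf)
  expect_equal(out$samples[421:521], wf$x)
  expect_true(all(out$samples[1:420] == 0))
  expect_equal(out$annotations$S3, 420)
  # zero S3 leaves the track unchanged
  wf0 <- wf; wf0$x <- wf$x * 0
  s1s2 <- audio_signal(stats::rnorm(858, sd = 0.1), 1000)
  expect_equal(superpose(s1s2, wf0)$samples, s1s2$samples)
  expect_error(superpose(track, wf, t_onset_ms = 2000), "timing error")
})

test_that("WAV files round-trip through the reader and writer", {
  x <- sin(2 * pi * 40 * seq(0, 0.5, by = 1e-3)) * 0.8
  sig <- audio_signal(x, 1000)
  p16 <- tempfile(fileext = ".wav")
  pf <- tempfile(fileext = ".wav")
  write_wav(sig, p16, "pcm16")
  write_wav(sig, pf, "float32")
  r16 <- read_wav(p16)
  rf <- read_wav(pf)
  expect_equal(r16$fs, 1000)
  expect_equal(r16$samples, x, tolerance = 1e-4)
  expect_equal(rf$samples, x, tolerance = 1e-7)
  unlink(c(p16, pf))
})
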