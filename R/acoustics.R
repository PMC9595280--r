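# Acoustic analysis: superposition with an S1-S2 track, phonocardiogram
# preprocessing, 15-Hz band-energy spectra and EBU R 128 / ITU-R BS.1770
# integrated loudness.

#' Construct an audio signal container
#'
#' @param samples Numeric vector of finite samples.
#' @param fs Sample rate (Hz), `> 0`; the canonical analysis rate is
#'   1000 Hz.
#' @param annotations Optional named list of onset markers (ms), e.g.
#'   `list(S1 = 10, S2 = 320, S3 = 470)`.
#' @return A list of class `audio_signal`.
#' @export
audio_signal <- function(samples, fs = 1000, annotations = NULL) {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs,
                 annotations = annotations),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.1f ms)\n",
              length(x$samples), x$fs, 1000 * length(x$samples) / x$fs))
  invisible(x)
}

#' Superpose an S3 waveform onto an S1-S2 track
#'
#' Sample-wise addition of the S3 displacement waveform into the track at
#' the given onset, without interference in occurrence times (the S3 model
#' contributes nothing before its onset).  The track may be an all-zero
#' stub when only the S3 is studied.
#'
#' @param s1s2_track An [audio_signal()] spanning one cardiac cycle.
#' @param s3 An `s3_waveform` (or `audio_signal`) at the same sample rate.
#' @param t_onset_ms Onset of the S3 within the track (ms); defaults to the
#'   waveform's own onset.
#' @return An [audio_signal()] with an `S3` annotation added.
#' @export
superpose <- function(s1s2_track, s3, t_onset_ms = NULL) {
  x <- s1s2_track$samples
  fs <- s1s2_track$fs
  s3_fs <- s3$fs
  if (!isTRUE(all.equal(fs, s3_fs)))
    stop("mismatched sample rates between track and S3 waveform")
  wave <- if (inherits(s3, "s3_waveform")) s3$x else s3$samples
  if (is.null(t_onset_ms)) t_onset_ms <- s3$t_onset_ms %||% 0
  i0 <- round(t_onset_ms * fs / 1000) + 1
  if (i0 < 1 || i0 > length(x))
    stop("timing error: S3 onset lies outside the track")
  idx <- i0:min(length(x), i0 + length(wave) - 1)
  x[idx] <- x[idx] + wave[seq_along(idx)]
  ann <- s1s2_track$annotations %||% list()
  ann$S3 <- t_onset_ms
  audio_signal(x, fs, ann)
}

resample_to <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  g <- gcd_int(round(fs_to), round(fs_from))
  signal::resample(x, round(fs_to) / g, round(fs_from) / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Preprocess a phonocardiogram recording
#'
#' The standard recipe for heart-sound recordings: resample to 1000 Hz,
#' zero-phase band-pass between 25 and 400 Hz, then remove spikes by
#' moving-window median clipping (local median over 20 ms; samples whose
#' residual exceeds 5 robust standard deviations are replaced by the local
#' median).
#'
#' @param raw An [audio_signal()] with sample rate `>= 1000` Hz.
#' @param band Band-pass edges (Hz).
#' @param despike_window_ms Window of the local median (ms).
#' @param despike_mads Clipping threshold in MAD units.
#' @return An [audio_signal()] at 1000 Hz.
#' @export
preprocess_pcg <- function(raw, band = c(25, 400), despike_window_ms = 20,
                           despike_mads = 5) {
  stopifnot(inherits(raw, "audio_signal"))
  if (raw$fs < 1000)
    stop("phonocardiogram sample rate must be >= 1000 Hz")
  x <- resample_to(raw$samples, raw$fs, 1000)
  fs <- 1000
  if (length(x) < 100)
    stop("insufficient data for filter warm-up")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  k <- 2 * floor(despike_window_ms * fs / 1000 / 2) + 1
  med <- stats::runmed(x, k)
  resid <- x - med
  s <- stats::mad(resid)
  if (s > 0) {
    bad <- abs(resid) > despike_mads * s
    x[bad] <- med[bad]
  }
  audio_signal(x, fs, raw$annotations)
}

#' Band-energy spectrum and dominant frequency
#'
#' Low-pass filters the signal at `lowpass_cutoff`, takes a Hann-windowed,
#' zero-padded magnitude spectrum (frequency resolution at least 0.5 Hz)
#' and integrates the area under the spectrum over consecutive bands of
#' `band_width` Hz by the trapezoidal rule.  Band energies are normalized
#' by the total so they sum to one.  The dominant frequency is the
#' location of the spectral maximum below the cutoff.
#'
#' @param signal An [audio_signal()], an `s3_waveform`, or a numeric
#'   vector (then `fs` must be given).
#' @param band_width Band width (Hz); default 15.
#' @param lowpass_cutoff Low-pass cutoff (Hz); default 300.
#' @param fs Sample rate when `signal` is a bare numeric vector.
#' @return A list of class `spectrum_bands`: `band_edges` (Hz),
#'   `band_energy` (normalized), `dominant_freq` (Hz), and the underlying
#'   `freq`/`magnitude` grids.
#' @export
band_energy_spectrum <- function(signal, band_width = 15,
                                 lowpass_cutoff = 300, fs = NULL) {
  if (inherits(signal, "audio_signal")) {
    x <- signal$samples; fs <- signal$fs
  } else if (inherits(signal, "s3_waveform")) {
    x <- signal$x; fs <- signal$fs
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("fs must be supplied for a bare numeric vector")
  }
  if (all(x == 0)) stop("undefined spectrum: all-zero signal")
  if (lowpass_cutoff < fs / 2) {
    bf <- signal::butter(6, lowpass_cutoff / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  xw <- x * w
  nfft <- 2^ceiling(log2(max(n, fs / 0.5)))
  mag <- Mod(stats::fft(c(xw, numeric(nfft - n))))[1:(nfft / 2 + 1)]
  freq <- (0:(nfft / 2)) * fs / nfft
  edges <- seq(0, lowpass_cutoff, by = band_width)
  nb <- length(edges) - 1
  be <- numeric(nb)
  for (i in seq_len(nb)) {
    sel <- freq >= edges[i] & freq <= edges[i + 1]
    be[i] <- pracma::trapz(freq[sel], mag[sel])
  }
  be <- be / sum(be)
  in_band <- freq > 0 & freq <= lowpass_cutoff
  dominant <- freq[in_band][which.max(mag[in_band])]
  structure(list(band_edges = edges, band_energy = be,
                 dominant_freq = dominant, freq = freq, magnitude = mag),
            class = "spectrum_bands")
}

# ITU-R BS.1770-4 K-weighting biquads, 48 kHz coefficients.
k_weight_48k <- function(x) {
  b1 <- c(1.53512485958697, -2.69169618940638, 1.19839281085285)
  a1 <- c(1, -1.69065929318241, 0.73248077421585)
  b2 <- c(1, -2, 1)
  a2 <- c(1, -1.99004745483398, 0.99007225036621)
  x <- as.numeric(signal::filter(b1, a1, x))
  as.numeric(signal::filter(b2, a2, x))
}

#' Integrated loudness (EBU R 128 / ITU-R BS.1770)
#'
#' Mono program-loudness pipeline: K-weighting (two-stage pre-filter at an
#' internal rate of 48 kHz), mean-square over 400 ms blocks with 75 %
#' overlap, the -0.691 dB offset, an absolute gate at -70 LUFS and a
#' relative gate 10 LU below the ungated level, and the energy average of
#' the surviving blocks.  Signals shorter than one gating block are
#' zero-padded to 400 ms.
#'
#' @param signal An [audio_signal()] or numeric vector (then `fs` needed).
#' @param fs Sample rate when `signal` is a bare vector.
#' @param gain Linear gain applied before measurement (use one common gain
#'   across conditions when comparing physical waveforms).
#' @return A list of class `loudness_value`: `lufs` (integrated loudness;
#'   `-Inf` when every block is below the absolute gate), `n_blocks`,
#'   `n_gated`, `gate_abs`, `gate_rel`.
#' @export
integrated_loudness <- function(signal, fs = NULL, gain = 1) {
  if (inherits(signal, "audio_signal")) {
    x <- signal$samples; fs <- signal$fs
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("fs must be supplied for a bare numeric vector")
  }
  x <- x * gain
  if (fs != 48000) x <- resample_to(x, fs, 48000)
  fs <- 48000
  blk <- round(0.4 * fs)
  if (length(x) < blk) x <- c(x, numeric(blk - length(x)))
  hop <- round(0.1 * fs)
  x <- k_weight_48k(x)
  starts <- seq(1, length(x) - blk + 1, by = hop)
  z <- vapply(starts, function(i) mean(x[i:(i + blk - 1)]^2), numeric(1))
  lb <- -0.691 + 10 * log10(pmax(z, .Machine$double.xmin))
  keep_abs <- lb > -70
  if (!any(keep_abs))
    return(structure(list(lufs = -Inf, n_blocks = length(z), n_gated = 0L,
                          gate_abs = -70, gate_rel = NA_real_),
                     class = "loudness_value"))
  gate_rel <- -0.691 + 10 * log10(mean(z[keep_abs])) - 10
  keep <- keep_abs & lb > gate_rel
  if (!any(keep)) keep <- keep_abs
  lufs <- -0.691 + 10 * log10(mean(z[keep]))
  structure(list(lufs = lufs, n_blocks = length(z), n_gated = sum(keep),
                 gate_abs = -70, gate_rel = gate_rel),
            class = "loudness_value")
}

#' @export
print.loudness_value <- function(x, ...) {
  cat(sprintf("<loudness> %.2f LUFS (%d/%d blocks above gates)\n",
              x$lufs, x$n_gated, x$n_blocks))
  invisible(x)
}

#' Export a band spectrum as CSV
#'
#' @param spec A `spectrum_bands`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_spectrum_csv <- function(spec, path) {
  nb <- length(spec$band_energy)
  utils::write.csv(
    data.frame(band_lo_hz = spec$band_edges[seq_len(nb)],
               band_hi_hz = spec$band_edges[seq_len(nb) + 1],
               energy = spec$band_energy),
    path, row.names = FALSE)
  invisible(path)
}
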