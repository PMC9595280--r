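# Minimal RIFF/WAVE reader and writer (mono or multi-channel PCM16 and
# IEEE float32).  Kept deliberately small: the package only needs plain
# WAV files for exporting synthesized sounds and reading phonocardiogram
# recordings.

#' Read a WAV file
#'
#' Supports uncompressed PCM 16-bit and IEEE float 32-bit, mono or
#' multi-channel (channels are averaged to mono).
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)
  x <- if (fmt$code == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$code == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32)")
  }
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_signal(x, fmt$fs)
}

#' Write a WAV file
#'
#' @param signal An [audio_signal()] (samples expected in `[-1, 1]` for
#'   PCM output; clipped otherwise).
#' @param path Output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- signal$samples
  fs <- as.integer(round(signal$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bytes_per <- 2L; code <- 1L
    pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  } else {
    bytes_per <- 4L; code <- 3L
  }
  data_sz <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(as.integer(8 * bytes_per), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (format == "pcm16") {
    writeBin(pcm, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}
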