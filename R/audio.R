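#' Audio signal container
#'
#' A pressure waveform in arbitrary units with its sample rate. Stimuli are
#' rendered and presented at 44.1 kHz.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sample_rate Sampling rate in Hz (positive).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), all(is.finite(samples)),
            is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Write an audio signal as a WAV file
#'
#' Minimal RIFF/WAVE writer for mono IEEE float (32 bit) or PCM (16 bit)
#' audio.
#'
#' @param audio An [audio_signal()].
#' @param path Output file path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(inherits(audio, "audio_signal"))
  x <- audio$samples
  fs <- as.integer(round(audio$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    data_size <- 4L * length(x)
  } else {
    fmt_code <- 1L; bits <- 16L
    data_size <- 2L * length(x)
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(pmin(round(x * 32767), 32767), -32768)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads RIFF/WAVE files holding mono 16-bit PCM or 32-bit IEEE float data,
#' the formats written by [write_wav()].
#'
#' @param path WAV file path.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt_code <- NULL; fs <- NULL; bits <- NULL; n_chan <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk in ", path)
      if (n_chan != 1L) stop("only mono WAV files are supported")
      if (fmt_code == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = size %/% 4L, size = 4,
                     endian = "little")
      } else if (fmt_code == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE) / 32767
      } else {
        stop("unsupported WAV encoding (format ", fmt_code, ", ", bits, " bit)")
      }
      return(audio_signal(x, fs))
    } else {
      readBin(con, raw(), n = size + size %% 2L)
    }
  }
}

# linear convolution via FFT, padded to a 2-3-5 smooth length
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1L
  n2 <- stats::nextn(n, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(n2 - length(x)))) *
              fft(c(h, numeric(n2 - length(h)))), inverse = TRUE)) / n2
  y[seq_len(n)]
}

# apply a linear-phase FIR (odd length) with the group delay compensated,
# i.e. zero-phase filtering with zero padding outside the record
fir_filter_zerophase <- function(x, h) {
  stopifnot(length(h) %% 2L == 1L)
  d <- (length(h) - 1L) %/% 2L
  y <- conv_fft(x, h)
  y[(d + 1L):(d + length(x))]
}

#' Resample a series with anti-alias filtering
#'
#' Lowpass-filters (zero-phase windowed-sinc at 0.45 of the lower Nyquist)
#' and linearly interpolates onto the target sample grid.
#'
#' @param x Numeric series.
#' @param from Input rate, Hz.
#' @param to Output rate, Hz.
#' @return Numeric series of length `round(length(x) * to / from)`.
#' @export
resample_series <- function(x, from, to) {
  stopifnot(from > 0, to > 0)
  if (from == to) return(x)
  cutoff <- 0.45 * min(from, to)
  ntaps <- min(2L * floor(3.3 * from / (0.2 * cutoff) / 2) + 1L, 4097L)
  if (ntaps >= 9L && cutoff < from / 2) {
    h <- signal::fir1(ntaps - 1L, 2 * cutoff / from, type = "low")
    x <- fir_filter_zerophase(x, h)
  }
  n_out <- max(1L, round(length(x) * to / from))
  t_out <- (seq_len(n_out) - 1) / to
  t_in <- (seq_along(x) - 1) / from
  approx(t_in, x, xout = pmin(t_out, max(t_in)), rule = 2)$y
}
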