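# Minimal BioSemi BDF (24-bit EDF variant) reader and writer.  Only the
# features this pipeline needs: channel selection by label, uniform sampling
# rate, continuous records.

#' Read channels from a BioSemi BDF file
#'
#' @param path BDF file path.
#' @param channels Character vector of channel labels to return (default all).
#' @return List with `channels` (named list of numeric series in physical
#'   units), `rate` (Hz) and `labels` (all labels present).
#' @export
read_bdf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  id0 <- readBin(con, raw(), n = 1)
  id <- readChar(con, 7)
  if (as.integer(id0) != 255L || !identical(id, "BIOSEMI"))
    stop("not a BDF file: ", path)
  readChar(con, 80); readChar(con, 80)   # subject, recording
  readChar(con, 8); readChar(con, 8)     # date, time
  readChar(con, 8)                       # header byte count
  readChar(con, 44)                      # version/reserved
  n_records <- as.integer(readChar(con, 8))
  rec_dur <- as.numeric(readChar(con, 8))
  n_chan <- as.integer(readChar(con, 4))
  read_fields <- function(width) {
    trimws(vapply(seq_len(n_chan), function(i) readChar(con, width), ""))
  }
  labels <- read_fields(16)
  read_fields(80)                        # transducer
  read_fields(8)                         # physical dimension
  phys_min <- as.numeric(read_fields(8))
  phys_max <- as.numeric(read_fields(8))
  dig_min <- as.numeric(read_fields(8))
  dig_max <- as.numeric(read_fields(8))
  read_fields(80)                        # prefiltering
  nsamp <- as.integer(read_fields(8))
  read_fields(32)                        # reserved
  if (length(unique(nsamp)) != 1)
    stop("channels with differing sampling rates are not supported")
  rate <- nsamp[1] / rec_dur
  want <- if (is.null(channels)) labels else channels
  missing <- setdiff(want, labels)
  if (length(missing))
    stop("channels not present in BDF: ", paste(missing, collapse = ", "))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- lapply(want, function(ch) numeric(n_records * nsamp[1]))
  names(out) <- want
  for (r in seq_len(n_records)) {
    for (ci in seq_len(n_chan)) {
      bytes <- readBin(con, integer(), n = 3L * nsamp[ci], size = 1,
                       signed = FALSE)
      if (labels[ci] %in% want) {
        b <- matrix(bytes, nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v[v >= 8388608] <- v[v >= 8388608] - 16777216
        phys <- phys_min[ci] + (v - dig_min[ci]) * gain[ci]
        out[[labels[ci]]][((r - 1) * nsamp[ci] + 1):(r * nsamp[ci])] <- phys
      }
    }
  }
  list(channels = out, rate = rate, labels = labels)
}

#' Write a BioSemi BDF file
#'
#' Minimal writer (one-second records, common rate, symmetric physical
#' range); intended for constructing small test recordings.
#'
#' @param channels Named list of equal-length numeric series.
#' @param rate Sampling rate in Hz; series lengths must be a multiple of it.
#' @param path Output path.
#' @param phys_range Physical range mapped onto the full 24-bit digital
#'   range.
#' @return `path`, invisibly.
#' @export
write_bdf <- function(channels, rate, path, phys_range = c(-262144, 262143)) {
  n_chan <- length(channels)
  stopifnot(n_chan >= 1, !is.null(names(channels)))
  n <- length(channels[[1]])
  for (ch in channels) stopifnot(length(ch) == n)
  if (n %% rate != 0) stop("series length must be a whole number of seconds")
  n_records <- n %/% rate
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  writeBin(as.raw(255L), con)
  writeChar("BIOSEMI", con, eos = NULL)
  writeChar(pad("synthetic", 80), con, eos = NULL)
  writeChar(pad("ldtrf test recording", 80), con, eos = NULL)
  writeChar(pad("01.01.00", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(256L * (1L + n_chan), 8), con, eos = NULL)
  writeChar(pad("24BIT", 44), con, eos = NULL)
  writeChar(pad(n_records, 8), con, eos = NULL)
  writeChar(pad(1, 8), con, eos = NULL)
  writeChar(pad(n_chan, 4), con, eos = NULL)
  wf <- function(vals, w) for (v in vals) writeChar(pad(v, w), con, eos = NULL)
  wf(names(channels), 16)
  wf(rep("synthetic", n_chan), 80)
  wf(rep("uV", n_chan), 8)
  wf(rep(phys_range[1], n_chan), 8)
  wf(rep(phys_range[2], n_chan), 8)
  wf(rep(-8388608, n_chan), 8)
  wf(rep(8388607, n_chan), 8)
  wf(rep("none", n_chan), 80)
  wf(rep(rate, n_chan), 8)
  wf(rep("", n_chan), 32)
  gain <- (phys_range[2] - phys_range[1]) / (8388607 - (-8388608))
  for (r in seq_len(n_records)) {
    for (ch in channels) {
      seg <- ch[((r - 1) * rate + 1):(r * rate)]
      v <- round((seg - phys_range[1]) / gain) - 8388608
      v <- pmax(pmin(v, 8388607), -8388608)
      v[v < 0] <- v[v < 0] + 16777216
      b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
      writeBin(as.raw(b), con)
    }
  }
  invisible(path)
}
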