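# Stimulus construction: pseudo-Poisson click trains and level-scheduled
# speech sessions (long 1-min fixed-level trials intermixed with short trials
# whose level changes every 5 s, cosine-ramped).

# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a pseudo-Poisson click train
#'
#' Inter-onset intervals are drawn as `min_ici` plus an exponential with mean
#' `1/rate - min_ici`, then the stochastic parts are rescaled by a common
#' factor so that exactly `round(duration * rate)` clicks fall inside the
#' requested duration.  This honours both the nominal click count and the
#' minimum inter-click interval.  Polarities alternate, starting with a
#' rarefaction click.
#'
#' @param duration Train duration in seconds.
#' @param rate Nominal click rate, clicks/second.
#' @param min_ici Minimum inter-click interval, seconds.
#' @param sample_rate Audio sample rate in Hz.
#' @param click_duration Rectangular click width in seconds (91 us, i.e. four
#'   samples at 44.1 kHz).
#' @param seed Integer seed.
#' @return An object of class `click_train` with fields `onsets`,
#'   `polarities`, `click_duration`, `sample_rate`, `duration`.
#' @export
generate_click_train <- function(duration, rate = 44, min_ici = 0.015,
                                 sample_rate = 44100, click_duration = 91e-6,
                                 seed) {
  stopifnot(duration >= 0, rate > 0, min_ici >= 0)
  if (rate * min_ici >= 1)
    stop("infeasible click parameters: rate * min_ici must be < 1")
  n <- round(duration * rate)
  if (n == 0) {
    return(structure(list(onsets = numeric(0), polarities = numeric(0),
                          click_duration = click_duration,
                          sample_rate = sample_rate, duration = duration),
                     class = "click_train"))
  }
  span <- duration - 1 / rate
  if (span <= n * min_ici)
    stop("infeasible click parameters: duration too short for ", n,
         " clicks at min_ici = ", min_ici)
  e <- with_seed(seed, rexp(n, rate = 1 / (1 / rate - min_ici)))
  b <- (span - n * min_ici) / sum(e)
  onsets <- cumsum(min_ici + b * e)
  polarities <- rep_len(c(1, -1), n) # +1 rarefaction, -1 condensation
  structure(list(onsets = onsets, polarities = polarities,
                 click_duration = click_duration, sample_rate = sample_rate,
                 duration = duration),
            class = "click_train")
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %d clicks over %.1f s (min ICI %.1f ms)\n",
              length(x$onsets), x$duration,
              if (length(x$onsets) > 1) 1000 * min(diff(x$onsets)) else NA))
  invisible(x)
}

#' Render a click train as audio
#'
#' Each click is a rectangular pulse of `round(click_duration * sample_rate)`
#' samples, signed by its polarity.
#'
#' @param train A `click_train`.
#' @return An [audio_signal()] covering the train duration.
#' @export
render_clicks <- function(train) {
  stopifnot(inherits(train, "click_train"))
  fs <- train$sample_rate
  n_click <- round(train$click_duration * fs)
  n <- round(train$duration * fs)
  x <- numeric(n)
  if (length(train$onsets)) {
    starts <- round(train$onsets * fs) + 1L
    if (any(diff(starts) < n_click)) stop("overlapping click pulses")
    for (i in seq_along(starts)) {
      idx <- starts[i]:(starts[i] + n_click - 1L)
      idx <- idx[idx <= n]
      x[idx] <- x[idx] + train$polarities[i]
    }
  }
  audio_signal(x, fs)
}

#' Build a level-scheduled trial sequence
#'
#' Long trials hold one level for the whole trial; short trials change level
#' every `short_segment` seconds, with each level appearing equally often
#' within the trial (a shuffled balanced multiset).  Long-trial levels are
#' balanced across the session and trial order is fully randomized, so every
#' level receives exactly the same total presentation time.
#'
#' @param n_long,n_short Trial counts; `n_long` must be a multiple of the
#'   number of levels.
#' @param levels Levels in dB (e.g. `c(72, 60, 48, 36)` for speech).
#' @param seed Integer seed.
#' @param trial_duration Trial length in seconds (60).
#' @param short_segment Segment length within short trials in seconds (5).
#' @return A `trial_schedule`: a data frame with columns `trial`, `type`,
#'   `start`, `end`, `level` (one row per constant-level segment, contiguous
#'   in session time) and a `levels` attribute.
#' @export
build_trial_schedule <- function(n_long, n_short, levels, seed,
                                 trial_duration = 60, short_segment = 5) {
  stopifnot(length(levels) >= 1, n_long >= 0, n_short >= 0)
  L <- length(levels)
  if (n_long %% L != 0)
    stop("n_long must be a multiple of the number of levels")
  n_seg <- trial_duration / short_segment
  if (n_short > 0 && (n_seg != round(n_seg) || n_seg %% L != 0))
    stop("short-trial length not divisible by segment count x levels")
  with_seed(seed, {
    types <- sample(c(rep("long", n_long), rep("short", n_short)))
    long_levels <- sample(rep(levels, n_long / L))
    rows <- vector("list", length(types))
    t0 <- 0
    i_long <- 0L
    for (i in seq_along(types)) {
      if (types[i] == "long") {
        i_long <- i_long + 1L
        rows[[i]] <- data.frame(trial = i, type = "long", start = t0,
                                end = t0 + trial_duration,
                                level = long_levels[i_long])
      } else {
        seg_levels <- sample(rep(levels, n_seg / L))
        starts <- t0 + short_segment * (seq_len(n_seg) - 1)
        rows[[i]] <- data.frame(trial = i, type = "short", start = starts,
                                end = starts + short_segment,
                                level = seg_levels)
      }
      t0 <- t0 + trial_duration
    }
    sched <- do.call(rbind, rows)
    if (is.null(sched))
      sched <- data.frame(trial = integer(0), type = character(0),
                          start = numeric(0), end = numeric(0),
                          level = numeric(0))
    attr(sched, "levels") <- levels
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

# sample-wise amplitude gain profile for a schedule: piecewise-constant
# 10^((level - reference)/20) with raised-cosine crossfades of width `ramp`
# centred on each level change
level_gain_profile <- function(schedule, n, fs, reference_level, ramp) {
  t_end <- max(schedule$end)
  g <- numeric(n)
  gains <- db_to_amplitude(schedule$level, reference_level)
  idx_start <- pmax(1L, floor(schedule$start * fs) + 1L)
  idx_end <- pmin(n, ceiling(schedule$end * fs))
  for (i in seq_len(nrow(schedule)))
    g[idx_start[i]:idx_end[i]] <- gains[i]
  if (n > ceiling(t_end * fs)) g[(ceiling(t_end * fs) + 1L):n] <- gains[nrow(schedule)]
  if (ramp > 0 && nrow(schedule) > 1) {
    for (i in seq_len(nrow(schedule) - 1L)) {
      g1 <- gains[i]; g2 <- gains[i + 1L]
      if (g1 == g2) next
      tb <- schedule$end[i]
      i0 <- max(1L, floor((tb - ramp / 2) * fs) + 1L)
      i1 <- min(n, ceiling((tb + ramp / 2) * fs))
      if (i0 > i1) next
      idx <- i0:i1
      tau <- pmin(pmax(((idx - 1) / fs - (tb - ramp / 2)) / ramp, 0), 1)
      g[idx] <- g1 + (g2 - g1) * (0.5 - 0.5 * cos(pi * tau))
    }
  }
  g
}

#' Apply scheduled level gains to audio
#'
#' Scales each schedule segment by `10^((level - reference_level)/20)` with a
#' raised-cosine crossfade of width `ramp` centred on every level change, so
#' that the gain at the midpoint of a change is the mean of the two segment
#' gains.
#'
#' @param audio An [audio_signal()] covering the schedule duration.
#' @param schedule A `trial_schedule`.
#' @param reference_level dB value mapped to unit gain (defaults to the
#'   loudest scheduled level).
#' @param ramp Crossfade width in seconds (0.5).
#' @return An [audio_signal()] of the same length.
#' @export
apply_level_gains <- function(audio, schedule,
                              reference_level = max(schedule$level),
                              ramp = 0.5) {
  stopifnot(inherits(audio, "audio_signal"), inherits(schedule, "trial_schedule"))
  fs <- audio$sample_rate
  n_needed <- floor(max(schedule$end) * fs)
  if (length(audio$samples) < n_needed)
    stop("audio (", length(audio$samples), " samples) shorter than schedule (",
         n_needed, " samples)")
  if (ramp >= min(schedule$end - schedule$start))
    stop("ramp must be shorter than the shortest segment")
  g <- level_gain_profile(schedule, length(audio$samples), fs,
                          reference_level, ramp)
  audio_signal(audio$samples * g, fs)
}

#' Write a trial schedule as structured text
#'
#' One tab-separated record per constant-level segment: trial index, trial
#' type, start (s), end (s), level (dB).
#'
#' @param schedule A `trial_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial schedule written by [write_schedule()]
#' @param path Input path.
#' @return A `trial_schedule`.
#' @export
read_schedule <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", "numeric",
                                  "numeric", "numeric"))
  attr(df, "levels") <- sort(unique(df$level), decreasing = TRUE)
  class(df) <- c("trial_schedule", "data.frame")
  df
}
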