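# Gaze-trace simulation, cleaning and per-bar-position summarization.

#' Generate a synthetic gaze/pupil trace
#'
#' Two-dimensional gaze around a fixation point plus a pupil-size channel,
#' with optional linear drift, blinks (flagged gaps with missing samples)
#' and pupil spikes (brief high-acceleration excursions emulating partial
#' pupil occlusions). Overlapping blink intervals are merged with a
#' warning.
#'
#' @param duration_s Trace duration, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @param fixation Fixation position (dva).
#' @param fixation_noise_sd Gaze noise SD, dva.
#' @param blinks data.frame with `onset_s`, `duration_s` (or NULL).
#' @param spikes data.frame with `time_s`, `amplitude`, `width_s`
#'   (or NULL); amplitude in pupil units.
#' @param drift_dva_per_s Length-2 linear gaze drift.
#' @param pupil_baseline,pupil_noise_sd Pupil channel baseline and noise.
#' @param seed Seed; NULL uses the current RNG state.
#' @return data.frame of class `gaze_trace` (time_s, x, y, pupil, valid)
#'   with attribute `rate_hz`; blink samples are NA with `valid = FALSE`.
#' @export
generate_gaze_trace <- function(duration_s, rate_hz = 100,
                                fixation = c(0, 0),
                                fixation_noise_sd = 0.05,
                                blinks = NULL, spikes = NULL,
                                drift_dva_per_s = c(0, 0),
                                pupil_baseline = 3, pupil_noise_sd = 0.005,
                                seed = NULL) {
  .stop_if(rate_hz <= 0, "rate_hz must be positive")
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  .with_seed(seed, {
    x <- fixation[1] + drift_dva_per_s[1] * t + rnorm(n, 0, fixation_noise_sd)
    y <- fixation[2] + drift_dva_per_s[2] * t + rnorm(n, 0, fixation_noise_sd)
    pupil <- pupil_baseline + rnorm(n, 0, pupil_noise_sd)
    valid <- rep(TRUE, n)
    if (!is.null(spikes) && nrow(spikes) > 0) {
      for (s in seq_len(nrow(spikes))) {
        ctr <- round(spikes$time_s[s] * rate_hz) + 1
        hw <- max(1, round(spikes$width_s[s] * rate_hz / 2))
        ix <- (ctr - hw):(ctr + hw)
        ix <- ix[ix >= 1 & ix <= n]
        pupil[ix] <- pupil[ix] +
          spikes$amplitude[s] * (1 - abs(ix - ctr) / (hw + 1))
      }
    }
    if (!is.null(blinks) && nrow(blinks) > 0) {
      b <- blinks[order(blinks$onset_s), , drop = FALSE]
      merged <- list(c(b$onset_s[1], b$onset_s[1] + b$duration_s[1]))
      if (nrow(b) > 1) for (i in 2:nrow(b)) {
        last <- merged[[length(merged)]]
        lo <- b$onset_s[i]; hi <- lo + b$duration_s[i]
        if (lo <= last[2]) {
          warning("overlapping blink intervals merged", call. = FALSE)
          merged[[length(merged)]] <- c(last[1], max(last[2], hi))
        } else merged[[length(merged) + 1]] <- c(lo, hi)
      }
      for (iv in merged) {
        ix <- which(t >= iv[1] & t < iv[2])
        x[ix] <- y[ix] <- pupil[ix] <- NA_real_
        valid[ix] <- FALSE
      }
    }
    structure(data.frame(time_s = t, x = x, y = y, pupil = pupil,
                         valid = valid),
              rate_hz = rate_hz, class = c("gaze_trace", "data.frame"))
  })
}

.interp_na <- function(v, t) {
  bad <- is.na(v)
  if (!any(bad)) return(v)
  approx(t[!bad], v[!bad], xout = t, rule = 2)$y
}

#' Clean a gaze trace
#'
#' Blink gaps are linearly interpolated. For pupil-occlusion spike
#' rejection the pupil channel is high-pass filtered (detection only);
#' samples whose filtered-pupil acceleration exceeds `accel_thresh`, and
#' their neighbors within `pad_s`, are invalidated and interpolated.
#' When a `bar_sequence` is supplied, within-pass drift is corrected by
#' subtracting the median gaze position of each bar pass.
#'
#' @param trace A `gaze_trace` (or data.frame with time_s, x, y, pupil,
#'   valid).
#' @param hp_cutoff_hz High-pass cutoff for spike detection, Hz.
#' @param accel_thresh Pupil acceleration threshold (pupil units / s^2).
#' @param pad_s Neighborhood around detected spikes to invalidate, seconds.
#' @param seq Optional `bar_sequence` enabling per-pass drift correction.
#' @return data.frame of class `clean_gaze_trace` with no missing samples;
#'   `valid` marks samples that were neither blink nor spike.
#' @export
clean_gaze <- function(trace, hp_cutoff_hz = 10, accel_thresh = 1e5,
                       pad_s = 5, seq = NULL) {
  rate <- attr(trace, "rate_hz")
  if (is.null(rate)) rate <- 1 / median(diff(trace$time_s))
  .stop_if(all(!trace$valid | is.na(trace$x)), "trace entirely invalid")
  t <- trace$time_s
  dt <- 1 / rate
  x <- .interp_na(ifelse(trace$valid, trace$x, NA), t)
  y <- .interp_na(ifelse(trace$valid, trace$y, NA), t)
  pupil <- .interp_na(ifelse(trace$valid, trace$pupil, NA), t)

  hp <- if (hp_cutoff_hz < rate / 2) {
    bf <- signal::butter(2, hp_cutoff_hz / (rate / 2), type = "high")
    as.numeric(signal::filtfilt(bf, pupil))
  } else pupil - mean(pupil)
  n <- length(pupil)
  accel <- rep(0, n)
  if (n >= 3)
    accel[2:(n - 1)] <- (hp[3:n] - 2 * hp[2:(n - 1)] + hp[1:(n - 2)]) / dt^2
  spike <- abs(accel) > accel_thresh
  if (any(spike)) {
    pad <- round(pad_s * rate)
    bad <- unique(unlist(lapply(which(spike), function(i)
      max(1, i - pad):min(n, i + pad))))
    x[bad] <- y[bad] <- pupil[bad] <- NA_real_
    x <- .interp_na(x, t)
    y <- .interp_na(y, t)
    pupil <- .interp_na(pupil, t)
  } else bad <- integer(0)

  valid <- trace$valid
  valid[bad] <- FALSE
  if (!is.null(seq)) {
    fr <- seq$frames
    for (p in unique(fr$pass[!is.na(fr$pass)])) {
      tw <- range(fr$time_s[which(fr$pass == p & fr$frame_type == "bar")])
      ix <- which(t >= tw[1] & t < tw[2] + seq$dwell_s)
      if (length(ix)) {
        x[ix] <- x[ix] - median(x[ix])
        y[ix] <- y[ix] - median(y[ix])
      }
    }
  }
  structure(data.frame(time_s = t, x = x, y = y, pupil = pupil,
                       valid = valid),
            rate_hz = rate, n_spike_samples = length(bad),
            class = c("clean_gaze_trace", "data.frame"))
}

#' Summarize gaze along the bar traversal direction per bar position
#'
#' Rotates gaze into each pass's traversal frame (component along the
#' direction of bar movement) and returns, for every bar position, the
#' median and standard deviation across passes of the per-pass median
#' along-traversal gaze component.
#'
#' @param trace A `clean_gaze_trace` (or gaze_trace without gaps).
#' @param seq The `bar_sequence` the trace was recorded under.
#' @return data.frame with position_index (0-based), median_along,
#'   sd_along, n_passes.
#' @export
gaze_summary_by_bar_position <- function(trace, seq) {
  .stop_if(max(trace$time_s) + 1e-9 <
             max(seq$frames$time_s[seq$frames$frame_type == "bar"]),
           "trace does not cover the bar sequence")
  fr <- seq$frames[seq$frames$frame_type == "bar", ]
  per_pass <- matrix(NA_real_, seq$n_passes, seq$n_positions)
  for (p in seq_len(seq$n_passes)) {
    rows <- fr[fr$pass == p, ]
    th <- rows$direction_deg[1] * pi / 180
    along <- trace$x * cos(th) + trace$y * sin(th)
    for (i in seq_len(nrow(rows))) {
      ix <- which(trace$time_s >= rows$time_s[i] &
                    trace$time_s < rows$time_s[i] + seq$dwell_s)
      if (length(ix))
        per_pass[p, rows$position_index[i] + 1L] <- median(along[ix])
    }
  }
  data.frame(position_index = seq_len(seq$n_positions) - 1L,
             median_along = apply(per_pass, 2, median, na.rm = TRUE),
             sd_along = apply(per_pass, 2, sd, na.rm = TRUE),
             n_passes = colSums(!is.na(per_pass)))
}

#' Write / read a gaze trace as TSV
#' @param trace A gaze trace data.frame.
#' @param path File path.
#' @export
write_gaze_trace <- function(trace, path) {
  write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_trace
#' @param rate_hz Sampling rate to attach on read; NULL infers from time_s.
#' @export
read_gaze_trace <- function(path, rate_hz = NULL) {
  d <- read.delim(path)
  if (is.null(rate_hz)) rate_hz <- 1 / median(diff(d$time_s))
  structure(d, rate_hz = rate_hz, class = c("gaze_trace", "data.frame"))
}
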