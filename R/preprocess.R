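# BOLD preprocessing: Savitzky-Golay detrending and percent signal change.

#' Savitzky-Golay detrending of a BOLD time series
#'
#' Estimates slow drift with a polynomial smoothing (Savitzky-Golay) filter
#' and subtracts it, re-adding the series mean. Even window lengths (in
#' samples) are rounded up to the next odd count; edges are handled by the
#' filter's built-in polynomial fits on truncated windows.
#'
#' @param ts Numeric time series.
#' @param tr_s Sampling interval, seconds.
#' @param window_s Filter window length, seconds (default 120).
#' @param order Polynomial order (default 3).
#' @return Detrended series with the original mean.
#' @export
savgol_detrend <- function(ts, tr_s, window_s = 120, order = 3) {
  n_w <- round(window_s / tr_s)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  n_w <- max(n_w, order + 2 + (order %% 2 == 1))   # odd and >= order + 2
  if (n_w %% 2 == 0) n_w <- n_w + 1
  .stop_if(n_w > length(ts), "window longer than the series")
  trend <- signal::sgolayfilt(ts, p = order, n = n_w)
  ts - trend + mean(ts)
}

#' Percent signal change
#'
#' 100 * (ts - mean) / mean, per run.
#'
#' @param ts Numeric time series with non-zero mean.
#' @return Series in percent-signal-change units.
#' @export
percent_signal_change <- function(ts) {
  m <- mean(ts)
  .stop_if(m == 0, "run mean is zero")
  100 * (ts - m) / m
}
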