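# Automatic A3 Threshold algorithms.
#
# Two generations are modeled:
#  * "Auto"  — per-cycle adaptive emulation of the first-generation rule: the
#    exact proprietary law is unpublished, so the simplest rule that
#    reproduces its documented failure mode is used (track the recent
#    A3-window maximum plus a margin). Sustained high-rate episodes, during
#    which the A3 window holds the summated A7 signal, drive the threshold
#    up until A7 undersensing occurs.
#  * "Auto+" — second generation: only cycles carrying an *isolated* A3 (no
#    A7) feed a 0.1 m/s^2-binned amplitude histogram; once per "day" the
#    nearest-rank 95th percentile plus a programmable margin becomes the new
#    threshold, which then stays constant until the next daily update.

#' A3 amplitude histogram (0 to 10 m/s^2, 0.1-wide bins)
#'
#' @param counts Optional integer vector of length 100 (per-bin counts).
#' @return Object of class `avs_a3_histogram` with `breaks` (bin edges),
#'   `counts` and `total`.
#' @export
a3_histogram <- function(counts = integer(100)) {
  if (length(counts) != 100L || any(counts < 0)) {
    stop_invalid("counts must be 100 non-negative bin counts")
  }
  structure(list(breaks = seq(0, 10, by = 0.1), counts = as.numeric(counts),
                 total = sum(counts)),
            class = "avs_a3_histogram")
}

# Bin index for an amplitude: value v falls in bin (0.1*(i-1), 0.1*i];
# amplitudes above the range are clipped to the top bin.
a3_bin_index <- function(x) {
  i <- ceiling(x / 0.1)
  pmin(pmax(i, 1L), 100L)
}

#' Accumulate one cycle into the daily A3 histogram
#'
#' The cycle's A3-window maximum is binned only when the cycle qualifies as
#' carrying an isolated A3: the beat is not ectopic, and either the AM fell
#' at least 40 ms after the A3 Window End (the A4 was outside the window) or
#' the instantaneous atrial rate was below 80 bpm. Amplitudes above the
#' histogram range are clipped into the top bin (with a warning).
#'
#' @param hist An [a3_histogram()].
#' @param cycle_summary List (or one-row data frame) with `a3win_max`,
#'   `am_ms` (AM time relative to the cycle origin, NA if none), `wend_ms`,
#'   `rate_bpm` (NA treated as slow) and `ectopic`.
#' @param config An [device_config()] (reserved for guard parameters).
#' @return The updated histogram.
#' @export
av2_accumulate <- function(hist, cycle_summary, config = device_config()) {
  stopifnot(inherits(hist, "avs_a3_histogram"))
  cs <- cycle_summary
  rate_slow <- is.na(cs$rate_bpm) || cs$rate_bpm < 80
  am_late <- !is.na(cs$am_ms) && cs$am_ms > cs$wend_ms + 40
  qualifies <- !isTRUE(cs$ectopic) && (am_late || rate_slow)
  if (!qualifies) return(hist)
  if (cs$a3win_max > 10) {
    warning("A3 amplitude above histogram range; clipped to top bin")
  }
  i <- a3_bin_index(cs$a3win_max)
  hist$counts[i] <- hist$counts[i] + 1
  hist$total <- hist$total + 1
  hist
}

# Nearest-rank percentile of the accumulated amplitudes; each stored value is
# represented by its bin's upper edge.
histogram_percentile <- function(hist, p = 0.95) {
  stopifnot(inherits(hist, "avs_a3_histogram"))
  if (hist$total <= 0) return(NA_real_)
  rank <- ceiling(p * hist$total)
  i <- which(cumsum(hist$counts) >= rank)[1]
  hist$breaks[i + 1L]
}

#' Daily A3 Threshold update from the amplitude histogram
#'
#' Threshold = nearest-rank 95th percentile of the accumulated isolated-A3
#' amplitudes plus the programmable amplitude margin; the histogram is reset
#' for the next day. An empty histogram yields no update (threshold `NA`;
#' callers retain the previous value).
#'
#' @param hist An [a3_histogram()].
#' @param margin Amplitude margin in m/s^2 (nominal 1.0).
#' @return List with `threshold` (m/s^2 or `NA`), `daily_a3` (the 95th
#'   percentile), and `histogram` (reset).
#' @export
av2_daily_update <- function(hist, margin = 1.0) {
  stopifnot(inherits(hist, "avs_a3_histogram"))
  chk_num(margin, "margin", min = 0)
  p95 <- histogram_percentile(hist, 0.95)
  list(threshold = if (is.na(p95)) NA_real_ else p95 + margin,
       daily_a3 = p95, histogram = a3_histogram())
}

#' State of the per-cycle adaptive ("Auto") A3 threshold emulation
#'
#' @param threshold Current threshold in m/s^2.
#' @return Object of class `avs_auto_state` with the recent A3-window-maxima
#'   buffer, a cycle counter and the current threshold.
#' @export
auto_state <- function(threshold = 2.5) {
  structure(list(buffer = numeric(0), cycles = 0L, threshold = threshold),
            class = "avs_auto_state")
}

#' One cycle of the per-cycle adaptive threshold emulation
#'
#' Appends the cycle's A3-window maximum to an 8-cycle buffer; every
#' `auto_update_cycles` cycles the threshold becomes
#' `clamp(max(buffer) + auto_margin, a4_threshold + auto_margin, auto_max)`
#' and the buffer restarts. Because the buffered value is the *window*
#' maximum, sustained A7-contaminated windows ratchet the threshold up —
#' the documented failure mode of the first-generation algorithm.
#'
#' @param state An [auto_state()].
#' @param cycle_a3_max A3-window maximum of the cycle, m/s^2 (>= 0).
#' @param config An [device_config()] supplying `a4_threshold`,
#'   `auto_update_cycles`, `auto_margin`, `auto_max`.
#' @return Updated `avs_auto_state`.
#' @export
auto_av_update <- function(state, cycle_a3_max, config = device_config()) {
  stopifnot(inherits(state, "avs_auto_state"))
  if (cycle_a3_max < 0) stop_invalid("cycle_a3_max must be >= 0")
  state$buffer <- c(state$buffer, cycle_a3_max)
  state$cycles <- state$cycles + 1L
  if (length(state$buffer) >= config$auto_update_cycles) {
    thr <- max(state$buffer) + config$auto_margin
    thr <- min(max(thr, config$a4_threshold + config$auto_margin),
               config$auto_max)
    state$threshold <- thr
    state$buffer <- numeric(0)
  }
  state
}

#' Extract the A3-threshold trajectory of a session
#'
#' @param log An `avs_event_log` from [run_session()].
#' @return Data frame `time_ms`, `algo`, `threshold` (one row per cycle),
#'   suitable for CSV export and threshold-drift plots.
#' @export
threshold_trajectory <- function(log) {
  stopifnot(inherits(log, "avs_event_log"))
  data.frame(time_ms = log$cycles$v_ms, algo = log$threshold_algo,
             threshold = log$cycles$a3_threshold)
}
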