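# Device sensing/pacing state machine.
#
# Cycle origin t = 0 is the ventricular event (VP/VS). Within a cycle:
#   [0, pvab)            post-ventricular atrial blanking: no atrial sensing
#   [pvab, wend)         A3 window: first rectified sample >= A3 Threshold -> AM
#   [wend, next V)       A4 window: first rectified sample >= A4 Threshold -> AM
# VE is emitted at the A3 Window End (wend). In VDD the AM is tracked with a
# ventricular pace AM + am_to_vp_delay later, delayed to the upper-tracking-
# rate boundary if needed; with no AM the lower-rate timeout paces. In VDI
# AMs are recorded but never tracked. One AM per cycle (no re-arming).
#
# Two engines share this logic: a dense engine scanning fully synthesized
# 1 kHz traces (validation) and an analytic event-level engine that evaluates
# the wavelet sum only where component supports intersect the sensing
# windows (long sessions).

#' Device configuration
#'
#' @param mode `"VDD"` (atrial-tracked ventricular pacing) or `"VDI"`.
#' @param pvab_ms Post-ventricular atrial blanking, ms (nominal 550).
#' @param upper_tracking_rate_bpm Maximum tracked rate (nominal 105).
#' @param lower_rate_bpm Lower (timeout) pacing rate (default 50).
#' @param a3_threshold Initial A3 Threshold, m/s^2 (default 2.5).
#' @param a4_threshold A4 Threshold, m/s^2 (default 1.5; must not exceed the
#'   A3 Threshold).
#' @param a3_window_end_min_ms,a3_window_end_max_ms Rate-adaptive A3 Window
#'   End bounds on the 25 ms programming grid (defaults 775 / 900).
#' @param am_to_vp_delay_ms AM-to-VP tracking delay, ms (default 20).
#' @param a3_amplitude_margin Margin added by the daily A3 threshold update,
#'   m/s^2 (nominal 1.0).
#' @param sampling_rate_hz Trace sampling rate (default 1000).
#' @param day_length_min Simulated "day" between daily threshold updates
#'   (default 1440 min; desk-scale runs compress it).
#' @param auto_update_cycles,auto_margin,auto_max Per-cycle adaptive ("Auto")
#'   algorithm knobs: update cadence in cycles, margin above the recent
#'   maximum, and upper clamp (defaults 8, 0.5, 6.0) — a behavioral emulation
#'   of the first-generation adaptive threshold.
#' @return Object of class `avs_device_config`.
#' @export
device_config <- function(mode = c("VDD", "VDI"), pvab_ms = 550,
                          upper_tracking_rate_bpm = 105, lower_rate_bpm = 50,
                          a3_threshold = 2.5, a4_threshold = 1.5,
                          a3_window_end_min_ms = 775,
                          a3_window_end_max_ms = 900,
                          am_to_vp_delay_ms = 20, a3_amplitude_margin = 1.0,
                          sampling_rate_hz = 1000, day_length_min = 1440,
                          auto_update_cycles = 8, auto_margin = 0.5,
                          auto_max = 6.0) {
  mode <- match.arg(mode)
  chk_num(pvab_ms, "pvab_ms", min = 0)
  chk_num(a3_threshold, "a3_threshold", min = 1e-9)
  chk_num(a4_threshold, "a4_threshold", min = 1e-9)
  chk_num(a3_amplitude_margin, "a3_amplitude_margin", min = 0)
  if (a4_threshold > a3_threshold) {
    stop_invalid("a4_threshold (%g) must not exceed a3_threshold (%g)",
                 a4_threshold, a3_threshold)
  }
  if (!(pvab_ms < a3_window_end_min_ms &&
        a3_window_end_min_ms <= a3_window_end_max_ms)) {
    stop_invalid("need pvab < a3_window_end_min <= a3_window_end_max")
  }
  if (a3_window_end_min_ms %% 25 != 0 || a3_window_end_max_ms %% 25 != 0) {
    stop_invalid("A3 Window End values must lie on the 25 ms grid")
  }
  if (upper_tracking_rate_bpm <= lower_rate_bpm) {
    stop_invalid("upper tracking rate must exceed the lower rate")
  }
  structure(
    list(mode = mode, pvab_ms = pvab_ms,
         upper_tracking_rate_bpm = upper_tracking_rate_bpm,
         lower_rate_bpm = lower_rate_bpm,
         a3_threshold = a3_threshold, a4_threshold = a4_threshold,
         a3_window_end_min_ms = a3_window_end_min_ms,
         a3_window_end_max_ms = a3_window_end_max_ms,
         am_to_vp_delay_ms = am_to_vp_delay_ms,
         a3_amplitude_margin = a3_amplitude_margin,
         sampling_rate_hz = sampling_rate_hz,
         day_length_min = day_length_min,
         auto_update_cycles = auto_update_cycles,
         auto_margin = auto_margin, auto_max = auto_max),
    class = "avs_device_config"
  )
}

#' Rate-adaptive A3 Window End
#'
#' Clamped linear interpolation between the programmed bounds: the maximum
#' for cycle lengths >= 1000 ms, the minimum for <= 667 ms, linear in
#' between, snapped to the 25 ms programming grid.
#'
#' @param config An [device_config()].
#' @param current_rr_ms Previous V-V interval in ms.
#' @return A3 Window End in ms.
#' @export
a3_window_end_for_rate <- function(config, current_rr_ms) {
  chk_num(current_rr_ms, "current_rr_ms", min = 1e-9)
  lo <- config$a3_window_end_min_ms; hi <- config$a3_window_end_max_ms
  if (current_rr_ms >= 1000) return(hi)
  if (current_rr_ms <= 667) return(lo)
  snap25_nearest(lo + (current_rr_ms - 667) / (1000 - 667) * (hi - lo))
}

# --- analytic signal evaluation --------------------------------------------

# Rectified wavelet-sum values on the integer-ms grid [lo, hi), restricted to
# where component supports lie (zero elsewhere, which no threshold > 0 can
# cross). amps/tps are parallel vectors of peak amplitude and peak time.
eval_rect_grid <- function(amps, tps, f, lo, hi) {
  hw <- ricker_halfwidth_ms(f)
  keep <- which(tps + hw > lo & tps - hw < hi)
  if (!length(keep)) return(NULL)
  glo <- max(lo, floor(min(tps[keep]) - hw))
  ghi <- min(hi, ceiling(max(tps[keep]) + hw) + 1)
  if (ghi <= glo) return(NULL)
  t <- seq.int(ceiling(glo), ghi - 1)
  raw <- numeric(length(t))
  for (i in keep) {
    d <- t - tps[i]
    idx <- which(d >= -hw & d <= hw)
    if (length(idx)) {
      u <- (pi * f * d[idx] / 1000)^2
      raw[idx] <- raw[idx] + amps[i] * (1 - 2 * u) * exp(-u)
    }
  }
  list(t = t, rect = abs(raw))
}

# First grid time where the rectified sum crosses thr in [lo, hi); NA if none.
first_crossing <- function(amps, tps, f, lo, hi, thr) {
  g <- eval_rect_grid(amps, tps, f, lo, hi)
  if (is.null(g)) return(NA_real_)
  i <- which(g$rect >= thr)
  if (!length(i)) NA_real_ else g$t[i[1]]
}

# Max of the rectified sum in [lo, hi) (0 when no support intersects).
window_max <- function(amps, tps, f, lo, hi) {
  g <- eval_rect_grid(amps, tps, f, lo, hi)
  if (is.null(g)) 0 else max(g$rect)
}

# Last grid time in [lo, hi) where the rectified sum is >= thr, with
# [mask_from, Inf) removed (used by Atrial Sensing Setup phase 2 to exclude
# detected-A4 support); NA if none.
last_exceedance <- function(amps, tps, f, lo, hi, thr, mask_from = Inf) {
  g <- eval_rect_grid(amps, tps, f, lo, hi)
  if (is.null(g)) return(NA_real_)
  ok <- g$rect >= thr & g$t < mask_from
  if (!any(ok)) NA_real_ else g$t[max(which(ok))]
}

# --- single-cycle dense engine ---------------------------------------------

# Shared scan of a rectified sample vector. Returns AM time (NA), the window
# it fired in, and the A3-window max.
scan_windows <- function(time_ms, rect, pvab, wend, horizon, thr3, thr4) {
  in3 <- time_ms >= pvab & time_ms < wend
  in4 <- time_ms >= wend & time_ms < horizon
  max3 <- if (any(in3)) max(rect[in3]) else 0
  am <- NA_real_; am_win <- NA_character_
  i3 <- which(in3 & rect >= thr3)
  if (length(i3)) {
    am <- time_ms[i3[1]]; am_win <- "A3"
  } else {
    i4 <- which(in4 & rect >= thr4)
    if (length(i4)) { am <- time_ms[i4[1]]; am_win <- "A4" }
  }
  list(am_ms = am, am_window = am_win, a3win_max = max3)
}

#' Run the sensing state machine over one synthesized cycle
#'
#' Dense-trace engine: scans a [synthesize_beat()] trace sample by sample
#' with the configured thresholds and timing cycles, and emits the cycle's
#' markers.
#'
#' @param config An [device_config()].
#' @param state Optional list carrying `last_vv_ms` (previous V-V interval,
#'   used for the rate-adaptive window end; defaults to the lower-rate
#'   interval), `a3_threshold` (overrides the configured threshold, e.g. from
#'   an adaptation algorithm) and `cycle_index`.
#' @param trace An `avs_beat_trace` spanning at least the lower-rate
#'   interval.
#' @param p_onset_ms P-wave onset in ms from the cycle origin, or `NULL`
#'   (recorded as a P marker only; detection works off the trace).
#' @return List with `markers` (data frame: `time_ms`, `kind`, `cycle`,
#'   `annotation`), `state` (updated), and `summary` (one-row data frame with
#'   the A3-window max, AM time, window end and active thresholds).
#' @export
run_cycle <- function(config, state = list(), trace, p_onset_ms = NULL) {
  stopifnot(inherits(config, "avs_device_config"),
            inherits(trace, "avs_beat_trace"))
  lri <- 60000 / config$lower_rate_bpm
  utr <- 60000 / config$upper_tracking_rate_bpm
  if (max(trace$time_ms) + trace$sample_period_ms < lri) {
    stop_invalid("trace (%g ms) shorter than the lower-rate interval (%g ms)",
                 max(trace$time_ms) + trace$sample_period_ms, lri)
  }
  last_vv <- if (!is.null(state$last_vv_ms)) state$last_vv_ms else lri
  thr3 <- if (!is.null(state$a3_threshold)) state$a3_threshold else config$a3_threshold
  cyc <- if (!is.null(state$cycle_index)) state$cycle_index else 1L
  wend <- a3_window_end_for_rate(config, last_vv)

  sc <- scan_windows(trace$time_ms, trace$samples, config$pvab_ms, wend, lri,
                     thr3, config$a4_threshold)
  vp <- if (config$mode == "VDD" && !is.na(sc$am_ms)) {
    min(max(sc$am_ms + config$am_to_vp_delay_ms, utr), lri)
  } else lri

  mk <- data.frame(time_ms = numeric(0), kind = character(0),
                   cycle = integer(0), annotation = character(0))
  add <- function(mk, t, kind, ann = "") {
    rbind(mk, data.frame(time_ms = t, kind = kind, cycle = cyc, annotation = ann))
  }
  if (!is.null(p_onset_ms)) mk <- add(mk, p_onset_ms, "P")
  if (!is.na(sc$am_ms)) {
    mk <- add(mk, sc$am_ms, "AM", sprintf("window=%s", sc$am_window))
  }
  mk <- add(mk, wend, "VE")
  mk <- add(mk, vp, "VP")
  mk <- mk[order(mk$time_ms), , drop = FALSE]
  row.names(mk) <- NULL

  list(markers = mk,
       state = list(last_vv_ms = vp, a3_threshold = thr3,
                    cycle_index = cyc + 1L),
       summary = data.frame(cycle = cyc, wend_ms = wend,
                            a3win_max = sc$a3win_max, am_ms = sc$am_ms,
                            am_window = if (is.na(sc$am_ms)) NA_character_ else sc$am_window,
                            a3_threshold = thr3,
                            a4_threshold = config$a4_threshold, vp_ms = vp))
}

# --- session engine --------------------------------------------------------

# Build the per-cycle component vectors (amps, tps) for the analytic engine.
# a4_s4: vector of A4 start times relative to the cycle origin.
cycle_components <- function(a3_amp, a4_amps, a4_s4, timing, e3) {
  on <- ricker_onset_ms(timing$f_hz)
  amps <- c(3.0, 2.0, a3_amp, a4_amps)     # A1/A2 fixed (inside PVAB)
  tps <- c(50, timing$a2_delay_ms + on, e3 - on, a4_s4 + on)
  list(amps = amps, tps = tps)
}

#' Simulate a full pacing session over a beat schedule
#'
#' Processes cardiac cycles in order through the sensing/pacing state
#' machine, optionally consulting an automatic A3-threshold algorithm
#' between cycles, and returns the marker stream plus per-cycle summaries.
#'
#' @param config An [device_config()].
#' @param schedule An `avs_beat_schedule` from [generate_session()].
#' @param threshold_algo `"none"` (fixed threshold), `"auto"` (per-cycle
#'   adaptive emulation, see [auto_av_update()]) or `"autoplus"`
#'   (daily-histogram algorithm, see [av2_daily_update()]).
#' @param seed Seed for the A3-end jitter stream (default: schedule's script
#'   seed offset; `NULL` uses the current RNG).
#' @param engine `"event"` (analytic, default) or `"dense"` (synthesizes and
#'   scans a 1 kHz trace per cycle; slow, for validation).
#' @return Object of class `avs_event_log`: list with `markers` (data frame
#'   `time_ms`, `kind` in \{P, AM, VE, VP, VS\}, `cycle`, `annotation`),
#'   `cycles` (per-cycle summary: A3-window max, AM time, window end, active
#'   A3 threshold, atrial rate, A7/ectopy flags) and `config`.
#' @export
run_session <- function(config, schedule, threshold_algo = c("none", "auto", "autoplus"),
                        seed = NULL, engine = c("event", "dense")) {
  stopifnot(inherits(config, "avs_device_config"),
            inherits(schedule, "avs_beat_schedule"))
  threshold_algo <- match.arg(threshold_algo)
  engine <- match.arg(engine)
  if (nrow(schedule) == 0L) stop_invalid("schedule is empty")
  timing <- attr(schedule, "timing")
  dur <- attr(schedule, "duration_ms")
  if (is.null(dur)) dur <- max(schedule$t_p_ms, schedule$t_v_ms, na.rm = TRUE)

  lri <- 60000 / config$lower_rate_bpm
  utr <- 60000 / config$upper_tracking_rate_bpm
  pvab <- config$pvab_ms
  f <- timing$f_hz
  a4d <- timing$a4_delay_ms
  hw <- ricker_halfwidth_ms(f)
  sup <- 2 * hw

  p_rows <- which(!is.na(schedule$t_p_ms))
  p_t <- schedule$t_p_ms[p_rows]
  p_a4 <- schedule$a4_amp[p_rows]
  p_cls <- schedule$class[p_rows]
  # instantaneous atrial rate preceding each P
  p_rate <- c(NA_real_, 60000 / diff(p_t))
  pvc_t <- sort(schedule$t_v_ms[!is.na(schedule$t_v_ms)])
  all_amp_t <- ifelse(is.na(schedule$t_p_ms), schedule$t_v_ms, schedule$t_p_ms)

  n_max <- as.integer(ceiling(dur / utr) + 4L)
  np <- length(p_t)
  na_amp <- length(all_amp_t)
  n_pvc <- length(pvc_t)

  S <- with_seed(seed, {
    Sv <- numeric(n_max); Swend <- numeric(n_max); Smax3 <- numeric(n_max)
    Sam <- rep(NA_real_, n_max); Samw <- rep(NA_character_, n_max)
    Sthr3 <- numeric(n_max); Srate <- rep(NA_real_, n_max)
    Sa7 <- logical(n_max); Sect <- logical(n_max)
    Svkind <- character(n_max); Sve <- numeric(n_max)

    thr3 <- config$a3_threshold
    astate <- auto_state(threshold = thr3)
    hist <- a3_histogram()
    day_ms <- config$day_length_min * 60000
    next_day <- day_ms

    v <- 0; last_vv <- lri
    pp <- 1L; ap <- 1L; pvp <- 1L
    k <- 0L
    while (v < dur && k < n_max) {
      k <- k + 1L
      # daily histogram update at day boundaries
      if (threshold_algo == "autoplus" && v >= next_day) {
        upd <- av2_daily_update(hist, config$a3_amplitude_margin)
        if (!is.na(upd$threshold)) {
          thr3 <- max(upd$threshold, config$a4_threshold + 0.1)
        }
        hist <- upd$histogram
        next_day <- next_day + day_ms
      }
      wend <- a3_window_end_for_rate(config, last_vv)
      # A3 amplitude for this cycle: the upcoming beat's draw
      while (ap < na_amp && all_amp_t[ap] <= v) ap <- ap + 1L
      a3_amp <- schedule$a3_amp[ap]
      e3 <- effective_a3_end(timing, last_vv)
      # A4 components whose support intersects this cycle's sensing span
      while (pp <= np && p_t[pp] + a4d + sup <= v) pp <- pp + 1L
      jj <- integer(0); j <- pp
      while (j <= np && p_t[j] + a4d - v < lri) {
        if (p_t[j] + a4d + sup - v > pvab) jj <- c(jj, j)
        j <- j + 1L
      }
      s4 <- p_t[jj] + a4d - v
      comps <- cycle_components(a3_amp, p_a4[jj], s4, timing, e3)

      if (engine == "event") {
        am <- first_crossing(comps$amps, comps$tps, f, pvab, wend, thr3)
        max3 <- window_max(comps$amps, comps$tps, f, pvab, wend)
        amw <- "A3"
        if (is.na(am)) {
          am <- first_crossing(comps$amps, comps$tps, f, wend, lri,
                               config$a4_threshold)
          amw <- "A4"
        }
      } else {
        g <- dense_cycle_trace(comps, timing, lri, config$sampling_rate_hz)
        sc <- scan_windows(g$t, g$rect, pvab, wend, lri, thr3,
                           config$a4_threshold)
        am <- sc$am_ms; amw <- sc$am_window; max3 <- sc$a3win_max
      }
      if (is.na(am)) amw <- NA_character_

      vp_rel <- if (config$mode == "VDD" && !is.na(am)) {
        min(max(am + config$am_to_vp_delay_ms, utr), lri)
      } else lri
      # a PVC ventricular ectopic pre-empts the scheduled pace
      while (pvp <= n_pvc && pvc_t[pvp] <= v) pvp <- pvp + 1L
      vkind <- "VP"; v_next <- v + vp_rel
      if (pvp <= n_pvc && pvc_t[pvp] < v_next) {
        v_next <- pvc_t[pvp]; vkind <- "VS"; pvp <- pvp + 1L
      }

      rate <- if (length(jj)) p_rate[jj[1]] else NA_real_
      ect <- vkind == "VS" || (length(jj) > 0 && any(p_cls[jj] == "PAC"))
      Sv[k] <- v; Swend[k] <- wend; Smax3[k] <- max3
      Sam[k] <- if (is.na(am)) NA_real_ else v + am
      Samw[k] <- amw; Sthr3[k] <- thr3; Srate[k] <- rate
      Sa7[k] <- length(s4) > 0 && any(s4 < e3)
      Sect[k] <- isTRUE(ect); Svkind[k] <- vkind; Sve[k] <- v + wend

      # threshold adaptation
      if (threshold_algo == "auto") {
        astate <- auto_av_update(astate, max3, config)
        thr3 <- astate$threshold
      } else if (threshold_algo == "autoplus") {
        hist <- av2_accumulate(
          hist,
          list(a3win_max = max3, am_ms = if (is.na(am)) NA_real_ else am,
               wend_ms = wend, rate_bpm = rate, ectopic = ect),
          config)
      }
      last_vv <- v_next - v
      v <- v_next
    }
    list(v = Sv, wend = Swend, max3 = Smax3, am = Sam, amw = Samw,
         thr3 = Sthr3, rate = Srate, a7 = Sa7, ect = Sect, vkind = Svkind,
         ve = Sve, k = k)
  })

  idx <- seq_len(S$k)
  cycles <- data.frame(cycle = idx, v_ms = S$v[idx], wend_ms = S$wend[idx],
                       a3win_max = S$max3[idx], am_ms = S$am[idx],
                       am_window = S$amw[idx], a3_threshold = S$thr3[idx],
                       rate_bpm = S$rate[idx], a7 = S$a7[idx],
                       ectopic = S$ect[idx], v_kind = S$vkind[idx],
                       ve_ms = S$ve[idx])
  markers <- rbind(
    data.frame(time_ms = cycles$v_ms, kind = cycles$v_kind,
               cycle = cycles$cycle, annotation = ""),
    data.frame(time_ms = cycles$ve_ms, kind = "VE", cycle = cycles$cycle,
               annotation = ""),
    data.frame(time_ms = cycles$am_ms[!is.na(cycles$am_ms)], kind = "AM",
               cycle = cycles$cycle[!is.na(cycles$am_ms)],
               annotation = sprintf("window=%s",
                                    cycles$am_window[!is.na(cycles$am_ms)])),
    data.frame(time_ms = p_t, kind = "P",
               cycle = findInterval(p_t, cycles$v_ms),
               annotation = p_cls)
  )
  markers <- markers[order(markers$time_ms, match(markers$kind, c("VS", "VP", "P", "AM", "VE"))), ]
  row.names(markers) <- NULL

  structure(list(markers = markers, cycles = cycles, config = config,
                 threshold_algo = threshold_algo),
            class = "avs_event_log")
}

# Dense per-cycle trace for the validation engine: synthesize the wavelet
# sum on the full sampling grid and rectify.
dense_cycle_trace <- function(comps, timing, duration_ms, sampling_rate_hz) {
  sp <- 1000 / sampling_rate_hz
  t <- seq(0, duration_ms - sp, by = sp)
  raw <- numeric(length(t))
  hw <- ricker_halfwidth_ms(timing$f_hz)
  for (i in seq_along(comps$amps)) {
    d <- t - comps$tps[i]
    idx <- which(d >= -hw & d <= hw)
    if (length(idx)) {
      raw[idx] <- raw[idx] +
        comps$amps[i] * ricker(d[idx], timing$f_hz)
    }
  }
  list(t = t, rect = abs(raw))
}

#' Write an event log's markers to CSV
#'
#' @param log An `avs_event_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "avs_event_log"))
  utils::write.csv(log$markers, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.avs_event_log <- function(x, ...) {
  cat(sprintf("<avs_event_log> %d cycles, %d markers, algo=%s, mode=%s\n",
              nrow(x$cycles), nrow(x$markers), x$threshold_algo,
              x$config$mode))
  invisible(x)
}
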