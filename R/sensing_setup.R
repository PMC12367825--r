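# Three-phase Atrial Sensing Setup.
#
# A ~24-min test run primarily in VDI mode (pacing at the lower rate while
# the sinus node runs free, so the A4 sweeps across the cycle):
#   phase 1 (default 20 min): per-vector-combination data collection. The
#     two-vector combination with the largest median A4 is chosen (1+2+3 if
#     none is large); the A3 Threshold is finalized and the A3 Window End
#     and A4 Threshold are initialized. The provisional window end is meant
#     to be generous: the observed A3 end uses a 0.5 m/s^2 perceptibility
#     floor (below the smallest programmable threshold).
#   phase 2 (default 2 min): the A3 Window End is adjusted from the time of
#     the last signal "close in amplitude" to the phase A4 Threshold,
#     implemented as the last time the rectified signal is within a 0.25
#     m/s^2 band below the threshold or above it (a decaying wavelet leaves
#     the band just after crossing thr - 0.25). The first-generation (AV)
#     device fixes that threshold at 1.2 m/s^2 — a small threshold that
#     tends to extend the window; the second generation (AV2) uses the
#     phase-1-initialized A4 Threshold, yielding shorter windows.
#   phase 3 (default 2 min): the A4 Threshold is finalized from the median
#     post-window A4 amplitude (identical in both variants).
#
# Variant differences: AV finalizes the A3 Threshold as the maximum observed
# A3-window amplitude + margin (contaminated by A7 at high rates or by A4
# sweeping through the window in VDI); AV2 uses the 95th percentile of
# isolated-A3 amplitudes + margin.

# Internal: simulate VDI cycles for one setup phase and collect per-cycle
# measurements. The sinus P clock runs free of the paced V. Ectopy is not
# modeled during setup (a resting test). Returns a data frame.
simulate_setup_phase <- function(script, config, duration_min, combo_seq,
                                 thr3, thr4, wend_ms, probe_thr = NULL,
                                 meas_thr = thr4) {
  timing <- script$timing
  f <- timing$f_hz
  a4d <- timing$a4_delay_ms
  on <- ricker_onset_ms(f)
  hw <- ricker_halfwidth_ms(f)
  pvab <- config$pvab_ms
  lri <- 60000 / config$lower_rate_bpm
  dur <- duration_min * 60000
  rest_rr <- script$hourly_interval_ms[1]
  n_cyc <- as.integer(ceiling(dur / lri))
  # Measurement scans stop at the programmable window-end ceiling (1100 ms)
  # plus one grid step: signal beyond it can never move a window end, and a
  # following cycle's A4 rising over the pace would otherwise leak in.
  hi_meas <- min(lri, 1125)

  # free-running sinus P train over the phase
  n_p <- as.integer(ceiling(dur / (rest_rr * 0.95))) + 3L
  p_t <- cumsum(modulate_interval(rest_rr, script$interval_variability, n_p))

  combo <- character(n_cyc); max3 <- numeric(n_cyc)
  am <- rep(NA_real_, n_cyc); qual <- logical(n_cyc)
  a3_end_obs <- rep(NA_real_, n_cyc); last_ex <- rep(NA_real_, n_cyc)
  a4_obs <- rep(NA_real_, n_cyc)

  pp <- 1L
  for (k in seq_len(n_cyc)) {
    v <- (k - 1L) * lri
    cmb <- combo_seq[((k - 1L) %% length(combo_seq)) + 1L]
    dists <- script$combos[[cmb]]
    a3_amp <- draw_amplitude(dists$a3)
    e3 <- effective_a3_end(timing, lri)
    while (pp <= length(p_t) && p_t[pp] + a4d + 2 * hw <= v) pp <- pp + 1L
    jj <- integer(0); j <- pp
    while (j <= length(p_t) && p_t[j] + a4d - v < lri) {
      if (p_t[j] + a4d + 2 * hw - v > pvab) jj <- c(jj, j)
      j <- j + 1L
    }
    s4 <- p_t[jj] + a4d - v
    a4_amps <- if (length(jj)) draw_amplitude(dists$a4, length(jj)) else numeric(0)
    comps <- cycle_components(a3_amp, a4_amps, s4, timing, e3)

    am_k <- first_crossing(comps$amps, comps$tps, f, pvab, wend_ms, thr3)
    if (is.na(am_k)) {
      am_k <- first_crossing(comps$amps, comps$tps, f, wend_ms, lri, thr4)
    }
    mask <- if (is.na(am_k)) Inf else am_k - 60
    combo[k] <- cmb
    max3[k] <- window_max(comps$amps, comps$tps, f, pvab, wend_ms)
    am[k] <- am_k
    qual[k] <- is.na(am_k) || am_k > wend_ms + 40
    if (!is.null(probe_thr) && qual[k]) {
      a3_end_obs[k] <- last_exceedance(comps$amps, comps$tps, f, pvab,
                                       hi_meas, probe_thr, mask_from = mask)
    }
    last_ex[k] <- last_exceedance(comps$amps, comps$tps, f, pvab, hi_meas,
                                  meas_thr, mask_from = mask)
    if (!is.na(am_k) && am_k >= wend_ms) {
      a4_obs[k] <- window_max(comps$amps, comps$tps, f, wend_ms, lri)
    }
  }
  data.frame(cycle = seq_len(n_cyc), combo = combo, a3win_max = max3,
             am_ms = am, qualifies = qual, a3_end_obs_ms = a3_end_obs,
             last_exceed_ms = last_ex, a4_obs = a4_obs)
}

# Nearest-rank percentile of a plain numeric vector.
nearest_rank <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[max(1L, ceiling(p * length(x)))]
}

#' Phase 1: vector-combination selection and A3 Threshold finalization
#'
#' The two-vector combination with the largest median A4 among those whose
#' median reaches `large_a4` (1.5 m/s^2) is chosen; `1+2+3` is the fallback
#' when none qualifies; ties break to the lowest-index combination. The AV
#' variant finalizes the A3 Threshold as the maximum observed A3-window
#' amplitude plus the margin; the AV2 variant as the nearest-rank 95th
#' percentile of isolated-A3 amplitudes plus the margin. The A4 Threshold is
#' initialized at half the chosen combination's median A4 (floored at 1.0)
#' and the A3 Window End at the latest observed A3 end, snapped up to the
#' 25 ms grid.
#'
#' @param stats Named list over vector combinations; each element a data
#'   frame with columns `a3win_max`, `qualifies` (isolated-A3 flag),
#'   `a3_end_obs_ms`, `a4_obs` (as produced during the phase-1 collection).
#' @param variant `"AV"` or `"AV2"`.
#' @param config An [device_config()] (margin, PVAB for clamping).
#' @param large_a4 "Large A4" criterion on the median, m/s^2 (default 1.5).
#' @return List: `combo`, `a3_threshold`, `initial_window_end_ms`,
#'   `initial_a4_threshold`, `median_a4` (per combination).
#' @export
phase1_select_vector <- function(stats, variant = c("AV2", "AV"),
                                 config = device_config(), large_a4 = 1.5) {
  variant <- match.arg(variant)
  if (!length(stats) || !all(vapply(stats, nrow, 0L) > 0)) {
    stop_invalid("setup failure: empty phase-1 statistics")
  }
  two_vec <- intersect(c("1+2", "1+3", "2+3"), names(stats))
  med_a4 <- vapply(stats, function(d) stats::median(d$a4_obs, na.rm = TRUE),
                   0)
  cand <- two_vec[!is.na(med_a4[two_vec]) & med_a4[two_vec] >= large_a4]
  combo <- if (length(cand)) cand[which.max(med_a4[cand])] else "1+2+3"
  d <- stats[[combo]]
  if (nrow(d) < 60) {
    warning(sprintf("phase 1: only %d cycles for combination %s (expect >= 60)",
                    nrow(d), combo))
  }
  a3_thr <- if (variant == "AV") {
    max(d$a3win_max) + config$a3_amplitude_margin
  } else {
    iso <- d$a3win_max[d$qualifies]
    if (!length(iso)) stop_invalid("setup failure: no isolated-A3 cycles observed")
    nearest_rank(iso, 0.95) + config$a3_amplitude_margin
  }
  a4_init <- max(stats::median(d$a4_obs, na.rm = TRUE) / 2, 1.0)
  if (is.na(a4_init)) a4_init <- 1.0
  ends <- d$a3_end_obs_ms[!is.na(d$a3_end_obs_ms)]
  wend_init <- if (length(ends)) {
    min(max(snap25_up(max(ends)), config$pvab_ms + 50), 1100)
  } else config$pvab_ms + 150
  list(combo = combo, a3_threshold = a3_thr,
       initial_window_end_ms = wend_init,
       initial_a4_threshold = a4_init, median_a4 = med_a4)
}

#' Phase 2: A3 Window End adjustment
#'
#' The Max A3 Window End is the latest time (over cycles) at which the
#' rectified signal exceeded the phase A4 Threshold
#' (detected-A4 support excluded), snapped up to the 25 ms grid; the Min is
#' 100 ms below; both are clamped to `[pvab + 25, 1100]`. When no cycle
#' shows a supra-threshold A3 the flagged defaults
#' `(pvab + 50, pvab + 150)` are returned.
#'
#' @param vdi_cycle_summaries Data frame with column `last_exceed_ms`
#'   (per-cycle last exceedance time, NA when none).
#' @param phase_a4_threshold The phase A4 Threshold used for the measurement
#'   (AV: fixed 1.2; AV2: phase-1 initialized value).
#' @param variant `"AV"` or `"AV2"` (recorded; the rule is shared).
#' @param config An [device_config()].
#' @param quantile_rank Order statistic over per-cycle last-exceedance times
#'   (default 1 = the strict latest; lower values robustify against stray
#'   contamination).
#' @return List: `min_ms`, `max_ms`, `flagged`.
#' @export
phase2_window_end <- function(vdi_cycle_summaries, phase_a4_threshold,
                              variant = c("AV2", "AV"),
                              config = device_config(), quantile_rank = 1.0) {
  variant <- match.arg(variant)
  le <- vdi_cycle_summaries$last_exceed_ms
  le <- le[!is.na(le)]
  lo_clamp <- config$pvab_ms + 25
  if (!length(le)) {
    return(list(min_ms = config$pvab_ms + 50, max_ms = config$pvab_ms + 150,
                flagged = TRUE))
  }
  max_ms <- snap25_up(nearest_rank(le, quantile_rank))
  max_ms <- min(max(max_ms, lo_clamp), 1100)
  min_ms <- min(max(max_ms - 100, lo_clamp), 1100)
  list(min_ms = min_ms, max_ms = max_ms, flagged = FALSE)
}

#' Phase 3: A4 Threshold finalization
#'
#' Half the median post-window A4 amplitude, clamped to
#' `[0.8, a3_threshold - 0.2]`. Identical in both device variants.
#'
#' @param cycle_summaries Data frame with column `a4_obs` (per-cycle
#'   post-window A4 amplitude, NA when the A4 was not detected there).
#' @param window_end_ms The fine-tuned Max A3 Window End (recorded).
#' @param a3_threshold Finalized A3 Threshold (upper clamp anchor).
#' @param initial_a4_threshold Fallback when no A4 was observed (flagged).
#' @return List: `a4_threshold`, `flagged`.
#' @export
phase3_a4_threshold <- function(cycle_summaries, window_end_ms, a3_threshold,
                                initial_a4_threshold = 1.0) {
  a4 <- cycle_summaries$a4_obs
  a4 <- a4[!is.na(a4)]
  if (!length(a4)) {
    return(list(a4_threshold = initial_a4_threshold, flagged = TRUE))
  }
  thr <- stats::median(a4) / 2
  thr <- min(max(thr, 0.8), a3_threshold - 0.2)
  list(a4_threshold = thr, flagged = FALSE)
}

#' Run the full three-phase Atrial Sensing Setup
#'
#' @param variant `"AV"` (first generation) or `"AV2"` (second generation).
#' @param script A [patient_script()].
#' @param config Base [device_config()]; its mode is forced to VDI and its
#'   provisional thresholds are used during phase-1 data collection.
#' @param durations_min Phase durations in minutes (default `c(20, 2, 2)`).
#' @param seed Seed (default: the script seed).
#' @return Object of class `avs_setup_result`: `chosen_vector_combo`,
#'   `a3_threshold`, `a3_window_end_min_ms`, `a3_window_end_max_ms`,
#'   `a4_threshold`, `variant`, `diagnostics` (per-phase).
#' @export
run_setup <- function(variant = c("AV2", "AV"), script,
                      config = device_config(mode = "VDI"),
                      durations_min = c(20, 2, 2), seed = script$seed) {
  variant <- match.arg(variant)
  stopifnot(inherits(script, "avs_patient_script"))
  if (length(durations_min) != 3L || any(durations_min <= 0)) {
    stop_invalid("durations_min must be three positive phase lengths")
  }
  lri <- 60000 / config$lower_rate_bpm
  wend_prov <- a3_window_end_for_rate(config, lri)
  with_seed(seed, {
    # Phase 1: rotate the four combinations cycle-by-cycle.
    p1 <- simulate_setup_phase(script, config, durations_min[1],
                               combo_seq = VECTOR_COMBOS,
                               thr3 = config$a3_threshold,
                               thr4 = config$a4_threshold,
                               wend_ms = wend_prov, probe_thr = 0.5)
    stats <- split(p1, p1$combo)
    sel <- phase1_select_vector(stats, variant, config)

    # Phase 2: chosen combination, finalized A3 Threshold, phase A4
    # Threshold per variant; the "close in amplitude" measurement accepts
    # signal from 0.25 m/s^2 below the phase threshold.
    phase_a4 <- if (variant == "AV") 1.2 else sel$initial_a4_threshold
    p2 <- simulate_setup_phase(script, config, durations_min[2],
                               combo_seq = sel$combo,
                               thr3 = sel$a3_threshold, thr4 = phase_a4,
                               wend_ms = sel$initial_window_end_ms,
                               meas_thr = max(phase_a4 - 0.25, 0.1))
    we <- phase2_window_end(p2, phase_a4, variant, config)

    # Phase 3: fine-tuned window end; A4 Threshold finalization (shared).
    p3 <- simulate_setup_phase(script, config, durations_min[3],
                               combo_seq = sel$combo,
                               thr3 = sel$a3_threshold,
                               thr4 = sel$initial_a4_threshold,
                               wend_ms = we$max_ms)
    a4f <- phase3_a4_threshold(p3, we$max_ms, sel$a3_threshold,
                               sel$initial_a4_threshold)

    structure(
      list(chosen_vector_combo = sel$combo,
           a3_threshold = sel$a3_threshold,
           a3_window_end_min_ms = we$min_ms,
           a3_window_end_max_ms = we$max_ms,
           a4_threshold = a4f$a4_threshold,
           variant = variant,
           diagnostics = list(phase1 = sel, phase2 = we, phase3 = a4f,
                              n_cycles = c(nrow(p1), nrow(p2), nrow(p3)))),
      class = "avs_setup_result")
  })
}

#' Build an ambulatory device configuration from a setup result
#'
#' @param result An `avs_setup_result`.
#' @param base An [device_config()] supplying the non-setup parameters.
#' @return An [device_config()] programmed with the setup-chosen thresholds
#'   and window ends, in VDD mode.
#' @export
config_from_setup <- function(result, base = device_config()) {
  stopifnot(inherits(result, "avs_setup_result"))
  device_config(
    mode = "VDD", pvab_ms = base$pvab_ms,
    upper_tracking_rate_bpm = base$upper_tracking_rate_bpm,
    lower_rate_bpm = base$lower_rate_bpm,
    a3_threshold = result$a3_threshold,
    a4_threshold = min(result$a4_threshold, result$a3_threshold),
    a3_window_end_min_ms = result$a3_window_end_min_ms,
    a3_window_end_max_ms = result$a3_window_end_max_ms,
    am_to_vp_delay_ms = base$am_to_vp_delay_ms,
    a3_amplitude_margin = base$a3_amplitude_margin,
    sampling_rate_hz = base$sampling_rate_hz,
    day_length_min = base$day_length_min,
    auto_update_cycles = base$auto_update_cycles,
    auto_margin = base$auto_margin, auto_max = base$auto_max)
}

#' @export
print.avs_setup_result <- function(x, ...) {
  cat(sprintf(
    "<avs_setup_result> variant=%s combo=%s A3thr=%.2f A4thr=%.2f window=[%d, %d] ms\n",
    x$variant, x$chosen_vector_combo, x$a3_threshold, x$a4_threshold,
    x$a3_window_end_min_ms, x$a3_window_end_max_ms))
  invisible(x)
}
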