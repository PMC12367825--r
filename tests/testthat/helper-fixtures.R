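# Shared fixtures: small scripts and crafted logs built in code.

# A script with identical distributions in all four combinations.
flat_script <- function(a3_mean = 2.0, a3_sd = 0.3, a4_mean = 4.0,
                        a4_sd = 0.5, interval_ms = 1000, variability = 0.05,
                        pac = 0, pvc = 0, timing = beat_timing(), seed = 1,
                        a4_scale = c(1, 1, 1, 1)) {
  combos <- lapply(seq_along(a4_scale), function(i) {
    list(a3 = amplitude_distribution(a3_mean, a3_sd),
         a4 = amplitude_distribution(a4_mean * a4_scale[i], a4_sd))
  })
  names(combos) <- c("1+2", "1+3", "2+3", "1+2+3")
  patient_script(combos, interval_ms, variability, pac, pvc, timing,
                 seed = seed, best_combo = "1+2")
}

# A noise-free script: degenerate amplitudes, no jitter, no modulation.
noisefree_script <- function(a3 = 2.2, a4 = 4.0, a3_end = 760,
                             interval_ms = 1000) {
  flat_script(a3_mean = a3, a3_sd = 0, a4_mean = a4, a4_sd = 0,
              interval_ms = interval_ms, variability = 0,
              timing = beat_timing(a3_signal_end_ms = a3_end,
                                   a3_end_variation_sd_ms = 0))
}

# Marker data frame from vectors of P and V times.
crafted_log <- function(p_times, v_times, v_kind = "VP") {
  rbind(data.frame(time_ms = p_times, kind = rep("P", length(p_times)),
                   cycle = seq_along(p_times),
                   annotation = rep("", length(p_times))),
        data.frame(time_ms = v_times, kind = rep(v_kind, length(v_times)),
                   cycle = seq_along(v_times),
                   annotation = rep("", length(v_times))))
}

# Independent all-pairs AVS matcher: for each P scan every V for the first
# later one (brute force oracle for compute_avs).
brute_force_avs <- function(p_times, v_times, window_ms = 300) {
  p_times <- sort(p_times); v_times <- sort(v_times)
  sync <- logical(0)
  for (p in p_times) {
    later <- v_times[v_times > p]
    if (!length(later)) next
    sync <- c(sync, (min(later) - p) <= window_ms)
  }
  mean(sync)
}

# Frozen high-precision Ricker oracle (independent symbolic evaluation of
# the wavelet formula at 20 significant digits).
RICKER_ORACLE <- data.frame(
  t_ms = c(0, 2, 5, 8, 15, 19.5, 22.5, 3, 10, 0.7),
  f_hz = c(20, 20, 20, 20, 20, 20, 20, 35, 12.5, 50),
  value = c(1.0,
            0.95324474612817473796,
            0.72717725997130740689,
            0.38423012039109839450,
            -0.31943995607776220118,
            -0.44626001674339602927,
            -0.40619587671834597133,
            0.70171129706648721996,
            0.59274176824746399616,
            0.96409258627125111465))
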