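# Virtual patients: statistical beat generators standing in for
# Holter-derived per-patient scripts.
#
# A patient is a set of truncated-normal A3/A4 amplitude distributions (one
# pair per accelerometer vector combination), an hourly mean sinus-interval
# profile with +/- 5% beat-to-beat modulation, per-beat ectopy probabilities
# and a waveform timing model. All draws are independent across beats.

VECTOR_COMBOS <- c("1+2", "1+3", "2+3", "1+2+3")

#' Truncated-normal amplitude distribution
#'
#' @param mean,sd Mean and SD in m/s^2 (`sd >= 0`).
#' @param min,max Truncation range; draws always fall in
#'   `[min * gain, max * gain]`.
#' @param gain Multiplicative gain (default 1), the free knob that the
#'   script-matching loop of a bench with real recordings would tune.
#' @return Object of class `avs_amp_dist`.
#' @export
amplitude_distribution <- function(mean, sd, min = mean - 2 * sd,
                                   max = mean + 2 * sd, gain = 1) {
  chk_num(mean, "mean", min = 0)
  chk_num(sd, "sd", min = 0)
  chk_num(gain, "gain", min = 0)
  if (!(min <= mean && mean <= max)) {
    stop_invalid("need min <= mean <= max (got %g, %g, %g)", min, mean, max)
  }
  structure(list(mean = mean, sd = sd, min = min, max = max, gain = gain),
            class = "avs_amp_dist")
}

#' Draw amplitudes from a truncated-normal distribution
#'
#' Rejection sampling from `N(mean, sd)` truncated to `[min, max]`, scaled by
#' `gain`. A degenerate `sd = 0` returns the mean.
#'
#' @param dist An [amplitude_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` in `[min * gain, max * gain]`.
#' @export
draw_amplitude <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "avs_amp_dist"))
  if (dist$sd == 0) return(rep(dist$mean * dist$gain, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), dist$mean, dist$sd)
    ok <- x >= dist$min & x <= dist$max
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out * dist$gain
}

#' Build a virtual-patient script
#'
#' @param combos Named list over the four vector combinations `"1+2"`,
#'   `"1+3"`, `"2+3"`, `"1+2+3"`; each element a list with components `a3`
#'   and `a4`, both [amplitude_distribution()] objects.
#' @param hourly_interval_ms Numeric vector of hourly mean sinus intervals in
#'   ms (all > 300 ms); recycled over the session duration.
#' @param interval_variability Beat-to-beat uniform modulation fraction
#'   (default 0.05, i.e. +/- 5%).
#' @param pac_probability,pvc_probability Per-beat ectopy probabilities in
#'   \[0, 0.5\].
#' @param timing A [beat_timing()] object.
#' @param seed Script-level seed (used when the script is simulated without
#'   an explicit seed).
#' @param id,archetype Optional identifier strings.
#' @param best_combo Optional metadata: the vector combination the generator
#'   built as the strongest-A4 one (what a correctly working setup should
#'   choose).
#' @return Object of class `avs_patient_script`.
#' @export
patient_script <- function(combos, hourly_interval_ms,
                           interval_variability = 0.05,
                           pac_probability = 0, pvc_probability = 0,
                           timing = beat_timing(), seed = NULL,
                           id = NULL, archetype = NULL, best_combo = NULL) {
  if (!is.list(combos) || !setequal(names(combos), VECTOR_COMBOS)) {
    missing <- setdiff(VECTOR_COMBOS, names(combos))
    stop_invalid("combos must name all vector combinations; missing: %s",
                 paste(missing, collapse = ", "))
  }
  for (nm in VECTOR_COMBOS) {
    el <- combos[[nm]]
    if (!is.list(el) || !inherits(el$a3, "avs_amp_dist") ||
        !inherits(el$a4, "avs_amp_dist")) {
      stop_invalid("combos[['%s']] must hold amplitude_distribution fields 'a3' and 'a4'", nm)
    }
  }
  if (!is.numeric(hourly_interval_ms) || !length(hourly_interval_ms) ||
      any(hourly_interval_ms <= 300)) {
    stop_invalid("hourly_interval_ms must all exceed 300 ms")
  }
  chk_num(interval_variability, "interval_variability", min = 0, max = 0.2)
  chk_num(pac_probability, "pac_probability", min = 0, max = 0.5)
  chk_num(pvc_probability, "pvc_probability", min = 0, max = 0.5)
  stopifnot(inherits(timing, "avs_beat_timing"))
  structure(
    list(combos = combos[VECTOR_COMBOS],
         hourly_interval_ms = as.numeric(hourly_interval_ms),
         interval_variability = interval_variability,
         pac_probability = pac_probability,
         pvc_probability = pvc_probability,
         timing = timing, seed = seed, id = id, archetype = archetype,
         best_combo = best_combo),
    class = "avs_patient_script"
  )
}

#' Modulate a mean sinus interval with bounded random variability
#'
#' Uniform draw in `[mean * (1 - v), mean * (1 + v)]` — the maximum-entropy
#' bounded choice for the stated +/- 5% beat-to-beat modulation.
#'
#' @param mean_interval_ms Mean interval in ms.
#' @param variability_fraction Fraction `v` in \[0, 0.2\] (default 0.05).
#' @param n Number of draws.
#' @return Numeric vector of modulated intervals.
#' @export
modulate_interval <- function(mean_interval_ms, variability_fraction = 0.05,
                              n = 1L) {
  chk_num(mean_interval_ms, "mean_interval_ms", min = 0)
  chk_num(variability_fraction, "variability_fraction", min = 0, max = 0.2)
  if (variability_fraction == 0) return(rep(mean_interval_ms, n))
  stats::runif(n, mean_interval_ms * (1 - variability_fraction),
               mean_interval_ms * (1 + variability_fraction))
}

#' Draw the parameters of a single beat
#'
#' @param script An [patient_script()] object.
#' @param vector_combo One of `"1+2"`, `"1+3"`, `"2+3"`, `"1+2+3"`.
#' @param hour_index 1-based index into the hourly interval profile
#'   (recycled).
#' @return List with `interval_ms`, `a3_amp`, `a4_amp`, `class` (one of
#'   `"sinus"`, `"PAC"`, `"PVC"`).
#' @export
sample_beat <- function(script, vector_combo, hour_index = 1L) {
  stopifnot(inherits(script, "avs_patient_script"))
  if (!vector_combo %in% names(script$combos)) {
    stop_invalid("unknown vector combination '%s'", vector_combo)
  }
  prof <- script$hourly_interval_ms
  mean_rr <- prof[((hour_index - 1L) %% length(prof)) + 1L]
  interval <- modulate_interval(mean_rr, script$interval_variability)
  u <- stats::runif(1L)
  cls <- if (u < script$pac_probability) "PAC"
         else if (u < script$pac_probability + script$pvc_probability) "PVC"
         else "sinus"
  co <- script$combos[[vector_combo]]
  list(interval_ms = interval,
       a3_amp = draw_amplitude(co$a3),
       a4_amp = if (cls == "PVC") NA_real_ else draw_amplitude(co$a4),
       class = cls)
}

#' Generate a Monte Carlo beat schedule for a session
#'
#' Beats tile `duration_min` using the hourly interval profile. Sinus beats
#' advance the P-wave clock by the modulated interval; a PAC fires its P-wave
#' at 70% of the scheduled interval and resets the sinus clock; a PVC emits a
#' ventricular ectopic event at 80% of the interval, carries no P-wave/A4,
#' and is followed by a compensatory pause (next P on the undisturbed clock).
#'
#' @param script A [patient_script()].
#' @param duration_min Session length in minutes.
#' @param vector_combo Vector combination to draw amplitudes for.
#' @param seed Seed (default: the script's own seed).
#' @param hour_length_min Minutes represented by one entry of the hourly
#'   profile (default 60; tests and desk-scale runs compress it).
#' @return Object of class `avs_beat_schedule`: data frame with columns
#'   `beat`, `class`, `t_p_ms` (P onset, NA for PVC), `t_v_ms` (ectopic
#'   ventricular event, NA otherwise), `a3_amp`, `a4_amp`, `interval_ms`,
#'   `hour`. The script's timing model is attached as attribute `timing`.
#' @export
generate_session <- function(script, duration_min, vector_combo = "1+2",
                             seed = script$seed, hour_length_min = 60) {
  stopifnot(inherits(script, "avs_patient_script"))
  if (!vector_combo %in% names(script$combos)) {
    stop_invalid("unknown vector combination '%s'", vector_combo)
  }
  chk_num(duration_min, "duration_min", min = 1e-9)
  dur_ms <- duration_min * 60000
  hour_ms <- hour_length_min * 60000
  with_seed(seed, {
    n_guess <- ceiling(dur_ms / (min(script$hourly_interval_ms) * 0.5)) + 8L
    cls <- character(n_guess); tp <- tv <- a3 <- a4 <- iv <- numeric(n_guess)
    hr <- integer(n_guess)
    t <- 0; k <- 0L
    while (t < dur_ms) {
      k <- k + 1L
      hour <- as.integer(t %/% hour_ms) + 1L
      b <- sample_beat(script, vector_combo, hour)
      cls[k] <- b$class; iv[k] <- b$interval_ms; hr[k] <- hour
      a3[k] <- b$a3_amp; a4[k] <- b$a4_amp
      if (b$class == "PVC") {
        tv[k] <- t + 0.8 * b$interval_ms
        tp[k] <- NA_real_
        t <- t + b$interval_ms      # compensatory pause
      } else if (b$class == "PAC") {
        tp[k] <- t + 0.7 * b$interval_ms
        tv[k] <- NA_real_
        t <- tp[k]
      } else {
        tp[k] <- t + b$interval_ms
        tv[k] <- NA_real_
        t <- tp[k]
      }
    }
    idx <- seq_len(k)
    out <- data.frame(beat = idx, class = cls[idx], t_p_ms = tp[idx],
                      t_v_ms = ifelse(cls[idx] == "PVC", tv[idx], NA_real_),
                      a3_amp = a3[idx], a4_amp = a4[idx],
                      interval_ms = iv[idx], hour = hr[idx])
    out <- out[is.na(out$t_p_ms) | out$t_p_ms <= dur_ms, , drop = FALSE]
    attr(out, "timing") <- script$timing
    attr(out, "duration_ms") <- dur_ms
    class(out) <- c("avs_beat_schedule", "data.frame")
    out
  })
}

# ---------------------------------------------------------------------------
# Synthetic cohort generator
# ---------------------------------------------------------------------------

#' Default archetype parameters for the synthetic cohort
#'
#' Three archetypes emulate the statistical structure and failure modes of
#' ambulatory recordings from complete-AV-block patients:
#' * `well_separated` — A4 well above A3; clean tracking at all rates;
#' * `a7_undersenser` — sustained 85-95 bpm episodes during which A3+A4
#'   superimpose (A7) and a per-cycle adaptive A3 threshold ratchets above
#'   the A7 amplitude;
#' * `a3_oversenser` — large, long A3 whose tail outlasts short A3 windows
#'   and crosses the A4 threshold.
#'
#' Ranges are uniform per-patient draws; amplitudes in m/s^2, times in ms.
#' @return Named list of archetype parameter lists.
#' @export
default_archetypes <- function() {
  list(
    well_separated = list(
      a3_mean = c(1.4, 1.8), a3_sd = 0.30,
      a4_mean = c(4.2, 5.0), a4_sd = 0.50,
      a3_end = c(720, 780),
      rest_rr = c(950, 1050), high_rr = c(740, 800)),
    a7_undersenser = list(
      a3_mean = c(1.6, 2.0), a3_sd = 0.35,
      a4_mean = c(4.2, 5.0), a4_sd = 0.45,
      a3_end = c(730, 790),
      rest_rr = c(950, 1050), high_rr = c(650, 690)),
    a3_oversenser = list(
      a3_mean = c(2.2, 2.6), a3_sd = 0.35,
      a4_mean = c(4.2, 5.0), a4_sd = 0.50,
      a3_end = c(840, 880),
      rest_rr = c(900, 1000), high_rr = c(680, 720))
  )
}

#' Generate a reproducible synthetic virtual-patient cohort
#'
#' Builds `n_patients` scripts by cycling through the archetypes in
#' `archetype_params` (default [default_archetypes()], weighted toward the
#' A7-undersenser failure mode). Per-combination A4 means differ (the
#' "chosen" combination is randomized among the two-vector combinations)
#' so Atrial Sensing Setup vector selection is non-trivial; each hourly
#' profile contains a rest block followed by a high-rate block crossing
#' 80 bpm.
#'
#' @param n_patients Cohort size (>= 1).
#' @param archetype_params Named list of archetype parameter lists.
#' @param seed Cohort seed (default 101; fixed seed = same cohort).
#' @param archetype_weights Integer recycling weights over the archetypes
#'   (default 1 well-separated : 2 A7-undersenser : 1 A3-oversenser).
#' @return List of [patient_script()] objects with `id` and `archetype` set.
#' @export
make_synthetic_cohort <- function(n_patients = 30,
                                  archetype_params = default_archetypes(),
                                  seed = 101,
                                  archetype_weights = c(1, 2, 1)) {
  if (n_patients < 1) stop_invalid("n_patients must be >= 1")
  arch_names <- rep(names(archetype_params),
                    times = rep_len(archetype_weights, length(archetype_params)))
  with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      arch <- arch_names[((i - 1L) %% length(arch_names)) + 1L]
      p <- archetype_params[[arch]]
      runif1 <- function(r) stats::runif(1L, r[1], r[2])
      a3_mean <- runif1(p$a3_mean)
      a4_mean <- runif1(p$a4_mean)
      rest <- runif1(p$rest_rr); high <- runif1(p$high_rr)
      # Chosen two-vector combination gets the full A4; the others are
      # attenuated projections; 1+2+3 sits just below the best two-vector mix.
      best <- sample(c("1+2", "1+3", "2+3"), 1L)
      a4_scale <- c("1+2" = 1, "1+3" = 1, "2+3" = 1, "1+2+3" = 0.9)
      for (nm in setdiff(c("1+2", "1+3", "2+3"), best)) {
        a4_scale[nm] <- stats::runif(1L, 0.5, 0.8)
      }
      combos <- lapply(VECTOR_COMBOS, function(nm) {
        list(a3 = amplitude_distribution(a3_mean * stats::runif(1L, 0.95, 1.05),
                                         p$a3_sd),
             a4 = amplitude_distribution(a4_mean * a4_scale[[nm]], p$a4_sd))
      })
      names(combos) <- VECTOR_COMBOS
      patient_script(
        combos = combos,
        hourly_interval_ms = c(rest, rest * 0.97, high, high * 1.02),
        interval_variability = 0.05,
        pac_probability = 0.01, pvc_probability = 0.01,
        timing = beat_timing(a3_signal_end_ms = runif1(p$a3_end),
                             a3_end_variation_sd_ms = 17),
        seed = sub_seed(seed, i),
        id = sprintf("VP%02d", i), archetype = arch, best_combo = best)
    })
  })
}

#' Cohort manifest
#'
#' @param cohort List of patient scripts from [make_synthetic_cohort()].
#' @return Data frame with patient id, archetype, seed and headline script
#'   parameters (chosen-combination medians are not included; they are
#'   discovered by Atrial Sensing Setup).
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(id = s$id, archetype = s$archetype, seed = s$seed,
               a3_signal_end_ms = s$timing$a3_signal_end_ms,
               rest_interval_ms = s$hourly_interval_ms[1],
               high_interval_ms = min(s$hourly_interval_ms))
  }))
}
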