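# Accelerometer waveform synthesis.
#
# Each intracardiac accelerometer deflection (A1, A2, A3, A4) is modeled as a
# Ricker wavelet with peak frequency f (default 20 Hz). A cardiac cycle's
# trace is the rectified (absolute value) sum of the scaled component
# wavelets sampled at a fixed rate; when the A4 wavelet support begins before
# the A3 signal end the two components superimpose into a single combined
# "A7" event (binary summation rule).

# Wavelet support half-width in ms: amplitude < 1e-5 beyond |t| > 2.5/f.
ricker_halfwidth_ms <- function(f_hz) 2.5 / f_hz * 1000

# Perceptible onset/offset half-width: |amplitude| has fallen to ~2% of the
# peak 0.8/f from the peak (40 ms at 20 Hz). A component whose nominal
# "start" (or "end") is given places its peak one onset width inside, so
# that e.g. the A3 signal visibly dies out at the scripted A3 Signal End.
ricker_onset_ms <- function(f_hz) 0.8 / f_hz * 1000

#' Ricker (Mexican hat) wavelet
#'
#' Dimensionless wavelet amplitude
#' \deqn{(1 - 2\pi^2 f^2 t^2)\, e^{-\pi^2 f^2 t^2}}
#' with `t` in milliseconds relative to the component peak and `f` the peak
#' frequency in Hz. The value lies in \[-0.446, 1\] and equals 1 at `t = 0`.
#'
#' @param t_ms Numeric vector, time from the wavelet peak in ms.
#' @param f_hz Peak frequency in Hz (default 20).
#' @return Numeric vector of wavelet amplitudes.
#' @examples
#' ricker(0)            # 1
#' ricker(5)            # ~0.7272
#' @export
ricker <- function(t_ms, f_hz = 20) {
  if (!is.numeric(f_hz) || length(f_hz) != 1L || !is.finite(f_hz) || f_hz <= 0) {
    stop_invalid("peak frequency 'f_hz' must be a positive number")
  }
  ts <- t_ms / 1000
  u <- (pi * f_hz * ts)^2
  (1 - 2 * u) * exp(-u)
}

#' Define a wavelet component of the accelerometer signal
#'
#' @param label One of `"A1"`, `"A2"`, `"A3"`, `"A4"`.
#' @param peak_amplitude Peak acceleration in m/s^2 (>= 0).
#' @param peak_time_ms Peak time in ms from the cycle origin (the ventricular
#'   event), or `NA` to let [synthesize_beat()] derive it from the timing.
#' @param peak_frequency_hz Peak frequency in Hz (default 20).
#' @return An object of class `avs_wavelet`.
#' @export
wavelet_component <- function(label, peak_amplitude, peak_time_ms = NA_real_,
                              peak_frequency_hz = 20) {
  label <- match.arg(label, c("A1", "A2", "A3", "A4"))
  chk_num(peak_amplitude, "peak_amplitude", min = 0)
  chk_num(peak_frequency_hz, "peak_frequency_hz")
  if (peak_frequency_hz <= 0) stop_invalid("peak_frequency_hz must be > 0")
  if (!is.na(peak_time_ms)) chk_num(peak_time_ms, "peak_time_ms", min = 0)
  structure(
    list(label = label, peak_amplitude = peak_amplitude,
         peak_time_ms = as.numeric(peak_time_ms),
         peak_frequency_hz = peak_frequency_hz),
    class = "avs_wavelet"
  )
}

#' Per-cycle timing model of the accelerometer components
#'
#' Encodes when the components occur within a cardiac cycle whose origin
#' (t = 0) is the ventricular event:
#' * A1 peak fixed at 50 ms (fixed amplitude, blanked by PVAB);
#' * A2 begins `a2_delay_ms` after the ventricular event (default 300 ms);
#' * A3 ends at `a3_signal_end_ms`, optionally jittered with Gaussian noise
#'   (`a3_end_variation_sd_ms` of 0, 17 or 33 ms) and optionally shortened
#'   with atrial rate above 60 bpm;
#' * A4 begins `a4_delay_ms` after the P-wave onset (default 90 ms).
#'
#' @param a2_delay_ms Ventricular event to A2 start, ms (default 300).
#' @param a4_delay_ms P-wave onset to A4 start, ms (default 90).
#' @param a3_signal_end_ms End of the A3 wavelet, ms from the ventricular
#'   event (default 760).
#' @param a3_end_variation_sd_ms Gaussian jitter SD applied to the A3 signal
#'   end; one of 0, 17 or 33 ms (default 0).
#' @param auto_adjust_a3_end Logical; if `TRUE` the A3 signal end is scaled by
#'   `RR / 1000` for cycles shorter than 1000 ms (rates above 60 bpm), with a
#'   floor of `a2_delay_ms + 100`. Default `FALSE`.
#' @param f_hz Peak frequency shared by all components (default 20 Hz).
#' @return An object of class `avs_beat_timing`.
#' @export
beat_timing <- function(a2_delay_ms = 300, a4_delay_ms = 90,
                        a3_signal_end_ms = 760, a3_end_variation_sd_ms = 0,
                        auto_adjust_a3_end = FALSE, f_hz = 20) {
  chk_num(a2_delay_ms, "a2_delay_ms", min = 0)
  chk_num(a4_delay_ms, "a4_delay_ms", min = 0)
  chk_num(a3_signal_end_ms, "a3_signal_end_ms", min = 0)
  if (!a3_end_variation_sd_ms %in% c(0, 17, 33)) {
    stop_invalid("a3_end_variation_sd_ms must be one of 0, 17, 33 (got %s)",
                 format(a3_end_variation_sd_ms))
  }
  if (f_hz <= 0) stop_invalid("f_hz must be > 0")
  structure(
    list(a2_delay_ms = a2_delay_ms, a4_delay_ms = a4_delay_ms,
         a3_signal_end_ms = a3_signal_end_ms,
         a3_end_variation_sd_ms = a3_end_variation_sd_ms,
         auto_adjust_a3_end = isTRUE(auto_adjust_a3_end), f_hz = f_hz),
    class = "avs_beat_timing"
  )
}

# Effective A3 signal end for a cycle: rate adjustment then Gaussian jitter.
# Consumes one rnorm() draw when the jitter SD is positive.
effective_a3_end <- function(timing, rr_ms = NULL) {
  e3 <- timing$a3_signal_end_ms
  if (isTRUE(timing$auto_adjust_a3_end) && !is.null(rr_ms) && rr_ms < 1000) {
    e3 <- max(e3 * rr_ms / 1000, timing$a2_delay_ms + 100)
  }
  if (timing$a3_end_variation_sd_ms > 0) {
    e3 <- e3 + stats::rnorm(1L, 0, timing$a3_end_variation_sd_ms)
  }
  e3
}

# Resolve component peak times from the timing model. A "start" of a wavelet
# is taken as peak - halfwidth (the point where its amplitude first becomes
# non-negligible); an "end" as peak + halfwidth.
resolve_components <- function(components, timing, p_onset_ms, a3_end_ms) {
  on <- ricker_onset_ms(timing$f_hz)
  lab <- vapply(components, `[[`, "", "label")
  for (i in seq_along(components)) {
    if (!is.na(components[[i]]$peak_time_ms)) next
    components[[i]]$peak_time_ms <- switch(
      components[[i]]$label,
      A1 = 50,
      A2 = timing$a2_delay_ms + on,
      A3 = a3_end_ms - on,
      A4 = {
        if (is.null(p_onset_ms) || is.na(p_onset_ms)) {
          stop_invalid("A4 component requires a P-wave onset time")
        }
        p_onset_ms + timing$a4_delay_ms + on
      }
    )
  }
  names(components) <- lab
  components
}

#' Synthesize one cardiac cycle's rectified accelerometer trace
#'
#' Sums the scaled Ricker wavelets of the supplied components on a fixed
#' sampling grid and rectifies (absolute value). When the A4 wavelet support
#' begins before the (jittered) A3 signal end, the A3 and A4 wavelets
#' superimpose sample-wise into a combined A7 event and the ground truth
#' flags `a7 = TRUE`.
#'
#' @param components List of [wavelet_component()] objects. Components with
#'   `peak_time_ms = NA` get their peak placed from `timing` (and `p_onset_ms`
#'   for A4).
#' @param timing A [beat_timing()] object.
#' @param p_onset_ms P-wave onset in ms from the cycle origin, or `NULL` when
#'   the cycle has no atrial contraction (e.g. a PVC).
#' @param duration_ms Trace length in ms (default: covers all components plus
#'   one wavelet half-width, at least 1200 ms).
#' @param sampling_rate_hz Sampling rate (default 1000 Hz); must be at least
#'   `4 * f` to avoid aliasing the wavelet.
#' @param seed Optional seed for the A3-end jitter draw.
#' @return An object of class `avs_beat_trace`: list with `time_ms`,
#'   `samples` (rectified, m/s^2), `samples_raw` (signed sum before
#'   rectification), `sample_period_ms`, and `ground_truth` (data frame of
#'   rendered peaks plus the `a7` flag and effective A3 end).
#' @export
synthesize_beat <- function(components, timing = beat_timing(),
                            p_onset_ms = NULL, duration_ms = NULL,
                            sampling_rate_hz = 1000, seed = NULL) {
  stopifnot(inherits(timing, "avs_beat_timing"))
  if (inherits(components, "avs_wavelet")) components <- list(components)
  if (sampling_rate_hz < 4 * timing$f_hz) {
    stop_invalid("sampling rate %g Hz would alias a %g Hz wavelet (need >= %g)",
                 sampling_rate_hz, timing$f_hz, 4 * timing$f_hz)
  }
  lab <- vapply(components, `[[`, "", "label")
  if (timing$a3_end_variation_sd_ms > 0 && "A3" %in% lab &&
      is.null(seed) &&
      !exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # ensure an RNG stream exists for the jitter draw
  }
  a3_end <- with_seed(seed, effective_a3_end(timing))
  components <- resolve_components(components, timing, p_onset_ms, a3_end)

  hw <- ricker_halfwidth_ms(timing$f_hz)
  peaks <- vapply(components, `[[`, 0, "peak_time_ms")
  amps <- vapply(components, `[[`, 0, "peak_amplitude")
  if (is.null(duration_ms)) {
    duration_ms <- max(1200, max(peaks) + hw)
  }
  sp_ms <- 1000 / sampling_rate_hz
  t <- seq(0, duration_ms - sp_ms, by = sp_ms)

  raw <- numeric(length(t))
  for (i in seq_along(components)) {
    cc <- components[[i]]
    idx <- which(abs(t - cc$peak_time_ms) <= hw)
    if (length(idx)) {
      raw[idx] <- raw[idx] +
        cc$peak_amplitude * ricker(t[idx] - cc$peak_time_ms, cc$peak_frequency_hz)
    }
  }

  a7 <- FALSE
  on <- ricker_onset_ms(timing$f_hz)
  if (all(c("A3", "A4") %in% lab)) {
    a4_start <- components[["A4"]]$peak_time_ms - on
    a7 <- a4_start < a3_end
  }
  # A1/A2 overlapping A3 is permitted (plain summation) but worth noting.
  if ("A3" %in% lab) {
    early <- peaks[lab %in% c("A1", "A2")] + hw
    if (length(early) && any(early > peaks[["A3"]] - hw)) {
      message("note: A1/A2 support overlaps A3; components summed")
    }
  }

  structure(
    list(time_ms = t, samples = abs(raw), samples_raw = raw,
         sample_period_ms = sp_ms,
         ground_truth = list(
           peaks = data.frame(label = lab, peak_time_ms = unname(peaks),
                              peak_amplitude = unname(amps)),
           a7 = a7, a3_end_ms = a3_end, p_onset_ms = p_onset_ms)),
    class = "avs_beat_trace"
  )
}

#' Export a beat trace as a two-column CSV
#'
#' Writes `time_ms, accel_m_s2` plus a JSON sidecar (`<path>.json`) with the
#' rendered component ground truth.
#'
#' @param trace An `avs_beat_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_beat_trace <- function(trace, path) {
  stopifnot(inherits(trace, "avs_beat_trace"))
  utils::write.csv(
    data.frame(time_ms = trace$time_ms, accel_m_s2 = trace$samples),
    path, row.names = FALSE)
  jsonlite::write_json(trace$ground_truth, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
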