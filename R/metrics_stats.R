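# AVS scoring, paired cohort statistics and survey arithmetic.

AVS_RATE_BREAKS <- c(0, 60, 70, 80, 90, 100, Inf)
AVS_RATE_LABELS <- c("<60", "60-70", "70-80", "80-90", "90-100", ">=100")

#' Compute atrioventricular synchrony from an event log
#'
#' A cardiac cycle is synchronous when a ventricular marker (VP or VS)
#' follows the P-wave onset by at most `window_ms` (default 300 ms). Each P
#' is matched to the first subsequent ventricular event; cycles without a
#' P-wave (PVCs) are excluded from the denominator, as are trailing P-waves
#' with no ventricular event. The rate bin of a cycle comes from the
#' preceding P-P interval.
#'
#' @param log An `avs_event_log` from [run_session()] (or a compatible
#'   marker data frame with columns `time_ms` and `kind`).
#' @param window_ms Synchrony window in ms (default 300).
#' @return Object of class `avs_report`: `overall_avs` (fraction), `n_cycles`
#'   (scored P-waves), `by_rate` (data frame: bin, n, avs), `avs_80_100`
#'   (aggregated 80-100 bpm synchrony), and `deltas` (per-P V delay).
#' @export
compute_avs <- function(log, window_ms = 300) {
  mk <- if (inherits(log, "avs_event_log")) log$markers else log
  p <- sort(mk$time_ms[mk$kind == "P"])
  v <- sort(mk$time_ms[mk$kind %in% c("VP", "VS")])
  if (!length(p)) {
    stop_invalid("undefined AVS: log contains no P markers")
  }
  # first V strictly after each P
  iv <- findInterval(p, v, left.open = FALSE) + 1L
  has_v <- iv <= length(v)
  delta <- rep(NA_real_, length(p))
  delta[has_v] <- v[iv[has_v]] - p[has_v]
  rate <- c(NA_real_, 60000 / diff(p))
  keep <- has_v
  sync <- delta[keep] <= window_ms
  rate_k <- rate[keep]
  bins <- cut(rate_k, AVS_RATE_BREAKS, labels = AVS_RATE_LABELS, right = FALSE)
  by_rate <- do.call(rbind, lapply(levels(bins), function(b) {
    i <- which(!is.na(bins) & bins == b)
    data.frame(bin = b, n = length(i),
               avs = if (length(i)) mean(sync[i]) else NA_real_)
  }))
  i80 <- which(!is.na(rate_k) & rate_k >= 80 & rate_k < 100)
  structure(
    list(overall_avs = mean(sync), n_cycles = sum(keep),
         by_rate = by_rate,
         avs_80_100 = if (length(i80)) mean(sync[i80]) else NA_real_,
         n_80_100 = length(i80),
         deltas = data.frame(p_ms = p[keep], delta_ms = delta[keep],
                             rate_bpm = rate_k, synchronous = sync)),
    class = "avs_report")
}

#' @export
print.avs_report <- function(x, ...) {
  cat(sprintf("<avs_report> overall AVS %.1f%% over %d cycles; 80-100 bpm: %s (n=%d)\n",
              100 * x$overall_avs, x$n_cycles,
              if (is.na(x$avs_80_100)) "NA" else sprintf("%.1f%%", 100 * x$avs_80_100),
              x$n_80_100))
  invisible(x)
}

#' McNemar's test for paired proportions
#'
#' Takes the two discordant-pair counts: `b` pairs positive under condition A
#' only and `c` pairs positive under condition B only. Uses the exact
#' two-sided binomial test for `b + c < 25`, otherwise the chi-square
#' approximation with continuity correction.
#'
#' @param b,c Non-negative discordant counts.
#' @return List: `statistic`, `p_value`, `method`, `flagged` (`TRUE` when
#'   `b = c = 0`, where `p = 1` by convention).
#' @export
mcnemar_paired <- function(b, c) {
  chk_num(b, "b", min = 0); chk_num(c, "c", min = 0)
  n <- b + c
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                flagged = TRUE))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    list(statistic = (b - c)^2 / n, p_value = p, method = "exact-binomial",
         flagged = FALSE)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi-square-cc", flagged = FALSE)
  }
}

#' Fraction of patients above an AVS cutoff
#'
#' Strict inequality: a patient at exactly the cutoff does not count.
#'
#' @param avs Numeric vector of per-patient AVS fractions.
#' @param cutoff Cutoff (default 0.70).
#' @return Fraction in \[0, 1\].
#' @export
proportion_above <- function(avs, cutoff = 0.70) {
  if (!length(avs)) stop_invalid("empty cohort")
  mean(avs > cutoff)
}

SURVEY_BIN_LABELS <- c("<5", "5-10", "11-20", ">20")
SURVEY_BIN_MIDPOINTS_MIN <- c(2.5, 7.5, 15.5, 25)

#' Device-check survey summary arithmetic
#'
#' Each device's responses are percentages over the duration bins
#' `<5`, `5-10`, `11-20`, `>20` minutes (midpoints 2.5, 7.5, 15.5, 25).
#' The median bin is the first with cumulative percentage >= 50; the
#' clinic-time saving is the difference of median-bin midpoints, and the
#' projected saving per 100 implants is `difference * 100 / 60` hours
#' (rounded to 0.1 h).
#'
#' @param tables Named list of two numeric vectors (percentages over the four
#'   bins, summing to <= 100), the first the reference (slower) device.
#' @return List: `median_bin`, `median_midpoint_min` (per device),
#'   `saving_min` (midpoint difference), `hours_saved_per_100`.
#' @export
survey_summary <- function(tables) {
  if (length(tables) != 2L) stop_invalid("survey_summary expects two devices")
  if (is.null(names(tables))) names(tables) <- c("device1", "device2")
  res <- lapply(tables, function(p) {
    if (length(p) != 4L || any(p < 0)) {
      stop_invalid("each table needs 4 non-negative bin percentages")
    }
    if (sum(p) > 100 + 1e-9) stop_invalid("percentages exceed 100")
    if (sum(p) < 100 - 1e-9) {
      message(sprintf("note: percentages sum to %g; remainder unspecified", sum(p)))
    }
    cum <- cumsum(p)
    i <- which(cum >= 50)[1]
    if (is.na(i)) stop_invalid("cumulative percentages never reach 50")
    list(bin = SURVEY_BIN_LABELS[i], mid = SURVEY_BIN_MIDPOINTS_MIN[i])
  })
  mids <- vapply(res, `[[`, 0, "mid")
  saving <- mids[[1]] - mids[[2]]
  list(median_bin = vapply(res, `[[`, "", "bin"),
       median_midpoint_min = mids,
       saving_min = saving,
       hours_saved_per_100 = round(saving * 100 / 60, 1))
}

#' Patient-level bootstrap confidence interval for a cohort mean
#'
#' @param x Per-patient values.
#' @param n_boot Resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed.
#' @return Named vector `mean`, `lower`, `upper`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 2000, conf = 0.95, seed = NULL) {
  if (!length(x)) stop_invalid("empty cohort")
  with_seed(seed, {
    m <- vapply(seq_len(n_boot),
                function(i) mean(sample(x, replace = TRUE)), 0)
    a <- (1 - conf) / 2
    c(mean = mean(x), lower = unname(stats::quantile(m, a)),
      upper = unname(stats::quantile(m, 1 - a)))
  })
}
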