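# Paired cohort experiments: run both device variants / both threshold
# algorithms over a cohort of virtual patients and compare.

#' Paired Atrial Sensing Setup comparison over a cohort
#'
#' Runs the three-phase setup for both device variants on every patient
#' (same per-patient seed for both, so the comparison is paired), then
#' simulates a resting VDD session with the chosen parameters and scores
#' AVS.
#'
#' @param cohort List of patient scripts.
#' @param config Base [device_config()].
#' @param durations_min Phase durations (default `c(20, 2, 2)`).
#' @param session_min Post-setup resting session length in minutes
#'   (default 30).
#' @param seed Base seed; per-patient sub-seeds are derived from it.
#' @return Data frame (one row per patient): setup outputs and post-setup
#'   AVS for both variants, plus `av2_shorter_wend`.
#' @export
setup_compare <- function(cohort, config = device_config(mode = "VDI"),
                          durations_min = c(20, 2, 2), session_min = 30,
                          seed = 1) {
  rows <- lapply(seq_along(cohort), function(i) {
    sc <- cohort[[i]]
    s_i <- sub_seed(seed, i)
    res <- lapply(c(AV = "AV", AV2 = "AV2"), function(vv) {
      st <- run_setup(vv, sc, config, durations_min, seed = s_i)
      cfg <- config_from_setup(st, base = config)
      # resting session at the first hourly interval
      rest <- patient_script(sc$combos, sc$hourly_interval_ms[1],
                             sc$interval_variability, sc$pac_probability,
                             sc$pvc_probability, sc$timing)
      sch <- generate_session(rest, session_min, st$chosen_vector_combo,
                              seed = sub_seed(s_i, 7))
      avs <- compute_avs(run_session(cfg, sch, seed = sub_seed(s_i, 11)))
      list(setup = st, avs = avs$overall_avs)
    })
    data.frame(
      id = if (is.null(sc$id)) sprintf("P%02d", i) else sc$id,
      archetype = if (is.null(sc$archetype)) NA_character_ else sc$archetype,
      combo_av = res$AV$setup$chosen_vector_combo,
      combo_av2 = res$AV2$setup$chosen_vector_combo,
      wend_max_av = res$AV$setup$a3_window_end_max_ms,
      wend_max_av2 = res$AV2$setup$a3_window_end_max_ms,
      wend_min_av = res$AV$setup$a3_window_end_min_ms,
      wend_min_av2 = res$AV2$setup$a3_window_end_min_ms,
      a3_thr_av = res$AV$setup$a3_threshold,
      a3_thr_av2 = res$AV2$setup$a3_threshold,
      a4_thr_av = res$AV$setup$a4_threshold,
      a4_thr_av2 = res$AV2$setup$a4_threshold,
      avs_av = res$AV$avs, avs_av2 = res$AV2$avs,
      av2_shorter_wend = res$AV2$setup$a3_window_end_max_ms <
        res$AV$setup$a3_window_end_max_ms)
  })
  do.call(rbind, rows)
}

#' Paired ambulatory threshold-algorithm comparison over a cohort
#'
#' For each patient, one beat schedule is generated and run twice through
#' the device — once with the per-cycle adaptive ("auto") A3 threshold and
#' once with the daily-histogram ("autoplus") algorithm — and AVS is scored
#' overall and in the 80-100 bpm range.
#'
#' @param cohort List of patient scripts.
#' @param config Ambulatory [device_config()] (VDD; short A3 window ends in
#'   the 700-800 ms range mirror the nominal ambulatory programming).
#' @param duration_min Session length per patient.
#' @param hour_length_min Minutes per hourly-profile entry (compressed for
#'   desk-scale runs).
#' @param seed Base seed.
#' @return Data frame per patient: AVS (overall and 80-100 bpm) and mean A3
#'   threshold under both algorithms.
#' @export
ambulatory_compare <- function(cohort,
                               config = device_config(
                                 a3_window_end_min_ms = 700,
                                 a3_window_end_max_ms = 800,
                                 a3_threshold = 3.5, a4_threshold = 2.0,
                                 day_length_min = 15),
                               duration_min = 60, hour_length_min = 20,
                               seed = 1) {
  rows <- lapply(seq_along(cohort), function(i) {
    sc <- cohort[[i]]
    s_i <- sub_seed(seed, 1000 + i)
    combo <- if (is.null(sc$best_combo)) "1+2" else sc$best_combo
    sch <- generate_session(sc, duration_min, combo, seed = s_i,
                            hour_length_min = hour_length_min)
    out <- lapply(c(auto = "auto", autoplus = "autoplus"), function(alg) {
      log <- run_session(config, sch, threshold_algo = alg,
                         seed = sub_seed(s_i, 3))
      list(avs = compute_avs(log),
           mean_thr = mean(log$cycles$a3_threshold))
    })
    data.frame(
      id = if (is.null(sc$id)) sprintf("P%02d", i) else sc$id,
      archetype = if (is.null(sc$archetype)) NA_character_ else sc$archetype,
      avs_auto = out$auto$avs$overall_avs,
      avs_autoplus = out$autoplus$avs$overall_avs,
      avs80_auto = out$auto$avs$avs_80_100,
      avs80_autoplus = out$autoplus$avs$avs_80_100,
      n80 = out$auto$avs$n_80_100,
      thr_auto = out$auto$mean_thr, thr_autoplus = out$autoplus$mean_thr)
  })
  do.call(rbind, rows)
}

#' Full paired cohort report
#'
#' Combines [setup_compare()] and [ambulatory_compare()] with the paired
#' statistics: proportions of patients above 70% AVS under each variant and
#' McNemar's test on the discordant pairs.
#'
#' @param cohort List of patient scripts.
#' @param seed Base seed.
#' @param setup_args,ambulatory_args Lists of extra arguments for the two
#'   stages.
#' @return List with `setup`, `ambulatory` (per-patient data frames) and
#'   `stats` (proportions, McNemar p-value, summary fractions).
#' @export
compare_cohort <- function(cohort, seed = 1, setup_args = list(),
                           ambulatory_args = list()) {
  su <- do.call(setup_compare, c(list(cohort = cohort, seed = seed), setup_args))
  am <- do.call(ambulatory_compare,
                c(list(cohort = cohort, seed = seed), ambulatory_args))
  over_av <- su$avs_av > 0.70
  over_av2 <- su$avs_av2 > 0.70
  mc <- mcnemar_paired(sum(over_av & !over_av2), sum(!over_av & over_av2))
  list(
    setup = su, ambulatory = am,
    stats = list(
      prop_above70_av = proportion_above(su$avs_av),
      prop_above70_av2 = proportion_above(su$avs_av2),
      mcnemar = mc,
      frac_av2_shorter_wend = mean(su$av2_shorter_wend),
      mean_avs80_auto = mean(am$avs80_auto, na.rm = TRUE),
      mean_avs80_autoplus = mean(am$avs80_autoplus, na.rm = TRUE)))
}

#' Render a cohort comparison as a Markdown report
#'
#' @param cmp Result of [compare_cohort()].
#' @return Character vector of Markdown lines.
#' @export
format_comparison_md <- function(cmp) {
  s <- cmp$stats
  c("# Paired cohort comparison",
    "",
    sprintf("* Patients: %d", nrow(cmp$setup)),
    sprintf("* AV2 shorter Max A3 Window End: %.0f%% of patients",
            100 * s$frac_av2_shorter_wend),
    sprintf("* Post-setup AVS > 70%%: AV %.0f%% vs AV2 %.0f%% (McNemar p = %.3g)",
            100 * s$prop_above70_av, 100 * s$prop_above70_av2,
            s$mcnemar$p_value),
    sprintf("* Mean 80-100 bpm ambulatory AVS: auto %.1f%% vs auto+ %.1f%%",
            100 * s$mean_avs80_auto, 100 * s$mean_avs80_autoplus),
    "",
    "| id | archetype | wend AV | wend AV2 | AVS AV | AVS AV2 | AVS80 auto | AVS80 auto+ |",
    "|----|-----------|---------|----------|--------|---------|------------|-------------|",
    sprintf("| %s | %s | %d | %d | %.2f | %.2f | %.2f | %.2f |",
            cmp$setup$id, cmp$setup$archetype, cmp$setup$wend_max_av,
            cmp$setup$wend_max_av2, cmp$setup$avs_av, cmp$setup$avs_av2,
            cmp$ambulatory$avs80_auto, cmp$ambulatory$avs80_autoplus))
}
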