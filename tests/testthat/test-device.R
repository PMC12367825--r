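cfg_fixed <- function(wend = 800, thr3 = 3.5, thr4 = 2.0, ...) {
  device_config(a3_window_end_min_ms = wend, a3_window_end_max_ms = wend,
                a3_threshold = thr3, a4_threshold = thr4, ...)
}

test_that("the rate-adaptive window end interpolates, clamps and snaps", {
  cfg <- device_config(a3_window_end_min_ms = 700, a3_window_end_max_ms = 800)
  expect_equal(a3_window_end_for_rate(cfg, 1200), 800)
  expect_equal(a3_window_end_for_rate(cfg, 1000), 800)
  expect_equal(a3_window_end_for_rate(cfg, 600), 700)
  expect_equal(a3_window_end_for_rate(cfg, 667), 700)
  expect_equal(a3_window_end_for_rate(cfg, 833), 750)
  expect_equal(a3_window_end_for_rate(cfg, 833) %% 25, 0)
})

test_that("device configuration invariants are enforced", {
  expect_error(device_config(a4_threshold = 4, a3_threshold = 3), "exceed")
  expect_error(device_config(pvab_ms = 800, a3_window_end_min_ms = 775), "pvab")
  expect_error(device_config(a3_window_end_min_ms = 780,
                             a3_window_end_max_ms = 900), "25 ms grid")
})

test_that("run_cycle hand-trace: supra-threshold A4 raises AM then VP", {
  # A4 peak at 850 (p = 720), amp 3.0 over threshold 2.0; window end 800
  tr <- synthesize_beat(
    list(wavelet_component("A1", 3), wavelet_component("A2", 2),
         wavelet_component("A3", 2.0),
         wavelet_component("A4", 3.0, peak_time_ms = 850)),
    beat_timing(a3_signal_end_ms = 650), p_onset_ms = 720,
    duration_ms = 1250)
  out <- run_cycle(cfg_fixed(800), trace = tr, p_onset_ms = 720)
  am <- out$markers$time_ms[out$markers$kind == "AM"]
  vp <- out$markers$time_ms[out$markers$kind == "VP"]
  # first crossing of 2.0 on the rising main lobe of a 3.0 wavelet: ~843 ms
  expect_gt(am, 835); expect_lt(am, 850)
  expect_equal(vp, am + 20)
  expect_equal(out$summary$am_window, "A4")
})

test_that("run_cycle timeout path: sub-threshold A4 paces at the lower rate", {
  tr <- synthesize_beat(
    list(wavelet_component("A3", 1.5),
         wavelet_component("A4", 1.0, peak_time_ms = 850)),
    beat_timing(a3_signal_end_ms = 650), p_onset_ms = 720,
    duration_ms = 1250)
  out <- run_cycle(cfg_fixed(800), trace = tr, p_onset_ms = 720)
  expect_false("AM" %in% out$markers$kind)
  expect_equal(out$markers$time_ms[out$markers$kind == "VP"], 1200)
})

test_that("no atrial sensing occurs during PVAB", {
  # huge A1/A2 entirely inside the 550 ms blanking window
  tr <- synthesize_beat(
    list(wavelet_component("A1", 8, peak_time_ms = 100),
         wavelet_component("A2", 8, peak_time_ms = 400)),
    beat_timing(), duration_ms = 1250)
  out <- run_cycle(cfg_fixed(800, thr3 = 1.0, thr4 = 0.5), trace = tr)
  expect_false("AM" %in% out$markers$kind)
})

test_that("run_cycle rejects traces shorter than the lower-rate interval", {
  tr <- synthesize_beat(list(wavelet_component("A3", 2)), beat_timing(),
                        duration_ms = 900)
  expect_error(run_cycle(cfg_fixed(800), trace = tr), "shorter")
})

test_that("sessions honor the rate limits: UTR <= V-V <= lower-rate interval", {
  s <- flat_script(interval_ms = 545, a4_mean = 4, a4_sd = 0)  # 110 bpm
  sch <- generate_session(s, 3, "1+2", seed = 2)
  cfg <- device_config(a3_window_end_min_ms = 700, a3_window_end_max_ms = 800,
                       a3_threshold = 3.5, a4_threshold = 2.0)
  log <- run_session(cfg, sch, seed = 3)
  vv <- diff(log$cycles$v_ms)
  expect_true(all(vv >= 60000 / 105 - 1e-9))
  expect_true(all(vv <= 60000 / 50 + 1e-9))
  # exactly one ventricular event per cycle; times strictly increasing
  expect_true(all(vv > 0))
  expect_equal(sum(log$markers$kind %in% c("VP", "VS")), nrow(log$cycles))
})

test_that("no AM ever falls inside PVAB and VDI never tracks", {
  s <- flat_script()
  sch <- generate_session(s, 5, "1+2", seed = 6)
  log <- run_session(cfg_fixed(800), sch, seed = 8)
  rel <- log$cycles$am_ms - log$cycles$v_ms
  expect_true(all(rel[!is.na(rel)] >= 550))
  vdi <- run_session(cfg_fixed(800, mode = "VDI"), sch, seed = 8)
  expect_true(all(diff(vdi$cycles$v_ms) == 1200))
  expect_gt(sum(!is.na(vdi$cycles$am_ms)), 0)  # AMs recorded, not tracked
})

test_that("single-cycle detection is monotone in the thresholds", {
  set.seed(13)
  for (i in 1:10) {
    tr <- synthesize_beat(
      list(wavelet_component("A3", runif(1, 1, 4)),
           wavelet_component("A4", runif(1, 1, 5),
                             peak_time_ms = runif(1, 600, 1100))),
      beat_timing(a3_signal_end_ms = runif(1, 650, 800)),
      p_onset_ms = 500, duration_ms = 1250)
    lo <- run_cycle(cfg_fixed(800, thr3 = 2.0, thr4 = 1.0), trace = tr,
                    p_onset_ms = 500)
    hi <- run_cycle(cfg_fixed(800, thr3 = 3.5, thr4 = 2.5), trace = tr,
                    p_onset_ms = 500)
    # raising thresholds can remove but never add a detection
    if (!is.na(hi$summary$am_ms)) expect_false(is.na(lo$summary$am_ms))
  }
})

test_that("dense and event engines agree to within one sample period", {
  for (k in 1:2) {
    s <- flat_script(a3_mean = 1.8 + 0.3 * k, a4_mean = 4.2,
                     interval_ms = c(1000, 700)[k],
                     timing = beat_timing(a3_signal_end_ms = 740 + 20 * k,
                                          a3_end_variation_sd_ms = 17),
                     seed = k)
    sch <- generate_session(s, 2, "1+2", seed = 20 + k)
    cfg <- device_config(a3_window_end_min_ms = 700,
                         a3_window_end_max_ms = 800,
                         a3_threshold = 3.5, a4_threshold = 2.0)
    e <- run_session(cfg, sch, seed = 30 + k, engine = "event")
    d <- run_session(cfg, sch, seed = 30 + k, engine = "dense")
    expect_equal(nrow(e$cycles), nrow(d$cycles))
    expect_identical(is.na(e$cycles$am_ms), is.na(d$cycles$am_ms))
    expect_true(all(abs(e$cycles$am_ms - d$cycles$am_ms) <= 1, na.rm = TRUE))
    expect_true(all(abs(e$cycles$v_ms - d$cycles$v_ms) <= 1))
  }
})

test_that("event logs round-trip to CSV", {
  s <- flat_script()
  log <- run_session(cfg_fixed(800), generate_session(s, 1, "1+2", seed = 1),
                     seed = 2)
  path <- tempfile(fileext = ".csv")
  write_event_log(log, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(log$markers))
  expect_setequal(unique(df$kind), unique(log$markers$kind))
  unlink(path)
})
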