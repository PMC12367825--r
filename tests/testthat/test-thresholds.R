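test_that("the per-cycle adaptive threshold tracks the recent maximum", {
  cfg <- device_config(a4_threshold = 1.5)
  st <- auto_state(threshold = 4.0)
  # constant isolated A3 max of 2.0: converges to 2.5 within two periods
  for (i in 1:16) st <- auto_av_update(st, 2.0, cfg)
  expect_equal(st$threshold, 2.5)
  # sustained A7-contaminated maxima of 5.0 ratchet it to 5.5
  for (i in 1:8) st <- auto_av_update(st, 5.0, cfg)
  expect_equal(st$threshold, 5.5)
  # ... so a subsequent 4.5 A7 would go undetected
  expect_lt(4.5, st$threshold)
  # fewer than a full buffer leaves the threshold unchanged
  st2 <- auto_state(threshold = 3.0)
  for (i in 1:7) st2 <- auto_av_update(st2, 6.0, cfg)
  expect_equal(st2$threshold, 3.0)
  # clamps: min a4 + margin, max 6.0
  st3 <- auto_state()
  for (i in 1:8) st3 <- auto_av_update(st3, 0.1, cfg)
  expect_equal(st3$threshold, 2.0)
  for (i in 1:8) st3 <- auto_av_update(st3, 9.0, cfg)
  expect_equal(st3$threshold, 6.0)
})

test_that("histogram accumulation applies the isolated-A3 guard", {
  h <- a3_histogram()
  cs <- function(max3, am, rate, ect = FALSE, wend = 800) {
    list(a3win_max = max3, am_ms = am, wend_ms = wend, rate_bpm = rate,
         ectopic = ect)
  }
  # AM 100 ms after the window end: qualifies
  h <- av2_accumulate(h, cs(2.1, 900, 95))
  expect_equal(h$total, 1)
  # A7 cycle: AM inside the window at 95 bpm: excluded
  h <- av2_accumulate(h, cs(5.0, 700, 95))
  expect_equal(h$total, 1)
  # slow rate qualifies even with AM inside the window
  h <- av2_accumulate(h, cs(2.0, 700, 60))
  expect_equal(h$total, 2)
  # ectopic beats never qualify
  h <- av2_accumulate(h, cs(2.0, 900, 60, ect = TRUE))
  expect_equal(h$total, 2)
})

test_that("qualifying cycles all land in the right amplitude bin", {
  h <- a3_histogram()
  for (i in 1:1000) {
    h <- av2_accumulate(h, list(a3win_max = 2.1, am_ms = 900, wend_ms = 800,
                                rate_bpm = 60, ectopic = FALSE))
  }
  expect_equal(h$total, 1000)
  expect_equal(h$counts[21], 1000)   # bin (2.0, 2.1]
  expect_equal(sum(h$counts), h$total)
  # out-of-range amplitudes clip into the top bin with a warning
  expect_warning(
    h2 <- av2_accumulate(a3_histogram(),
                         list(a3win_max = 12, am_ms = 900, wend_ms = 800,
                              rate_bpm = 60, ectopic = FALSE)),
    "clipped")
  expect_equal(h2$counts[100], 1)
})

test_that("the daily update takes the nearest-rank 95th percentile plus margin", {
  h <- a3_histogram()
  for (i in 1:50) {
    h <- av2_accumulate(h, list(a3win_max = 2.1, am_ms = 900, wend_ms = 800,
                                rate_bpm = 60, ectopic = FALSE))
  }
  up <- av2_daily_update(h, margin = 1.0)
  expect_identical(up$threshold, 3.1)
  expect_equal(up$histogram$total, 0)  # reset for the next day

  # 100 distinct values 0.1 .. 10.0: nearest-rank 95th is 9.5
  h2 <- a3_histogram()
  for (v in seq(0.1, 10, by = 0.1)) {
    h2 <- av2_accumulate(h2, list(a3win_max = v - 1e-9, am_ms = 900,
                                  wend_ms = 800, rate_bpm = 60,
                                  ectopic = FALSE))
  }
  expect_equal(av2_daily_update(h2, 1.0)$threshold, 10.5)

  # margin 0 with a single stored value is the identity
  h3 <- av2_accumulate(a3_histogram(),
                       list(a3win_max = 3.3, am_ms = 900, wend_ms = 800,
                            rate_bpm = 60, ectopic = FALSE))
  expect_equal(av2_daily_update(h3, 0)$threshold, 3.3)

  # empty histogram signals no update
  expect_true(is.na(av2_daily_update(a3_histogram(), 1)$threshold))
})

test_that("histogram percentile agrees with a sort-based oracle", {
  set.seed(31)
  for (n in c(1, 3, 17, 120, 400)) {
    x <- runif(n, 0, 9.9)
    h <- a3_histogram()
    for (v in x) {
      h <- av2_accumulate(h, list(a3win_max = v, am_ms = 900, wend_ms = 800,
                                  rate_bpm = 60, ectopic = FALSE))
    }
    oracle <- sort(x)[ceiling(0.95 * n)]
    expect_lt(abs(avsim:::histogram_percentile(h, 0.95) - oracle), 0.1 + 1e-9)
  }
})

test_that("threshold trajectories: daily algorithm steps only at day boundaries", {
  s <- flat_script(a4_mean = 4.2, seed = 5,
                   timing = beat_timing(a3_signal_end_ms = 760,
                                        a3_end_variation_sd_ms = 17))
  sch <- generate_session(s, 12, "1+2", seed = 40)
  cfg <- device_config(a3_window_end_min_ms = 700, a3_window_end_max_ms = 800,
                       a3_threshold = 3.5, a4_threshold = 2.0,
                       day_length_min = 4)
  lg <- run_session(cfg, sch, threshold_algo = "autoplus", seed = 41)
  tj <- threshold_trajectory(lg)
  ch <- which(diff(tj$threshold) != 0)
  # change points only just after multiples of the day length
  day_ms <- 4 * 60000
  expect_true(all(abs(tj$time_ms[ch + 1] %% day_ms) <= 1300))
  expect_lte(length(ch), 3)
  # the per-cycle algorithm may move every 8 cycles
  la <- run_session(cfg, sch, threshold_algo = "auto", seed = 41)
  expect_gt(length(unique(la$cycles$a3_threshold)), 3)
})

test_that("paired run on an A7-undersenser: daily algorithm stays lower and syncs better", {
  sc <- make_synthetic_cohort(6, seed = 101)[[2]]
  stopifnot(sc$archetype == "a7_undersenser")
  sch <- generate_session(sc, 24, sc$best_combo, seed = 50,
                          hour_length_min = 8)
  cfg <- device_config(a3_window_end_min_ms = 700, a3_window_end_max_ms = 800,
                       a3_threshold = 3.5, a4_threshold = 2.0,
                       day_length_min = 6)
  a <- run_session(cfg, sch, threshold_algo = "auto", seed = 51)
  p <- run_session(cfg, sch, threshold_algo = "autoplus", seed = 51)
  expect_lte(mean(p$cycles$a3_threshold), mean(a$cycles$a3_threshold))
  ra <- compute_avs(a); rp <- compute_avs(p)
  expect_gt(rp$avs_80_100, ra$avs_80_100)
})
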