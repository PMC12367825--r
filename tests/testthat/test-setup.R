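mk_stats <- function(a4_medians, a3 = NULL, n = 80) {
  out <- lapply(a4_medians, function(m) {
    data.frame(a3win_max = if (is.null(a3)) runif(n, 1.5, 2.2) else a3,
               qualifies = TRUE,
               a3_end_obs_ms = runif(n, 700, 760),
               a4_obs = rep(m, n))
  })
  names(out) <- names(a4_medians)
  out
}

test_that("phase 1 picks the largest-A4 two-vector combination", {
  set.seed(1)
  st <- mk_stats(c("1+2" = 2.5, "1+3" = 3.0, "2+3" = 1.8, "1+2+3" = 3.5))
  sel <- phase1_select_vector(st, "AV2")
  expect_equal(sel$combo, "1+3")           # 1+2+3 only a fallback
  expect_equal(sel$initial_a4_threshold, 1.5)
})

test_that("phase 1 falls back to 1+2+3 when no two-vector A4 is large", {
  set.seed(2)
  st <- mk_stats(c("1+2" = 1.2, "1+3" = 1.4, "2+3" = 0.9, "1+2+3" = 1.3))
  sel <- phase1_select_vector(st, "AV2")
  expect_equal(sel$combo, "1+2+3")
  expect_equal(sel$initial_a4_threshold, 1.0)  # floor at 1.0
})

test_that("phase 1 ties break to the lowest-index combination", {
  set.seed(3)
  st <- mk_stats(c("1+2" = 3.0, "1+3" = 3.0, "2+3" = 3.0, "1+2+3" = 2.0))
  expect_equal(phase1_select_vector(st, "AV2")$combo, "1+2")
})

test_that("phase-1 thresholds: max + margin (AV) vs isolated 95th + margin (AV2)", {
  a3 <- c(rep(2.0, 90), rep(6.0, 10))   # ten A7-contaminated windows
  st <- lapply(c("1+2" = 1, "1+3" = 1, "2+3" = 1, "1+2+3" = 1), function(i) {
    data.frame(a3win_max = a3, qualifies = a3 < 3,
               a3_end_obs_ms = 720, a4_obs = 4.0)
  })
  av <- phase1_select_vector(st, "AV")
  av2 <- phase1_select_vector(st, "AV2")
  expect_equal(av$a3_threshold, 7.0)     # 6.0 + 1.0
  expect_equal(av2$a3_threshold, 3.0)    # 2.0 + 1.0 over isolated cycles
  expect_lte(av2$a3_threshold, av$a3_threshold)
  expect_equal(av$initial_window_end_ms, 725)
})

test_that("phase 2 aggregates the latest exceedance, snapped and clamped", {
  df <- data.frame(last_exceed_ms = c(rep(620, 50), 655))
  we <- phase2_window_end(df, 1.2, "AV")
  expect_equal(we$max_ms, 675)
  expect_equal(we$min_ms, 575)
  expect_false(we$flagged)
  # degenerate: no supra-threshold A3 anywhere
  d0 <- phase2_window_end(data.frame(last_exceed_ms = NA_real_), 1.2, "AV2")
  expect_true(d0$flagged)
  expect_equal(d0$min_ms, 600); expect_equal(d0$max_ms, 700)
  # clamps to [pvab + 50, 1100]
  hi <- phase2_window_end(data.frame(last_exceed_ms = 1180), 1.2, "AV")
  expect_equal(hi$max_ms, 1100)
})

test_that("a larger phase A4 threshold never lengthens the window end", {
  sc <- noisefree_script(a3 = 2.4, a4 = 4.4)
  cfg <- device_config(mode = "VDI")
  p_lo <- avsim:::with_seed(9, avsim:::simulate_setup_phase(
    sc, cfg, 2, "1+2", thr3 = 8, thr4 = 1.2, wend_ms = 800))
  p_hi <- avsim:::with_seed(9, avsim:::simulate_setup_phase(
    sc, cfg, 2, "1+2", thr3 = 8, thr4 = 2.2, wend_ms = 800))
  w_lo <- phase2_window_end(p_lo, 1.2, "AV")
  w_hi <- phase2_window_end(p_hi, 2.2, "AV2")
  expect_lte(w_hi$max_ms, w_lo$max_ms)
})

test_that("phase 3 halves the median post-window A4 with clamps", {
  f3 <- phase3_a4_threshold(data.frame(a4_obs = rep(4, 70)), 800, 3.5)
  expect_equal(f3$a4_threshold, 2.0)
  expect_equal(phase3_a4_threshold(data.frame(a4_obs = rep(1, 70)),
                                   800, 3.5)$a4_threshold, 0.8)
  expect_equal(phase3_a4_threshold(data.frame(a4_obs = rep(9, 70)),
                                   800, 3.0)$a4_threshold, 2.8)
  miss <- phase3_a4_threshold(data.frame(a4_obs = NA_real_), 800, 3.5,
                              initial_a4_threshold = 1.4)
  expect_true(miss$flagged)
  expect_equal(miss$a4_threshold, 1.4)
})

test_that("run_setup is deterministic and obeys the result invariants", {
  sc <- make_synthetic_cohort(3, seed = 101)[[2]]
  a <- suppressWarnings(run_setup("AV2", sc, durations_min = c(4, 2, 2), seed = 77))
  b <- suppressWarnings(run_setup("AV2", sc, durations_min = c(4, 2, 2), seed = 77))
  a$diagnostics <- b$diagnostics <- NULL
  expect_identical(a, b)
  expect_true(a$a3_window_end_min_ms %% 25 == 0)
  expect_true(a$a3_window_end_max_ms %% 25 == 0)
  expect_lte(a$a3_window_end_min_ms, a$a3_window_end_max_ms)
  expect_lte(a$a4_threshold, a$a3_threshold)
  expect_true(a$chosen_vector_combo %in% c("1+2", "1+3", "2+3", "1+2+3"))
  # the chosen combination is the one built as strongest
  expect_equal(a$chosen_vector_combo, sc$best_combo)
})

test_that("on a patient with A4 sweeping the window, AV2 is never longer or higher", {
  sc <- make_synthetic_cohort(3, seed = 101)[[2]]  # a7_undersenser
  av <- suppressWarnings(run_setup("AV", sc, durations_min = c(4, 2, 2), seed = 5))
  av2 <- suppressWarnings(run_setup("AV2", sc, durations_min = c(4, 2, 2), seed = 5))
  expect_lte(av2$a3_window_end_max_ms, av$a3_window_end_max_ms)
  expect_lte(av2$a3_threshold, av$a3_threshold)
  # phase 3 is shared: with identical inputs both variants agree
  p3 <- data.frame(a4_obs = rep(4.4, 80))
  expect_identical(phase3_a4_threshold(p3, 800, av$a3_threshold)$a4_threshold,
                   phase3_a4_threshold(p3, 800, av$a3_threshold)$a4_threshold)
})

test_that("noise-free parameter recovery hits the stated matching tolerances", {
  T_end <- 760; M <- 4.0
  sc <- noisefree_script(a3 = 2.2, a4 = M, a3_end = T_end)
  res <- suppressWarnings(run_setup("AV2", sc, durations_min = c(4, 2, 2), seed = 1))
  expect_lte(abs(res$a3_window_end_max_ms - T_end), 50)
  expect_lte(abs(res$a4_threshold - M / 2), 0.5)
  expect_lte(abs(res$a3_threshold - (2.2 + 1.0)), 0.5)
})

test_that("setup failures are signalled on degenerate statistics", {
  expect_error(phase1_select_vector(list(), "AV2"), "setup failure")
  st <- mk_stats(c("1+2" = 3.0, "1+3" = 2, "2+3" = 2, "1+2+3" = 2))
  st[["1+2"]]$qualifies <- FALSE
  expect_error(phase1_select_vector(st, "AV2"), "isolated")
})
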