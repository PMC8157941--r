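make_pat <- function(times_ms, pat_ms, hr_bpm, flag = "good") {
  out <- data.frame(times_ms = times_ms, pat_ms = pat_ms, hr_bpm = hr_bpm,
                    flag = flag)
  class(out) <- c("pat_series", "data.frame")
  out
}

test_that("PAT equals the simulated delay to within one PPG sample", {
  sim <- quiet_session(60, seed = 11, maternal_hr_bpm = 75, true_pat_ms = 250)
  b <- detect_r_peaks(get_stream(sim$session, "ecg"))
  p <- detect_ppg_pulses(get_stream(sim$session, "ppg_ir"))
  pat <- compute_pat(b, p)
  expect_true(all(abs(pat$pat_ms - 250) <= 1000 / 256 + 1e-6))
})

test_that("PAT matching is strict-after and skips unmatched beats", {
  r <- beat_series(c(1000, 2000, 3000), "r_peak")
  # pulse exactly at an R time is not matched to that beat
  p <- beat_series(c(1000, 2250), "ppg_pulse")
  pat <- compute_pat(r, p)
  expect_false(1000 %in% pat$times_ms)
  expect_equal(pat$pat_ms[pat$times_ms == 2000], 250)
  # alternating missing pulses: one PAT per matched beat only
  r2 <- beat_series(seq(1000, 10000, by = 1000), "r_peak")
  p2 <- beat_series(seq(1250, 10000, by = 2000), "ppg_pulse")
  pat2 <- compute_pat(r2, p2)
  expect_identical(nrow(pat2), length(p2$times_ms))
  expect_true(all(pat2$pat_ms == 250))
  expect_error(compute_pat(beat_series(c(1, 2, 3) * 1000, "r_peak"),
                           beat_series(c(500, 900), "ppg_pulse")),
               "overlap")
})

test_that("noise-free linear data is recovered exactly; constant design errors", {
  set.seed(2)
  n <- 100
  pat <- rnorm(n, 250, 20); hr <- rnorm(n, 80, 8)
  y <- -0.5 * pat + 0.3 * hr + 180
  ps <- make_pat(cumsum(rep(800, n)), pat, hr)
  ref <- data.frame(time_ms = ps$times_ms, sbp_mmhg = y)
  cal <- fit_bp_calibration(ps, ref, mode = "continuous", calib_window_ms = 70000)
  expect_equal(unname(cal$sbp), c(-0.5, 0.3, 180), tolerance = 1e-8)
  ps0 <- make_pat(cumsum(rep(800, n)), rep(250, n), rep(80, n))
  expect_error(fit_bp_calibration(ps0, ref, mode = "continuous"), "degenerate")
})

test_that("coefficients recover within 10% median error over 100 noisy draws, RMSE <= 3 mmHg", {
  set.seed(42)
  errs <- matrix(NA_real_, 100, 3)
  rmse <- numeric(100)
  for (d in 1:100) {
    a <- runif(1, -0.8, -0.2); b <- runif(1, 0.1, 0.5); cc <- runif(1, 150, 210)
    n <- 300
    pat <- rnorm(n, 250, 20); hr <- rnorm(n, 80, 8)
    y <- a * pat + b * hr + cc + rnorm(n, 0, 2)
    ps <- make_pat(cumsum(rep(750, n)), pat, hr)
    half <- 1:150
    ref <- data.frame(time_ms = ps$times_ms[half], sbp_mmhg = y[half])
    cal <- fit_bp_calibration(ps, ref, mode = "continuous",
                              calib_window_ms = diff(range(ps$times_ms[half])))
    errs[d, ] <- abs((cal$sbp - c(a, b, cc)) / c(a, b, cc))
    hold <- 151:300
    pred <- cal$sbp["a_pat"] * pat[hold] + cal$sbp["b_hr"] * hr[hold] + cal$sbp["c"]
    rmse[d] <- sqrt(mean((pred - (a * pat[hold] + b * hr[hold] + cc))^2))
  }
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
  expect_lt(stats::median(errs[, 3]), 0.10)
  expect_lte(stats::median(rmse), 3)
})

test_that("cuff-mode calibration zeroes the mean residual at the reference times", {
  set.seed(3)
  n <- 600
  tms <- cumsum(rep(800, n))
  pat <- 250 + 30 * sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, 0, 3)
  hr <- 80 + 8 * cos(seq(0, 4 * pi, length.out = n)) + rnorm(n, 0, 1)
  y <- -0.4 * pat + 0.25 * hr + 170 + rnorm(n, 0, 2)
  ps <- make_pat(tms, pat, hr)
  cuff_idx <- c(60, 200, 350, 500)
  ref <- data.frame(time_ms = tms[cuff_idx], sbp_mmhg = y[cuff_idx])
  cal <- fit_bp_calibration(ps, ref, mode = "cuff")
  pred <- predict_bp(ps, cal, smooth_window_ms = 1)$sbp
  at_ref <- vapply(ref$time_ms, function(t) {
    w <- abs(ps$times_ms - t) <= 30000
    mean(cal$sbp["a_pat"] * ps$pat_ms[w] + cal$sbp["b_hr"] * ps$hr_bpm[w] + cal$sbp["c"])
  }, numeric(1))
  expect_lt(abs(mean(at_ref - ref$sbp_mmhg)), 1e-8)
  expect_error(fit_bp_calibration(ps, ref[1, , drop = FALSE], mode = "cuff"), "2")
})

test_that("prediction at the calibration means returns the mean reference BP", {
  set.seed(4)
  n <- 200
  pat <- rnorm(n, 250, 20); hr <- rnorm(n, 80, 8)
  y <- -0.5 * pat + 0.3 * hr + 180 + rnorm(n, 0, 2)
  ps <- make_pat(cumsum(rep(800, n)), pat, hr)
  ref <- data.frame(time_ms = ps$times_ms, sbp_mmhg = y)
  cal <- fit_bp_calibration(ps, ref, mode = "continuous",
                            calib_window_ms = diff(range(ps$times_ms)))
  at_means <- make_pat(c(1000, 2000, 3000), rep(mean(pat), 3), rep(mean(hr), 3))
  pred <- predict_bp(at_means, cal, smooth_window_ms = 1)$sbp
  expect_equal(unique(round(pred$values, 6)), round(mean(y), 6))
})

test_that("predicted BP is strictly decreasing in PAT for negative a_pat at fixed HR", {
  cal <- structure(list(sbp = c(a_pat = -0.5, b_hr = 0.3, c = 180), dbp = NULL,
                        mode = "continuous", use_hr = TRUE,
                        calib_window_ms = 50000, n_ref = 100),
                   class = "bp_calibration")
  ps <- make_pat(cumsum(rep(800, 50)), seq(200, 300, length.out = 50), rep(80, 50))
  pred <- predict_bp(ps, cal, smooth_window_ms = 1)$sbp
  expect_true(all(diff(pred$values) < 0))
})

test_that("cold-pressor scenario raises predicted SBP with the right sign on every beat", {
  base <- scenario_config(duration_s = 480, maternal_hr_bpm = 80, true_pat_ms = 250,
                          sbp_mmhg = 120, dbp_mmhg = 80, noise = noiseless, seed = 4)
  cp <- cold_pressor_scenario(base)
  sim <- simulate_session(cp)
  ep <- sim$truth$cp_epoch_s
  expect_identical(length(ep), 2L)
  b <- detect_r_peaks(get_stream(sim$session, "ecg"))
  p <- detect_ppg_pulses(get_stream(sim$session, "ppg_ir"))
  pat <- compute_pat(b, p)
  # PAT minimum falls inside the epoch
  expect_true(dplyr_between <- {
    tmin <- pat$times_ms[which.min(pat$pat_ms)]
    tmin >= ep[1] * 1000 && tmin <= ep[2] * 1000
  })
  tt <- seq(0, 480000, by = 1000)
  ref <- data.frame(time_ms = tt, sbp_mmhg = sim$truth$sbp_mmhg(tt / 1000))
  cal <- fit_bp_calibration(pat, ref, mode = "continuous", calib_window_ms = 300000)
  pred <- predict_bp(pat, cal, smooth_window_ms = 5000)$sbp
  in_ep <- pred$times_ms > (ep[1] + 20) * 1000 & pred$times_ms < (ep[2] - 10) * 1000
  before <- pred$times_ms < (ep[1] - 20) * 1000
  base_mean <- mean(pred$values[before], na.rm = TRUE)
  steps <- pred$values[in_ep] - base_mean
  steps <- steps[!is.na(steps)]
  expect_gte(length(steps), 100)
  expect_true(all(steps > 0))
  # reverting the epoch restores the baseline configuration
  rv <- revert_cold_pressor(cp)
  for (f in names(base)) expect_identical(rv[[f]], base[[f]])
})

test_that("single-point-style cuff calibration holds mean error under 10 mmHg over a long session", {
  # hour-scale stationary labor session, calibrated from two early cuff reads
  set.seed(6)
  n_beats <- 4500                                  # ~1 h at 75 bpm
  tms <- cumsum(rep(800, n_beats))
  pat <- 250 + 10 * sin(seq(0, 20 * pi, length.out = n_beats)) + rnorm(n_beats, 0, 4)
  hr <- 80 + 5 * cos(seq(0, 14 * pi, length.out = n_beats)) + rnorm(n_beats, 0, 2)
  truth <- -0.4 * pat + 0.25 * hr + 170
  ps <- make_pat(tms, pat, hr)
  ref <- data.frame(time_ms = tms[c(100, 300)],
                    sbp_mmhg = truth[c(100, 300)] + rnorm(2, 0, 2))
  cal <- fit_bp_calibration(ps, ref, mode = "cuff")
  pred <- predict_bp(ps, cal, smooth_window_ms = 10000)$sbp
  expect_lte(abs(mean(pred$values - truth, na.rm = TRUE)), 10)
})
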