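test_that("noise-free R-peak detection recovers the exact beat count across 50-200 bpm", {
  for (hr in c(50, 80, 110, 140, 170, 200)) {
    sim <- quiet_session(60, seed = 7, maternal_hr_bpm = hr)
    b <- detect_r_peaks(get_stream(sim$session, "ecg"))
    truth <- sim$truth$maternal_beats_ms
    expect_identical(length(b), length(truth), label = paste("count at", hr, "bpm"))
    expect_lt(max(abs(b$times_ms - truth)), 1000 / 512 + 1e-6)
  }
})

test_that("R-peak detection at 10 dB SNR keeps sensitivity and PPV at or above 0.98", {
  sim <- quiet_session(120, seed = 3, maternal_hr_bpm = 90)
  ecg <- get_stream(sim$session, "ecg")
  set.seed(101)
  ecg$samples <- ecg$samples + stats::rnorm(length(ecg$samples),
                                            0, sqrt(mean(ecg$samples^2) / 10))
  b <- detect_r_peaks(ecg)
  mr <- match_rates(b$times_ms, sim$truth$maternal_beats_ms, 50)
  expect_gte(mr["sensitivity"], 0.98)
  expect_gte(mr["ppv"], 0.98)
})

test_that("constant ECG yields an empty series with a warning, short ECG errors", {
  flat <- sensor_stream(rep(0.3, 512 * 10), 512, "ecg", "chest")
  expect_warning(b <- detect_r_peaks(flat), "constant")
  expect_identical(length(b), 0L)
  expect_error(detect_r_peaks(sensor_stream(rnorm(512), 512, "ecg", "chest")), "5 s")
})

test_that("hr_from_beats matches brute-force 60000/mean-interval on every window", {
  set.seed(4)
  rr <- runif(120, 600, 1100)
  beats <- beat_series(cumsum(rr), "r_peak")
  win <- 15000
  hv <- hr_from_beats(beats, win)
  for (k in seq_along(hv$times_ms)) {
    s <- hv$times_ms[k] - win / 2
    w <- beats$times_ms[beats$times_ms >= s & beats$times_ms < s + win]
    expected <- if (length(w) < 2) NA_real_ else 60000 / mean(diff(w))
    expect_equal(hv$values[k], expected)
  }
})

test_that("interval-to-rate arithmetic: 635 ms -> 94 bpm, 1000 ms -> 60, 344 ms -> 174.42", {
  beats <- beat_series(seq(0, by = 635, length.out = 20), "r_peak")
  hv <- hr_from_beats(beats, 12000)
  expect_identical(unique(format_vital(hv$values, "hr_bpm")), 94)
  beats2 <- beat_series(seq(0, by = 1000, length.out = 20), "r_peak")
  expect_identical(unique(hr_from_beats(beats2, 12000)$values), 60)
  beats3 <- beat_series(seq(0, by = 344, length.out = 30), "r_peak")
  v <- unique(hr_from_beats(beats3, 6000)$values)
  expect_equal(v, 60000 / 344)
  expect_equal(round(v, 2), 174.42)
})

test_that("windows with fewer than two beats are missing", {
  beats <- beat_series(c(0, 700, 1400, 30000), "r_peak")
  hv <- hr_from_beats(beats, 5000, step_ms = 5000)
  expect_true(anyNA(hv$values))
})

test_that("PPG pulse detection recovers rate and the PAT delay to one sample", {
  sim <- quiet_session(60, seed = 5, maternal_hr_bpm = 75, true_pat_ms = 250)
  p <- detect_ppg_pulses(get_stream(sim$session, "ppg_ir"))
  truth <- sim$truth$pulse_times_ms
  rate <- 60000 / mean(diff(p$times_ms))
  expect_lte(abs(rate - 75), 1)
  nearest <- vapply(p$times_ms, function(t) min(abs(truth - t)), numeric(1))
  expect_lt(max(nearest), 1000 / 256 + 1e-6)
  flat <- sensor_stream(rep(1, 256 * 10), 256, "ppg_ir", "limb")
  expect_identical(length(detect_ppg_pulses(flat)), 0L)
})

test_that("SpO2 follows the ratio-of-ratios closed form and clamps at 100", {
  sim <- quiet_session(60, seed = 5, spo2_ratio_R = 0.5)
  s <- sim$session
  v <- compute_spo2(get_stream(s, "ppg_red"), get_stream(s, "ppg_ir"), 10000)
  expect_true(all(abs(v$values - 97.5) < 0.15))
  # R = 0.4 sits exactly on the clamp boundary (110 - 25 * 0.4 = 100)
  sim2 <- quiet_session(60, seed = 5, spo2_ratio_R = 0.4)
  v2 <- compute_spo2(get_stream(sim2$session, "ppg_red"), get_stream(sim2$session, "ppg_ir"), 10000)
  expect_true(all(v2$values >= 99.99))
  # R well below the boundary clamps exactly at 100
  sim3 <- quiet_session(30, seed = 5, spo2_ratio_R = 0.2)
  v3 <- compute_spo2(get_stream(sim3$session, "ppg_red"), get_stream(sim3$session, "ppg_ir"), 10000)
  expect_true(all(v3$values == 100))
})

test_that("SpO2 is monotone decreasing in R and missing on degenerate input", {
  vals <- vapply(c(0.4, 0.6, 0.8, 1.0, 1.5), function(R) {
    sim <- quiet_session(30, seed = 5, spo2_ratio_R = R)
    mean(compute_spo2(get_stream(sim$session, "ppg_red"),
                      get_stream(sim$session, "ppg_ir"), 10000)$values)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  sim <- quiet_session(30, seed = 5)
  red0 <- get_stream(sim$session, "ppg_red"); red0$samples[] <- 0
  expect_warning(
    v <- compute_spo2(red0, get_stream(sim$session, "ppg_ir"), 10000),
    "nonpositive")
  expect_true(all(is.na(v$values)))
})

test_that("respiratory rate recovers the breathing frequency from accel + EDR fusion", {
  sim <- quiet_session(180, seed = 5, resp_hz = 0.25)
  ecg <- get_stream(sim$session, "ecg")
  b <- detect_r_peaks(ecg)
  rr <- respiratory_rate(get_stream(sim$session, "accel"), b, ecg)
  expect_true(all(abs(rr$values - 15) <= 0.5))
  sim2 <- quiet_session(180, seed = 5, resp_hz = 0.2)
  ecg2 <- get_stream(sim2$session, "ecg")
  rr2 <- respiratory_rate(get_stream(sim2$session, "accel"), detect_r_peaks(ecg2), ecg2)
  expect_true(all(abs(rr2$values - 12) <= 0.5))
})

test_that("respiratory rate is missing without modulation and invariant to offset/gain", {
  sim <- quiet_session(180, seed = 5, resp_hz = 0.25)
  ecg <- get_stream(sim$session, "ecg")
  b <- detect_r_peaks(ecg)
  acc <- get_stream(sim$session, "accel")
  # no modulation in the respiratory band on any source
  sim0 <- simulate_session(scenario_config(duration_s = 180, seed = 5, resp_hz = 1e-4,
                                           noise = noiseless))
  ecg0 <- get_stream(sim0$session, "ecg")
  rr0 <- respiratory_rate(get_stream(sim0$session, "accel"),
                          detect_r_peaks(ecg0), ecg0)
  expect_true(all(is.na(rr0$values)))
  # DC offset and uniform gain invariance
  rr_ref <- respiratory_rate(acc, b, ecg)$values
  acc2 <- acc; acc2$samples <- acc2$samples * 3.7 + 0.5
  rr_tr <- respiratory_rate(acc2, b, ecg)$values
  expect_equal(rr_tr, rr_ref, tolerance = 1e-4)
})

test_that("temperature smoothing is identity on constants, rejects spikes, tracks ramps", {
  const <- sensor_stream(rep(36.8, 100), 0.2, "temp", "chest")
  expect_true(all(temperature_series(const)$values == 36.8))
  spiky <- sensor_stream(c(rep(36.8, 50), 40, rep(36.8, 49)), 0.2, "temp", "chest")
  expect_true(all(temperature_series(spiky)$values == 36.8))
  sim <- quiet_session(3600, seed = 5, temp_c = c(36, 38))
  tv <- temperature_series(get_stream(sim$session, "temp", "chest"))
  truth <- 36 + 2 * (tv$times_ms / 1000) / 3600
  expect_lt(max(abs(tv$values - truth)), 0.05)
})

test_that("out-of-range vitals become missing, never clipped", {
  v <- vital_series(c(0, 1, 2), c(80, 500, -5), "hr_bpm")
  expect_equal(v$values, c(80, NA, NA))
})
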