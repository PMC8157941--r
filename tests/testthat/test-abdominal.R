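test_that("Doppler envelope is zero on silence and localizes a single burst", {
  silent <- sensor_stream(rep(0, 504 * 10), 504, "doppler", "abdominal")
  env <- doppler_envelope(silent)
  expect_true(all(env$samples == 0))
  x <- rep(0, 504 * 10)
  t <- (0:(504 * 10 - 1)) / 504
  in_b <- t >= 5 & t < 5.1
  x[in_b] <- sin(2 * pi * 100 * t[in_b])
  env2 <- doppler_envelope(sensor_stream(x, 504, "doppler", "abdominal"))
  pk <- which.max(env2$samples)
  expect_true(abs(t[pk] - 5.05) < 0.1)
  expect_lt(max(env2$samples[t < 4.5 | t > 5.6]), 0.1 * max(env2$samples))
})

test_that("envelope peak count matches the S1+S2 burst count at 140 bpm", {
  sim <- quiet_session(60, seed = 5, fetal_hr_bpm = 140, s1_s2_gap_ms = 150)
  env <- doppler_envelope(get_stream(sim$session, "doppler"))
  x <- env$samples
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  pk <- pk[x[pk] > 0.25 * max(x)]
  n_truth <- 2 * length(sim$truth$fetal_beats_ms)
  expect_lte(abs(length(pk) - n_truth), 2)
})

test_that("FHR detection pairs S1/S2 and reports 140, never the doubled 280", {
  sim <- quiet_session(60, seed = 5, fetal_hr_bpm = 140, s1_s2_gap_ms = 150)
  out <- detect_fhr(doppler_envelope(get_stream(sim$session, "doppler")))
  v <- out$fhr$values[!is.na(out$fhr$values)]
  expect_gt(length(v), 0)
  expect_true(all(abs(v - 140) <= 2))
  expect_false(any(abs(v - 280) <= 30))
  expect_equal(length(out$beats$times_ms), length(sim$truth$fetal_beats_ms),
               tolerance = 0.02)
})

test_that("no doubled rate across the admissible S1-S2 gap range", {
  for (gap in c(100, 150, 200)) {
    sim <- quiet_session(40, seed = 8, fetal_hr_bpm = 130, s1_s2_gap_ms = gap)
    out <- detect_fhr(doppler_envelope(get_stream(sim$session, "doppler")))
    v <- out$fhr$values[!is.na(out$fhr$values)]
    expect_true(all(abs(v - 130) <= 3), label = paste("gap", gap))
  }
})

test_that("FHR is missing on silence and tracks a 110->180 bpm sweep within 3 bpm", {
  silent <- sensor_stream(rep(0, 504 * 30), 504, "doppler", "abdominal")
  out <- detect_fhr(doppler_envelope(silent))
  expect_true(all(is.na(out$fhr$values)))
  ramp <- function(t) 110 + (180 - 110) * t / 300
  sim <- simulate_session(scenario_config(duration_s = 300, fetal_hr_bpm = ramp,
                                          noise = noiseless, seed = 6))
  out2 <- detect_fhr(doppler_envelope(get_stream(sim$session, "doppler")))
  ok <- !is.na(out2$fhr$values)
  expect_gt(mean(ok), 0.9)
  truth <- ramp((out2$fhr$times_ms[ok]) / 1000)
  expect_lte(max(abs(out2$fhr$values[ok] - truth)), 3)
})

test_that("Doppler audio export normalizes to [-1, 1] at 504 Hz, losslessly", {
  sim <- quiet_session(20, seed = 5)
  dop <- get_stream(sim$session, "doppler")
  f <- withr::local_tempfile(fileext = ".wav")
  export_doppler_audio(dop, f)
  w <- read_wav(f)
  expect_equal(w$rate_hz, 504)
  expect_equal(max(abs(w$samples)), 1.0)
  norm <- dop$samples / max(abs(dop$samples))
  expect_lt(max(abs(w$samples - norm)), 1 / 32767 + 1e-9)
  # idempotence after the first normalization
  f2 <- withr::local_tempfile(fileext = ".wav")
  export_doppler_audio(sensor_stream(w$samples, 504, "doppler", "abdominal"), f2)
  w2 <- read_wav(f2)
  expect_lt(max(abs(w2$samples - w$samples)), 1 / 32767 + 1e-9)
  # degenerate inputs
  zeros <- sensor_stream(rep(0, 504), 504, "doppler", "abdominal")
  f3 <- withr::local_tempfile(fileext = ".wav")
  export_doppler_audio(zeros, f3)
  expect_true(all(read_wav(f3)$samples == 0))
  expect_error(export_doppler_audio(sensor_stream(numeric(0), 504, "doppler", "abdominal"), f3),
               "empty")
})

test_that("three scheduled contractions are detected with onsets within 15 s", {
  cs <- data.frame(onset_s = c(100, 280, 460), duration_s = c(60, 70, 60),
                   amplitude = c(30, 40, 35))
  sim <- simulate_session(scenario_config(duration_s = 600,
                                          contraction_schedule = cs, seed = 5))
  dc <- detect_contractions(get_stream(sim$session, "ehg1"),
                            get_stream(sim$session, "ehg2"))
  expect_identical(nrow(dc$events), 3L)
  expect_true(all(abs(dc$events$onset_ms - sim$truth$contractions$onset_ms) <= 15000))
  expect_true(all(dc$events$onset_ms < dc$events$peak_ms))
  expect_true(all(dc$events$peak_ms < dc$events$offset_ms))
})

test_that("flat EHG yields zero events; gain on both channels leaves the count unchanged", {
  flat <- sensor_stream(rep(0, 500 * 600), 500, "ehg1", "abdominal")
  flat2 <- sensor_stream(rep(0, 500 * 600), 500, "ehg2", "abdominal")
  expect_identical(nrow(detect_contractions(flat, flat2)$events), 0L)
  cs <- data.frame(onset_s = c(120, 360), duration_s = c(60, 60), amplitude = c(30, 30))
  sim <- simulate_session(scenario_config(duration_s = 600,
                                          contraction_schedule = cs, seed = 9))
  e1 <- get_stream(sim$session, "ehg1"); e2 <- get_stream(sim$session, "ehg2")
  n0 <- nrow(detect_contractions(e1, e2)$events)
  e1g <- e1; e1g$samples <- e1g$samples * 4.2
  e2g <- e2; e2g$samples <- e2g$samples * 4.2
  expect_identical(nrow(detect_contractions(e1g, e2g)$events), n0)
})

test_that("EHG calibration maps the tocogram affinely to mmHg", {
  cs <- data.frame(onset_s = 150, duration_s = 60, amplitude = 30)
  sim <- simulate_session(scenario_config(duration_s = 400,
                                          contraction_schedule = cs, seed = 5))
  e1 <- get_stream(sim$session, "ehg1"); e2 <- get_stream(sim$session, "ehg2")
  raw <- detect_contractions(e1, e2)
  cal <- ehg_calibration(gain = 2, offset = 5)
  cald <- detect_contractions(e1, e2, calib = cal)
  expect_equal(cald$tocogram$samples, 2 * raw$tocogram$samples + 5)
  expect_equal(cald$tocogram$units, "mmHg")
  expect_error(ehg_calibration(gain = -1), "gain")
})

test_that("fetal ECG isolation: recall >= 0.9 and maternal residual < 20% at amplitude ratio 0.1", {
  sim <- simulate_session(scenario_config(duration_s = 120, maternal_hr_bpm = 94.49,
                                          fetal_hr_bpm = 174.42, fetal_amp_ratio = 0.1,
                                          seed = 5))
  b <- detect_r_peaks(get_stream(sim$session, "ecg"))
  abd <- get_stream(sim$session, "ehg1")
  iso <- isolate_fetal_ecg(abd, b)
  mr <- match_rates(iso$fetal$times_ms, sim$truth$fetal_beats_ms, 50)
  expect_gte(mr["sensitivity"], 0.9)
  idx <- round(sim$truth$maternal_beats_ms / 1000 * 500) + 1
  idx <- idx[idx > 3 & idx < stream_length(abd) - 3]
  pk <- function(x) mean(vapply(idx, function(i) max(abs(x[(i - 3):(i + 3)])), numeric(1)))
  expect_lt(pk(iso$residual$samples) / pk(abd$samples), 0.2)
})

test_that("residual energy at maternal beats strictly drops; degenerate mixtures behave", {
  sim <- simulate_session(scenario_config(duration_s = 60, maternal_hr_bpm = 94.49,
                                          fetal_hr_bpm = 174.42, seed = 6))
  b <- detect_r_peaks(get_stream(sim$session, "ecg"))
  abd <- get_stream(sim$session, "ehg1")
  iso <- isolate_fetal_ecg(abd, b)
  idx <- round(sim$truth$maternal_beats_ms / 1000 * 500) + 1
  idx <- idx[idx > 3 & idx < stream_length(abd) - 3]
  en <- function(x) sum(vapply(idx, function(i) sum(x[(i - 3):(i + 3)]^2), numeric(1)))
  expect_lt(en(iso$residual$samples), en(abd$samples))
  # fetal-only mixture: residual ~ input, beats recovered
  sim0 <- simulate_session(scenario_config(duration_s = 60, maternal_hr_bpm = 94.49,
                                           fetal_hr_bpm = 174.42, maternal_abd_amp = 1e-6,
                                           fetal_amp_ratio = 1e7, noise = noiseless, seed = 6))
  bb <- detect_r_peaks(get_stream(sim0$session, "ecg"))
  abd0 <- get_stream(sim0$session, "ehg1")
  iso0 <- isolate_fetal_ecg(abd0, bb)
  expect_lt(max(abs(iso0$residual$samples - abd0$samples)),
            0.05 * max(abs(abd0$samples)))
  mr0 <- match_rates(iso0$fetal$times_ms, sim0$truth$fetal_beats_ms, 50)
  expect_gte(mr0["sensitivity"], 0.95)
  # no fetal component: empty fetal series with warning
  simM <- simulate_session(scenario_config(duration_s = 60, maternal_hr_bpm = 94.49,
                                           fetal_amp_ratio = 0, noise = noiseless, seed = 6))
  bM <- detect_r_peaks(get_stream(simM$session, "ecg"))
  expect_warning(isoM <- isolate_fetal_ecg(get_stream(simM$session, "ehg1"), bM),
                 "no fetal")
  expect_identical(length(isoM$fetal$times_ms), 0L)
  # too few maternal beats
  expect_error(isolate_fetal_ecg(get_stream(simM$session, "ehg1"),
                                 beat_series(c(1000, 2000), "r_peak")),
               "10 maternal beats")
})
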