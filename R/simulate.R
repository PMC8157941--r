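#' Scenario configuration for the session simulator
#'
#' Describes a synthetic maternal-fetal monitoring session with full ground
#' truth. Rate-like fields (`maternal_hr_bpm`, `fetal_hr_bpm`,
#' `true_pat_ms`) accept a single number, a step schedule as a two-column
#' `data.frame(start_s, value)`, or a function of time in seconds.
#'
#' @param duration_s session length in seconds.
#' @param maternal_hr_bpm maternal heart rate (bpm).
#' @param fetal_hr_bpm fetal heart rate (bpm).
#' @param fetal_amp_ratio fetal/maternal ECG amplitude ratio on the abdominal
#'   channel; the fetal ECG runs about an order of magnitude below the
#'   maternal projection, hence the default 0.1.
#' @param maternal_abd_amp amplitude of the maternal ECG projection on the
#'   abdominal biopotential channels (uV; ~100 uV is typical of surface
#'   abdominal recordings).
#' @param true_pat_ms ground-truth pulse arrival time (ms) from R-peak to PPG
#'   pulse peak.
#' @param spo2_ratio_R ground-truth ratio-of-ratios R realized by the red/IR
#'   PPG amplitudes (0.5 maps to 97.5% with the default calibration).
#' @param resp_hz respiratory frequency (Hz); 0.25 Hz = 15 breaths/min.
#' @param s1_s2_gap_ms interval between the S1 (AV-valve closure) and S2
#'   (semilunar-valve closure) Doppler sounds of each fetal beat.
#' @param posture_schedule `data.frame(start_s, posture)` with postures among
#'   supine, lateral, hands_knees, high_fowlers.
#' @param contraction_schedule `data.frame(onset_s, duration_s, amplitude)`
#'   of uterine contraction bursts (amplitude in envelope units, ~uV).
#' @param motion_schedule optional `data.frame(start_s, end_s)` of high-motion
#'   (walking-like) epochs injected into the accelerometer.
#' @param temp_c chest skin temperature: single value or `c(from, to)` linear
#'   ramp over the session.
#' @param sbp_mmhg,dbp_mmhg ground-truth systolic/diastolic pressure (number,
#'   step schedule or function), used to generate cuff/continuous references.
#' @param noise named list of additive Gaussian noise SDs per channel group:
#'   `ecg` (mV), `ppg` (fraction of DC), `accel` (g), `doppler`, `ehg` (uV),
#'   `temp` (degC). Defaults are mild, realistic noise floors.
#' @param baseline_wander logical; add 0.05 Hz baseline wander to ECG/PPG.
#' @param seed RNG seed (mandatory; the session is deterministic given it).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(duration_s = 600,
                            maternal_hr_bpm = 80,
                            fetal_hr_bpm = 140,
                            fetal_amp_ratio = 0.1,
                            maternal_abd_amp = 100,
                            true_pat_ms = 250,
                            spo2_ratio_R = 0.5,
                            resp_hz = 0.25,
                            s1_s2_gap_ms = 150,
                            posture_schedule = data.frame(start_s = 0, posture = "supine"),
                            contraction_schedule = NULL,
                            motion_schedule = NULL,
                            temp_c = 36.8,
                            sbp_mmhg = 120,
                            dbp_mmhg = 80,
                            noise = list(),
                            baseline_wander = FALSE,
                            seed = 1L) {
  noise_def <- list(ecg = 0.01, ppg = 0.001, accel = 0.01, doppler = 0.01,
                    ehg = 2, temp = 0.01)
  noise_def[names(noise)] <- noise
  if (is.null(seed)) stop("seed is mandatory for reproducible simulation")
  if (!is.null(contraction_schedule) && nrow(contraction_schedule) > 1) {
    cs <- contraction_schedule[order(contraction_schedule$onset_s), ]
    ends <- cs$onset_s + cs$duration_s
    if (any(cs$onset_s[-1] < ends[-nrow(cs)]))
      stop("contraction schedule has overlapping bursts")
  }
  structure(list(
    duration_s = duration_s, maternal_hr_bpm = maternal_hr_bpm,
    fetal_hr_bpm = fetal_hr_bpm, fetal_amp_ratio = fetal_amp_ratio,
    maternal_abd_amp = maternal_abd_amp, true_pat_ms = true_pat_ms,
    spo2_ratio_R = spo2_ratio_R, resp_hz = resp_hz,
    s1_s2_gap_ms = s1_s2_gap_ms, posture_schedule = posture_schedule,
    contraction_schedule = contraction_schedule, motion_schedule = motion_schedule,
    temp_c = temp_c, sbp_mmhg = sbp_mmhg, dbp_mmhg = dbp_mmhg,
    noise = noise_def, baseline_wander = baseline_wander,
    seed = as.integer(seed), cp_epoch = NULL
  ), class = "scenario_config")
}

# Evaluate a constant / step-schedule / function field at time t (seconds).
schedule_at <- function(spec, t) {
  if (is.function(spec)) return(spec(t))
  if (is.data.frame(spec)) {
    idx <- findInterval(t, spec[[1]])
    idx[idx < 1L] <- 1L
    return(spec[[2]][idx])
  }
  rep(spec, length(t))
}

# Event times (s) for an instantaneous rate schedule in events/min.
# Events are kept clear of the recording edge (tail_s) so every emitted
# complex is fully contained in the stream.
event_times <- function(rate_spec, duration_s, t_start = 0.35, tail_s = 0.4) {
  t <- t_start; out <- numeric(0)
  while (t < duration_s - tail_s) {
    out <- c(out, t)
    t <- t + 60 / schedule_at(rate_spec, t)
  }
  out
}

# Gaussian-sum PQRST template evaluated at offsets u (s) from the R peak.
pqrst <- function(u, width_scale = 1) {
  g <- function(a, mu, sd) a * exp(-((u - mu)^2) / (2 * (sd * width_scale)^2))
  g(0.08, -0.16, 0.025) + g(-0.10, -0.028, 0.010) + g(1.00, 0, 0.011) +
    g(-0.14, 0.030, 0.011) + g(0.22, 0.22, 0.055)
}

# Add template pulses at event times into a sampled signal (in place).
add_events <- function(sig, rate_hz, times_s, amps, fun, support_s) {
  n <- length(sig)
  for (k in seq_along(times_s)) {
    i0 <- max(1L, floor((times_s[k] - support_s[1]) * rate_hz) + 1L)
    i1 <- min(n, ceiling((times_s[k] + support_s[2]) * rate_hz) + 1L)
    if (i1 < i0) next
    u <- ((i0:i1) - 1) / rate_hz - times_s[k]
    sig[i0:i1] <- sig[i0:i1] + amps[k] * fun(u)
  }
  sig
}

# Asymmetric-Gaussian PPG pulse: peak exactly at u = 0, unit amplitude.
ppg_pulse <- function(u) {
  ifelse(u < 0, exp(-u^2 / (2 * 0.06^2)), exp(-u^2 / (2 * 0.16^2)))
}

canonical_gravity <- list(
  supine = c(0, 0, -1),
  lateral = c(1, 0, 0),
  hands_knees = c(0, 0, 1),
  high_fowlers = c(0, -sqrt(2) / 2, -sqrt(2) / 2)
)

#' Simulate a full multi-sensor session with ground truth
#'
#' Emits every stream the pipeline consumes, at the network's native rates:
#' chest ECG 512 Hz (Gaussian-sum PQRST train with respiratory amplitude
#' modulation of the R wave), chest accelerometer 52 Hz (gravity baseline per
#' scheduled posture plus a respiratory sinusoid on x/y and optional motion
#' bursts), chest and limb temperature 0.2 Hz, red/IR PPG 256 Hz (pulse waves
#' delayed by the true PAT, with AC/DC amplitudes realizing the configured
#' ratio-of-ratios), abdominal Doppler 504 Hz (Hann-windowed S1/S2 tone-burst
#' pairs per fetal beat), and two abdominal biopotential channels 500 Hz
#' (maternal ECG projection + fetal ECG at the configured amplitude ratio +
#' EHG contraction bursts). Deterministic given the config seed.
#'
#' @param config a [scenario_config()].
#' @return list of class `mfv_simulation` with elements `session`
#'   (a [synced_session()]) and `truth` (ground-truth event times, per-beat
#'   PAT, posture labels, contraction events, and reference BP).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  D <- config$duration_s
  nz <- config$noise

  m_beats <- event_times(config$maternal_hr_bpm, D)
  f_beats <- event_times(config$fetal_hr_bpm, D, t_start = 0.5)
  pat_s <- schedule_at(config$true_pat_ms, m_beats) / 1000
  pulses <- m_beats + pat_s
  breath_times <- if (0.25 / config$resp_hz <= D)
    seq(0.25 / config$resp_hz, D, by = 1 / config$resp_hz) else numeric(0)

  # chest ECG, 512 Hz, respiratory (EDR) modulation of R amplitude
  n_ecg <- round(D * 512)
  edr <- 1 + 0.15 * sin(2 * pi * config$resp_hz * m_beats)
  ecg <- add_events(numeric(n_ecg), 512, m_beats, edr, pqrst, c(0.30, 0.40))
  if (nz$ecg > 0) ecg <- ecg + stats::rnorm(n_ecg, 0, nz$ecg)
  if (config$baseline_wander)
    ecg <- ecg + 0.1 * sin(2 * pi * 0.05 * (seq_len(n_ecg) - 1) / 512)

  # limb PPG, 256 Hz; AC amplitudes realize the ratio-of-ratios R
  n_ppg <- round(D * 256)
  pshape <- add_events(numeric(n_ppg), 256, pulses, rep(1, length(pulses)),
                       ppg_pulse, c(0.25, 0.50))
  pshape <- pshape - mean(pshape)   # keep the window mean (DC) at exactly 1
  ac_ir <- 0.04
  ac_red <- config$spo2_ratio_R * ac_ir
  ppg_ir <- 1 + ac_ir * pshape
  ppg_red <- 1 + ac_red * pshape
  if (nz$ppg > 0) {
    ppg_ir <- ppg_ir + stats::rnorm(n_ppg, 0, nz$ppg)
    ppg_red <- ppg_red + stats::rnorm(n_ppg, 0, nz$ppg)
  }

  # chest accelerometer, 52 Hz: posture gravity + respiration on x/y
  n_acc <- round(D * 52)
  t_acc <- (seq_len(n_acc) - 1) / 52
  post_lab <- as.character(schedule_at(config$posture_schedule, t_acc))
  gvec <- t(vapply(post_lab, function(p) canonical_gravity[[p]], numeric(3)))
  resp_wave <- 0.03 * sin(2 * pi * config$resp_hz * t_acc)
  acc <- gvec
  acc[, 1] <- acc[, 1] + resp_wave
  acc[, 2] <- acc[, 2] + 0.7 * resp_wave
  if (nz$accel > 0) acc <- acc + matrix(stats::rnorm(3 * n_acc, 0, nz$accel), ncol = 3)
  if (!is.null(config$motion_schedule)) {
    for (r in seq_len(nrow(config$motion_schedule))) {
      in_ep <- t_acc >= config$motion_schedule$start_s[r] & t_acc < config$motion_schedule$end_s[r]
      acc[in_ep, ] <- acc[in_ep, ] + matrix(stats::rnorm(3 * sum(in_ep), 0, 0.5), ncol = 3)
    }
  }
  colnames(acc) <- c("x", "y", "z")

  # skin temperature, 0.2 Hz (chest; limb runs ~0.5 degC cooler)
  n_tmp <- max(1, round(D * 0.2))
  t_tmp <- (seq_len(n_tmp) - 1) * 5
  tc <- config$temp_c
  temp_chest <- if (length(tc) == 2) tc[1] + (tc[2] - tc[1]) * t_tmp / D else rep(tc[1], n_tmp)
  if (nz$temp > 0) temp_chest <- temp_chest + stats::rnorm(n_tmp, 0, nz$temp)
  temp_limb <- temp_chest - 0.5

  # abdominal Doppler, 504 Hz: S1 (50 ms, 90 Hz) + S2 (30 ms, 110 Hz) bursts
  n_dop <- round(D * 504)
  burst <- function(dur_s, f_hz) {
    function(u) {
      w <- numeric(length(u))
      in_b <- u >= 0 & u <= dur_s
      w[in_b] <- sin(pi * u[in_b] / dur_s)^2 * sin(2 * pi * f_hz * u[in_b])
      w
    }
  }
  dop <- add_events(numeric(n_dop), 504, f_beats, rep(1, length(f_beats)),
                    burst(0.050, 90), c(0, 0.055))
  dop <- add_events(dop, 504, f_beats + config$s1_s2_gap_ms / 1000,
                    rep(0.8, length(f_beats)), burst(0.030, 110), c(0, 0.035))
  if (nz$doppler > 0) dop <- dop + stats::rnorm(n_dop, 0, nz$doppler)

  # abdominal biopotential, 500 Hz x2: maternal + fetal ECG + EHG bursts
  n_abd <- round(D * 500)
  t_abd <- (seq_len(n_abd) - 1) / 500
  mk_abd <- function(m_gain, f_gain) {
    x <- add_events(numeric(n_abd), 500, m_beats,
                    rep(config$maternal_abd_amp * m_gain, length(m_beats)),
                    pqrst, c(0.30, 0.40))
    x <- add_events(x, 500, f_beats,
                    rep(config$maternal_abd_amp * config$fetal_amp_ratio * f_gain, length(f_beats)),
                    function(u) pqrst(u, width_scale = 0.6), c(0.20, 0.26))
    x
  }
  ehg1 <- mk_abd(1.0, 1.0)
  ehg2 <- mk_abd(0.8, 0.9)
  truth_contr <- NULL
  if (!is.null(config$contraction_schedule)) {
    cs <- config$contraction_schedule
    for (r in seq_len(nrow(cs))) {
      on <- cs$onset_s[r]; du <- cs$duration_s[r]; am <- cs$amplitude[r]
      in_c <- t_abd >= on & t_abd <= on + du
      u <- (t_abd[in_c] - on) / du
      env <- tukey_win(u, 0.25)
      osc <- sin(2 * pi * 0.5 * t_abd[in_c]) + 0.5 * sin(2 * pi * 0.71 * t_abd[in_c] + 1)
      ehg1[in_c] <- ehg1[in_c] + am * env * osc
      ehg2[in_c] <- ehg2[in_c] + 0.9 * am * env * osc
    }
    truth_contr <- data.frame(onset_ms = cs$onset_s * 1000,
                              peak_ms = (cs$onset_s + cs$duration_s / 2) * 1000,
                              offset_ms = (cs$onset_s + cs$duration_s) * 1000,
                              amplitude = cs$amplitude)
  }
  if (nz$ehg > 0) {
    ehg1 <- ehg1 + stats::rnorm(n_abd, 0, nz$ehg)
    ehg2 <- ehg2 + stats::rnorm(n_abd, 0, nz$ehg)
  }

  streams <- list(
    sensor_stream(ecg, 512, "ecg", "chest", units = "mV"),
    sensor_stream(acc, 52, "accel", "chest", units = "g"),
    sensor_stream(temp_chest, 0.2, "temp", "chest", units = "degC"),
    sensor_stream(temp_limb, 0.2, "temp", "limb", units = "degC"),
    sensor_stream(ppg_red, 256, "ppg_red", "limb", units = "adu"),
    sensor_stream(ppg_ir, 256, "ppg_ir", "limb", units = "adu"),
    sensor_stream(dop, 504, "doppler", "abdominal", units = "au"),
    sensor_stream(ehg1, 500, "ehg1", "abdominal", units = "uV"),
    sensor_stream(ehg2, 500, "ehg2", "abdominal", units = "uV")
  )

  truth <- list(
    maternal_beats_ms = m_beats * 1000,
    fetal_beats_ms = f_beats * 1000,
    pulse_times_ms = pulses * 1000,
    breath_times_ms = breath_times * 1000,
    pat_ms = pat_s * 1000,
    spo2_ratio_R = config$spo2_ratio_R,
    resp_brpm = config$resp_hz * 60,
    posture = data.frame(time_ms = t_acc * 1000, posture = post_lab,
                         stringsAsFactors = FALSE),
    contractions = truth_contr,
    sbp_mmhg = function(t_s) schedule_at(config$sbp_mmhg, t_s),
    dbp_mmhg = function(t_s) schedule_at(config$dbp_mmhg, t_s),
    cp_epoch_s = config$cp_epoch
  )
  structure(list(session = synced_session(streams), truth = truth,
                 config = config), class = "mfv_simulation")
}

# Tukey (tapered-cosine) window on u in [0, 1] with taper fraction alpha.
tukey_win <- function(u, alpha = 0.25) {
  w <- rep(1, length(u))
  lo <- u < alpha / 2
  hi <- u > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - u[hi]) / alpha - 1)))
  w[u < 0 | u > 1] <- 0
  w
}

#' Derive a cold-pressor variant of a scenario
#'
#' Inserts one 120-s epoch in the middle of the session during which PAT
#' drops by 15%, HR rises by 10 bpm and ground-truth systolic pressure rises
#' by 20 mmHg (diastolic by 10 mmHg) — the stereotyped hemodynamic response
#' to cold-pressor stimulation used to exercise the PAT-to-BP chain.
#'
#' @param baseline a [scenario_config()] with constant (scalar) HR, PAT and
#'   BP fields.
#' @return a modified `scenario_config` with the epoch recorded in
#'   `$cp_epoch`.
#' @export
cold_pressor_scenario <- function(baseline) {
  stopifnot(inherits(baseline, "scenario_config"))
  for (f in c("maternal_hr_bpm", "true_pat_ms", "sbp_mmhg", "dbp_mmhg"))
    if (!is.numeric(baseline[[f]]) || length(baseline[[f]]) != 1)
      stop("cold_pressor_scenario needs scalar ", f)
  mid <- baseline$duration_s / 2
  ep <- c(mid - 60, mid + 60)
  step3 <- function(v0, v1) data.frame(start_s = c(0, ep[1], ep[2]), value = c(v0, v1, v0))
  cfg <- baseline
  cfg$true_pat_ms <- step3(baseline$true_pat_ms, baseline$true_pat_ms * 0.85)
  cfg$maternal_hr_bpm <- step3(baseline$maternal_hr_bpm, baseline$maternal_hr_bpm + 10)
  cfg$sbp_mmhg <- step3(baseline$sbp_mmhg, baseline$sbp_mmhg + 20)
  cfg$dbp_mmhg <- step3(baseline$dbp_mmhg, baseline$dbp_mmhg + 10)
  cfg$cp_epoch <- ep
  cfg
}

#' Revert a cold-pressor scenario to its baseline
#' @param config a scenario produced by [cold_pressor_scenario()].
#' @return the baseline `scenario_config`.
#' @export
revert_cold_pressor <- function(config) {
  stopifnot(inherits(config, "scenario_config"), !is.null(config$cp_epoch))
  for (f in c("maternal_hr_bpm", "true_pat_ms", "sbp_mmhg", "dbp_mmhg"))
    config[[f]] <- config[[f]]$value[1]
  config$cp_epoch <- NULL
  config
}
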