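#' Heart rate from detected beats
#'
#' Sliding-window rate: HR = 60000 / mean(R-R interval in ms) over each
#' window, using good-quality beats only. Windows with fewer than two usable
#' beats yield a missing value. Values are kept unrounded; use
#' [format_vital()] for the clinical display channel.
#'
#' @param beats a [beat_series()].
#' @param window_ms window length (ms).
#' @param step_ms hop between windows (ms); defaults to half the window.
#' @return a [vital_series()] of `hr_bpm` (timestamps at window centers).
#' @export
hr_from_beats <- function(beats, window_ms, step_ms = window_ms / 2) {
  t <- beats$times_ms[beats$quality == "good"]
  if (!length(beats$times_ms)) return(vital_series(numeric(0), numeric(0), "hr_bpm", window_ms))
  span <- range(beats$times_ms)
  starts <- seq(span[1], max(span[1], span[2] - window_ms), by = step_ms)
  vals <- vapply(starts, function(s) {
    w <- t[t >= s & t < s + window_ms]
    if (length(w) < 2) return(NA_real_)
    60000 / mean(diff(w))
  }, numeric(1))
  vital_series(starts + window_ms / 2, vals, "hr_bpm", window_ms)
}

#' Detect PPG pulse peaks
#'
#' Band-passes the photoplethysmogram to the cardiac band, picks prominent
#' maxima with a refractory period, and refines each to the raw-signal pulse
#' peak (the default fiducial; the systolic foot can be selected for
#' pulse-arrival-time robustness work).
#'
#' @param ppg a PPG [sensor_stream()] (red or IR, canonically 256 Hz).
#' @param fiducial `"peak"` (default) or `"foot"` (intersecting-tangent
#'   approximation: the minimum preceding the peak).
#' @param band_hz cardiac pass band.
#' @param refractory_ms minimum pulse separation.
#' @return a [beat_series()] of kind `ppg_pulse`.
#' @export
detect_ppg_pulses <- function(ppg, fiducial = c("peak", "foot"),
                              band_hz = c(0.5, 8), refractory_ms = 270) {
  fiducial <- match.arg(fiducial)
  fs <- ppg$rate_hz
  x <- ppg$samples
  if (length(x) < 5 * fs) stop("need at least 5 s of PPG")
  if (stats::sd(x[is.finite(x)]) == 0) return(beat_series(numeric(0), "ppg_pulse"))
  bp <- bandpass(x, fs, band_hz, 2)
  pk <- local_maxima(bp)
  # filter start-up transients: a pulse cannot be resolved at the record edge
  edge <- round(0.3 * fs)
  pk <- pk[pk > edge & pk <= length(x) - round(0.1 * fs)]
  if (!length(pk)) return(beat_series(numeric(0), "ppg_pulse"))
  thr <- 0.3 * stats::quantile(bp[pk], 0.9, names = FALSE)
  pk <- pk[bp[pk] > thr]
  refr <- round(refractory_ms / 1000 * fs)
  keep <- integer(0)
  for (i in pk) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (bp[i] > bp[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  w <- round(0.12 * fs)
  raw <- x; raw[!is.finite(raw)] <- -Inf
  n <- length(x)
  idx <- vapply(keep, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    lo + which.max(raw[lo:hi]) - 1L
  }, numeric(1))
  if (fiducial == "foot") {
    fw <- round(0.35 * fs)
    raw_min <- x; raw_min[!is.finite(raw_min)] <- Inf
    idx <- vapply(idx, function(i) {
      lo <- max(1L, i - fw)
      lo + which.min(raw_min[lo:i]) - 1L
    }, numeric(1))
  }
  idx <- sort(unique(idx))
  beat_series(ppg$t0_ms + (idx - 1) * 1000 / fs, "ppg_pulse")
}

#' SpO2 by the ratio-of-ratios method
#'
#' Per window, the pulsatile (AC, peak-to-trough of detected pulses) and
#' baseline (DC, window mean) components of each wavelength give
#' R = (AC_red/DC_red) / (AC_ir/DC_ir), mapped through the linear empirical
#' calibration SpO2 = c0 - c1 * R and clamped to [0, 100]. The default
#' coefficients (c0 = 110, c1 = 25) are the conventional empirical curve and
#' are overridable, as device-specific coefficients always are.
#'
#' @param red,ir red and infrared PPG [sensor_stream()]s (time-overlapping).
#' @param window_ms averaging window (ms).
#' @param c0,c1 linear calibration coefficients.
#' @param pulses optional precomputed [beat_series()] of PPG pulses; detected
#'   on the IR channel when omitted.
#' @return a [vital_series()] of `spo2_pct`.
#' @export
compute_spo2 <- function(red, ir, window_ms = 10000, c0 = 110, c1 = 25, pulses = NULL) {
  t_red <- stream_times_ms(red); t_ir <- stream_times_ms(ir)
  lo <- max(t_red[1], t_ir[1]); hi <- min(t_red[length(t_red)], t_ir[length(t_ir)])
  if (hi <= lo) stop("red and IR channels do not overlap in time")
  if (is.null(pulses)) {
    pulses <- tryCatch(detect_ppg_pulses(ir), error = function(e) beat_series(numeric(0), "ppg_pulse"))
  }
  starts <- seq(lo, max(lo, hi - window_ms), by = window_ms)
  pulse_amps <- function(stream, p_ms) {
    idx <- round((p_ms - stream$t0_ms) / 1000 * stream$rate_hz) + 1L
    idx <- idx[idx >= 1 & idx <= stream_length(stream)]
    if (length(idx) < 2) return(NULL)
    vapply(2:length(idx), function(k) {
      seg <- stream$samples[idx[k - 1L]:idx[k]]
      stream$samples[idx[k]] - min(seg, na.rm = TRUE)
    }, numeric(1))
  }
  degenerate <- FALSE
  vals <- vapply(starts, function(s) {
    in_w <- function(t) t >= s & t < s + window_ms
    dc_r <- mean(red$samples[in_w(t_red)], na.rm = TRUE)
    dc_i <- mean(ir$samples[in_w(t_ir)], na.rm = TRUE)
    if (!is.finite(dc_r) || !is.finite(dc_i) || dc_r <= 0 || dc_i <= 0) {
      degenerate <<- TRUE
      return(NA_real_)
    }
    p_ms <- pulses$times_ms[in_w(pulses$times_ms)]
    if (length(p_ms) < 2) return(NA_real_)
    ar <- pulse_amps(red, p_ms); ai <- pulse_amps(ir, p_ms)
    if (is.null(ar) || is.null(ai)) return(NA_real_)
    ac_r <- mean(ar); ac_i <- mean(ai)
    if (!is.finite(ac_i) || ac_i <= 0) return(NA_real_)
    R <- (ac_r / dc_r) / (ac_i / dc_i)
    max(0, min(100, c0 - c1 * R))
  }, numeric(1))
  if (degenerate) warning("nonpositive DC component in an SpO2 window; values set missing")
  vital_series(starts + window_ms / 2, vals, "spo2_pct", window_ms)
}

# Dominant frequency of x (sampled at fs) within [f_lo, f_hi], by
# zero-padded periodogram with parabolic peak interpolation.
# Returns c(freq_hz, quality) where quality is the fraction of in-band power
# within +-0.05 Hz of the peak.
dominant_freq <- function(x, fs, f_lo = 0.1, f_hi = 1.0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0) return(c(NA_real_, 0))
  # linear detrend so slow drift does not masquerade as a band-edge peak
  x <- stats::.lm.fit(cbind(1, seq_len(n)), x)$residuals
  nfft <- 2^ceiling(log2(n * 8))
  sp <- abs(stats::fft(c(x * signal::hanning(n), numeric(nfft - n))))^2
  f <- (seq_len(nfft) - 1) * fs / nfft
  band <- which(f >= f_lo & f <= f_hi)
  if (length(band) < 3) return(c(NA_real_, 0))
  p <- sp[band]
  k <- which.max(p)
  # parabolic interpolation around the peak bin
  kk <- band[k]
  if (kk > 1 && kk < nfft) {
    a <- sp[kk - 1]; b <- sp[kk]; cc <- sp[kk + 1]
    d <- (a - cc) / (2 * (a - 2 * b + cc + 1e-300))
    fpk <- f[kk] + d * fs / nfft
  } else fpk <- f[kk]
  near <- abs(f[band] - fpk) <= 0.05
  qual <- sum(p[near]) / sum(p)
  c(fpk, qual)
}

# weighted median
wmedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Respiratory rate by accelerometer/ECG fusion
#'
#' Three estimators per window: dominant respiratory-band (0.1-1.0 Hz)
#' frequency of the x and y chest-accelerometer axes (chest-wall movement),
#' and of the ECG-derived respiration signal (beat-to-beat R-amplitude
#' modulation). Estimates whose spectral concentration falls below the
#' quality gate are dropped; the rest are fused by quality-weighted median.
#' Invariant to accelerometer DC offset and uniform axis gain.
#'
#' @param accel chest accelerometer [sensor_stream()] with `x` and `y`
#'   columns (52 Hz vitals stream by default; the 416 Hz IMU stream is
#'   accepted and decimated, the respiratory band being far below either
#'   Nyquist).
#' @param beats maternal R-peak [beat_series()] (for the EDR estimator).
#' @param ecg the chest ECG [sensor_stream()] the beats came from.
#' @param window_ms analysis window, at least 30 s.
#' @param step_ms hop between windows.
#' @param quality_gate minimum spectral concentration to accept an estimate.
#' @return a [vital_series()] of `rr_brpm`.
#' @export
respiratory_rate <- function(accel, beats, ecg, window_ms = 60000,
                             step_ms = window_ms / 2, quality_gate = 0.35) {
  if (window_ms < 30000) stop("respiratory window must be at least 30 s")
  if (!is.matrix(accel$samples) || !all(c("x", "y") %in% colnames(accel$samples)))
    stop("accel stream must have x and y columns")
  fs_tgt <- 4
  acc4 <- resample(accel, fs_tgt)
  t4 <- stream_times_ms(acc4)
  edr_t <- beats$times_ms
  edr_a <- numeric(0)
  if (length(edr_t) >= 4) {
    idx <- round((edr_t - ecg$t0_ms) / 1000 * ecg$rate_hz) + 1L
    ok <- idx >= 1 & idx <= stream_length(ecg)
    edr_t <- edr_t[ok]
    edr_a <- ecg$samples[idx[ok]]
  }
  span <- range(t4)
  starts <- seq(span[1], max(span[1], span[2] - window_ms), by = step_ms)
  vals <- vapply(starts, function(s) {
    in_w <- t4 >= s & t4 < s + window_ms
    ests <- c(); wts <- c()
    est_one <- function(xw) {
      xw <- xw[is.finite(xw)]
      if (length(xw) < 16 || stats::sd(xw) == 0) return(NULL)
      detr <- stats::.lm.fit(cbind(1, seq_along(xw)), xw)$residuals
      if (stats::var(detr) == 0) return(NULL)
      xb <- bandpass(xw, fs_tgt, c(0.1, 1.0), 3)
      # in-band power must be a real fraction of the window's variance,
      # otherwise sub-band drift masquerades as a clean narrow-band peak
      if (stats::var(xb) < 0.05 * stats::var(detr)) return(NULL)
      dq <- dominant_freq(xb, fs_tgt)
      if (!is.finite(dq[1]) || dq[2] < quality_gate) return(NULL)
      # peaks hugging the lower band edge within the window's spectral
      # resolution are drift leakage, not breathing
      if (dq[1] < 0.1 + 2000 / window_ms) return(NULL)
      dq
    }
    for (ax in c("x", "y")) {
      dq <- est_one(acc4$samples[in_w, ax])
      if (!is.null(dq)) { ests <- c(ests, dq[1] * 60); wts <- c(wts, dq[2]) }
    }
    if (length(edr_a) >= 4) {
      in_b <- edr_t >= s & edr_t < s + window_ms
      if (sum(in_b) >= 6) {
        tt <- edr_t[in_b]
        grid <- seq(tt[1], tt[length(tt)], by = 1000 / fs_tgt)
        e4 <- stats::approx(tt, edr_a[in_b], xout = grid)$y
        dq <- est_one(e4)
        if (!is.null(dq)) { ests <- c(ests, dq[1] * 60); wts <- c(wts, dq[2]) }
      }
    }
    if (!length(ests)) return(NA_real_)
    wmedian(ests, wts)
  }, numeric(1))
  vital_series(starts + window_ms / 2, vals, "rr_brpm", window_ms)
}

#' Smoothed skin-temperature trend
#'
#' Moving-median smoothing of the 0.2 Hz temperature channel; robust to
#' single-sample spikes. Chest (central) and limb (peripheral) streams are
#' smoothed separately by calling this once per stream.
#'
#' @param temp a temperature [sensor_stream()] (0.2 Hz canonical).
#' @param smooth_window_ms median window (ms); defaults to 5 minutes.
#' @return a [vital_series()] of `temp_c`.
#' @export
temperature_series <- function(temp, smooth_window_ms = 300000) {
  x <- temp$samples
  n <- length(x)
  k <- max(1L, round(smooth_window_ms / 1000 * temp$rate_hz))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  sm <- if (k >= 3 && n >= 3) as.numeric(stats::runmed(x, k, endrule = "median")) else x
  vital_series(stream_times_ms(temp), sm, "temp_c", smooth_window_ms)
}
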