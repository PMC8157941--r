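#' Fetal beat series with S1/S2 valve-sound pairing
#'
#' One fetal heartbeat is a pair of Doppler-audible valve closures: S1
#' (tricuspid/mitral) followed 80-250 ms later by S2 (pulmonary semilunar).
#' Beat times are the S1 times of accepted pairs.
#'
#' @param times_ms beat times (ms), one per S1-S2 pair.
#' @param s1_times_ms,s2_times_ms the paired valve-sound times.
#' @param quality per-beat flag.
#' @export
fetal_beat_series <- function(times_ms, s1_times_ms = times_ms,
                              s2_times_ms = numeric(0), quality = NULL) {
  if (is.null(quality)) quality <- rep("good", length(times_ms))
  structure(list(times_ms = as.double(times_ms),
                 s1_times_ms = as.double(s1_times_ms),
                 s2_times_ms = as.double(s2_times_ms),
                 quality = quality),
            class = c("fetal_beat_series", "beat_series"))
}

#' Affine EHG-to-pressure calibration
#'
#' Maps the electrohysterogram envelope (arbitrary units) to mmHg against a
#' reference tocodynamometer segment: pressure = gain * envelope + offset.
#'
#' @param gain mmHg per envelope unit (> 0).
#' @param offset mmHg baseline.
#' @export
ehg_calibration <- function(gain, offset = 0) {
  if (!is.numeric(gain) || gain <= 0) stop("calibration gain must be > 0")
  structure(list(gain = gain, offset = offset), class = "ehg_calibration")
}

#' Rectified low-pass envelope of the Doppler signal
#'
#' Full-wave rectification followed by a zero-phase low-pass below 30 Hz at
#' the native rate. Raw audio-band Doppler and pre-enveloped signals are
#' auto-detected by spectral content (a pre-enveloped trace has little power
#' above 40 Hz and skips rectification); the heuristic can be overridden.
#'
#' @param doppler an abdominal Doppler [sensor_stream()] (504 Hz canonical).
#' @param cutoff_hz envelope low-pass cutoff.
#' @param input `"auto"`, `"raw"` (rectify) or `"envelope"` (pass through
#'   the low-pass only).
#' @return a [sensor_stream()] holding the envelope.
#' @export
doppler_envelope <- function(doppler, cutoff_hz = 30, input = c("auto", "raw", "envelope")) {
  input <- match.arg(input)
  fs <- doppler$rate_hz
  x <- doppler$samples
  if (length(x) < 5 * fs) stop("need at least 5 s of Doppler signal")
  x[!is.finite(x)] <- 0
  if (input == "auto") {
    if (stats::sd(x) == 0) {
      input <- "raw"
    } else {
      sp <- abs(stats::fft(x - mean(x)))^2
      f <- (seq_along(sp) - 1) * fs / length(sp)
      half <- f <= fs / 2
      hf <- sum(sp[half & f > 40]) / sum(sp[half])
      input <- if (hf > 0.2) "raw" else "envelope"
    }
  }
  env <- if (input == "raw") abs(x) else x
  if (stats::sd(env) > 0) {
    bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
    env <- as.numeric(signal::filtfilt(bf, env))
    env[env < 0] <- 0
  }
  out <- doppler
  out$samples <- env
  out$label <- paste0(doppler$label, "_env")
  out
}

#' Fetal heart rate from the Doppler envelope
#'
#' Envelope peaks are paired into S1/S2 doublets by a greedy nearest-gap rule
#' with the physiological S1-S2 prior (80-250 ms), preventing each beat's two
#' valve sounds from being counted as two beats. The beat period itself is
#' confirmed by windowed autocorrelation of the envelope (3.75-s windows,
#' 0.25-s step by cardiotocography convention), searched over the fetal band
#' (60-240 bpm); windows whose normalized autocorrelation peak falls below
#' the confidence threshold report a missing rate. FHR = 60000 / period.
#'
#' @param envelope output of [doppler_envelope()].
#' @param window_ms autocorrelation window (ms).
#' @param step_ms hop between windows (ms).
#' @param conf_threshold minimum normalized autocorrelation peak.
#' @param gap_ms admissible S1-to-S2 interval (ms).
#' @param fhr_range_bpm physiological fetal rate band.
#' @return list with `beats` (a [fetal_beat_series()]) and `fhr`
#'   (a [vital_series()] of `fhr_bpm`).
#' @export
detect_fhr <- function(envelope, window_ms = 3750, step_ms = 250,
                       conf_threshold = 0.45, gap_ms = c(80, 250),
                       fhr_range_bpm = c(60, 240)) {
  fs <- envelope$rate_hz
  x <- envelope$samples
  x[!is.finite(x)] <- 0
  n <- length(x)
  t_ms <- stream_times_ms(envelope)

  # --- windowed autocorrelation -> period and confidence per window
  lag_lo <- floor(60000 / fhr_range_bpm[2] / 1000 * fs)
  lag_hi <- ceiling(60000 / fhr_range_bpm[1] / 1000 * fs)
  w <- round(window_ms / 1000 * fs)
  hop <- max(1L, round(step_ms / 1000 * fs))
  starts <- seq(1L, max(1L, n - w + 1L), by = hop)
  fhr_t <- fhr_v <- numeric(length(starts))
  per_smp <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(min(n, starts[k] + w - 1L))]
    fhr_t[k] <- t_ms[starts[k]] + window_ms / 2
    if (length(seg) < lag_hi + 2 || stats::sd(seg) == 0) { fhr_v[k] <- NA; next }
    seg <- seg - mean(seg)
    ac <- stats::acf(seg, lag.max = lag_hi, plot = FALSE, demean = FALSE)$acf[, 1, 1]
    idx <- (lag_lo + 1L):(lag_hi + 1L)
    pk <- idx[which.max(ac[idx])]
    conf <- ac[pk] / ac[1]
    if (!is.finite(conf) || conf < conf_threshold) { fhr_v[k] <- NA; next }
    lag <- pk - 1L
    if (lag > 1L && lag < lag_hi) {          # parabolic refinement
      a <- ac[pk - 1]; b <- ac[pk]; cc <- ac[pk + 1]
      lag <- lag + (a - cc) / (2 * (a - 2 * b + cc + 1e-300))
    }
    per_smp[k] <- lag
    fhr_v[k] <- 60000 / (lag / fs * 1000)
  }

  # --- peak picking and S1/S2 pairing
  pk <- local_maxima(x)
  if (length(pk)) {
    thr <- 0.25 * stats::quantile(x[pk], 0.95, names = FALSE)
    pk <- pk[x[pk] > thr]
    # collapse plateaus / ripples closer than 50 ms, keeping the larger
    min_sep <- round(0.05 * fs)
    keep <- integer(0)
    for (i in pk) {
      if (length(keep) && i - keep[length(keep)] < min_sep) {
        if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    pk <- keep
  }
  s1 <- s2 <- numeric(0)
  used <- rep(FALSE, length(pk))
  glo <- gap_ms[1] / 1000 * fs; ghi <- gap_ms[2] / 1000 * fs
  k <- 1L
  while (k <= length(pk)) {
    if (used[k]) { k <- k + 1L; next }
    j <- k + 1L
    mate <- NA_integer_
    while (j <= length(pk) && (pk[j] - pk[k]) <= ghi) {
      if (!used[j] && (pk[j] - pk[k]) >= glo) { mate <- j; break }
      j <- j + 1L
    }
    if (!is.na(mate)) {
      s1 <- c(s1, pk[k]); s2 <- c(s2, pk[mate])
      used[k] <- used[mate] <- TRUE
    }
    k <- k + 1L
  }
  beats <- fetal_beat_series(t_ms[s1], t_ms[s1], t_ms[s2])
  list(beats = beats,
       fhr = vital_series(fhr_t, fhr_v, "fhr_bpm", window_ms))
}

#' Export the Doppler signal as audio
#'
#' Normalizes the signal so that the largest absolute sample is 1 (all-zero
#' input stays zero) and writes a lossless PCM WAV file encoded at the
#' sensor's original 504 Hz sampling rate, replicating the audible Doppler
#' output of a bedside monitor.
#'
#' @param doppler an abdominal Doppler [sensor_stream()].
#' @param path output `.wav` path.
#' @return the path, invisibly; attributes `peak` (pre-normalization max
#'   |sample|) and `rate_hz` record what was encoded.
#' @export
export_doppler_audio <- function(doppler, path) {
  x <- doppler$samples
  if (!length(x)) stop("cannot export an empty Doppler stream")
  x[!is.finite(x)] <- 0
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  write_wav(x, doppler$rate_hz, path)
  out <- structure(path, peak = peak, rate_hz = doppler$rate_hz)
  invisible(out)
}

#' Detect uterine contractions from two-channel EHG
#'
#' Each channel is restricted to the electrohysterography band
#' (0.34-1.0 Hz, after decimation to 10 Hz), converted to a 60-s RMS
#' envelope, and the two channels fused by pointwise maximum. A
#' baseline-adaptive threshold (running median plus a multiple of the MAD)
#' marks candidate events; each event's onset and offset are then refined to
#' the half-height crossings of its own envelope peak, which undoes the
#' smearing of the RMS window. The fused envelope is returned as a tocogram,
#' mapped to mmHg when a calibration is supplied.
#'
#' @param ehg_ch1,ehg_ch2 abdominal biopotential [sensor_stream()]s (500 Hz
#'   canonical; the two electrode pairs are interchangeable).
#' @param calib optional [ehg_calibration()].
#' @param band_hz EHG band (Hz).
#' @param rms_window_s RMS envelope window (s).
#' @param threshold_k MAD multiplier over the running-median baseline.
#' @param min_duration_s,max_duration_s plausible contraction duration
#'   bounds; out-of-band events are flagged, not dropped.
#' @return list with `events` (data.frame onset_ms, peak_ms, offset_ms,
#'   amplitude, flag) and `tocogram` (a [sensor_stream()]).
#' @export
detect_contractions <- function(ehg_ch1, ehg_ch2, calib = NULL,
                                band_hz = c(0.34, 1.0), rms_window_s = 60,
                                threshold_k = 6, min_duration_s = 30,
                                max_duration_s = 300) {
  fs10 <- 10
  env_one <- function(s) {
    x <- s$samples; x[!is.finite(x)] <- 0
    s$samples <- x
    d <- resample(s, fs10)
    if (stats::sd(d$samples) == 0) return(list(t = stream_times_ms(d), e = d$samples * 0))
    bf <- signal::butter(3, band_hz / (fs10 / 2), type = "pass")
    b <- as.numeric(signal::filtfilt(bf, d$samples))
    w <- round(rms_window_s * fs10)
    e <- sqrt(moving_mean(b^2, w))
    e[is.na(e)] <- 0
    list(t = stream_times_ms(d), e = e)
  }
  e1 <- env_one(ehg_ch1); e2 <- env_one(ehg_ch2)
  n <- min(length(e1$e), length(e2$e))
  env <- pmax(e1$e[seq_len(n)], e2$e[seq_len(n)])
  t_ms <- e1$t[seq_len(n)]

  events <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                       offset_ms = numeric(0), amplitude = numeric(0),
                       flag = character(0))
  if (any(env > 0)) {
    # contractions can occupy most of a labor record, so the baseline is the
    # lower envelope quantile and its own fluctuation, not the global median
    base <- stats::quantile(env, 0.10, names = FALSE)
    spread <- stats::mad(env[env <= stats::quantile(env, 0.30)])
    thr <- base + max(threshold_k * spread, base, 1e-12)
    above <- env > thr
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      i0 <- starts[g]; i1 <- ends[g]
      pk <- i0 + which.max(env[i0:i1]) - 1L
      half <- base + 0.5 * (env[pk] - base)
      on <- pk; while (on > 1L && env[on - 1L] > half) on <- on - 1L
      off <- pk; while (off < n && env[off + 1L] > half) off <- off + 1L
      dur_s <- (t_ms[off] - t_ms[on]) / 1000
      flag <- if (dur_s < min_duration_s || dur_s > max_duration_s) "suspect" else "good"
      events <- rbind(events, data.frame(
        onset_ms = t_ms[on], peak_ms = t_ms[pk], offset_ms = t_ms[off],
        amplitude = env[pk] - base, flag = flag))
    }
    # merge events whose refined extents overlap (one burst, two crossings)
    if (nrow(events) > 1) {
      keep <- rep(TRUE, nrow(events))
      for (k in 2:nrow(events)) {
        if (events$onset_ms[k] <= events$offset_ms[k - 1]) {
          events$offset_ms[k - 1] <- max(events$offset_ms[k - 1], events$offset_ms[k])
          events$amplitude[k - 1] <- max(events$amplitude[k - 1], events$amplitude[k])
          keep[k] <- FALSE
        }
      }
      events <- events[keep, , drop = FALSE]
    }
  }
  toco_vals <- env
  units <- "au"
  if (!is.null(calib)) {
    toco_vals <- calib$gain * env + calib$offset
    events$amplitude <- calib$gain * events$amplitude
    units <- "mmHg"
  }
  toco <- sensor_stream(toco_vals, fs10, "tocogram", ehg_ch1$sensor,
                        t0_ms = t_ms[1], units = units)
  list(events = events, tocogram = toco)
}

#' Isolate the fetal ECG by maternal template cancellation
#'
#' The chest sensor's R-peak times index the maternal QRS complexes in the
#' abdominal biopotential channel; a median template (+-400 ms around the
#' R-peak, wide enough to span the full PQRST complex including the T-wave
#' tail) is built and subtracted at every maternal beat with a per-beat
#' least-squares amplitude scale. Fetal R-peaks — roughly an order of
#' magnitude smaller — are then detected on the residual with the QRS chain
#' retuned for fetal beat rates (about 1.7-4 Hz, i.e. a 200-ms refractory
#' and a wider pass band for the narrower fetal complexes).
#'
#' @param abd_ecg abdominal biopotential [sensor_stream()] (500 Hz).
#' @param maternal_beats chest [beat_series()] of maternal R-peaks, on the
#'   same session clock.
#' @param template_halfwidth_ms half-width of the maternal template (ms).
#' @return list with `residual` (a [sensor_stream()]) and `fetal`
#'   (a [beat_series()] of fetal beats).
#' @export
isolate_fetal_ecg <- function(abd_ecg, maternal_beats, template_halfwidth_ms = 400) {
  fs <- abd_ecg$rate_hz
  x <- abd_ecg$samples
  x[!is.finite(x)] <- 0
  n <- length(x)
  t0 <- abd_ecg$t0_ms
  m_idx <- round((maternal_beats$times_ms - t0) / 1000 * fs) + 1L
  hw <- round(template_halfwidth_ms / 1000 * fs)
  m_idx <- m_idx[m_idx >= 1 & m_idx <= n]
  full <- m_idx - hw >= 1 & m_idx + hw <= n
  if (sum(full) < 10)
    stop("need at least 10 maternal beats inside the abdominal record for a template")
  # re-center each beat on the local abdominal maximum (inter-sensor jitter)
  snap <- round(0.02 * fs)
  m_idx <- vapply(m_idx, function(i) {
    lo <- max(1L, i - snap); hi <- min(n, i + snap)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, numeric(1))
  m_idx <- sort(unique(m_idx))
  full <- m_idx - hw >= 1 & m_idx + hw <= n
  if (sum(full) < 10)
    stop("need at least 10 maternal beats inside the abdominal record for a template")
  seg0 <- vapply(m_idx[full], function(i) x[(i - hw):(i + hw)], numeric(2 * hw + 1))
  templ <- apply(seg0, 1, stats::median)
  # a real maternal projection is beat-coherent: its median template retains
  # the per-window peak. An incoherent (maternal-free) channel gives a
  # near-flat template; subtracting it would only project out fetal signal.
  window_pk <- stats::median(apply(abs(seg0), 2, max))
  if (max(abs(templ)) < 0.25 * window_pk) templ[] <- 0

  # Two cancellation passes. Each pass subtracts, per beat, the least-squares
  # fit on (template, template derivative) — the derivative term absorbs
  # sub-sample misalignment between the chest and abdominal sampling grids.
  # The second pass rebuilds the template from the residual: beat-coherent
  # leftovers (fit bias from fetal overlap, window-edge effects) survive the
  # median and are removed, incoherent fetal signal does not.
  # each beat subtracts only inside its own inter-beat cell (midpoint to
  # midpoint): overlapping windows would otherwise remove the neighbor bleed
  # that is also baked into the median template, i.e. subtract it twice
  nb <- length(m_idx)
  cell_lo <- pmax(1, pmax(m_idx - hw, c(1, ceiling((m_idx[-nb] + m_idx[-1]) / 2 + 0.5))))
  cell_hi <- pmin(n, pmin(m_idx + hw, c(floor((m_idx[-nb] + m_idx[-1]) / 2), n)))
  res <- x
  subtract_pass <- function(res, templ) {
    dtempl <- c(0, diff(templ))
    G <- cbind(templ, dtempl)
    if (sum(templ^2) == 0) return(res)
    for (k in seq_len(nb)) {
      i <- m_idx[k]
      win <- cell_lo[k]:cell_hi[k]
      sel <- win - (i - hw) + 1L
      Gs <- G[sel, , drop = FALSE]
      gg <- crossprod(Gs)
      if (det(gg) < 1e-12) next
      ab <- solve(gg, crossprod(Gs, res[win]))
      res[win] <- res[win] - Gs %*% ab
    }
    res
  }
  res <- subtract_pass(res, templ)
  if (sum(templ^2) > 0) {
    seg1 <- vapply(m_idx[full], function(i) res[(i - hw):(i + hw)], numeric(2 * hw + 1))
    res <- subtract_pass(res, apply(seg1, 1, stats::median))
  }
  residual <- abd_ecg
  residual$samples <- res
  residual$label <- paste0(abd_ecg$label, "_residual")
  fetal_cfg <- pan_tompkins_config(band_hz = c(8, 30), integration_ms = 80,
                                   refractory_ms = 200)
  res_stream <- residual
  fetal <- tryCatch(detect_r_peaks(res_stream, fetal_cfg),
                    error = function(e) beat_series(numeric(0), "r_peak"),
                    warning = function(w) beat_series(numeric(0), "r_peak"))
  # amplitude gate: a true fetal complex, while an order of magnitude below
  # the maternal one, still stands clear of the cancellation residue
  if (length(fetal$times_ms)) {
    f_idx <- pmin(pmax(round((fetal$times_ms - t0) / 1000 * fs) + 1L, 1L), n)
    floor_amp <- 0.05 * max(abs(templ))
    keep <- abs(res[f_idx]) > floor_amp
    fetal <- beat_series(fetal$times_ms[keep], "r_peak", fetal$quality[keep])
  }
  if (!length(fetal$times_ms))
    warning("no fetal peaks detected on the residual")
  fetal$kind <- "fetal_beat"
  list(residual = residual, fetal = fetal)
}
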