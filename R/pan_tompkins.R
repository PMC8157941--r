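#' Tunable constants of the QRS detection chain
#'
#' The classic Pan-Tompkins chain — band-pass, derivative, squaring, moving
#' integration, adaptive dual thresholds with search-back — with every
#' constant exposed. Defaults follow the original design: 5-15 Hz pass band,
#' 150 ms integration window, 200 ms refractory period, search-back at
#' 1.66x the running R-R average using half the main threshold.
#'
#' @param band_hz pass band (Hz) of the zero-phase Butterworth filter.
#' @param filter_order Butterworth order.
#' @param integration_ms moving-window integration length (ms).
#' @param refractory_ms minimum separation between accepted beats (ms).
#' @param threshold_frac fraction of (signal - noise) level above the noise
#'   level at which a candidate is accepted.
#' @param searchback_factor multiple of the running R-R average that triggers
#'   search-back with the lowered threshold.
#' @param searchback_frac fraction of the main threshold used in search-back.
#' @param snr_suspect factor over the noise level below which an accepted
#'   beat is flagged `suspect`.
#' @export
pan_tompkins_config <- function(band_hz = c(5, 15), filter_order = 2,
                                integration_ms = 150, refractory_ms = 200,
                                threshold_frac = 0.25, searchback_factor = 1.66,
                                searchback_frac = 0.5, snr_suspect = 2.0) {
  list(band_hz = band_hz, filter_order = filter_order,
       integration_ms = integration_ms, refractory_ms = refractory_ms,
       threshold_frac = threshold_frac, searchback_factor = searchback_factor,
       searchback_frac = searchback_frac, snr_suspect = snr_suspect)
}

# Zero-phase Butterworth band-pass with reflection padding (tames the
# filter start-up transient at the record edges); NA gaps become zeros.
bandpass <- function(x, fs, band_hz, order = 2) {
  x[!is.finite(x)] <- 0
  w <- band_hz / (fs / 2)
  bf <- signal::butter(order, w, type = "pass")
  n <- length(x)
  pad <- min(n - 1L, max(10L, ceiling(2 * fs / band_hz[1])))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

moving_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = FALSE))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect maternal R-peaks on chest ECG (modified Pan-Tompkins)
#'
#' Band-pass filters the ECG, differentiates, squares and integrates over a
#' moving window, then applies adaptive dual thresholds with a refractory
#' period and search-back. Each accepted detection is refined to the raw-ECG
#' maximum just before the integrated peak, so beat times land on the R wave
#' itself. Beats whose integrated peak sits close to the running noise level
#' are flagged `suspect`.
#'
#' @param ecg a chest ECG [sensor_stream()] (canonically 512 Hz).
#' @param config constants from [pan_tompkins_config()].
#' @return a [beat_series()] of kind `r_peak`.
#' @export
detect_r_peaks <- function(ecg, config = pan_tompkins_config()) {
  fs <- ecg$rate_hz
  x <- ecg$samples
  if (length(x) < 5 * fs) stop("need at least 5 s of ECG")
  if (stats::sd(x[is.finite(x)]) == 0) {
    warning("constant ECG signal: no beats detectable")
    return(beat_series(numeric(0), "r_peak"))
  }
  bp <- bandpass(x, fs, config$band_hz, config$filter_order)
  # five-point derivative, squared, integrated
  der <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w_int <- max(3L, round(config$integration_ms / 1000 * fs))
  intg <- moving_mean(sq, w_int)
  intg[is.na(intg)] <- 0

  cand <- local_maxima(intg)
  cand <- cand[intg[cand] > 0]
  if (!length(cand)) return(beat_series(numeric(0), "r_peak"))

  refr <- round(config$refractory_ms / 1000 * fs)
  init <- intg[seq_len(min(length(intg), round(2 * fs)))]
  spk <- 0.6 * max(init)
  npk <- 0.5 * mean(init)
  thr <- function() npk + config$threshold_frac * (spk - npk)

  accepted <- integer(0)
  acc_val <- numeric(0)
  rr_hist <- numeric(0)
  noise_cand <- integer(0)
  for (i in cand) {
    v <- intg[i]
    if (length(accepted) && (i - accepted[length(accepted)]) < refr) {
      # within refractory: keep whichever candidate is stronger
      if (v > acc_val[length(acc_val)]) {
        accepted[length(accepted)] <- i
        acc_val[length(acc_val)] <- v
        spk <- 0.125 * v + 0.875 * spk
      }
      next
    }
    if (v > thr()) {
      # search-back first: did we miss a beat in a long gap?
      if (length(accepted) && length(rr_hist) >= 2) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        gap <- i - accepted[length(accepted)]
        if (gap > config$searchback_factor * rr_avg && length(noise_cand)) {
          inside <- noise_cand[noise_cand > accepted[length(accepted)] + refr &
                               noise_cand < i - refr]
          if (length(inside)) {
            j <- inside[which.max(intg[inside])]
            if (intg[j] > config$searchback_frac * thr()) {
              accepted <- c(accepted, j); acc_val <- c(acc_val, intg[j])
              spk <- 0.25 * intg[j] + 0.75 * spk
              rr_hist <- c(rr_hist, j - accepted[length(accepted) - 1L])
              accepted <- sort(accepted)
            }
          }
        }
      }
      if (length(accepted)) rr_hist <- c(rr_hist, i - accepted[length(accepted)])
      accepted <- c(accepted, i)
      acc_val <- c(acc_val, v)
      spk <- 0.125 * v + 0.875 * spk
      noise_cand <- integer(0)
    } else {
      npk <- 0.125 * v + 0.875 * npk
      noise_cand <- c(noise_cand, i)
    }
  }
  if (!length(accepted)) return(beat_series(numeric(0), "r_peak"))

  # refine each accepted peak to the raw R wave; the whole chain is
  # zero-phase, so the integrated peak sits on the QRS complex itself
  half_w <- round(0.1 * fs)
  n <- length(x)
  raw <- x; raw[!is.finite(raw)] <- -Inf
  r_idx <- vapply(accepted, function(i) {
    lo <- max(1L, i - half_w); hi <- min(n, i + half_w)
    lo + which.max(raw[lo:hi]) - 1L
  }, numeric(1))
  dup <- duplicated(r_idx)
  r_idx <- r_idx[!dup]; acc_val <- acc_val[!dup]
  ord <- order(r_idx)
  r_idx <- r_idx[ord]; acc_val <- acc_val[ord]
  # enforce refractory on refined times, keeping the stronger beat
  keep <- rep(TRUE, length(r_idx))
  last <- 1L
  for (k in seq_along(r_idx)[-1]) {
    if (r_idx[k] - r_idx[last] < refr) {
      if (acc_val[k] > acc_val[last]) { keep[last] <- FALSE; last <- k } else keep[k] <- FALSE
    } else last <- k
  }
  r_idx <- r_idx[keep]; acc_val <- acc_val[keep]
  quality <- ifelse(acc_val < config$snr_suspect * max(npk, 1e-12), "suspect", "good")
  beat_series(ecg$t0_ms + (r_idx - 1) * 1000 / fs, "r_peak", quality)
}
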