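#' Detected cardiac/pulse event series
#'
#' Ordered event times (ms on the session clock) with a per-event quality
#' flag. Consecutive maternal R-peak intervals outside the physiological
#' [250, 2000] ms band are flagged `suspect` rather than dropped.
#'
#' @param times_ms strictly increasing event times (ms).
#' @param kind event source: `r_peak`, `ppg_pulse`, `fetal_beat`, `s1`, `s2`.
#' @param quality per-event flag, `"good"` or `"suspect"`.
#' @return an object of class `beat_series`.
#' @export
beat_series <- function(times_ms, kind = c("r_peak", "ppg_pulse", "fetal_beat", "s1", "s2"),
                        quality = NULL) {
  kind <- match.arg(kind)
  times_ms <- as.double(times_ms)
  if (is.unsorted(times_ms, strictly = TRUE)) stop("event times must be strictly increasing")
  if (is.null(quality)) quality <- rep("good", length(times_ms))
  if (kind == "r_peak" && length(times_ms) > 1) {
    rr <- diff(times_ms)
    bad <- which(rr < 250 | rr > 2000)
    quality[unique(c(bad, bad + 1L))] <- "suspect"
  }
  structure(list(times_ms = times_ms, kind = kind, quality = quality),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$times_ms)
  cat(sprintf("<beat_series> %d %s events", n, x$kind))
  if (n > 1) cat(sprintf(", mean interval %.1f ms", mean(diff(x$times_ms))))
  cat(sprintf(", %d suspect\n", sum(x$quality != "good")))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times_ms)

vital_ranges <- list(
  hr_bpm = c(20, 300), spo2_pct = c(0, 100), rr_brpm = c(2, 80),
  temp_c = c(25, 45), fhr_bpm = c(60, 240),
  sbp_mmhg = c(40, 280), dbp_mmhg = c(40, 280)
)

#' Timestamped derived vital-sign series
#'
#' Values outside the physiological range of the vital are set to missing —
#' never silently clipped (the single exception is the SpO2 upper clamp at
#' 100%, applied by the ratio-of-ratios mapping itself). Unrounded values are
#' retained; display rounding is the job of [format_vital()].
#'
#' @param times_ms timestamps (ms, session clock; typically window centers).
#' @param values derived values (may contain `NA`).
#' @param vital one of `hr_bpm`, `spo2_pct`, `rr_brpm`, `temp_c`, `fhr_bpm`,
#'   `sbp_mmhg`, `dbp_mmhg`.
#' @param window_ms averaging window used to derive the values.
#' @return an object of class `vital_series`.
#' @export
vital_series <- function(times_ms, values, vital, window_ms = NA_real_) {
  if (!vital %in% names(vital_ranges)) stop("unknown vital: ", vital)
  values <- as.double(values)
  rng <- vital_ranges[[vital]]
  oob <- !is.na(values) & (values < rng[1] | values > rng[2])
  values[oob] <- NA_real_
  structure(list(times_ms = as.double(times_ms), values = values,
                 vital = vital, window_ms = window_ms),
            class = "vital_series")
}

#' @export
print.vital_series <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("<vital_series> %s: %d points (%d missing)", x$vital,
              length(x$values), sum(!ok)))
  if (any(ok)) cat(sprintf(", mean %.2f", mean(x$values[ok])))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.vital_series <- function(x, ...) {
  data.frame(time_ms = x$times_ms, vital = x$vital, value = x$values)
}

#' Clinical display rounding for a vital value
#'
#' HR/FHR/RR round to the nearest integer and SpO2 to one decimal, matching
#' clinical display convention; the underlying series always keeps unrounded
#' values.
#'
#' @param values numeric values.
#' @param vital vital name as in [vital_series()].
#' @export
format_vital <- function(values, vital) {
  switch(vital,
         hr_bpm = , fhr_bpm = , rr_brpm = round(values),
         spo2_pct = round(values, 1),
         sbp_mmhg = , dbp_mmhg = round(values),
         temp_c = round(values, 1),
         values)
}
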