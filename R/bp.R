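#' Per-beat pulse arrival time
#'
#' Matches each maternal R-peak to the first PPG pulse strictly after it and
#' before the next R-peak; PAT is the interval between the two, the transit
#' time of the pressure wave from the heart to the limb site. Unmatched
#' beats are skipped. The concurrent heart rate is attached from the R-R
#' interval ending at each matched beat.
#'
#' @param r_peaks maternal [beat_series()] (kind `r_peak`).
#' @param ppg_pulses limb [beat_series()] (kind `ppg_pulse`), same session
#'   clock.
#' @return data.frame of class `pat_series`: `times_ms` (R-peak time),
#'   `pat_ms`, `hr_bpm`, `flag` (PAT outside (0, 1000) ms is flagged).
#' @export
compute_pat <- function(r_peaks, ppg_pulses) {
  rt <- r_peaks$times_ms
  pt <- ppg_pulses$times_ms
  if (!length(rt) || !length(pt) ||
      max(pt) <= min(rt) || min(pt) >= max(rt) + 2000)
    stop("R-peak and PPG pulse series do not overlap in time")
  out <- data.frame(times_ms = numeric(0), pat_ms = numeric(0),
                    hr_bpm = numeric(0), flag = character(0))
  nb <- length(rt)
  for (k in seq_len(nb)) {
    upper <- if (k < nb) rt[k + 1] else Inf
    cand <- pt[pt > rt[k] & pt < upper]
    if (!length(cand)) next
    pat <- cand[1] - rt[k]
    hr <- if (k > 1) 60000 / (rt[k] - rt[k - 1]) else NA_real_
    flag <- if (pat > 0 && pat < 1000) "good" else "suspect"
    out <- rbind(out, data.frame(times_ms = rt[k], pat_ms = pat,
                                 hr_bpm = hr, flag = flag))
  }
  class(out) <- c("pat_series", "data.frame")
  out
}

#' Fit the linear PAT(+HR) to blood-pressure calibration
#'
#' Ordinary-least-squares fit of BP = a_pat * PAT + b_hr * HR + c, one
#' coefficient triple each for systolic and diastolic pressure. In
#' `continuous` mode the reference is a dense gold-standard trace and the
#' default calibration window is the first 50 s of overlap. In `cuff` mode
#' the reference is a handful of sphygmomanometer readings; PAT and HR are
#' averaged within +-30 s of each cuff time, the global linear coefficients
#' are fitted across readings, and the mean residual at the reference times
#' is forced to zero by a final intercept offset. On physiological data the
#' fitted `a_pat` is negative: pressure and arrival time move inversely.
#'
#' @param pat a `pat_series` from [compute_pat()].
#' @param reference data.frame with `time_ms` and one or both of `sbp_mmhg`,
#'   `dbp_mmhg`.
#' @param mode `"continuous"` or `"cuff"`.
#' @param use_hr include the HR term (drop for a PAT-only line).
#' @param calib_window_ms continuous-mode calibration window (default 50 s).
#' @param cuff_halfwidth_ms half-width for averaging PAT/HR around each cuff
#'   reading.
#' @return an object of class `bp_calibration` with `sbp` and `dbp`
#'   coefficient vectors `(a_pat, b_hr, c)`.
#' @export
fit_bp_calibration <- function(pat, reference, mode = c("continuous", "cuff"),
                               use_hr = TRUE, calib_window_ms = 50000,
                               cuff_halfwidth_ms = 30000) {
  mode <- match.arg(mode)
  stopifnot(inherits(pat, "pat_series"), "time_ms" %in% names(reference))
  ok <- pat$flag == "good" & is.finite(pat$hr_bpm)
  p <- pat[ok, , drop = FALSE]
  if (stats::sd(p$pat_ms) < 1e-9 && stats::sd(p$hr_bpm) < 1e-9)
    stop("degenerate calibration: PAT and HR are constant")
  targets <- intersect(c("sbp_mmhg", "dbp_mmhg"), names(reference))
  if (!length(targets)) stop("reference has neither sbp_mmhg nor dbp_mmhg")

  if (mode == "continuous") {
    lo <- max(min(p$times_ms), min(reference$time_ms))
    hi <- min(max(p$times_ms), max(reference$time_ms))
    if (hi - lo < calib_window_ms)
      stop("continuous calibration needs at least ", calib_window_ms / 1000,
           " s of overlap with the reference")
    win <- p$times_ms >= lo & p$times_ms <= lo + calib_window_ms
    p <- p[win, , drop = FALSE]
    design <- data.frame(pat = p$pat_ms, hr = p$hr_bpm)
    ref_at <- function(col) stats::approx(reference$time_ms, reference[[col]],
                                          xout = p$times_ms, rule = 2)$y
    resp <- lapply(targets, ref_at)
  } else {
    if (nrow(reference) < 2) stop("cuff calibration needs at least 2 readings")
    rows <- lapply(reference$time_ms, function(tc) {
      w <- p[abs(p$times_ms - tc) <= cuff_halfwidth_ms, , drop = FALSE]
      if (!nrow(w)) return(c(NA, NA))
      c(mean(w$pat_ms), mean(w$hr_bpm))
    })
    m <- do.call(rbind, rows)
    keep <- stats::complete.cases(m)
    if (sum(keep) < 2) stop("fewer than 2 cuff readings have PAT within the window")
    design <- data.frame(pat = m[keep, 1], hr = m[keep, 2])
    resp <- lapply(targets, function(col) reference[[col]][keep])
  }
  names(resp) <- targets

  fit_one <- function(y) {
    df <- cbind(design, y = y)
    use_hr_here <- use_hr && nrow(df) >= 3 && stats::sd(df$hr) > 1e-9
    f <- if (use_hr_here) stats::lm(y ~ pat + hr, data = df) else stats::lm(y ~ pat, data = df)
    cf <- stats::coef(f)
    if (anyNA(cf)) stop("degenerate calibration: rank-deficient design")
    out <- c(a_pat = unname(cf["pat"]),
             b_hr = if ("hr" %in% names(cf)) unname(cf["hr"]) else 0,
             c = unname(cf["(Intercept)"]))
    if (mode == "cuff") {
      pred <- out["a_pat"] * design$pat + out["b_hr"] * design$hr + out["c"]
      out["c"] <- out["c"] + mean(y - pred)     # zero mean residual at refs
    }
    out
  }
  cal <- list(sbp = if ("sbp_mmhg" %in% targets) fit_one(resp$sbp_mmhg) else NULL,
              dbp = if ("dbp_mmhg" %in% targets) fit_one(resp$dbp_mmhg) else NULL,
              mode = mode, use_hr = use_hr, calib_window_ms = calib_window_ms,
              n_ref = if (mode == "cuff") nrow(design) else nrow(design))
  class(cal) <- "bp_calibration"
  cal
}

#' @export
print.bp_calibration <- function(x, ...) {
  cat(sprintf("<bp_calibration> mode=%s, n=%d\n", x$mode, x$n_ref))
  for (side in c("sbp", "dbp")) if (!is.null(x[[side]]))
    cat(sprintf("  %s: %.4f mmHg/ms * PAT + %.4f mmHg/bpm * HR + %.2f mmHg\n",
                toupper(side), x[[side]]["a_pat"], x[[side]]["b_hr"], x[[side]]["c"]))
  invisible(x)
}

#' @export
coef.bp_calibration <- function(object, ...) {
  do.call(rbind, Filter(Negate(is.null), object[c("sbp", "dbp")]))
}

#' Predict continuous blood pressure from PAT
#'
#' Per-beat linear prediction followed by moving-median smoothing; values
#' outside the plausible [40, 280] mmHg range become missing rather than
#' being clipped.
#'
#' @param pat a `pat_series`.
#' @param calib a `bp_calibration`.
#' @param smooth_window_ms moving-median window over beats (ms).
#' @return list of [vital_series()]: `sbp` and (when calibrated) `dbp`.
#' @export
predict_bp <- function(pat, calib, smooth_window_ms = 10000) {
  stopifnot(inherits(calib, "bp_calibration"))
  ok <- pat$flag == "good" & is.finite(pat$hr_bpm)
  p <- pat[ok, , drop = FALSE]
  one <- function(cf, vital) {
    if (is.null(cf)) return(NULL)
    raw <- cf["a_pat"] * p$pat_ms + cf["b_hr"] * p$hr_bpm + cf["c"]
    if (length(raw) >= 3) {
      med_rr <- stats::median(diff(p$times_ms))
      k <- max(1L, round(smooth_window_ms / med_rr))
      if (k %% 2 == 0) k <- k + 1L
      k <- min(k, if (length(raw) %% 2 == 1) length(raw) else length(raw) - 1L)
      if (k >= 3) raw <- as.numeric(stats::runmed(raw, k, endrule = "median"))
    }
    raw[raw < 40 | raw > 280] <- NA_real_
    vital_series(p$times_ms, raw, vital, smooth_window_ms)
  }
  list(sbp = one(calib$sbp, "sbp_mmhg"), dbp = one(calib$dbp, "dbp_mmhg"))
}

#' @export
predict.bp_calibration <- function(object, pat, smooth_window_ms = 10000, ...) {
  predict_bp(pat, object, smooth_window_ms)
}
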