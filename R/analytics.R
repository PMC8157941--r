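#' Bland-Altman agreement between two vital series
#'
#' Pairs device and reference points by nearest neighbor within a time
#' tolerance (each reference point used at most once), and reports the mean
#' difference (device - reference), its sample SD (n-1 denominator), and the
#' 95% limits of agreement mean +- 1.96 * SD, together with the per-pair
#' (mean, difference) points for plotting.
#'
#' @param device,reference [vital_series()] objects (or anything with
#'   `times_ms` and `values`).
#' @param pairing_tolerance_ms maximum |time difference| for a pair
#'   (default 5 s).
#' @return an object of class `bland_altman` with fields `n_pairs`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, and `points`.
#' @export
bland_altman <- function(device, reference, pairing_tolerance_ms = 5000) {
  dt <- device$times_ms; dv <- device$values
  rt <- reference$times_ms; rv <- reference$values
  okd <- !is.na(dv); okr <- !is.na(rv)
  dt <- dt[okd]; dv <- dv[okd]; rt <- rt[okr]; rv <- rv[okr]
  used <- rep(FALSE, length(rt))
  dev_p <- ref_p <- numeric(0)
  for (k in seq_along(dt)) {
    if (!length(rt)) break
    j <- which.min(ifelse(used, Inf, abs(rt - dt[k])))
    if (!length(j) || used[j] || abs(rt[j] - dt[k]) > pairing_tolerance_ms) next
    used[j] <- TRUE
    dev_p <- c(dev_p, dv[k]); ref_p <- c(ref_p, rv[j])
  }
  if (length(dev_p) < 2) stop("fewer than 2 matched pairs within tolerance")
  d <- dev_p - ref_p
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(n_pairs = length(d), mean_diff = md, sd_diff = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                 points = data.frame(mean = (dev_p + ref_p) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d pairs\n", x$n_pairs))
  cat(sprintf("  mean difference %.3f (SD %.3f)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% limits of agreement [%.3f, %.3f]\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$diff,
                 xlab = "mean of methods", ylab = "difference (device - reference)",
                 pch = 16, col = grDevices::adjustcolor("black", 0.4), ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("blue", "red", "red"))
  invisible(x)
}

heatmap_default_binwidth <- c(hr_bpm = 1, spo2_pct = 1, rr_brpm = 1,
                              sbp_mmhg = 2, dbp_mmhg = 2, fhr_bpm = 1,
                              temp_c = 0.1)

#' Session time-to-vital distribution heat map
#'
#' Pools one vital over sessions into a 2-D histogram of (session time,
#' value), and additionally normalizes the counts within each 4-h window of
#' the time axis (up to 24 h) so that long labors remain visible next to the
#' majority that last only a few hours: each populated window block of the
#' normalized matrix sums to 1.
#'
#' @param sessions list of [vital_series()] (one per monitored session), all
#'   of the same vital.
#' @param value_binwidth value-axis bin width; defaults per vital (1 bpm HR,
#'   1% SpO2, 1 breath/min RR, 2 mmHg SBP).
#' @param time_binwidth_min time-axis bin width in minutes (default 5).
#' @param window_h normalization window (default 4 h).
#' @param max_h time-axis extent (default 24 h).
#' @return an object of class `vital_heatmap`: `counts` and `normalized`
#'   matrices (value bins x time bins), bin edges, and the vital label.
#' @export
time_to_vital_heatmap <- function(sessions, value_binwidth = NULL,
                                  time_binwidth_min = 5, window_h = 4,
                                  max_h = 24) {
  if (inherits(sessions, "vital_series")) sessions <- list(sessions)
  if (!length(sessions)) stop("need at least one session")
  vital <- sessions[[1]]$vital
  t_all <- unlist(lapply(sessions, `[[`, "times_ms")) / 3.6e6   # hours
  v_all <- unlist(lapply(sessions, `[[`, "values"))
  ok <- !is.na(v_all) & t_all <= max_h
  t_all <- t_all[ok]; v_all <- v_all[ok]
  if (!length(v_all)) stop("no non-missing values to pool")
  if (is.null(value_binwidth))
    value_binwidth <- unname(heatmap_default_binwidth[vital])
  if (is.na(value_binwidth)) value_binwidth <- diff(range(v_all)) / 50 + 1e-9
  v_edges <- seq(floor(min(v_all) / value_binwidth) * value_binwidth,
                 ceiling(max(v_all) / value_binwidth) * value_binwidth + value_binwidth,
                 by = value_binwidth)
  t_edges <- seq(0, max_h, by = time_binwidth_min / 60)
  vi <- findInterval(v_all, v_edges, rightmost.closed = TRUE)
  ti <- findInterval(t_all, t_edges, rightmost.closed = TRUE)
  keep <- ti >= 1 & ti < length(t_edges)
  counts <- matrix(0, length(v_edges) - 1L, length(t_edges) - 1L)
  for (k in which(keep)) counts[vi[k], ti[k]] <- counts[vi[k], ti[k]] + 1
  norm <- counts
  t_mid <- (t_edges[-1] + t_edges[-length(t_edges)]) / 2
  blk <- pmin(floor(t_mid / window_h), max_h / window_h - 1)
  for (b in unique(blk)) {
    cols <- which(blk == b)
    tot <- sum(counts[, cols])
    if (tot > 0) norm[, cols] <- counts[, cols] / tot
  }
  structure(list(counts = counts, normalized = norm, value_edges = v_edges,
                 time_edges_h = t_edges, window_h = window_h, vital = vital),
            class = "vital_heatmap")
}

#' @export
print.vital_heatmap <- function(x, ...) {
  cat(sprintf("<vital_heatmap> %s: %d value bins x %d time bins, %d samples\n",
              x$vital, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Plain-text session report
#'
#' Assembles a deterministic Markdown report with one panel per derived
#' series: the four maternal vitals (HR, SpO2, RR, temperature), the fetal
#' heart rate, the uterine-activity strip and the posture timeline, plus a
#' blood-pressure trace when a calibration was available, and a QC summary.
#' Panels whose input series is absent are marked absent rather than
#' failing.
#'
#' @param session the source [synced_session()] (for the QC inventory).
#' @param derived named list of derived objects; recognized names: `hr`,
#'   `spo2`, `rr`, `temp` ([vital_series()]), `fhr` (vital_series),
#'   `contractions` (from [detect_contractions()]), `posture`
#'   (`posture_series`), `bp` (list from [predict_bp()]).
#' @param path optional file to write; when `NULL` the lines are returned.
#' @return character vector of Markdown lines, invisibly when written.
#' @export
session_report <- function(session, derived, path = NULL) {
  if (!length(derived)) stop("need at least one derived series")
  L <- c("# Session report", "")
  L <- c(L, sprintf("Streams: %s", paste(names(session$streams), collapse = ", ")), "")
  vital_panel <- function(name, vs) {
    if (is.null(vs)) return(sprintf("## %s\n\n(panel absent: no input stream)", name))
    ok <- !is.na(vs$values)
    if (!any(ok)) return(sprintf("## %s\n\nno valid values", name))
    sprintf("## %s\n\nn = %d, mean = %.2f, range = [%.2f, %.2f] %s",
            name, sum(ok), mean(vs$values[ok]), min(vs$values[ok]),
            max(vs$values[ok]), vs$vital)
  }
  L <- c(L, vital_panel("Heart rate", derived$hr), "")
  L <- c(L, vital_panel("SpO2", derived$spo2), "")
  L <- c(L, vital_panel("Respiratory rate", derived$rr), "")
  L <- c(L, vital_panel("Temperature", derived$temp), "")
  L <- c(L, vital_panel("Fetal heart rate", derived$fhr), "")
  if (!is.null(derived$contractions)) {
    ev <- derived$contractions$events
    L <- c(L, "## Uterine activity", "",
           sprintf("%d contraction event(s) detected", nrow(ev)), "")
  } else L <- c(L, "## Uterine activity", "", "(panel absent: no input stream)", "")
  if (!is.null(derived$posture)) {
    tab <- table(derived$posture$posture)
    L <- c(L, "## Posture timeline", "",
           paste(sprintf("%s: %.1f%%", names(tab), 100 * tab / sum(tab)),
                 collapse = ", "), "")
  } else L <- c(L, "## Posture timeline", "", "(panel absent: no input stream)", "")
  if (!is.null(derived$bp)) {
    L <- c(L, vital_panel("Blood pressure (systolic)", derived$bp$sbp), "")
  }
  qc <- sprintf("QC: %d derived series present, %d absent",
                sum(!vapply(derived, is.null, logical(1))),
                sum(vapply(derived, is.null, logical(1))))
  L <- c(L, "## Quality control", "", qc, "")
  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}
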