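#' Canonical sampling rates of the sensor network
#'
#' Named vector of the native sampling rates (Hz) of each channel produced by
#' the chest, limb and abdominal sensors: chest ECG 512, chest high-rate IMU
#' 416, chest accelerometer vitals stream 52, skin temperature 0.2, limb PPG
#' 256, abdominal Doppler 504, abdominal biopotential (EHG / abdominal ECG)
#' 500.
#'
#' @export
canonical_rates <- c(
  ecg = 512, imu = 416, accel = 52, temp = 0.2,
  ppg_red = 256, ppg_ir = 256, doppler = 504,
  ehg1 = 500, ehg2 = 500, abd_ecg = 500
)

#' Construct a single-channel (or accelerometer xyz) sensor stream
#'
#' A `sensor_stream` is one uniformly sampled channel: the samples, the
#' sampling rate, the session-relative start time in milliseconds, the body
#' site of the sensor that produced it, and the physical units. Missing
#' samples are `NA`; downstream operations skip, never silently interpolate
#' across, gaps longer than two sample periods.
#'
#' @param samples numeric vector, or a numeric matrix with named columns for
#'   multi-axis channels (accelerometer `x`,`y`,`z`).
#' @param rate_hz sampling rate in Hz (> 0).
#' @param label channel name, e.g. `"ecg"`, `"accel"`, `"doppler"`.
#' @param sensor body site: `"chest"`, `"limb"` or `"abdominal"`.
#' @param t0_ms session-relative time of the first sample (ms).
#' @param units physical unit string (e.g. `"mV"`, `"g"`, `"degC"`).
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(samples, rate_hz, label, sensor = c("chest", "limb", "abdominal"),
                          t0_ms = 0, units = "") {
  sensor <- match.arg(sensor)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (is.matrix(samples)) {
    if (is.null(colnames(samples))) stop("matrix samples need named columns (e.g. x, y, z)")
    storage.mode(samples) <- "double"
  } else {
    samples <- as.double(samples)
  }
  structure(
    list(label = label, sensor = sensor, rate_hz = rate_hz,
         t0_ms = as.double(t0_ms), samples = samples, units = units),
    class = "sensor_stream"
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  n <- stream_length(x)
  cat(sprintf("<sensor_stream> %s/%s: %d samples @ %g Hz (%.1f s), t0 = %g ms%s\n",
              x$sensor, x$label, n, x$rate_hz, n / x$rate_hz, x$t0_ms,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Number of samples in a stream
#' @param stream a `sensor_stream`.
#' @export
stream_length <- function(stream) {
  if (is.matrix(stream$samples)) nrow(stream$samples) else length(stream$samples)
}

#' Sample timestamps of a stream (ms, session clock)
#' @param stream a `sensor_stream`.
#' @export
stream_times_ms <- function(stream) {
  stream$t0_ms + (seq_len(stream_length(stream)) - 1) * 1000 / stream$rate_hz
}

#' Construct a synchronized multi-sensor session
#'
#' Bundles a set of [sensor_stream()]s expressed on one session clock
#' (milliseconds since the first sample of the earliest stream) together with
#' sparse reference measurements (e.g. cuff blood pressure). The network's
#' out-of-band time synchronization keeps inter-sensor clock skew within
#' `sync_tolerance_ms` (1 ms by default).
#'
#' @param streams list of `sensor_stream` objects; no two streams may share
#'   the same (sensor, label) pair.
#' @param references optional data frame of sparse reference measurements,
#'   e.g. columns `time_ms`, `sbp_mmhg`, `dbp_mmhg`.
#' @param sync_tolerance_ms maximum tolerated inter-sensor clock skew (ms).
#' @return an object of class `synced_session`.
#' @export
synced_session <- function(streams, references = NULL, sync_tolerance_ms = 1) {
  if (!length(streams)) stop("a session needs at least one stream")
  if (!all(vapply(streams, inherits, logical(1), "sensor_stream")))
    stop("streams must all be sensor_stream objects")
  keys <- vapply(streams, function(s) paste(s$sensor, s$label, sep = "/"), character(1))
  if (anyDuplicated(keys)) stop("duplicate (sensor, label) pair: ", keys[duplicated(keys)][1])
  names(streams) <- keys
  structure(list(streams = streams, references = references,
                 sync_tolerance_ms = sync_tolerance_ms),
            class = "synced_session")
}

#' @export
print.synced_session <- function(x, ...) {
  cat(sprintf("<synced_session> %d streams, sync tolerance %g ms\n",
              length(x$streams), x$sync_tolerance_ms))
  for (s in x$streams) print(s)
  if (!is.null(x$references))
    cat(sprintf("  references: %d rows (%s)\n", nrow(x$references),
                paste(names(x$references), collapse = ", ")))
  invisible(x)
}

#' Fetch one stream from a session by label (and optionally sensor)
#' @param session a `synced_session`.
#' @param label channel name.
#' @param sensor optional body site to disambiguate.
#' @export
get_stream <- function(session, label, sensor = NULL) {
  hit <- Filter(function(s) s$label == label && (is.null(sensor) || s$sensor == sensor),
                session$streams)
  if (!length(hit)) return(NULL)
  hit[[1]]
}

#' Shift per-sensor clocks of a session
#'
#' Applies a clock-offset correction per body site: every stream's start time
#' is shifted by its sensor's offset. Reference measurements are left on the
#' session clock. Aligning with zero offsets is the identity, and alignment
#' composes additively: `align(align(s, a), b)` equals `align(s, a + b)`.
#'
#' @param session a `synced_session`.
#' @param offsets named numeric vector of clock offsets in ms, names among
#'   `chest`, `limb`, `abdominal`. Each |offset| must be below 60 s.
#' @return the aligned `synced_session`.
#' @export
align <- function(session, offsets) {
  if (length(offsets) && is.null(names(offsets)))
    stop("offsets must be named by sensor")
  if (any(abs(offsets) >= 60000))
    stop("sensor clock offset exceeds 60 s; refusing to align")
  session$streams <- lapply(session$streams, function(s) {
    off <- offsets[s$sensor]
    if (!is.na(off)) s$t0_ms <- s$t0_ms + as.double(off)
    s
  })
  session
}

#' Resample a stream by linear interpolation
#'
#' Linear interpolation on the closed original time span; the output keeps
#' the stream's start time and covers no more than the original span.
#'
#' @param stream a `sensor_stream`.
#' @param target_hz target rate in Hz (> 0).
#' @return a `sensor_stream` at `target_hz`.
#' @export
resample <- function(stream, target_hz) {
  if (!is.numeric(target_hz) || target_hz <= 0) stop("target_hz must be > 0")
  n <- stream_length(stream)
  if (n == 0L) stop("cannot resample an empty stream")
  if (isTRUE(all.equal(target_hz, stream$rate_hz))) return(stream)
  t_old <- stream_times_ms(stream)
  span_ms <- t_old[n] - t_old[1]
  n_new <- floor(span_ms * target_hz / 1000) + 1
  t_new <- stream$t0_ms + (seq_len(n_new) - 1) * 1000 / target_hz
  interp1 <- function(y) {
    if (n == 1L) return(rep(y, n_new))
    stats::approx(t_old, y, xout = t_new, rule = 1)$y
  }
  if (is.matrix(stream$samples)) {
    out <- apply(stream$samples, 2, interp1)
    if (!is.matrix(out)) out <- matrix(out, nrow = n_new, dimnames = list(NULL, colnames(stream$samples)))
  } else {
    out <- interp1(stream$samples)
  }
  stream$samples <- out
  stream$rate_hz <- target_hz
  stream
}

# Locate runs of usable (non-NA) samples; gaps > 2 sample periods split runs.
# Returns a two-column matrix of (start, end) indices.
usable_runs <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) return(matrix(integer(0), ncol = 2))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(starts[keep], ends[keep])
}
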