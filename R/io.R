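#' Read a multi-channel session from EDF or CSV
#'
#' CSV is the long waveform dialect written by [write_session()]:
#' UTF-8, header `time_ms,sensor,channel,value[,units]`, one row per sample.
#' Multi-axis channels use dotted names (`accel.x`, `accel.y`, `accel.z`) and
#' are regrouped into one matrix-valued stream. EDF files are read with the
#' built-in 16-bit reader; all channels keep their native rates. Channel
#' labels outside the canonical set are preserved with a warning.
#'
#' @param path file to read.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by extension).
#' @param aliases optional named character vector mapping file channel names
#'   to canonical labels.
#' @return a [synced_session()].
#' @export
read_session <- function(path, format = c("auto", "edf", "csv"), aliases = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  streams <- if (format == "edf") read_edf_streams(path) else read_csv_streams(path)
  if (!is.null(aliases)) {
    streams <- lapply(streams, function(s) {
      if (s$label %in% names(aliases)) s$label <- unname(aliases[s$label])
      s
    })
  }
  known <- vapply(streams, function(s) s$label %in% names(canonical_rates), logical(1))
  if (any(!known))
    warning("unknown channel label(s) preserved as-is: ",
            paste(unique(vapply(streams[!known], `[[`, character(1), "label")), collapse = ", "))
  synced_session(streams)
}

#' Write a session to EDF or CSV
#'
#' @param session a [synced_session()].
#' @param path output file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by extension).
#' @details EDF data records are 5 s long so that every canonical rate
#'   (including 0.2 Hz temperature) yields an integer number of samples per
#'   record; each signal is padded with its last value to a whole record, so
#'   exact round-trips need durations that fill whole records. EDF encoding
#'   is 16-bit, so values round-trip with quantization error bounded by
#'   (physical range)/65534.
#' @export
write_session <- function(session, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") write_edf_streams(session$streams, path) else write_csv_streams(session$streams, path)
  invisible(path)
}

# ---- CSV (long format: time_ms, sensor, channel, value, units) ----

write_csv_streams <- function(streams, path) {
  rows <- lapply(streams, function(s) {
    t <- stream_times_ms(s)
    if (is.matrix(s$samples)) {
      do.call(rbind, lapply(colnames(s$samples), function(ax) {
        data.frame(time_ms = t, sensor = s$sensor,
                   channel = paste(s$label, ax, sep = "."),
                   value = s$samples[, ax], units = s$units)
      }))
    } else {
      data.frame(time_ms = t, sensor = s$sensor, channel = s$label,
                 value = s$samples, units = s$units)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, fileEncoding = "UTF-8")
}

read_csv_streams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("time_ms", "sensor", "channel", "value")
  if (!all(need %in% names(df))) stop("CSV is not in the long waveform format (", paste(need, collapse = ","), ")")
  if (anyDuplicated(df[c("time_ms", "sensor", "channel")]))
    stop("duplicate (time, sensor, channel) rows in CSV")
  df$base <- sub("\\.[a-z]+$", "", df$channel)
  out <- list()
  for (key in unique(paste(df$sensor, df$base, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub_df <- df[df$sensor == parts[1] & df$base == parts[2], ]
    axes <- sort(unique(sub_df$channel))
    first <- sub_df[sub_df$channel == axes[1], ]
    first <- first[order(first$time_ms), ]
    t <- first$time_ms
    if (length(t) < 2) rate <- 1 else rate <- 1000 / stats::median(diff(t))
    units <- if ("units" %in% names(sub_df)) as.character(sub_df$units[1]) else ""
    if (length(axes) > 1L) {
      mats <- sapply(axes, function(a) {
        d <- sub_df[sub_df$channel == a, ]
        d$value[order(d$time_ms)]
      })
      colnames(mats) <- sub("^.*\\.", "", axes)
      samples <- mats
    } else {
      samples <- first$value
    }
    out[[length(out) + 1L]] <- sensor_stream(samples, rate, parts[2], parts[1],
                                             t0_ms = t[1], units = units)
  }
  out
}

# ---- EDF (16-bit European Data Format, 5-s records) ----

edf_record_s <- 5

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

sensor_code <- c(chest = "C", limb = "L", abdominal = "A")

write_edf_streams <- function(streams, path) {
  # expand matrix streams to one EDF signal per axis
  sigs <- list()
  for (s in streams) {
    if (is.matrix(s$samples)) {
      for (ax in colnames(s$samples)) {
        s2 <- s; s2$samples <- s$samples[, ax]; s2$label <- paste(s$label, ax, sep = ".")
        sigs[[length(sigs) + 1L]] <- s2
      }
    } else sigs[[length(sigs) + 1L]] <- s
  }
  spr <- vapply(sigs, function(s) s$rate_hz * edf_record_s, numeric(1))
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("EDF export needs rate * ", edf_record_s, " s to be an integer number of samples")
  spr <- as.integer(round(spr))
  n_rec <- max(vapply(seq_along(sigs), function(i) ceiling(stream_length(sigs[[i]]) / spr[i]), numeric(1)))
  ns <- length(sigs)

  ph <- lapply(sigs, function(s) {
    x <- s$samples
    lo <- suppressWarnings(min(x, na.rm = TRUE)); hi <- suppressWarnings(max(x, na.rm = TRUE))
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    if (hi <= lo) hi <- lo + 1
    c(lo, hi)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad_ascii("0", 8), con, eos = NULL)
  writeChar(pad_ascii("X", 80), con, eos = NULL)            # patient id
  writeChar(pad_ascii("mfv session", 80), con, eos = NULL)  # recording id
  writeChar(pad_ascii("01.01.00", 8), con, eos = NULL)
  writeChar(pad_ascii("00.00.00", 8), con, eos = NULL)
  writeChar(pad_ascii(256 * (ns + 1), 8), con, eos = NULL)
  writeChar(pad_ascii("", 44), con, eos = NULL)
  writeChar(pad_ascii(n_rec, 8), con, eos = NULL)
  writeChar(pad_ascii(edf_record_s, 8), con, eos = NULL)
  writeChar(pad_ascii(ns, 4), con, eos = NULL)

  lab <- vapply(sigs, function(s) paste(sensor_code[s$sensor], s$label, sep = "/"), character(1))
  for (v in lab) writeChar(pad_ascii(v, 16), con, eos = NULL)
  for (s in sigs) writeChar(pad_ascii("", 80), con, eos = NULL)           # transducer
  for (s in sigs) writeChar(pad_ascii(s$units, 8), con, eos = NULL)       # phys dim
  for (p in ph) writeChar(pad_ascii(formatC(p[1], digits = 6, format = "g"), 8), con, eos = NULL)
  for (p in ph) writeChar(pad_ascii(formatC(p[2], digits = 6, format = "g"), 8), con, eos = NULL)
  for (s in sigs) writeChar(pad_ascii(-32767, 8), con, eos = NULL)
  for (s in sigs) writeChar(pad_ascii(32767, 8), con, eos = NULL)
  for (s in sigs) writeChar(pad_ascii("", 80), con, eos = NULL)           # prefilter
  for (i in seq_len(ns)) writeChar(pad_ascii(spr[i], 8), con, eos = NULL)
  # per-signal reserved field carries the stream start time (ms) as ASCII
  for (s in sigs) writeChar(pad_ascii(sprintf("t0=%.3f", s$t0_ms), 32), con, eos = NULL)

  dig <- lapply(seq_along(sigs), function(i) {
    x <- sigs[[i]]$samples
    want <- n_rec * spr[i]
    if (length(x) < want) x <- c(x, rep(if (length(x)) x[length(x)] else 0, want - length(x)))
    p <- ph[[i]]
    x[!is.finite(x)] <- p[1]
    as.integer(round((x - p[1]) / (p[2] - p[1]) * 65534) - 32767)
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_streams <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)
  units <- trimws(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  resv <- trimws(vapply(seq_len(ns), function(i) rd(32), character(1)))

  raw_sig <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little", signed = TRUE)
      raw_sig[[i]] <- c(raw_sig[[i]], d)
    }
  }
  code2sensor <- stats::setNames(names(sensor_code), sensor_code)
  sigs <- lapply(seq_len(ns), function(i) {
    phys <- pmin[i] + (raw_sig[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
    parts <- strsplit(labs[i], "/", fixed = TRUE)[[1]]
    sensor <- if (length(parts) == 2 && parts[1] %in% names(code2sensor)) code2sensor[[parts[1]]] else "chest"
    label <- if (length(parts) == 2) parts[2] else labs[i]
    t0 <- 0
    if (grepl("^t0=", resv[i])) t0 <- as.numeric(sub("^t0=", "", resv[i]))
    sensor_stream(phys, spr[i] / rec_s, label, sensor, t0_ms = t0, units = units[i])
  })
  # regroup dotted axis labels into matrix streams
  base <- vapply(sigs, function(s) sub("\\.[a-z]+$", "", s$label), character(1))
  key <- paste(vapply(sigs, `[[`, character(1), "sensor"), base)
  out <- list()
  for (k in unique(key)) {
    grp <- sigs[key == k]
    if (length(grp) == 1L) { out[[length(out) + 1L]] <- grp[[1]]; next }
    axes <- vapply(grp, function(s) sub("^.*\\.", "", s$label), character(1))
    m <- do.call(cbind, lapply(grp, `[[`, "samples")); colnames(m) <- axes
    s0 <- grp[[1]]; s0$samples <- m; s0$label <- base[key == k][1]
    out[[length(out) + 1L]] <- s0
  }
  out
}

# ---- WAV (PCM 16-bit mono) ----

#' Write a mono PCM 16-bit WAV file
#' @param samples numeric vector in [-1, 1].
#' @param rate_hz sampling rate written to the header.
#' @param path output file.
#' @export
write_wav <- function(samples, rate_hz, path) {
  pcm <- as.integer(pmax(-32767, pmin(32767, round(samples * 32767))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(rate_hz)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rate_hz) * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM 16-bit WAV file
#' @param path file to read.
#' @return list with `samples` (numeric in [-1, 1]) and `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF") stop("not a RIFF/WAV file")
  readBin(con, integer(), 1, size = 4, endian = "little")
  readChar(con, 4, useBytes = TRUE)
  rate <- NA_real_; nbytes <- 0L
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) stop("no data chunk in WAV file")
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), sz / 2, size = 2, endian = "little", signed = FALSE)
      rate <- fmt[3] + fmt[4] * 65536
    } else if (id == "data") { nbytes <- sz; break } else readBin(con, raw(), sz)
  }
  pcm <- readBin(con, integer(), nbytes / 2, size = 2, endian = "little", signed = TRUE)
  list(samples = pcm / 32767, rate_hz = rate)
}
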