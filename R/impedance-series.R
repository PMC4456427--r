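#' Standard ECIS acquisition frequencies
#'
#' The 11-point frequency grid of the ECIS instrument family, in Hz
#' (62.5 Hz to 64 kHz in octave steps).
#'
#' @export
ecis_frequencies <- function() {
  c(62.5, 125, 250, 500, 1000, 2000, 4000, 8000, 16000, 32000, 64000)
}

#' Multi-frequency complex impedance time series
#'
#' Container for an ECIS experiment: complex impedance indexed by
#' (time, well, frequency). Times are stored in seconds (instrument native);
#' analysis-facing channel traces are in hours. Cells that were never
#' measured, or read as NA, are flagged missing rather than dropped.
#'
#' @param times numeric vector, seconds since experiment start, strictly
#'   increasing.
#' @param wells character vector of well identifiers.
#' @param frequencies numeric vector of frequencies in Hz, strictly
#'   increasing and positive.
#' @param z complex array of dimension `length(times) x length(wells) x
#'   length(frequencies)`, impedance in Ohm. May contain NA for missing
#'   sweeps.
#' @param metadata list with electrode geometry: `electrode_area_cm2`
#'   (default 5e-4), `electrode_diameter_um` (default 250),
#'   `medium_resistivity_ohm_cm` (default 54).
#' @return an object of class `ecis_its`.
#' @export
impedance_timeseries <- function(times, wells, frequencies, z,
                                 metadata = list()) {
  times <- as.numeric(times)
  wells <- as.character(wells)
  frequencies <- as.numeric(frequencies)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_domain("times must be strictly increasing (first offending index: ",
                which(diff(times) <= 0)[1] + 1, ")")
  }
  if (any(frequencies <= 0) || (length(frequencies) > 1 &&
                                any(diff(frequencies) <= 0))) {
    stop_domain("frequencies must be positive and strictly increasing")
  }
  dims <- c(length(times), length(wells), length(frequencies))
  if (!is.array(z) || !all(dim(z) == dims)) {
    stop_domain("z must be a complex array of dim (time, well, frequency)")
  }
  storage.mode(z) <- "complex"
  miss <- is.na(z)
  if (any(Re(z)[!miss] < 0)) {
    stop_domain("negative resistance (Re Z < 0) encountered")
  }
  md <- list(electrode_area_cm2 = 5e-4, electrode_diameter_um = 250,
             medium_resistivity_ohm_cm = 54)
  md[names(metadata)] <- metadata
  structure(list(times = times, wells = wells, frequencies = frequencies,
                 z = z, missing = miss, metadata = md),
            class = "ecis_its")
}

#' @export
print.ecis_its <- function(x, ...) {
  cat("<ecis_its> ", length(x$times), " sweeps x ", length(x$wells),
      " wells x ", length(x$frequencies), " frequencies\n", sep = "")
  cat("  time span: ", round(min(x$times) / 3600, 2), " - ",
      round(max(x$times) / 3600, 2), " h; ",
      sum(x$missing), " missing cells\n", sep = "")
  invisible(x)
}

#' Convert a complex impedance to its series resistance and capacitance
#'
#' Interprets Z as a series RC circuit, the reporting convention of
#' lock-in-amplifier based ECIS instruments (in-phase and out-of-phase
#' components): R = Re(Z), C = -1 / (2 pi f Im(Z)). When Im(Z) >= 0 the
#' sample is non-capacitive and C is returned as NA with `capacitive`
#' FALSE.
#'
#' @param z complex impedance in Ohm (vectorised).
#' @param f frequency in Hz (scalar or vector recycled against `z`).
#' @return list with numeric `R` (Ohm), `C` (F, NA where undefined) and
#'   logical `capacitive`.
#' @export
complex_to_series_rc <- function(z, f) {
  if (any(f <= 0)) stop_domain("f must be > 0")
  cap <- !is.na(z) & Im(z) < 0
  C <- rep(NA_real_, length(z))
  C[cap] <- -1 / (2 * pi * rep_len(f, length(z))[cap] * Im(z[cap]))
  list(R = Re(z), C = C, capacitive = cap)
}

#' Extract a single-frequency resistance or capacitance channel
#'
#' Pulls one well's trace at one acquisition frequency out of an
#' [impedance_timeseries()] and converts it to the series-RC channel
#' presentation used throughout ECIS analysis (e.g. R at 4 kHz, C at
#' 64 kHz). Times are converted to hours; missing sweeps propagate as NA.
#'
#' @param ts an `ecis_its` object.
#' @param well well identifier.
#' @param f frequency in Hz; must be one of `ts$frequencies`.
#' @param kind `"R"` (resistance, Ohm) or `"C"` (capacitance, F).
#' @return an `ecis_channel` object: data.frame with columns `time_h`,
#'   `value`, and attributes `kind`, `well`, `frequency_hz`, `units`.
#' @export
extract_channel <- function(ts, well, f, kind = c("R", "C")) {
  kind <- match.arg(kind)
  stopifnot(inherits(ts, "ecis_its"))
  iw <- match(well, ts$wells)
  if (is.na(iw)) stop_domain("unknown well: ", well)
  jf <- which(abs(ts$frequencies - f) < 1e-9)
  if (length(jf) != 1) stop_domain("frequency ", f, " Hz not in acquisition grid")
  z <- ts$z[, iw, jf]
  rc <- complex_to_series_rc(z, f)
  value <- if (kind == "R") rc$R else rc$C
  value[ts$missing[, iw, jf]] <- NA_real_
  channel_trace(ts$times / 3600, value, kind = kind, well = well,
                frequency_hz = f)
}

#' Construct a channel trace
#'
#' @param time_h times in hours.
#' @param value channel values (Ohm for R, F for C).
#' @param kind `"R"` or `"C"`.
#' @param well well identifier.
#' @param frequency_hz acquisition frequency.
#' @return an `ecis_channel` data.frame.
#' @export
channel_trace <- function(time_h, value, kind = c("R", "C"), well = "A1",
                          frequency_hz = 4000) {
  kind <- match.arg(kind)
  if (length(time_h) != length(value)) {
    stop_domain("time_h and value must have the same length")
  }
  structure(data.frame(time_h = as.numeric(time_h),
                       value = as.numeric(value)),
            kind = sprintf("%s@%gkHz", kind, frequency_hz / 1000),
            channel = kind, well = well, frequency_hz = frequency_hz,
            units = if (kind == "R") "Ohm" else "F",
            class = c("ecis_channel", "data.frame"))
}

#' Restrict a channel trace to a time window
#'
#' @param trace an `ecis_channel`.
#' @param from,to window bounds in hours (inclusive).
#' @return the windowed `ecis_channel` (attributes preserved).
#' @export
window_channel <- function(trace, from = -Inf, to = Inf) {
  keep <- trace$time_h >= from & trace$time_h <= to
  out <- trace[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("kind", "channel", "well", "frequency_hz", "units")] <-
    attributes(trace)[c("kind", "channel", "well", "frequency_hz", "units")]
  class(out) <- class(trace)
  out
}

#' Read a multi-frequency impedance time course from CSV
#'
#' Two dialects are supported. `"long"` (canonical): columns `time_s, well,
#' frequency_hz, z_real_ohm, z_imag_ohm`, one row per (sweep, well,
#' frequency). `"wide"` (instrument-export style): columns `time_s, well`
#' and paired `R_<freq>` / `C_<freq>` columns holding the series resistance
#' in Ohm and series capacitance in nF at each frequency; these are
#' converted to complex impedance on read (Z = R - i/(2 pi f C)).
#' Combinations absent from the file, or with NA values, become flagged
#' missing cells. Duplicated (time, well, frequency) rows are an error.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param metadata optional metadata list, see [impedance_timeseries()].
#' @return an `ecis_its` object.
#' @export
read_timecourse <- function(path, dialect = c("long", "wide"),
                            metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_domain("file not found: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  if (dialect == "long") {
    need <- c("time_s", "well", "frequency_hz", "z_real_ohm", "z_imag_ohm")
    miss <- setdiff(need, names(dt))
    if (length(miss)) {
      stop_domain("malformed header in read_timecourse: missing column(s) ",
                  paste(miss, collapse = ", "))
    }
    long <- data.frame(time_s = as.numeric(dt$time_s),
                       well = as.character(dt$well),
                       frequency_hz = as.numeric(dt$frequency_hz),
                       z = complex(real = as.numeric(dt$z_real_ohm),
                                   imaginary = as.numeric(dt$z_imag_ohm)))
  } else {
    need <- c("time_s", "well")
    miss <- setdiff(need, names(dt))
    if (length(miss)) {
      stop_domain("malformed header in read_timecourse: missing column(s) ",
                  paste(miss, collapse = ", "))
    }
    rcols <- grep("^R_", names(dt), value = TRUE)
    freqs <- as.numeric(sub("^R_", "", rcols))
    if (!length(rcols) || any(is.na(freqs))) {
      stop_domain("malformed header in read_timecourse: no parseable R_<freq> columns")
    }
    ccols <- paste0("C_", sub("^R_", "", rcols))
    if (!all(ccols %in% names(dt))) {
      stop_domain("malformed header in read_timecourse: missing column(s) ",
                  paste(setdiff(ccols, names(dt)), collapse = ", "))
    }
    pieces <- lapply(seq_along(rcols), function(k) {
      f <- freqs[k]
      R <- as.numeric(dt[[rcols[k]]])
      C_nf <- as.numeric(dt[[ccols[k]]])
      im <- -1 / (2 * pi * f * (C_nf * 1e-9))
      data.frame(time_s = as.numeric(dt$time_s),
                 well = as.character(dt$well),
                 frequency_hz = f,
                 z = complex(real = R, imaginary = im))
    })
    long <- do.call(rbind, pieces)
  }

  key <- paste(long$time_s, long$well, long$frequency_hz, sep = "\r")
  if (anyDuplicated(key)) {
    stop_domain("duplicated (time, well, frequency) row at file row ",
                which(duplicated(key))[1])
  }
  times <- sort(unique(long$time_s))
  # reject files whose per-well time ordering is broken before sorting hides it
  for (w in unique(long$well)) {
    tw <- long$time_s[long$well == w]
    tw_by_freq <- split(tw, long$frequency_hz[long$well == w])
    for (v in tw_by_freq) {
      if (length(v) > 1 && any(diff(v) < 0)) {
        stop_domain("non-monotone time within well ", w,
                    " (first offending row index: ",
                    which(diff(v) < 0)[1] + 1, ")")
      }
    }
  }
  wells <- unique(long$well)
  freqs <- sort(unique(long$frequency_hz))
  z <- array(NA_complex_, c(length(times), length(wells), length(freqs)))
  it <- match(long$time_s, times)
  iw <- match(long$well, wells)
  jf <- match(long$frequency_hz, freqs)
  z[cbind(it, iw, jf)] <- long$z
  impedance_timeseries(times, wells, freqs, z, metadata)
}

#' Write a multi-frequency impedance time course to CSV (long dialect)
#'
#' Inverse of [read_timecourse()] for the canonical long dialect. Missing
#' cells are omitted from the file (they are reconstructed as flagged
#' missing on read).
#'
#' @param ts an `ecis_its` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(ts, path) {
  stopifnot(inherits(ts, "ecis_its"))
  idx <- which(!ts$missing, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  z <- ts$z[idx]
  # numeric columns as 17-significant-digit strings so the round trip is
  # bit-exact for doubles
  g17 <- function(x) sprintf("%.17g", x)
  dt <- data.table::data.table(
    time_s = g17(ts$times[idx[, 1]]),
    well = ts$wells[idx[, 2]],
    frequency_hz = g17(ts$frequencies[idx[, 3]]),
    z_real_ohm = g17(Re(z)),
    z_imag_ohm = g17(Im(z)))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}
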