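#' Uniformly sampled voltage or current trace
#'
#' The substrate of every analysis stage: a numeric vector of samples with a
#' sampling rate, a start time and physical units (mV for voltage, pA for
#' current).  Time is in seconds with t = 0 at the trace start by default;
#' sample indices are 0-based in time arithmetic and all windows are
#' half-open \code{[start, end)}.
#'
#' @param samples numeric vector, all finite, length >= 2.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param units \code{"mV"} or \code{"pA"}.
#' @param channel_id free-text channel label.
#' @return An object of class \code{time_series}.
#' @examples
#' ts <- time_series(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), 1000)
#' duration(ts)
#' @export
time_series <- function(samples, sampling_rate, t0 = 0, units = "mV",
                        channel_id = "ch0") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("time_series needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("non-finite samples in trace")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar (Hz)")
  units <- match.arg(units, c("mV", "pA"))
  structure(list(samples = samples, sampling_rate = as.numeric(sampling_rate),
                 t0 = as.numeric(t0), units = units,
                 channel_id = as.character(channel_id)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s | %d samples @ %g Hz | %.3f s | [%s]\n",
              x$channel_id, length(x$samples), x$sampling_rate,
              duration(x), x$units))
  invisible(x)
}

#' @rdname time_series
#' @param x a \code{time_series}.
#' @export
duration <- function(x) length(x$samples) / x$sampling_rate

#' Sample times of a trace, in seconds
#' @param x a \code{time_series}.
#' @return numeric vector \code{t0 + (0:(n-1))/rate}.
#' @export
time_points <- function(x) x$t0 + (seq_along(x$samples) - 1) / x$sampling_rate

#' Oscillation band definition
#'
#' The three canonical bands used throughout: theta 5--14 Hz, low gamma
#' 25--55 Hz, high gamma 56--120 Hz.  \code{band_definition(label)} returns
#' the canonical band; explicit edges may be supplied for non-standard bands.
#'
#' @param label \code{"theta"}, \code{"low_gamma"} or \code{"high_gamma"}.
#' @param f_low,f_high band edges in Hz; default to the canonical values.
#' @return An object of class \code{band_definition}.
#' @export
band_definition <- function(label, f_low = NULL, f_high = NULL) {
  canon <- list(theta = c(5, 14), low_gamma = c(25, 55), high_gamma = c(56, 120))
  label <- match.arg(label, names(canon))
  if (is.null(f_low)) f_low <- canon[[label]][1]
  if (is.null(f_high)) f_high <- canon[[label]][2]
  if (!(f_low > 0 && f_low < f_high))
    stop("band edges must satisfy 0 < f_low < f_high")
  structure(list(label = label, f_low = f_low, f_high = f_high),
            class = "band_definition")
}

#' Filter specification
#'
#' Houses the filter settings the analyses use (0.2--50 Hz LFP band for the
#' spike-triggered average, > 500 Hz for multi-unit activity, 300--4500 Hz
#' for spike extraction).  Filters are IIR (Butterworth) designs applied
#' zero-phase (forward-backward) by default, so that filtering introduces no
#' group delay into latency measurements.
#'
#' @param kind \code{"lowpass"}, \code{"highpass"} or \code{"bandpass"}.
#' @param cutoffs one cutoff (low/highpass) or two ordered cutoffs (bandpass), Hz.
#' @param order filter order (default 4).
#' @param zero_phase apply forward-backward (default \code{TRUE}).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(kind, cutoffs, order = 4L, zero_phase = TRUE) {
  kind <- match.arg(kind, c("lowpass", "highpass", "bandpass"))
  cutoffs <- as.numeric(cutoffs)
  if (kind == "bandpass") {
    if (length(cutoffs) != 2L || !(0 < cutoffs[1] && cutoffs[1] < cutoffs[2]))
      stop("bandpass needs two ordered positive cutoffs")
  } else if (length(cutoffs) != 1L || cutoffs <= 0) {
    stop(kind, " needs one positive cutoff")
  }
  structure(list(kind = kind, cutoffs = cutoffs, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Apply an IIR filter to a trace
#'
#' Designs a Butterworth filter from \code{spec} and applies it to the trace,
#' forward-backward (zero phase) when \code{spec$zero_phase} is set.  Length
#' and sampling rate are preserved.
#'
#' @param trace a \code{time_series}.
#' @param spec a \code{filter_spec}; all cutoffs must lie below the Nyquist
#'   frequency of \code{trace}.
#' @return the filtered \code{time_series}.
#' @export
bandpass_filter <- function(trace, spec) {
  stopifnot(inherits(trace, "time_series"), inherits(spec, "filter_spec"))
  nyq <- trace$sampling_rate / 2
  if (any(spec$cutoffs >= nyq))
    stop("filter cutoff at or above Nyquist (", nyq, " Hz)")
  w <- spec$cutoffs / nyq
  run <- function(bf, x) if (spec$zero_phase) signal::filtfilt(bf, x)
                         else as.numeric(signal::filter(bf, x))
  x0 <- trace$samples
  # remove the DC level before high-pass stages: it is rejected by the filter
  # anyway, and subtracting it first avoids large edge transients
  if (spec$kind != "lowpass") x0 <- x0 - mean(x0)
  # bandpass as highpass-lowpass cascade: a direct bandpass design is
  # numerically unstable when the cutoffs sit many decades apart (e.g.
  # 0.2-50 Hz at a 10 kHz rate)
  y <- if (spec$kind == "bandpass") {
    run(signal::butter(spec$order, w[2], type = "low"),
        run(signal::butter(spec$order, w[1], type = "high"), x0))
  } else {
    type <- if (spec$kind == "lowpass") "low" else "high"
    run(signal::butter(spec$order, w, type = type), x0)
  }
  out <- trace
  out$samples <- as.numeric(y)
  out
}

#' Extract a time window from a trace
#'
#' Half-open window \code{[t_start, t_end)} relative to the trace's own time
#' base; the result keeps \code{t0 = t_start} and contains
#' \code{floor((t_end - t_start) * rate)} samples.
#'
#' @param trace a \code{time_series}.
#' @param t_start,t_end window bounds in seconds, within the trace span.
#' @return a \code{time_series}.
#' @export
segment <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "time_series"))
  n <- length(trace$samples)
  t_last <- trace$t0 + n / trace$sampling_rate
  if (!(trace$t0 <= t_start && t_start < t_end && t_end <= t_last + 1e-9))
    stop("segment window [", t_start, ", ", t_end, ") out of trace range")
  i0 <- round((t_start - trace$t0) * trace$sampling_rate)
  cnt <- floor((t_end - t_start) * trace$sampling_rate + 1e-9)
  out <- trace
  out$samples <- trace$samples[(i0 + 1):(i0 + cnt)]
  out$t0 <- t_start
  out
}

#' Read a trace from disk
#'
#' Two on-disk layouts are supported.  \code{csv}: two columns
#' \code{time_s,value} with a header, plus a JSON sidecar \code{<name>.meta}
#' carrying \code{sampling_rate}, \code{units} and \code{channel_id}.
#' \code{rawbin}: little-endian float64 samples in \code{<name>.f64} with the
#' same sidecar.  Both round-trip bit-exactly with \code{\link{write_trace}}.
#'
#' @param path path to the \code{.csv} or \code{.f64} file.
#' @param format \code{"csv"} or \code{"rawbin"}.
#' @return a \code{time_series}.
#' @export
read_trace <- function(path, format = c("csv", "rawbin")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- paste0(sub("\\.(csv|f64)$", "", path), ".meta")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("sampling_rate", "units"))
    if (is.null(meta[[field]]))
      stop("sidecar metadata lacks required field '", field, "'")
  samples <- if (format == "csv") {
    utils::read.csv(path)$value
  } else {
    n <- file.info(path)$size / 8
    readBin(path, "double", n = n, size = 8, endian = "little")
  }
  if (!all(is.finite(samples))) stop("non-finite samples in ", path)
  time_series(samples, meta$sampling_rate,
              t0 = if (is.null(meta$t0)) 0 else meta$t0,
              units = meta$units,
              channel_id = if (is.null(meta$channel_id)) "ch0" else meta$channel_id)
}

#' @rdname read_trace
#' @param trace a \code{time_series} to write.
#' @export
write_trace <- function(trace, path, format = c("csv", "rawbin")) {
  format <- match.arg(format)
  stopifnot(inherits(trace, "time_series"))
  meta_path <- paste0(sub("\\.(csv|f64)$", "", path), ".meta")
  jsonlite::write_json(list(sampling_rate = trace$sampling_rate,
                            units = trace$units, t0 = trace$t0,
                            channel_id = trace$channel_id),
                       meta_path, auto_unbox = TRUE, digits = NA)
  if (format == "csv") {
    # %.17g keeps the CSV round-trip bit-exact for float64 samples
    utils::write.csv(data.frame(time_s = sprintf("%.17g", time_points(trace)),
                                value = sprintf("%.17g", trace$samples)),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    writeBin(trace$samples, path, size = 8, endian = "little")
  }
  invisible(path)
}
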