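#' Welch power spectral density estimate
#'
#' Averages windowed periodograms over 50%-overlapping Hann segments.  With
#' the default 2048-sample window at 10 kHz the bin width is 10000/2048 =
#' 4.88 Hz, i.e. roughly 5 Hz frequency resolution.  The one-sided density
#' is scaled so that its integral over [0, Nyquist] equals the signal
#' variance (each segment is mean-subtracted before windowing).
#'
#' @param trace a \code{\link{time_series}} at least one window long.
#' @param window_len segment length in samples (default 2048).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param window_kind taper; only \code{"hanning"} is provided.
#' @return An object of class \code{psd_estimate}: \code{freqs} (Hz),
#'   \code{density} (power per Hz), \code{window_len}, \code{overlap},
#'   \code{window_kind}, \code{n_segments}.
#' @export
welch_psd <- function(trace, window_len = 2048L, overlap = 0.5,
                      window_kind = "hanning") {
  stopifnot(inherits(trace, "time_series"))
  x <- trace$samples
  n <- length(x)
  window_len <- as.integer(window_len)
  if (n < window_len)
    stop("trace shorter than one window (", window_len, " samples)")
  window_kind <- match.arg(window_kind, "hanning")
  fs <- trace$sampling_rate
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, window_len - 1) / (window_len - 1))
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq(1L, n - window_len + 1L, by = step)
  nfreq <- window_len %/% 2 + 1L
  acc <- numeric(nfreq)
  scale <- fs * sum(w^2)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[1:nfreq]
  }
  dens <- acc / length(starts)
  # one-sided: double everything except DC and (even n) Nyquist
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (window_len %% 2 == 0) dbl[nfreq] <- 1
  dens <- dens * dbl
  structure(list(freqs = (0:(nfreq - 1L)) * fs / window_len, density = dens,
                 window_len = window_len, overlap = overlap,
                 window_kind = window_kind, n_segments = length(starts)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, df = %.3f Hz, %d segments (%s %d, %.0f%% overlap)\n",
              length(x$freqs), x$freqs[2], x$n_segments, x$window_kind,
              x$window_len, 100 * x$overlap))
  invisible(x)
}

#' Relative amplitude of a band signal
#'
#' The band signal centred on its own mean and divided by the standard
#' deviation of the raw LFP it was extracted from.  Normalizing by the raw
#' trace (rather than the band itself) makes band power comparable across
#' recordings and genotypes with different overall LFP amplitude.
#'
#' @param band a \code{band_signal} from \code{\link{assemble_band}}.
#' @return dimensionless numeric vector, same length as the band.
#' @export
relative_amplitude <- function(band) {
  stopifnot(inherits(band, "band_signal"))
  if (!is.finite(band$source_sd) || band$source_sd <= 0)
    stop("source trace has zero standard deviation")
  (band$samples - mean(band$samples)) / band$source_sd
}

#' Average relative power of a band
#'
#' Mean of the squared relative amplitude, i.e. the band's variance as a
#' fraction of the raw LFP variance.  Dimensionless; invariant under global
#' rescaling of the recording.
#'
#' @inheritParams relative_amplitude
#' @return scalar in \code{[0, ...)}; for a band equal to its source, 1.
#' @export
average_relative_power <- function(band) {
  z <- relative_amplitude(band)
  sum(z^2) / length(z)
}

#' Band occurrence frequency
#'
#' Counts oscillation cycles whose amplitude exceeds a threshold.  The band
#' signal is z-scored against its own mean and standard deviation; a cycle is
#' the interval between consecutive upward zero crossings of the z-scored
#' signal, and it is counted when its peak absolute z exceeds
#' \code{threshold_sd}.  Dividing the count by the trace duration gives the
#' occurrence frequency in Hz.  With the default threshold of 2 sd only
#' cycles beyond roughly the 95th amplitude percentile count; a pure
#' constant-amplitude sinusoid (peak z = sqrt(2)) therefore yields zero.
#'
#' Note the z-scoring here uses the band's own sd, unlike
#' \code{\link{relative_amplitude}} which normalizes by the raw LFP sd.
#'
#' @inheritParams relative_amplitude
#' @param threshold_sd amplitude threshold in band standard deviations
#'   (default 2).
#' @return An object of class \code{occurrence_result}: \code{band} label,
#'   \code{cycle_count}, \code{duration} (s), \code{occurrence_frequency}
#'   (Hz), \code{threshold_sd}.
#' @export
band_occurrence_frequency <- function(band, threshold_sd = 2) {
  stopifnot(inherits(band, "band_signal"))
  x <- band$samples
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("flat band signal: occurrence undefined")
  z <- (x - mean(x)) / s
  up <- which(z[-length(z)] < 0 & z[-1] >= 0)   # upward zero crossings
  if (length(up) < 2) stop("band has fewer than 2 zero crossings")
  count <- 0L
  for (k in seq_len(length(up) - 1L)) {
    if (max(abs(z[(up[k] + 1L):up[k + 1L]])) > threshold_sd) count <- count + 1L
  }
  dur <- length(x) / band$sampling_rate
  structure(list(band = band$band$label, cycle_count = count, duration = dur,
                 occurrence_frequency = count / dur, threshold_sd = threshold_sd),
            class = "occurrence_result")
}

#' @export
print.occurrence_result <- function(x, ...) {
  cat(sprintf("<occurrence_result> %s: %d cycles / %.1f s = %.3f Hz (threshold %g sd)\n",
              x$band, x$cycle_count, x$duration, x$occurrence_frequency,
              x$threshold_sd))
  invisible(x)
}

#' Band metrics table
#'
#' Convenience wrapper: decomposes nothing itself, but given an
#' \code{imf_set} and its source trace computes, per canonical band, the
#' average relative power and the occurrence frequency.
#'
#' @param imfset an \code{imf_set}.
#' @param source the raw \code{time_series}.
#' @param bands character vector of canonical band labels.
#' @param threshold_sd occurrence threshold (default 2).
#' @return data.frame: band, average_relative_power, cycle_count,
#'   occurrence_frequency_hz, duration_s.
#' @export
band_metrics <- function(imfset, source,
                         bands = c("theta", "low_gamma", "high_gamma"),
                         threshold_sd = 2) {
  rows <- lapply(bands, function(b) {
    bs <- assemble_band(imfset, band_definition(b), source)
    occ <- if (bs$empty) NULL else
      tryCatch(band_occurrence_frequency(bs, threshold_sd),
               error = function(e) NULL)
    data.frame(band = b,
               average_relative_power = if (bs$empty) 0 else average_relative_power(bs),
               cycle_count = if (is.null(occ)) NA_integer_ else occ$cycle_count,
               occurrence_frequency_hz = if (is.null(occ)) NA_real_ else occ$occurrence_frequency,
               duration_s = duration(source))
  })
  do.call(rbind, rows)
}
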