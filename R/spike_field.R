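#' Construct a spike train
#'
#' @param times spike times in seconds, strictly increasing.
#' @param source_id label of the source recording.
#' @param detection optional list recording how the spikes were obtained.
#' @return An object of class \code{spike_train} with fields \code{times},
#'   \code{n}, \code{source_id}, \code{detection}.
#' @export
spike_train <- function(times, source_id = "unknown", detection = list()) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  structure(list(times = times, n = length(times), source_id = source_id,
                 detection = detection),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes from %s\n", x$n, x$source_id))
  invisible(x)
}

#' Threshold spike detection on a filtered extracellular trace
#'
#' Filters the raw trace (default band 300--4500 Hz), estimates a robust
#' noise level as \code{median(|x|)/0.6745} (raw sd would be inflated by the
#' spikes themselves), and takes each excursion of the filtered trace beyond
#' \code{threshold_sd} times that level as a spike.  The spike time is the
#' extremum of the excursion, not the threshold crossing, for sub-millisecond
#' timing stability; detections closer than \code{refractory_s} are merged,
#' keeping the larger one.  Polarity is auto-detected from the larger
#' absolute extremum of the filtered trace.
#'
#' @param trace raw extracellular \code{\link{time_series}}, > 1 s long.
#' @param filter a \code{\link{filter_spec}}; default bandpass 300--4500 Hz
#'   (a highpass at 500 Hz is the usual choice for MUA extraction before
#'   spike-triggered averaging).
#' @param threshold_sd detection threshold in robust noise sd (default 5).
#' @param refractory_s merge window in seconds (default 1 ms).
#' @return a \code{spike_train}.
#' @export
detect_spikes <- function(trace,
                          filter = filter_spec("bandpass", c(300, 4500)),
                          threshold_sd = 5, refractory_s = 0.001) {
  stopifnot(inherits(trace, "time_series"))
  if (duration(trace) <= 1)
    stop("trace too short for a stable noise estimate (need > 1 s)")
  filt <- bandpass_filter(trace, filter)
  x <- filt$samples
  noise_sd <- stats::median(abs(x)) / 0.6745
  if (noise_sd == 0) stop("degenerate input: zero noise level")
  thr <- threshold_sd * noise_sd
  # polarity from the dominant absolute extremum
  negative <- abs(min(x)) >= abs(max(x))
  y <- if (negative) -x else x
  above <- y > thr
  if (!any(above)) {
    return(spike_train(numeric(0), trace$channel_id,
                       detection = list(filter = filter, threshold_sd = threshold_sd,
                                        refractory_s = refractory_s,
                                        noise_sd = noise_sd, negative = negative)))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  peak_idx <- mapply(function(s, e) s - 1L + which.max(y[s:e]), starts, ends)
  peak_amp <- y[peak_idx]
  # merge within the refractory window, keep the larger excursion
  ord <- order(peak_idx)
  peak_idx <- peak_idx[ord]; peak_amp <- peak_amp[ord]
  keep_idx <- integer(0); keep_amp <- numeric(0)
  ref_samp <- refractory_s * trace$sampling_rate
  for (j in seq_along(peak_idx)) {
    if (length(keep_idx) > 0 && peak_idx[j] - keep_idx[length(keep_idx)] < ref_samp) {
      if (peak_amp[j] > keep_amp[length(keep_amp)]) {
        keep_idx[length(keep_idx)] <- peak_idx[j]
        keep_amp[length(keep_amp)] <- peak_amp[j]
      }
    } else {
      keep_idx <- c(keep_idx, peak_idx[j])
      keep_amp <- c(keep_amp, peak_amp[j])
    }
  }
  spike_train(trace$t0 + (keep_idx - 1) / trace$sampling_rate,
              trace$channel_id,
              detection = list(filter = filter, threshold_sd = threshold_sd,
                               refractory_s = refractory_s,
                               noise_sd = noise_sd, negative = negative))
}

#' Spike-triggered average LFP
#'
#' Band-passes the LFP (default 0.2--50 Hz), cuts a symmetric window
#' (default 1 s each side) around every spike, and averages across spikes.
#' Spikes within one window of either trace edge are skipped.  Alongside the
#' average waveform, the means over the 250 ms immediately before and after
#' the spike are reported; recordings whose multi-unit rate falls below
#' \code{min_rate_hz} (1 Hz) are flagged excluded rather than averaged.
#'
#' @param lfp raw LFP \code{\link{time_series}} sharing a time base with the
#'   spikes.
#' @param spikes a \code{\link{spike_train}}.
#' @param window_s half-window in seconds (default 1).
#' @param lfp_band two cutoffs in Hz for the LFP band (default c(0.2, 50)).
#' @param min_rate_hz exclusion threshold on the spike rate (default 1).
#' @return An object of class \code{sta_result}: \code{lags} (s),
#'   \code{mean_lfp} (mV), \code{n_spikes}, \code{pre_mean}, \code{post_mean}
#'   (mV over [-0.25, 0) and [0, 0.25) s), \code{excluded}, \code{reason}.
#' @export
spike_triggered_average <- function(lfp, spikes, window_s = 1.0,
                                    lfp_band = c(0.2, 50), min_rate_hz = 1.0) {
  stopifnot(inherits(lfp, "time_series"), inherits(spikes, "spike_train"))
  rate_hz <- spikes$n / duration(lfp)
  half <- round(window_s * lfp$sampling_rate)
  lags <- (-half:half) / lfp$sampling_rate
  if (rate_hz < min_rate_hz) {
    return(structure(list(lags = lags, mean_lfp = rep(NA_real_, 2 * half + 1),
                          n_spikes = 0L, pre_mean = NA_real_, post_mean = NA_real_,
                          excluded = TRUE,
                          reason = sprintf("spike rate %.3f Hz below %.3f Hz", rate_hz, min_rate_hz)),
                     class = "sta_result"))
  }
  flt <- bandpass_filter(lfp, filter_spec("bandpass", lfp_band))
  x <- flt$samples
  n <- length(x)
  idx <- round((spikes$times - lfp$t0) * lfp$sampling_rate) + 1L
  ok <- idx - half >= 1L & idx + half <= n
  idx <- idx[ok]
  if (length(idx) == 0L) stop("no spikes with a full window inside the trace")
  acc <- numeric(2L * half + 1L)
  for (i in idx) acc <- acc + x[(i - half):(i + half)]
  mean_lfp <- acc / length(idx)
  pre <- lags >= -0.25 & lags < 0
  post <- lags >= 0 & lags < 0.25
  structure(list(lags = lags, mean_lfp = mean_lfp, n_spikes = length(idx),
                 pre_mean = mean(mean_lfp[pre]), post_mean = mean(mean_lfp[post]),
                 excluded = FALSE, reason = NULL),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  if (x$excluded) {
    cat("<sta_result> EXCLUDED:", x$reason, "\n")
  } else {
    cat(sprintf("<sta_result> %d spikes; pre(-250-0 ms) %.4f mV, post(0-250 ms) %.4f mV\n",
                x$n_spikes, x$pre_mean, x$post_mean))
  }
  invisible(x)
}

#' Peri-spike band-power profile
#'
#' For each spike, the second before and the second after are split into ten
#' 100-ms bins each (20 bins total); the band's average relative power is
#' computed inside every bin and averaged across spikes.  Bins are computed
#' per spike independently, so windows of nearby spikes may overlap.
#'
#' @param band a \code{band_signal} derived from the LFP simultaneous with
#'   the spikes.
#' @param spikes a \code{\link{spike_train}}.
#' @return An object of class \code{spike_power_profile}: \code{band} label,
#'   \code{bin_edges} (21 edges from -1 to 1 s), \code{power_per_bin}
#'   (length 20, dimensionless), \code{n_spikes}.
#' @export
spike_power_profile <- function(band, spikes) {
  stopifnot(inherits(band, "band_signal"), inherits(spikes, "spike_train"))
  if (!is.finite(band$source_sd) || band$source_sd <= 0)
    stop("source trace has zero standard deviation")
  fs <- band$sampling_rate
  z <- (band$samples - mean(band$samples)) / band$source_sd
  n <- length(z)
  bin_len <- round(0.1 * fs)
  half <- 10L * bin_len
  idx <- round(spikes$times * fs) + 1L
  idx <- idx[idx - half >= 1L & idx + half <= n]
  if (length(idx) == 0L) stop("no spikes with a full 1 s window inside the trace")
  acc <- numeric(20L)
  for (i in idx) {
    seg2 <- z[(i - half):(i + half - 1L)]^2
    acc <- acc + colMeans(matrix(seg2, nrow = bin_len))
  }
  structure(list(band = band$band$label,
                 bin_edges = seq(-1, 1, by = 0.1),
                 power_per_bin = acc / length(idx),
                 n_spikes = length(idx)),
            class = "spike_power_profile")
}

#' @export
print.spike_power_profile <- function(x, ...) {
  cat(sprintf("<spike_power_profile> %s, %d spikes, 20 x 100 ms bins\n",
              x$band, x$n_spikes))
  invisible(x)
}
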