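#' Interspike-interval burst detection
#'
#' A burst is a sequence of two or more action potentials firing at >= 20 Hz,
#' i.e. a maximal run of consecutive interspike intervals each at most
#' \code{max_isi_s}.  Detection is a greedy left-to-right run-length scan, so
#' bursts are disjoint and ordered; burst boundaries are the first and last
#' spike of the run, with no padding.
#'
#' @param spikes a \code{\link{spike_train}}.
#' @param max_isi_s intra-burst ISI ceiling in seconds.  The 20 Hz burst
#'   definition corresponds to 0.05 s (the default); values used in practice
#'   range over 20--50 ms, and values outside that range raise a warning.
#' @return An object of class \code{burst_set}: data.frame \code{bursts}
#'   (start_s, end_s, n_spikes), \code{max_isi_s}, \code{source}.
#' @export
detect_bursts <- function(spikes, max_isi_s = 0.05) {
  stopifnot(inherits(spikes, "spike_train"))
  if (max_isi_s < 0.02 || max_isi_s > 0.05)
    warning("max_isi_s = ", max_isi_s, " s outside the usual 20-50 ms range")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0))
  if (spikes$n < 2L)
    return(structure(list(bursts = empty, max_isi_s = max_isi_s,
                          source = spikes$source_id), class = "burst_set"))
  t <- spikes$times
  inburst <- diff(t) <= max_isi_s
  d <- diff(c(FALSE, inburst, FALSE))
  run_start <- which(d == 1L)          # index into the ISI sequence
  run_end <- which(d == -1L) - 1L
  bursts <- data.frame(start_s = t[run_start],
                       end_s = t[run_end + 1L],
                       n_spikes = run_end - run_start + 2L)
  structure(list(bursts = bursts, max_isi_s = max_isi_s,
                 source = spikes$source_id),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts (max ISI %g ms) from %s\n",
              nrow(x$bursts), 1000 * x$max_isi_s, x$source))
  invisible(x)
}

#' Firing-rate decomposition
#'
#' Splits a unit's firing into total, single-spike and burst rates, plus the
#' mean within-burst firing frequency.  Spike counts are conserved: singles
#' plus intra-burst spikes equal the total.
#'
#' @param spikes a \code{\link{spike_train}}.
#' @param bursts the \code{burst_set} derived from those spikes.
#' @param duration_s recording duration in seconds (> 0).
#' @return An object of class \code{firing_metrics}: \code{total_rate},
#'   \code{single_rate}, \code{burst_rate} (all Hz), \code{intraburst_rate}
#'   (Hz, mean over bursts of (n_spikes - 1)/(end - start); \code{NA} with no
#'   bursts), \code{n_spikes}, \code{n_bursts}, \code{duration_s}.
#' @export
firing_metrics <- function(spikes, bursts, duration_s) {
  stopifnot(inherits(spikes, "spike_train"), inherits(bursts, "burst_set"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  b <- bursts$bursts
  n_burst_spikes <- sum(b$n_spikes)
  intraburst <- if (nrow(b) > 0)
    mean((b$n_spikes - 1L) / (b$end_s - b$start_s))
  else NA_real_
  structure(list(total_rate = spikes$n / duration_s,
                 single_rate = (spikes$n - n_burst_spikes) / duration_s,
                 burst_rate = nrow(b) / duration_s,
                 intraburst_rate = intraburst,
                 n_spikes = spikes$n, n_bursts = nrow(b),
                 duration_s = duration_s),
            class = "firing_metrics")
}

#' @export
print.firing_metrics <- function(x, ...) {
  cat(sprintf("<firing_metrics> total %.2f Hz | single %.2f Hz | burst %.2f Hz | intraburst %.1f Hz\n",
              x$total_rate, x$single_rate, x$burst_rate, x$intraburst_rate))
  invisible(x)
}

#' Spike half-width
#'
#' Full width of the spike waveform at half of its peak amplitude, in ms.
#' Baseline is the median of the first 20% of the window; polarity is taken
#' from the larger absolute deflection; crossing times are linearly
#' interpolated between samples.
#'
#' @param waveform a \code{\link{time_series}} holding one spike waveform.
#' @return half-width in milliseconds.
#' @export
spike_half_width <- function(waveform) {
  stopifnot(inherits(waveform, "time_series"))
  x <- waveform$samples
  n <- length(x)
  base <- stats::median(x[seq_len(max(2L, floor(0.2 * n)))])
  y <- x - base
  if (abs(min(y)) > abs(max(y))) y <- -y
  pk <- which.max(y)
  if (y[pk] <= 0) stop("no peak above baseline")
  half <- y[pk] / 2
  left <- NULL
  for (i in seq(pk, 2L)) {
    if (y[i - 1L] < half && y[i] >= half) {
      left <- (i - 1L) + (half - y[i - 1L]) / (y[i] - y[i - 1L])
      break
    }
  }
  right <- NULL
  for (i in seq(pk, n - 1L)) {
    if (y[i] >= half && y[i + 1L] < half) {
      right <- i + (y[i] - half) / (y[i] - y[i + 1L])
      break
    }
  }
  if (is.null(left) || is.null(right))
    stop("waveform does not cross half amplitude on both sides of the peak")
  1000 * (right - left) / waveform$sampling_rate
}
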