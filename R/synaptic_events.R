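#' Biexponential synaptic-current template
#'
#' \code{(1 - exp(-t/rise)) * exp(-t/decay)}, peak-normalized, with the sign
#' of the configured polarity.  Default kinetics: rise 0.5 ms / decay 8 ms
#' for IPSC-like events; use rise 0.3 ms / decay 4 ms for EPSC-like ones.
#'
#' @param rise_ms,decay_ms time constants in ms.
#' @param rate sampling rate in Hz.
#' @param duration_ms template length in ms (default rise + 5 x decay).
#' @param polarity \code{"negative"} (inward current) or \code{"positive"}.
#' @return numeric vector, peak amplitude 1 (or -1).
#' @export
make_template <- function(rise_ms, decay_ms, rate, duration_ms = NULL,
                          polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (is.null(duration_ms)) duration_ms <- rise_ms + 5 * decay_ms
  t <- seq(0, duration_ms / 1000, by = 1 / rate)
  y <- (1 - exp(-t / (rise_ms / 1000))) * exp(-t / (decay_ms / 1000))
  y <- y / max(y)
  if (polarity == "negative") -y else y
}

#' Sliding-template synaptic event detection
#'
#' The template is slid along the trace one sample at a time and optimally
#' scaled and offset (least squares) against the data at each position; the
#' detection criterion is the fitted scale divided by its standard error
#' (the Clements-Bekkers criterion).  Local maxima of the criterion above
#' \code{criterion_threshold} yield events; candidates closer than one
#' template length keep the higher score.  Because both scale and its error
#' grow linearly with the data, the criterion -- and hence detection -- is
#' invariant to amplitude rescaling of the recording.
#'
#' @param trace a \code{\link{time_series}} (current, pA).
#' @param template numeric template, shorter than the trace, e.g. from
#'   \code{\link{make_template}}; its dominant deflection must have the
#'   configured polarity.
#' @param criterion_threshold detection threshold (default 3).
#' @param polarity \code{"negative"} or \code{"positive"} event polarity.
#' @param keep_series also attach the full per-position \code{scale} and
#'   \code{score} series as attributes (for diagnostics).
#' @return data.frame of class \code{synaptic_events}: \code{onset_s},
#'   \code{peak_amplitude_pA} (signed), \code{detection_score}.
#' @export
template_detect <- function(trace, template, criterion_threshold = 3,
                            polarity = c("negative", "positive"),
                            keep_series = FALSE) {
  stopifnot(inherits(trace, "time_series"))
  polarity <- match.arg(polarity)
  Tm <- as.numeric(template)
  M <- length(Tm)
  d <- trace$samples
  N <- length(d)
  if (M >= N) stop("template must be shorter than the trace")
  if (stats::sd(Tm) == 0) stop("flat template")
  pk <- if (polarity == "negative") min(Tm) else max(Tm)
  if ((polarity == "negative") != (abs(min(Tm)) > abs(max(Tm))))
    stop("template polarity does not match the requested event polarity")

  S_T <- sum(Tm); S_T2 <- sum(Tm^2)
  denom <- S_T2 - S_T^2 / M
  npos <- N - M + 1L
  # running cross-products and window sums
  ctd <- stats::filter(d, rev(Tm), method = "convolution", sides = 1)
  S_TD <- as.numeric(ctd[M:N])
  cs <- cumsum(c(0, d)); cs2 <- cumsum(c(0, d^2))
  S_D <- cs[(M + 1L):(N + 1L)] - cs[1:npos]
  S_D2 <- cs2[(M + 1L):(N + 1L)] - cs2[1:npos]

  scale <- (S_TD - S_T * S_D / M) / denom
  offset <- (S_D - scale * S_T) / M
  sse <- S_D2 + scale^2 * S_T2 + M * offset^2 -
    2 * scale * S_TD - 2 * offset * S_D + 2 * scale * offset * S_T
  sse[sse < 0] <- 0
  se <- sqrt(sse / (M - 1L))
  # a perfect (zero-residual) fit has an unbounded criterion
  score <- ifelse(se > 0, scale / se, ifelse(scale > 0, Inf, 0))

  # local maxima of the criterion above threshold
  cand <- which(score > criterion_threshold)
  cand <- cand[cand > 1L & cand < npos]
  cand <- cand[score[cand] >= score[cand - 1L] & score[cand] >= score[cand + 1L]]
  # enforce min separation of one template length, higher score wins
  keep <- logical(length(cand))
  taken <- rep(FALSE, npos)
  for (j in order(score[cand], decreasing = TRUE)) {
    i <- cand[j]
    if (!taken[i]) {
      keep[j] <- TRUE
      lo <- max(1L, i - M + 1L); hi <- min(npos, i + M - 1L)
      taken[lo:hi] <- TRUE
    }
  }
  ev <- sort(cand[keep])
  out <- data.frame(onset_s = trace$t0 + (ev - 1L) / trace$sampling_rate,
                    peak_amplitude_pA = scale[ev] * pk,
                    detection_score = score[ev])
  class(out) <- c("synaptic_events", "data.frame")
  if (keep_series) {
    attr(out, "scale_series") <- scale
    attr(out, "score_series") <- score
  }
  out
}

#' Spontaneous-event summary statistics
#'
#' @param events a \code{synaptic_events} data.frame (or anything with an
#'   \code{onset_s} and \code{peak_amplitude_pA} column).
#' @param duration_s recording duration in seconds (> 0).
#' @return list: \code{frequency_hz}, \code{mean_amplitude_pA} (magnitude;
#'   \code{NA} when no events), \code{n_events}.
#' @export
event_statistics <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- nrow(events)
  list(frequency_hz = n / duration_s,
       mean_amplitude_pA = if (n > 0) mean(abs(events$peak_amplitude_pA)) else NA_real_,
       n_events = n)
}

#' 20--80% rise time of an evoked current
#'
#' Baseline is the mean over \code{baseline_window} seconds at the start of
#' the sweep; the rise time is the time for the response to climb from 20%
#' to 80% of its baseline-to-peak amplitude, with crossing times linearly
#' interpolated between samples.  Invariant to amplitude scaling and
#' baseline offset.
#'
#' @param evoked a stimulus-aligned sweep (\code{\link{time_series}}) with at
#'   least 1 ms of pre-stimulus baseline.
#' @param baseline_window baseline length in seconds (default 1 ms).
#' @param polarity \code{"negative"} or \code{"positive"}.
#' @return rise time in ms.
#' @export
rise_time_20_80 <- function(evoked, baseline_window = 0.001,
                            polarity = c("negative", "positive")) {
  stopifnot(inherits(evoked, "time_series"))
  polarity <- match.arg(polarity)
  fs <- evoked$sampling_rate
  nb <- max(2L, round(baseline_window * fs))
  x <- evoked$samples
  y <- x - mean(x[seq_len(nb)])
  if (polarity == "negative") y <- -y
  pk <- which.max(y)
  amp <- y[pk]
  if (amp <= 3 * stats::sd(y[seq_len(nb)]))
    stop("peak indistinguishable from baseline noise")
  cross <- function(level) {
    target <- level * amp
    i <- pk
    while (i > 1L && y[i - 1L] >= target) i <- i - 1L
    if (i == 1L) return(1)
    (i - 1L) + (target - y[i - 1L]) / (y[i] - y[i - 1L])
  }
  1000 * (cross(0.8) - cross(0.2)) / fs
}

#' Monoexponential decay fit of an evoked current
#'
#' Fits \code{y(t) = A * exp(-t / tau)} to the decay phase, from the peak of
#' the baseline-subtracted response to \code{fit_end} seconds after it, by
#' Levenberg-Marquardt least squares with log-linear starting values.
#'
#' @inheritParams rise_time_20_80
#' @param fit_end end of the fitted decay window, seconds after the peak.
#' @return An object of class \code{evoked_kinetics}: \code{peak_pA} (signed
#'   baseline-to-peak), \code{rise_20_80_ms}, \code{decay_tau_ms},
#'   \code{decay_A_pA}, \code{fit_residual} (rms, pA).
#' @export
fit_decay_monoexp <- function(evoked, fit_end, baseline_window = 0.001,
                              polarity = c("negative", "positive")) {
  stopifnot(inherits(evoked, "time_series"))
  polarity <- match.arg(polarity)
  fs <- evoked$sampling_rate
  nb <- max(2L, round(baseline_window * fs))
  x <- evoked$samples
  base <- mean(x[seq_len(nb)])
  y <- x - base
  sgn <- if (polarity == "negative") -1 else 1
  y <- sgn * y
  pk <- which.max(y)
  i_end <- min(length(y), pk + round(fit_end * fs))
  if (i_end - pk + 1L < 5L) stop("decay segment too short (< 5 samples)")
  seg <- y[pk:i_end]
  tt <- (seq_along(seg) - 1L) / fs
  if (seg[length(seg)] >= seg[1L])
    stop("segment does not decay; cannot fit an exponential")
  pos <- seg > 0
  lf <- stats::lm(log(seg[pos]) ~ tt[pos])
  start <- list(A = exp(unname(stats::coef(lf)[1])),
                tau = max(1e-5, -1 / unname(stats::coef(lf)[2])))
  fit <- minpack.lm::nlsLM(seg ~ A * exp(-tt / tau), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  rise <- tryCatch(rise_time_20_80(evoked, baseline_window, polarity),
                   error = function(e) NA_real_)
  structure(list(peak_pA = sgn * y[pk], rise_20_80_ms = rise,
                 decay_tau_ms = 1000 * unname(co["tau"]),
                 decay_A_pA = sgn * unname(co["A"]),
                 fit_residual = rms),
            class = "evoked_kinetics")
}

#' @export
print.evoked_kinetics <- function(x, ...) {
  cat(sprintf("<evoked_kinetics> peak %.1f pA | rise(20-80) %.2f ms | tau %.1f ms (rms %.2f pA)\n",
              x$peak_pA, x$rise_20_80_ms, x$decay_tau_ms, x$fit_residual))
  invisible(x)
}

#' Toxin-sensitive component of an evoked current
#'
#' The fraction of the total current blocked by a presynaptic calcium-channel
#' toxin, computed from mean stable amplitudes before and after the drug:
#' \code{100 * (1 - mean(post) / mean(control))}.  N-type block
#' (omega-conotoxin GVIA) isolates the CCK-interneuron component; P/Q-type
#' block (omega-agatoxin IVA) the PV-interneuron component.
#'
#' @param control_amps,post_drug_amps stable response amplitudes (pA
#'   magnitudes), at least 5 sweeps each.
#' @return list of class \code{component_split}: \code{control_amp_pA},
#'   \code{post_drug_amp_pA}, \code{sensitive_percent}, \code{flagged}
#'   (\code{TRUE} when the apparent fraction is negative).
#' @export
toxin_component <- function(control_amps, post_drug_amps) {
  if (length(control_amps) < 5L || length(post_drug_amps) < 5L)
    warning("fewer than 5 stable sweeps per condition")
  mc <- mean(control_amps); mp <- mean(post_drug_amps)
  if (!is.finite(mc) || mc <= 0) stop("non-positive mean control amplitude")
  pct <- 100 * (1 - mp / mc)
  structure(list(control_amp_pA = mc, post_drug_amp_pA = mp,
                 sensitive_percent = pct, flagged = pct < 0),
            class = "component_split")
}

#' @export
print.component_split <- function(x, ...) {
  cat(sprintf("<component_split> %.1f -> %.1f pA: %.1f%% toxin-sensitive%s\n",
              x$control_amp_pA, x$post_drug_amp_pA, x$sensitive_percent,
              if (x$flagged) " (negative: flagged)" else ""))
  invisible(x)
}

#' Short-term plasticity ratio of a 5-pulse train
#'
#' Responses to five stimuli at 20 Hz; the depression index is the ratio of
#' the fifth to the first amplitude.
#'
#' @param amplitudes exactly five response amplitudes (pA), first > 0.
#' @param stim_rate_hz stimulation rate (default 20).
#' @return list of class \code{train_response}: \code{amplitudes_pA},
#'   \code{ratio_last_first}, \code{stim_rate_hz}.
#' @export
train_ratio <- function(amplitudes, stim_rate_hz = 20) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != 5L) stop("a 5-pulse train needs exactly 5 amplitudes")
  if (amplitudes[1] <= 0) stop("first response must be positive")
  structure(list(amplitudes_pA = amplitudes,
                 ratio_last_first = amplitudes[5] / amplitudes[1],
                 stim_rate_hz = stim_rate_hz),
            class = "train_response")
}

#' @export
print.train_response <- function(x, ...) {
  cat(sprintf("<train_response> 5 @ %g Hz; last/first = %.3f\n",
              x$stim_rate_hz, x$ratio_last_first))
  invisible(x)
}
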