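# Shared fixture builders: everything is generated in code at test time.

tone_trace <- function(freq, dur, rate, amplitude = 1, phase = 0,
                       noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (1:round(dur * rate)) / rate
  x <- amplitude * cos(2 * pi * freq * t + phase)
  if (noise_sd > 0) x <- x + noise_sd * rnorm(length(x))
  time_series(x, rate)
}

# two tones at 8 and 40 Hz plus white noise; returns trace and the true
# component samples for variance-routing oracles
two_tone_fixture <- function(dur = 4, rate = 1000, a8 = 1, a40 = 1,
                             noise_sd = 0.1, seed = 42) {
  set.seed(seed)
  t <- (1:round(dur * rate)) / rate
  c8 <- a8 * cos(2 * pi * 8 * t)
  c40 <- a40 * cos(2 * pi * 40 * t)
  x <- c8 + c40 + noise_sd * rnorm(length(t))
  list(trace = time_series(x, rate), c8 = c8, c40 = c40)
}

# fraction of a true component's variance captured by a band reconstruction
# (regression of the band onto the component; 1 = fully routed)
capture_fraction <- function(band_samples, component) {
  stats::cov(band_samples, component) / stats::var(component)
}

# dominant FFT frequency of a vector, in Hz
fft_peak_hz <- function(x, rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[1:(n %/% 2)]
  (which.max(sp) - 1) * rate / n
}

# independent run-length burst oracle: plain loop over the ISI sequence
brute_force_bursts <- function(times, max_isi) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0), n_spikes = integer(0))
  if (length(times) < 2) return(out)
  i <- 1
  while (i < length(times)) {
    if (times[i + 1] - times[i] <= max_isi) {
      j <- i + 1
      while (j < length(times) && times[j + 1] - times[j] <= max_isi) j <- j + 1
      out <- rbind(out, data.frame(start_s = times[i], end_s = times[j],
                                   n_spikes = j - i + 1L))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# band_signal wrapper for hand-built samples (bypasses the decomposition)
manual_band <- function(samples, rate, label = "low_gamma", source_sd = NULL) {
  structure(list(band = band_definition(label), samples = samples,
                 source_sd = if (is.null(source_sd)) stats::sd(samples) else source_sd,
                 member_imfs = 1L, sampling_rate = rate, empty = FALSE),
            class = "band_signal")
}

# match detected event/spike times to ground truth within a tolerance;
# returns recall, precision and the per-truth timing errors of matches
match_times <- function(detected, truth, tol_s) {
  if (length(truth) == 0) return(list(recall = NA, precision = NA, errors = numeric(0)))
  err <- vapply(truth, function(tt)
    if (length(detected)) min(abs(detected - tt)) else Inf, numeric(1))
  hits <- err <= tol_s
  matched_det <- vapply(detected, function(dd) min(abs(truth - dd)) <= tol_s, logical(1))
  list(recall = mean(hits),
       precision = if (length(detected)) mean(matched_det) else NA,
       errors = err[hits])
}
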