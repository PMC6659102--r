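#' Recipes for synthetic recordings
#'
#' Seeded generators produce every input class the pipeline consumes,
#' together with a ground-truth record sufficient to score each downstream
#' estimator (component amplitudes, spike/burst times, event onsets, true
#' component fractions, behavioral occupancy) without re-deriving anything
#' from the generated data.
#'
#' \code{lfp_recipe} describes an LFP-like voltage trace as a sum of
#' components: \code{tone} (fixed-amplitude sinusoid), \code{slow_wave}
#' (alias for a low-frequency tone; anesthesia slow waves sit near 1 Hz),
#' \code{band_limited_noise} (white noise FFT-restricted to a band) and
#' \code{amplitude_burst} (a tone whose amplitude is multiplied by
#' \code{burst_gain} inside scheduled burst windows), plus white measurement
#' noise.  The default recipe emulates anesthetized hippocampal LFP: a
#' 0.2 mV slow wave at 1 Hz, 0.05 mV theta at 8 Hz, and low-amplitude gamma.
#'
#' Each component draws from a sub-stream seeded deterministically from the
#' recipe seed and the component index, so edits to one component leave the
#' others' realizations unchanged.
#'
#' @param duration_s trace duration (s).
#' @param rate_hz sampling rate (Hz); all component frequencies must stay
#'   below the Nyquist frequency.
#' @param components list of component descriptions (see above).
#' @param noise_sd_mV white measurement-noise sd (mV).
#' @param seed integer seed.
#' @return a list of class \code{lfp_recipe}.
#' @export
lfp_recipe <- function(duration_s = 10, rate_hz = 1000,
                       components = list(
                         list(kind = "slow_wave", freq = 1, amplitude = 0.2),
                         list(kind = "tone", freq = 8, amplitude = 0.05),
                         list(kind = "tone", freq = 40, amplitude = 0.02)),
                       noise_sd_mV = 0.01, seed = 1L) {
  if (duration_s <= 0) stop("duration must be positive")
  for (cmp in components) {
    f <- if (!is.null(cmp$freq)) cmp$freq else max(cmp$band)
    if (f >= rate_hz / 2) stop("component frequency at or above Nyquist")
  }
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 components = components, noise_sd_mV = noise_sd_mV,
                 seed = as.integer(seed)),
            class = "lfp_recipe")
}

sub_seed <- function(seed, k) (as.integer(seed) + 10007L * as.integer(k)) %% 2147483629L

#' Generate a synthetic LFP trace
#'
#' @param recipe an \code{\link{lfp_recipe}}.
#' @return list with \code{trace} (a \code{\link{time_series}}) and
#'   \code{truth}: per-component sample matrices, realized variances, burst
#'   schedules, and the noise realization.
#' @export
gen_lfp <- function(recipe) {
  stopifnot(inherits(recipe, "lfp_recipe"))
  n <- round(recipe$duration_s * recipe$rate_hz)
  t <- (0:(n - 1)) / recipe$rate_hz
  comp_samples <- list()
  schedules <- list()
  for (k in seq_along(recipe$components)) {
    cmp <- recipe$components[[k]]
    set.seed(sub_seed(recipe$seed, k))
    kind <- match.arg(cmp$kind, c("tone", "slow_wave", "band_limited_noise",
                                  "amplitude_burst"))
    ph <- if (!is.null(cmp$phase)) cmp$phase else 0
    s <- switch(kind,
      tone = ,
      slow_wave = cmp$amplitude * cos(2 * pi * cmp$freq * t + ph),
      band_limited_noise = {
        w <- stats::rnorm(n)
        W <- stats::fft(w)
        f <- (0:(n - 1)) * recipe$rate_hz / n
        f <- pmin(f, recipe$rate_hz - f)          # two-sided frequency axis
        W[f < cmp$band[1] | f > cmp$band[2]] <- 0
        bl <- Re(stats::fft(W, inverse = TRUE) / n)
        cmp$amplitude * bl / stats::sd(bl)        # amplitude = target sd
      },
      amplitude_burst = {
        gain <- rep(1, n)
        n_cyc <- if (!is.null(cmp$burst_cycles)) cmp$burst_cycles else 5
        for (t0 in cmp$burst_times) {
          i0 <- round(t0 * recipe$rate_hz) + 1L
          i1 <- min(n, i0 + round(n_cyc / cmp$freq * recipe$rate_hz) - 1L)
          gain[i0:i1] <- cmp$burst_gain
        }
        schedules[[length(schedules) + 1L]] <-
          list(component = k, burst_times = cmp$burst_times,
               burst_cycles = n_cyc, burst_gain = cmp$burst_gain)
        cmp$amplitude * gain * cos(2 * pi * cmp$freq * t + ph)
      })
    comp_samples[[k]] <- s
  }
  set.seed(sub_seed(recipe$seed, 0L))
  noise <- if (recipe$noise_sd_mV > 0) recipe$noise_sd_mV * stats::rnorm(n)
           else numeric(n)
  x <- Reduce(`+`, comp_samples, accumulate = FALSE) + noise
  trace <- time_series(x, recipe$rate_hz, units = "mV", channel_id = "synth-lfp")
  truth <- list(components = comp_samples,
                component_var = vapply(comp_samples, stats::var, numeric(1)),
                noise = noise, noise_var = stats::var(noise),
                schedules = schedules, recipe = recipe)
  list(trace = trace, truth = truth)
}

#' Spike-train recipe
#'
#' \code{poisson}: homogeneous Poisson firing.  \code{bursting}: Poisson
#' burst onsets, each burst \code{spikes_per_burst} spikes at
#' \code{intraburst_hz} (>= 20 Hz to satisfy the burst definition), plus
#' optional independent single spikes.  \code{phase_locked}: one spike per
#' cycle (with participation probability \code{p_cycle}) at a stated phase
#' of a target oscillation, jittered.
#'
#' @param mode \code{"poisson"}, \code{"bursting"} or \code{"phase_locked"}.
#' @param duration_s train duration (s).
#' @param rate_hz single-spike rate (poisson mode / bursting extras).
#' @param burst list \code{(burst_rate_hz, spikes_per_burst, intraburst_hz)}.
#' @param locking list \code{(freq, phase, jitter_s, p_cycle)}; phase in
#'   radians of a cosine component (\code{pi} = trough).
#' @param seed integer seed.
#' @return a list of class \code{spike_recipe}.
#' @export
spike_recipe <- function(mode = c("poisson", "bursting", "phase_locked"),
                         duration_s = 60, rate_hz = 1,
                         burst = list(burst_rate_hz = 1, spikes_per_burst = 3,
                                      intraburst_hz = 80),
                         locking = list(freq = 1, phase = pi, jitter_s = 0,
                                        p_cycle = 1),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "bursting" && burst$intraburst_hz < 20)
    stop("intraburst rate must be >= 20 Hz to form bursts")
  structure(list(mode = mode, duration_s = duration_s, rate_hz = rate_hz,
                 burst = burst, locking = locking, seed = as.integer(seed)),
            class = "spike_recipe")
}

#' Generate a synthetic spike train
#'
#' @param recipe a \code{\link{spike_recipe}}.
#' @param carrier optional \code{\link{time_series}}: when supplied together
#'   with \code{waveform}, the spike waveform is embedded additively into a
#'   copy of the carrier at each spike time (for testing threshold
#'   detection).
#' @param waveform optional list \code{(amplitude, half_width_ms, negative)}
#'   describing the embedded biphasic spike shape; default amplitude is in
#'   the carrier's units.
#' @return list with \code{spikes} (a \code{\link{spike_train}}),
#'   \code{trace} (carrier with embedded waveforms, or \code{NULL}) and
#'   \code{truth} (true spike and burst times).
#' @export
gen_spikes <- function(recipe, carrier = NULL, waveform = NULL) {
  stopifnot(inherits(recipe, "spike_recipe"))
  set.seed(sub_seed(recipe$seed, 1L))
  D <- recipe$duration_s
  burst_spans <- NULL
  times <- switch(recipe$mode,
    poisson = {
      tt <- cumsum(stats::rexp(ceiling(recipe$rate_hz * D * 2 + 50),
                               rate = max(recipe$rate_hz, 1e-9)))
      tt[tt < D]
    },
    bursting = {
      b <- recipe$burst
      isi <- 1 / b$intraburst_hz
      span <- (b$spikes_per_burst - 1) * isi
      # hard-core renewal process: bursts stay distinct at any 20-50 ms
      # criterion, while the mean onset interval still equals 1/burst_rate
      min_gap <- span + 0.06
      mean_gap <- 1 / b$burst_rate_hz
      if (mean_gap <= min_gap)
        stop("burst rate too high for non-overlapping bursts")
      n_draw <- ceiling(D / mean_gap * 2 + 50)
      onsets <- cumsum(min_gap + stats::rexp(n_draw, rate = 1 / (mean_gap - min_gap)))
      onsets <- onsets[onsets < D - span]
      burst_spans <- data.frame(start_s = onsets, end_s = onsets + span,
                                n_spikes = b$spikes_per_burst)
      bs <- unlist(lapply(onsets, function(o) o + (0:(b$spikes_per_burst - 1)) * isi))
      singles <- if (recipe$rate_hz > 0) {
        s <- cumsum(stats::rexp(ceiling(recipe$rate_hz * D * 2 + 50),
                                rate = recipe$rate_hz))
        s <- s[s < D]
        # keep singles isolated from bursts and from each other, so the
        # generated train's ground truth is unambiguous at any 20-50 ms
        # burst criterion
        s <- s[c(TRUE, diff(s) > 0.06)]
        keep <- vapply(s, function(x) all(x < onsets - 0.06 | x > onsets + span + 0.06),
                       logical(1))
        s[keep]
      } else numeric(0)
      sort(c(bs, singles))
    },
    phase_locked = {
      l <- recipe$locking
      # cosine component: phase pi (trough) at t = (k + 1/2)/freq
      k <- 0:(floor(D * l$freq) - 1)
      tt <- (k + l$phase / (2 * pi)) / l$freq
      tt <- tt[stats::runif(length(tt)) <= l$p_cycle]
      if (l$jitter_s > 0) tt <- tt + stats::rnorm(length(tt), sd = l$jitter_s)
      sort(tt[tt > 0 & tt < D])
    })
  times <- times[c(TRUE, diff(times) > 1e-6)]
  spikes <- spike_train(times, source_id = paste0("synth-", recipe$mode))
  trace <- NULL
  if (!is.null(carrier)) {
    if (is.null(waveform)) waveform <- list(amplitude = 1, half_width_ms = 0.3,
                                            negative = TRUE)
    trace <- embed_waveforms(carrier, times, waveform)
  }
  list(spikes = spikes, trace = trace,
       truth = list(times = times, bursts = burst_spans, recipe = recipe))
}

# additively embed a biphasic spike waveform at each spike time
embed_waveforms <- function(carrier, times, waveform) {
  fs <- carrier$sampling_rate
  sigma <- waveform$half_width_ms / 1000 / 2.355        # FWHM -> Gaussian sd
  tw <- seq(-4 * sigma, 8 * sigma, by = 1 / fs)
  w <- exp(-tw^2 / (2 * sigma^2)) -
       0.35 * exp(-(tw - 3 * sigma)^2 / (2 * (2 * sigma)^2))  # rebound
  w <- waveform$amplitude * w / max(abs(w))
  if (isTRUE(waveform$negative)) w <- -w
  x <- carrier$samples
  n <- length(x)
  off <- round(4 * sigma * fs)                          # peak sample of w
  for (tt in times) {
    i0 <- round(tt * fs) + 1L - off
    j <- seq_along(w) + i0 - 1L
    ok <- j >= 1L & j <= n
    x[j[ok]] <- x[j[ok]] + w[ok]
  }
  out <- carrier
  out$samples <- x
  out
}

#' Whole-cell current recipe
#'
#' \code{spontaneous}: biexponential synaptic events at Poisson onsets with
#' lognormal-free (truncated normal) amplitudes, on Gaussian noise.
#' \code{evoked}: stimulus-aligned sweeps whose amplitude is split between a
#' toxin-sensitive and a toxin-resistant component with known fractions;
#' \code{drug = TRUE} zeroes the sensitive component.  With
#' \code{train = TRUE} each sweep carries five pulses at 20 Hz following
#' \code{train_profile} (relative amplitudes; the default profile depresses
#' to 0.48 of the first response).
#'
#' @param mode \code{"spontaneous"} or \code{"evoked"}.
#' @param duration_s spontaneous-trace duration (s).
#' @param rate_hz sampling rate (Hz).
#' @param event_rate_hz spontaneous event rate (Hz).
#' @param amp_mean_pA,amp_cv event/sweep amplitude mean (pA) and CV.
#' @param rise_ms,decay_ms event kinetics.
#' @param noise_sd_pA recording noise sd.
#' @param evoked list: \code{total_amp_pA}, \code{fractions} (named, sums to
#'   1), \code{n_sweeps}, \code{sweep_dur_s}, \code{stim_t_s}, \code{drug},
#'   \code{train}, \code{train_profile}.
#' @param seed integer seed.
#' @return a list of class \code{current_recipe}.
#' @export
current_recipe <- function(mode = c("spontaneous", "evoked"),
                           duration_s = 60, rate_hz = 10000,
                           event_rate_hz = 0.5, amp_mean_pA = 30, amp_cv = 0.2,
                           rise_ms = 1, decay_ms = 8, noise_sd_pA = 3,
                           evoked = list(total_amp_pA = 100,
                                         fractions = c(sensitive = 0.582,
                                                       resistant = 0.418),
                                         n_sweeps = 10, sweep_dur_s = 0.25,
                                         stim_t_s = 0.02, drug = FALSE,
                                         train = FALSE,
                                         train_profile = c(1, 0.8, 0.65, 0.55, 0.48)),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "evoked" && abs(sum(evoked$fractions) - 1) > 1e-9)
    stop("evoked component fractions must sum to 1")
  if (rise_ms < 0 || decay_ms <= 0) stop("invalid kinetic time constants")
  structure(list(mode = mode, duration_s = duration_s, rate_hz = rate_hz,
                 event_rate_hz = event_rate_hz, amp_mean_pA = amp_mean_pA,
                 amp_cv = amp_cv, rise_ms = rise_ms, decay_ms = decay_ms,
                 noise_sd_pA = noise_sd_pA, evoked = evoked,
                 seed = as.integer(seed)),
            class = "current_recipe")
}

biexp_kernel <- function(rise_ms, decay_ms, rate, duration_ms = NULL) {
  if (is.null(duration_ms)) duration_ms <- rise_ms + 8 * decay_ms
  t <- seq(0, duration_ms / 1000, by = 1 / rate)
  # rise_ms = 0 gives an instant-rise, purely monoexponential event
  y <- if (rise_ms > 0)
    (1 - exp(-t / (rise_ms / 1000))) * exp(-t / (decay_ms / 1000))
  else exp(-t / (decay_ms / 1000))
  y / max(y)
}

#' Generate a synthetic whole-cell current recording
#'
#' @param recipe a \code{\link{current_recipe}}.
#' @return \code{spontaneous} mode: list with \code{trace} (pA
#'   \code{\link{time_series}}, events negative-going) and \code{truth}
#'   (onsets, amplitudes).  \code{evoked} mode: list with \code{sweeps} (list
#'   of stimulus-aligned \code{time_series}), \code{amplitudes_pA} (true
#'   per-sweep, per-pulse baseline-to-peak magnitudes) and \code{truth}
#'   (fractions, kinetics, profile).
#' @export
gen_current_trace <- function(recipe) {
  stopifnot(inherits(recipe, "current_recipe"))
  set.seed(sub_seed(recipe$seed, 2L))
  fs <- recipe$rate_hz
  kern <- biexp_kernel(recipe$rise_ms, recipe$decay_ms, fs)
  if (recipe$mode == "spontaneous") {
    n <- round(recipe$duration_s * fs)
    onsets <- cumsum(stats::rexp(ceiling(recipe$event_rate_hz * recipe$duration_s * 2 + 50),
                                 rate = recipe$event_rate_hz))
    onsets <- onsets[onsets < recipe$duration_s - length(kern) / fs]
    amps <- pmax(recipe$amp_mean_pA * 0.1,
                 stats::rnorm(length(onsets), recipe$amp_mean_pA,
                              recipe$amp_cv * recipe$amp_mean_pA))
    x <- recipe$noise_sd_pA * stats::rnorm(n)
    for (j in seq_along(onsets)) {
      i0 <- round(onsets[j] * fs) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      x[idx] <- x[idx] - amps[j] * kern      # inward (negative) events
    }
    trace <- time_series(x, fs, units = "pA", channel_id = "synth-current")
    return(list(trace = trace,
                truth = list(onsets = onsets, amplitudes_pA = amps,
                             recipe = recipe)))
  }
  ev <- recipe$evoked
  stim_i <- round(ev$stim_t_s * fs) + 1L
  n <- round(ev$sweep_dur_s * fs)
  profile <- if (isTRUE(ev$train)) ev$train_profile else 1
  isi_i <- round(fs / 20)                     # 5 pulses at 20 Hz
  sweeps <- vector("list", ev$n_sweeps)
  amp_mat <- matrix(NA_real_, ev$n_sweeps, length(profile))
  frac_live <- sum(ev$fractions[setdiff(names(ev$fractions),
                                        if (isTRUE(ev$drug)) "sensitive" else character(0))])
  for (s in seq_len(ev$n_sweeps)) {
    x <- recipe$noise_sd_pA * stats::rnorm(n)
    a1 <- ev$total_amp_pA * frac_live *
      max(0.05, 1 + recipe$amp_cv * stats::rnorm(1))
    for (p in seq_along(profile)) {
      i0 <- stim_i + (p - 1L) * isi_i
      idx <- i0:min(n, i0 + length(kern) - 1L)
      amp_mat[s, p] <- a1 * profile[p]
      x[idx] <- x[idx] - amp_mat[s, p] * kern[seq_along(idx)]
    }
    sweeps[[s]] <- time_series(x, fs, units = "pA",
                               channel_id = sprintf("synth-evoked-%02d", s))
  }
  list(sweeps = sweeps, amplitudes_pA = amp_mat,
       truth = list(fractions = ev$fractions, drug = isTRUE(ev$drug),
                    rise_ms = recipe$rise_ms, decay_ms = recipe$decay_ms,
                    profile = profile, stim_t_s = ev$stim_t_s, recipe = recipe))
}

#' Generate synthetic behavioral data
#'
#' Three-chamber sessions: per-animal compartment times drawn as Gaussian
#' around a base investigation time, with the preferred compartment shifted
#' by the stated preference, so cohorts realize the preference on average.
#' Open field: a fixed-step random walk (step length = speed / rate) with
#' uniform turning angles and reflecting walls, whose realized path speed is
#' recorded in the truth.
#'
#' @param effect list: \code{preference_sociability_s},
#'   \code{preference_novelty_s}, \code{base_time_s} (mean time for the
#'   non-preferred compartment), \code{time_sd_s}, \code{speed_mm_s}.
#' @param n_animals animals per cohort (default 9).
#' @param track_duration_s open-field session length (default 600 s).
#' @param track_rate_hz position sampling rate (default 25 Hz).
#' @param seed integer seed.
#' @return list: \code{sessions} (list of \code{\link{chamber_session}},
#'   sociability then novelty per animal), \code{track} (one
#'   \code{\link{open_field_track}}), \code{truth}.
#' @export
gen_behavior <- function(effect = list(preference_sociability_s = 70,
                                       preference_novelty_s = 34,
                                       base_time_s = 85, time_sd_s = 15,
                                       speed_mm_s = 65.8),
                         n_animals = 9, track_duration_s = 600,
                         track_rate_hz = 25, seed = 1L) {
  set.seed(sub_seed(seed, 3L))
  sessions <- list()
  for (a in seq_len(n_animals)) {
    t_obj <- max(0, stats::rnorm(1, effect$base_time_s, effect$time_sd_s))
    t_mou <- max(0, stats::rnorm(1, effect$base_time_s + effect$preference_sociability_s,
                                 effect$time_sd_s))
    sessions[[length(sessions) + 1L]] <-
      chamber_session("sociability", t_mouse_s = t_mou, t_object_s = t_obj)
    t_fam <- max(0, stats::rnorm(1, effect$base_time_s, effect$time_sd_s))
    t_nov <- max(0, stats::rnorm(1, effect$base_time_s + effect$preference_novelty_s,
                                 effect$time_sd_s))
    sessions[[length(sessions) + 1L]] <-
      chamber_session("novelty", t_novel_s = t_nov, t_familiar_s = t_fam)
  }
  # random walk with fixed step length and reflecting walls
  n <- round(track_duration_s * track_rate_hz)
  step_cm <- (effect$speed_mm_s / 10) / track_rate_hz
  ang <- cumsum(stats::rnorm(n - 1, sd = 0.4))
  x <- numeric(n); y <- numeric(n)
  x[1] <- 30; y[1] <- 30
  for (i in 2:n) {
    x[i] <- x[i - 1] + step_cm * cos(ang[i - 1])
    y[i] <- y[i - 1] + step_cm * sin(ang[i - 1])
    if (x[i] < 0) x[i] <- -x[i]
    if (x[i] > 60) x[i] <- 120 - x[i]
    if (y[i] < 0) y[i] <- -y[i]
    if (y[i] > 60) y[i] <- 120 - y[i]
  }
  track <- open_field_track(x, y, track_rate_hz)
  realized <- sum(sqrt(diff(x)^2 + diff(y)^2)) / 100          # m
  list(sessions = sessions, track = track,
       truth = list(effect = effect, n_animals = n_animals,
                    realized_distance_m = realized,
                    realized_speed_mm_s = 1000 * realized / track_duration_s))
}
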