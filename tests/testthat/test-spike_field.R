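make_embedded_fixture <- function(n_target = 50, dur = 60, rate = 10000,
                                  snr = 8, seed = 5) {
  set.seed(seed + 1000)
  noise_sd <- 0.02
  carrier <- time_series(noise_sd * rnorm(dur * rate), rate, units = "mV")
  rec <- spike_recipe("poisson", duration_s = dur, rate_hz = n_target / dur,
                      seed = seed)
  gen_spikes(rec, carrier = carrier,
             waveform = list(amplitude = snr * noise_sd, half_width_ms = 0.3,
                             negative = TRUE))
}

test_that("threshold detection recovers embedded spikes precisely", {
  g <- make_embedded_fixture()
  det <- detect_spikes(g$trace)
  m <- match_times(det$times, g$truth$times, 1e-3)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  expect_lt(max(m$errors), 5e-4)          # sub-half-millisecond timing
})

test_that("pure noise yields almost no detections at 5 sd", {
  set.seed(12)
  tr <- time_series(0.02 * rnorm(60 * 10000), 10000)
  det <- detect_spikes(tr)
  expect_lt(det$n / 60, 0.1)              # false-positive rate < 0.1 Hz
  expect_error(detect_spikes(time_series(rep(0, 20001), 10000)),
               "zero noise")
})

sta_fixture <- function(noise_sd, dur = 300, seed = 11) {
  lr <- lfp_recipe(dur, 1000, components = list(
    list(kind = "slow_wave", freq = 1, amplitude = 0.2)),
    noise_sd_mV = noise_sd, seed = seed)
  g <- gen_lfp(lr)
  sp <- gen_spikes(spike_recipe("phase_locked", duration_s = dur,
                                locking = list(freq = 1, phase = pi,
                                               jitter_s = 0, p_cycle = 1),
                                seed = 2))
  list(lfp = g$trace, spikes = sp$spikes)
}

test_that("STA recovers a trough-locked slow wave", {
  fx <- sta_fixture(noise_sd = 0.05)
  sta <- spike_triggered_average(fx$lfp, fx$spikes)
  expect_false(sta$excluded)
  expect_equal(min(sta$mean_lfp), -0.2, tolerance = 0.15)
  # closed-form window mean of -0.2 cos(2 pi t) over [0, 0.25] s
  analytic <- -0.2 * sin(2 * pi * 0.25) / (2 * pi * 0.25)
  expect_lt(abs(sta$post_mean - analytic) / abs(analytic), 0.10)
})

test_that("without noise the STA trough sits exactly at lag zero", {
  fx <- sta_fixture(noise_sd = 0)
  sta <- spike_triggered_average(fx$lfp, fx$spikes)
  # the 1 Hz STA is periodic over the +/- 1 s window: take the central cycle
  central <- which(abs(sta$lags) <= 0.5)
  trough <- sta$lags[central][which.min(sta$mean_lfp[central])]
  expect_lte(abs(trough), 1 / fx$lfp$sampling_rate)
})

test_that("spikes at random phases average the slow wave away", {
  lr <- lfp_recipe(300, 1000, components = list(
    list(kind = "slow_wave", freq = 1, amplitude = 0.2)),
    noise_sd_mV = 0.02, seed = 21)
  g <- gen_lfp(lr)
  sp <- gen_spikes(spike_recipe("poisson", duration_s = 300, rate_hz = 2,
                                seed = 31))
  sta <- spike_triggered_average(g$trace, sp$spikes)
  # per-spike standard error of the post-window mean
  flt <- bandpass_filter(g$trace, filter_spec("bandpass", c(0.2, 50)))
  idx <- round(sp$spikes$times * 1000) + 1
  idx <- idx[idx > 1000 & idx + 1000 <= length(flt$samples)]
  per_spike <- vapply(idx, function(i) mean(flt$samples[i:(i + 249)]), numeric(1))
  se <- sd(per_spike) / sqrt(length(per_spike))
  expect_lt(abs(sta$post_mean), 3 * se)
})

test_that("sparse multi-unit activity triggers the exclusion rule", {
  fx <- sta_fixture(noise_sd = 0.02, dur = 60)
  few <- spike_train(fx$spikes$times[seq(1, fx$spikes$n, by = 2)][1:25])
  sta <- spike_triggered_average(fx$lfp, few)   # 25 spikes / 60 s < 1 Hz
  expect_true(sta$excluded)
  expect_match(sta$reason, "below")
})

test_that("pre/post means agree with per-spike segment averaging", {
  fx <- sta_fixture(noise_sd = 0.05, dur = 120)
  sta <- spike_triggered_average(fx$lfp, fx$spikes)
  flt <- bandpass_filter(fx$lfp, filter_spec("bandpass", c(0.2, 50)))
  idx <- round(fx$spikes$times * 1000) + 1
  idx <- idx[idx - 1000 >= 1 & idx + 1000 <= length(flt$samples)]
  post2 <- mean(vapply(idx, function(i) mean(flt$samples[i:(i + 249)]), numeric(1)))
  pre2 <- mean(vapply(idx, function(i) mean(flt$samples[(i - 250):(i - 1)]), numeric(1)))
  expect_equal(sta$post_mean, post2, tolerance = 1e-12)
  expect_equal(sta$pre_mean, pre2, tolerance = 1e-12)
})

test_that("STA of deterministic fixtures is bit-reproducible", {
  fx <- sta_fixture(noise_sd = 0.05, dur = 60)
  a <- spike_triggered_average(fx$lfp, fx$spikes)
  b <- spike_triggered_average(fx$lfp, fx$spikes)
  expect_identical(a$mean_lfp, b$mean_lfp)
})

test_that("peri-spike power profile sees a pre-spike amplitude doubling", {
  rate <- 1000
  dur <- 120
  t <- (1:(dur * rate)) / rate
  spikes <- seq(5, dur - 5, by = 2)
  gain <- rep(1, length(t))
  for (s in spikes) gain[t >= s - 0.2 & t < s] <- 2
  band <- manual_band(gain * 0.02 * cos(2 * pi * 40 * t), rate,
                      source_sd = 0.1)
  prof <- spike_power_profile(band, spike_train(spikes))
  expect_equal(length(prof$power_per_bin), 20)
  baseline <- mean(prof$power_per_bin[1:8])
  boosted <- mean(prof$power_per_bin[9:10])   # bins covering [-0.2, 0)
  expect_equal(boosted / baseline, 4, tolerance = 0.15)
})

test_that("a stationary band yields a flat 20-bin profile and zero band zero power", {
  rate <- 1000
  t <- (1:(60 * rate)) / rate
  band <- manual_band(0.02 * cos(2 * pi * 40 * t), rate, source_sd = 0.1)
  set.seed(44)
  spikes <- sort(runif(40, 2, 58))
  prof <- spike_power_profile(band, spike_train(spikes))
  expect_lt(diff(range(prof$power_per_bin)) / mean(prof$power_per_bin), 0.02)
  zero <- manual_band(rep(0, length(t)), rate, source_sd = 0.1)
  expect_true(all(spike_power_profile(zero, spike_train(spikes))$power_per_bin == 0))
})
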