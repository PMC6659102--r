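test_that("an exact template copy is found at its onset with unit scale", {
  rate <- 10000
  tmpl <- make_template(1, 8, rate)
  x <- numeric(2 * rate)                       # 2 s of silence
  onset_i <- 4201
  x[onset_i:(onset_i + length(tmpl) - 1)] <- 30 * tmpl
  ev <- template_detect(time_series(x, rate, units = "pA"), tmpl, 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, (onset_i - 1) / rate)
  expect_equal(ev$peak_amplitude_pA, -30, tolerance = 1e-9)
})

test_that("sliding-template detection matches a per-position least-squares oracle", {
  rate <- 5000
  tmpl <- make_template(1, 8, rate)
  cr <- current_recipe("spontaneous", duration_s = 1, rate_hz = rate,
                       event_rate_hz = 3, seed = 9)
  g <- gen_current_trace(cr)
  d <- g$trace$samples                        # <= 5000 samples
  M <- length(tmpl)
  ev <- template_detect(g$trace, tmpl, 3, keep_series = TRUE)
  scale_series <- attr(ev, "scale_series")
  score_series <- attr(ev, "score_series")
  # oracle: explicit lm fit of data ~ template at sampled positions
  set.seed(1)
  positions <- sort(sample(length(d) - M, 60))
  for (i in positions) {
    fit <- lm(d[i:(i + M - 1)] ~ tmpl)
    scale_hat <- unname(coef(fit)[2])
    se_hat <- sqrt(sum(residuals(fit)^2) / (M - 1))
    expect_equal(scale_series[i], scale_hat, tolerance = 1e-8)
    expect_equal(score_series[i], scale_hat / se_hat, tolerance = 1e-6)
  }
})

test_that("embedded events are detected with high recall and precision", {
  cr <- current_recipe("spontaneous", duration_s = 30, event_rate_hz = 1,
                       amp_mean_pA = 30, noise_sd_pA = 3, seed = 3)
  g <- gen_current_trace(cr)
  ev <- template_detect(g$trace, make_template(1, 8, 10000), 3)
  m <- match_times(ev$onset_s, g$truth$onsets, 2e-3)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)
})

test_that("noise-only traces produce almost no events at threshold 4", {
  set.seed(14)
  tr <- time_series(3 * rnorm(60 * 5000), 5000, units = "pA")
  ev <- template_detect(tr, make_template(1, 8, 5000), 4)
  expect_lte(nrow(ev), 1)
  expect_error(template_detect(tr, rep(1, 100), 3), "flat template")
})

test_that("event statistics count and average correctly", {
  ev <- data.frame(onset_s = seq(1, 59, by = 2), peak_amplitude_pA = rep(-30, 30),
                   detection_score = 5)
  st <- event_statistics(ev, 60)
  expect_equal(st$frequency_hz, 0.5)
  expect_equal(st$mean_amplitude_pA, 30)
  empty <- event_statistics(ev[0, ], 60)
  expect_equal(empty$frequency_hz, 0)
  expect_true(is.na(empty$mean_amplitude_pA))
  # Poisson generator rate is recovered within counting error
  cr <- current_recipe("spontaneous", duration_s = 120, rate_hz = 5000,
                       event_rate_hz = 10, amp_mean_pA = 50, noise_sd_pA = 2,
                       decay_ms = 4, rise_ms = 0.5, seed = 12)
  g <- gen_current_trace(cr)
  est <- event_statistics(data.frame(onset_s = g$truth$onsets,
                                     peak_amplitude_pA = -g$truth$amplitudes_pA),
                          120)
  expect_equal(est$frequency_hz, 10, tolerance = 0.1)
})

test_that("20-80% rise time matches closed forms and is invariant to scaling", {
  rate <- 100000
  t <- seq(0, 0.05, by = 1 / rate)
  tau_r <- 0.002
  expo <- c(rep(0, 100), 1 - exp(-t / tau_r))          # saturating rise
  ts <- time_series(-100 * expo, rate, units = "pA")
  expect_equal(rise_time_20_80(ts), 1000 * tau_r * log(4), tolerance = 0.02)
  ramp <- c(rep(0, 100), seq(0, 1, length.out = round(0.01 * rate)), rep(1, 200))
  ts_ramp <- time_series(-50 * ramp, rate, units = "pA")
  expect_equal(rise_time_20_80(ts_ramp), 6.0, tolerance = 0.01)
  expect_equal(rise_time_20_80(time_series(-13 * expo + 5, rate)),
               rise_time_20_80(ts))
  expect_error(rise_time_20_80(time_series(rep(0, 1000), rate)),
               "indistinguishable")
})

test_that("noiseless monoexponential decay is recovered exactly", {
  cr <- current_recipe("evoked", rise_ms = 0, decay_ms = 30, noise_sd_pA = 0,
                       seed = 2,
                       evoked = list(total_amp_pA = 100,
                                     fractions = c(sensitive = 0.582,
                                                   resistant = 0.418),
                                     n_sweeps = 1, sweep_dur_s = 0.25,
                                     stim_t_s = 0.02, drug = FALSE,
                                     train = FALSE, train_profile = 1))
  g <- gen_current_trace(cr)
  k <- fit_decay_monoexp(g$sweeps[[1]], fit_end = 0.15)
  expect_equal(k$decay_tau_ms, 30, tolerance = 0.1 / 30)
  expect_lt(k$fit_residual, 1e-6)
})

test_that("decay estimates separate control-like and KO-like kinetics", {
  fit_tau <- function(tau_ms, seed) {
    cr <- current_recipe("evoked", rise_ms = 0.5, decay_ms = tau_ms,
                         noise_sd_pA = 5, seed = seed,
                         evoked = list(total_amp_pA = 100,
                                       fractions = c(sensitive = 0.5,
                                                     resistant = 0.5),
                                       n_sweeps = 10, sweep_dur_s = 0.25,
                                       stim_t_s = 0.02, drug = FALSE,
                                       train = FALSE, train_profile = 1))
    g <- gen_current_trace(cr)
    vapply(g$sweeps, function(s)
      fit_decay_monoexp(s, fit_end = 0.15)$decay_tau_ms, numeric(1))
  }
  ctrl <- fit_tau(31.1, 5)     # control-like mean decay
  ko <- fit_tau(26.2, 6)       # knockout-like mean decay
  ci <- function(x) mean(x) + c(-1, 1) * qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
  expect_lt(ci(ko)[2], ci(ctrl)[1])   # non-overlapping 95% CIs at n = 10
})

test_that("the toxin split is exact algebraically and flags negatives", {
  for (f in c(0.1, 0.3, 0.582, 0.9)) {
    x <- c(100, 95, 105, 98, 102)
    split <- toxin_component(x, x * (1 - f))
    expect_equal(split$sensitive_percent, 100 * f)
    expect_false(split$flagged)
  }
  expect_equal(toxin_component(rep(100, 5), rep(40, 5))$sensitive_percent, 60)
  expect_equal(toxin_component(rep(80, 5), rep(80, 5))$sensitive_percent, 0)
  expect_true(toxin_component(rep(50, 5), rep(60, 5))$flagged)
  expect_error(toxin_component(rep(0, 5), rep(1, 5)), "non-positive")
})

test_that("5-pulse train ratios reproduce the printed depression means", {
  tr <- train_ratio(c(100, 80, 65, 55, 48))
  expect_equal(tr$ratio_last_first, 0.48)
  expect_equal(train_ratio(rep(70, 5))$ratio_last_first, 1.0)
  expect_equal(train_ratio(c(100, 70, 50, 35, 28))$ratio_last_first, 0.28)
  expect_error(train_ratio(c(100, 80, 65)), "exactly 5")
  expect_error(train_ratio(c(-1, 1, 1, 1, 1)), "positive")
})
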