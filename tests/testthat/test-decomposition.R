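test_that("a monotone ramp yields no IMFs and an exact residual", {
  ts <- time_series(seq(0, 1, length.out = 100), 1000)
  dec <- sift_emd(ts)
  expect_equal(ncol(dec$imfs), 0)
  expect_equal(dec$residual, ts$samples)
})

test_that("a single tone is captured almost entirely by the first IMF", {
  ts <- tone_trace(10, 1, 1000)
  dec <- sift_emd(ts)
  expect_gte(var(dec$imfs[, 1]) / var(ts$samples), 0.95)
  expect_equal(fft_peak_hz(dec$imfs[, 1], 1000), 10, tolerance = 0.101)
})

test_that("EMD separates two tones into IMFs ordered high to low frequency", {
  set.seed(3)
  t <- (1:4000) / 1000
  x <- cos(2 * pi * 10 * t) + cos(2 * pi * 80 * t)
  dec <- sift_emd(time_series(x, 1000))
  v <- apply(dec$imfs, 2, var)
  dom <- order(v, decreasing = TRUE)[1:2]
  dom <- sort(dom)                       # IMF order = frequency order
  expect_equal(fft_peak_hz(dec$imfs[, dom[1]], 1000), 80, tolerance = 1)
  expect_equal(fft_peak_hz(dec$imfs[, dom[2]], 1000), 10, tolerance = 1)
  expect_gt(dec$mean_inst_freq[dom[1]], dec$mean_inst_freq[dom[2]])
})

test_that("EMD is complete and IMFs approximately satisfy the IMF conditions", {
  tt <- two_tone_fixture()
  dec <- sift_emd(tt$trace)
  recon <- rowSums(dec$imfs) + dec$residual
  expect_lt(max(abs(recon - tt$trace$samples)), 1e-10 * sd(tt$trace$samples))
  # IMF condition (extrema ~ zero crossings) holds approximately; check the
  # IMFs that carry real signal (>= 10% of source variance)
  vtot <- var(tt$trace$samples)
  for (k in which(apply(dec$imfs, 2, var) >= 0.10 * vtot)) {
    imf <- dec$imfs[, k]
    nz <- sum(diff(sign(imf)) != 0)
    ne <- sum(diff(sign(diff(imf))) != 0)
    expect_lte(abs(ne - nz), max(1, 0.10 * nz))
  }
})

test_that("mean instantaneous frequency matches tones and chirps", {
  expect_equal(mean_instantaneous_frequency(tone_trace(8, 2, 1000)), 8,
               tolerance = 0.02 * 8)
  expect_equal(mean_instantaneous_frequency(tone_trace(40, 2, 1000)), 40,
               tolerance = 0.02 * 40)
  # linear chirp 5 -> 15 Hz: time-mean instantaneous frequency is 10 Hz
  t <- (1:8000) / 1000
  chirp <- cos(2 * pi * (5 * t + 10 * t^2 / (2 * 8)))
  expect_equal(mean_instantaneous_frequency(chirp, 1000), 10,
               tolerance = 0.05 * 10)
  expect_error(mean_instantaneous_frequency(rep(1, 100), 1000), "undefined")
})

test_that("band assembly routes tones to their canonical bands", {
  ts8 <- tone_trace(8, 4, 1000, noise_sd = 0.01, seed = 1)
  dec <- sift_emd(ts8)
  th <- assemble_band(dec, band_definition("theta"), ts8)
  expect_gte(var(th$samples) / var(ts8$samples), 0.90)
  for (b in c("low_gamma", "high_gamma")) {
    bs <- assemble_band(dec, band_definition(b), ts8)
    expect_lte(var(bs$samples) / var(ts8$samples), 0.05)
  }
  ts40 <- tone_trace(40, 4, 1000, noise_sd = 0.01, seed = 2)
  dec40 <- sift_emd(ts40)
  lg <- assemble_band(dec40, band_definition("low_gamma"), ts40)
  expect_gte(var(lg$samples) / var(ts40$samples), 0.90)
})

test_that("a constant trace produces empty, flagged bands", {
  dc <- time_series(rep(2, 256), 1000)
  dec <- sift_emd(dc)
  expect_equal(ncol(dec$imfs), 0)
  bs <- assemble_band(dec, band_definition("theta"), dc)
  expect_true(bs$empty)
  expect_true(all(bs$samples == 0))
  expect_error(assemble_band(dec, band_definition("theta", 400, 600), dc),
               "Nyquist")
})

test_that("CEEMDAN is bit-reproducible, complete, and rejects bad parameters", {
  tt <- two_tone_fixture(dur = 2)
  a <- ceemdan(tt$trace, n_realizations = 20, seed = 7)
  b <- ceemdan(tt$trace, n_realizations = 20, seed = 7)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residual, b$residual)
  recon <- rowSums(a$imfs) + a$residual
  expect_lt(max(abs(recon - tt$trace$samples)), 1e-10 * sd(tt$trace$samples))
  expect_error(ceemdan(tt$trace, noise_sd = 0), "noise_sd")
  expect_error(ceemdan(tt$trace, n_realizations = 1), "n_realizations")
})

test_that("CEEMDAN routes two-tone variance like plain EMD", {
  tt <- two_tone_fixture(dur = 2)
  routes <- lapply(list(sift_emd(tt$trace),
                        ceemdan(tt$trace, n_realizations = 50, seed = 3)),
                   function(dec) c(
    theta = capture_fraction(assemble_band(dec, band_definition("theta"),
                                           tt$trace)$samples, tt$c8),
    lg = capture_fraction(assemble_band(dec, band_definition("low_gamma"),
                                        tt$trace)$samples, tt$c40)))
  expect_lt(abs(routes[[1]]["theta"] - routes[[2]]["theta"]), 0.10)
  expect_lt(abs(routes[[1]]["lg"] - routes[[2]]["lg"]), 0.10)
})

test_that("mean IMF frequency decreases with IMF index on broadband input", {
  set.seed(9)
  ts <- time_series(rnorm(4000), 1000)
  dec <- sift_emd(ts)
  f <- dec$mean_inst_freq[!is.na(dec$mean_inst_freq)]
  frac_dec <- mean(diff(f) < 0)
  expect_gte(frac_dec, 0.90)
})

test_that("CEEMDAN band variances are stable across seeds", {
  tt <- two_tone_fixture(dur = 2)
  vars <- sapply(c(11, 22, 33), function(s) {
    dec <- ceemdan(tt$trace, n_realizations = 100, seed = s)
    c(var(assemble_band(dec, band_definition("theta"), tt$trace)$samples),
      var(assemble_band(dec, band_definition("low_gamma"), tt$trace)$samples))
  })
  expect_lt(diff(range(vars[1, ])) / mean(vars[1, ]), 0.05)
  expect_lt(diff(range(vars[2, ])) / mean(vars[2, ]), 0.05)
})
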