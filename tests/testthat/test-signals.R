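test_that("hydrostatic calibration recovers exact slopes with R^2 = 1", {
  for (slope in c(1.596, 1.722)) {
    pts <- generate_calibration_points(slope, c(2, 4, 6, 8), noise_sd = 0)
    fit <- fit_hydrostatic_calibration(pts)
    expect_equal(fit$slope, slope, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$intercept, 0, tolerance = 1e-9)
  }
})

test_that("noisy calibration keeps the slope within 3 standard errors", {
  hits <- vapply(1:50, function(s) {
    pts <- generate_calibration_points(1.596, c(2, 4, 6, 8, 10),
                                       noise_sd = 0.05, seed = s)
    fit <- fit_hydrostatic_calibration(pts)
    se <- summary(fit$fit)$coefficients["voltage", "Std. Error"]
    expect_gt(fit$r_squared, 0)
    expect_lt(fit$r_squared, 1)
    abs(fit$slope - 1.596) < 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("calibration fit rejects underdetermined input", {
  expect_error(fit_hydrostatic_calibration(
    data.frame(depth_cm = c(4, 4), voltage = c(2.5, 2.5))),
    "underdetermined")
})

test_that("subglottal zeroing subtracts the silence-period mean", {
  fs <- 8000
  x <- rep(3.4, fs)
  z <- zero_subglottal(x, fs, c(0, 0.5))
  expect_equal(z$offset, 3.4)
  expect_true(all(z$signal == 0))
  # idempotence: a second pass finds nothing left to remove
  z2 <- zero_subglottal(z$signal, fs, c(0, 0.5))
  expect_equal(z2$offset, 0)
  expect_error(zero_subglottal(x, fs, c(0, 0.02)), "50 ms")
})

test_that("intraglottal zeroing anchors the most-negative cycle trough", {
  x <- generate_stylized_igp(stylized_cycle_params(), 0.4) - 1.3
  z <- zero_intraglottal(x, 8000)
  expect_equal(z$offset, 1.3, tolerance = 1e-6)
  expect_equal(min(z$cycle_minima) + z$offset - 1.3, -1.3, tolerance = 1e-6)
  # already-zeroed signal needs no offset
  z2 <- zero_intraglottal(x + 1.3, 8000)
  expect_equal(z2$offset, 0, tolerance = 1e-6)
  # a non-oscillating signal is an error, not a silent zero
  expect_error(zero_intraglottal(rep(2.2, 8000), 8000), "oscillation")
})

test_that("tied minima give the same offset regardless of position", {
  base <- generate_stylized_igp(stylized_cycle_params(), 0.4)
  cyc <- detect_cycles(base, 8000)
  x1 <- base
  i_first <- round(cyc[2] * 8000) - 20
  i_later <- round(cyc[8] * 8000) - 20
  x1[i_first] <- -0.9
  x2 <- base
  x2[i_later] <- -0.9
  expect_equal(zero_intraglottal(x1, 8000)$offset,
               zero_intraglottal(x2, 8000)$offset, tolerance = 1e-9)
})

test_that("cycle detection finds one impulse per 8 ms period", {
  x <- generate_stylized_igp(stylized_cycle_params(f0 = 125), 0.1)
  cyc <- detect_cycles(x, 8000)
  expect_true(length(cyc) %in% c(12, 13))
  expect_equal(median(diff(cyc)), 0.008, tolerance = 0.01)
  expect_error(detect_cycles(rep(1, 800), 8000), "oscillation")
})

test_that("cycle jitter is recovered from detected intervals", {
  x <- generate_stylized_igp(stylized_cycle_params(jitter_sd = 0.01,
                                                   seed = 4), 2)
  cyc <- detect_cycles(x, 8000)
  cv <- sd(diff(cyc)) / mean(diff(cyc))
  expect_gt(cv, 0.004)
  expect_lt(cv, 0.02)
})

test_that("per-cycle peaks recover the stylized impulse amplitude", {
  x <- generate_stylized_igp(stylized_cycle_params(impulse_amp = 9,
                                                   trough_level = 0), 0.4)
  cyc <- detect_cycles(x, 8000)
  pk <- peak_collision_per_cycle(x, 8000, cyc)
  expect_equal(length(pk$peaks), length(cyc))
  # sampling can shave up to ~2.5% off the raised-cosine impulse peak
  expect_true(all(pk$peaks > 8.7 & pk$peaks < 9.001))
  expect_equal(pk$f0_mean, 126.1, tolerance = 0.02)
})

test_that("per-cycle peaks of a constant signal equal the constant", {
  x <- generate_stylized_igp(stylized_cycle_params(), 0.4)
  cyc <- detect_cycles(x, 8000)
  pk <- peak_collision_per_cycle(rep(4.2, length(x)), 8000, cyc)
  expect_true(all(pk$peaks == 4.2))
})

test_that("peak extraction is offset-equivariant after intraglottal zeroing", {
  x <- generate_stylized_igp(stylized_cycle_params(noise_sd = 0.1,
                                                   seed = 2), 0.4)
  cyc <- detect_cycles(x, 8000)
  pk0 <- peak_collision_per_cycle(zero_intraglottal(x, 8000)$signal, 8000,
                                  cyc)
  pk1 <- peak_collision_per_cycle(zero_intraglottal(x - 2.7, 8000)$signal,
                                  8000, cyc)
  expect_equal(pk0$peaks, pk1$peaks, tolerance = 1e-9)
})

test_that("autocorrelation f0 is exact on an 8 ms pulse train", {
  x <- rep(c(1, rep(0, 63)), 60)
  expect_equal(as.numeric(estimate_f0(x, 8000)), 125, tolerance = 0.005)
})

test_that("autocorrelation f0 resolves a 126.1 Hz tone to 0.2 Hz", {
  t <- (0:3999) / 8000
  x <- sin(2 * pi * 126.1 * t)
  expect_equal(as.numeric(estimate_f0(x, 8000)), 126.1, tolerance = 0.2)
})

test_that("f0 estimation is amplitude invariant", {
  t <- (0:3999) / 8000
  x <- sin(2 * pi * 113.7 * t)
  expect_identical(as.numeric(estimate_f0(x, 8000)),
                   as.numeric(estimate_f0(250 * x, 8000)))
})

test_that("integer-sample periods are recovered within 0.5 Hz at any fs", {
  for (fs in c(8000, 16000)) {
    for (period in c(30, 64, 87, 101)) {
      f_true <- fs / period
      if (f_true < 72 || f_true > 295) next
      x <- rep(sin(2 * pi * seq_len(period) / period)^3, 40)
      expect_equal(as.numeric(estimate_f0(x, fs)), f_true, tolerance = 0.5)
    }
  }
})

test_that("white noise is declared unvoiced, not an error", {
  set.seed(9)
  f0 <- estimate_f0(rnorm(4000), 8000)
  expect_true(is.na(f0))
  expect_lt(attr(f0, "voicing"), 0.3)
})

test_that("SPL follows the 20 log10(rms / 20 uPa) definition", {
  t <- (0:79999) / 8000
  x <- 0.02 * sqrt(2) * sin(2 * pi * 500 * t)
  expect_equal(as.numeric(compute_spl(x)), 60, tolerance = 0.01)
  expect_equal(as.numeric(compute_spl(2 * x)) - as.numeric(compute_spl(x)),
               20 * log10(2), tolerance = 1e-6)
  silent <- compute_spl(numeric(100))
  expect_identical(as.numeric(silent), -Inf)
  expect_true(attr(silent, "silence"))
})

test_that("strike-zone criteria pass the full stylized waveform", {
  x <- generate_stylized_igp(stylized_cycle_params(noise_sd = 0.1), 0.5)
  r <- strike_zone_check(x, 8000)
  expect_true(r$in_strike_zone)
  expect_true(r$c1_impulsive && r$c2_rounded && r$c3_trough)
})

test_that("strike-zone criteria reject the three stylized failure modes", {
  # sensor above the strike zone: rounded aerodynamic peak only
  x1 <- generate_stylized_igp(stylized_cycle_params(impulse_amp = 0,
                                                    noise_sd = 0.1), 0.5)
  expect_false(strike_zone_check(x1, 8000)$c1_impulsive)
  # no rounded open-phase peak
  x2 <- generate_stylized_igp(stylized_cycle_params(rounded_amp = 0,
                                                    noise_sd = 0.1), 0.5)
  expect_false(strike_zone_check(x2, 8000)$c2_rounded)
  # baseline never returns to zero before the impulse
  x3 <- generate_stylized_igp(stylized_cycle_params(trough_level = 3,
                                                    noise_sd = 0.1), 0.5)
  expect_false(strike_zone_check(x3, 8000)$c3_trough)
})

test_that("co-location test separates same-site from different-site sensors", {
  b <- fx_clean_bundle()
  fs <- b$fs_signal
  sel <- round(0.35 * fs):round(0.7 * fs)
  igp <- decode_channel(b, "IGP")[sel]
  sgp <- decode_channel(b, "SGP")[sel]
  expect_identical(colocation_test(igp, igp, fs)$verdict, "same")
  expect_equal(colocation_test(igp, igp, fs)$zero_lag_correlation, 1)
  # amplitude invariance
  expect_identical(colocation_test(igp, 0.5 * igp, fs)$verdict, "same")
  # intraglottal vs subglottal waveshapes differ by construction
  expect_identical(colocation_test(igp, sgp, fs)$verdict, "different")
})
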