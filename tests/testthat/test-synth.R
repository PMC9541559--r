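test_that("a seed is mandatory and fixes the bundle exactly", {
  expect_error(generate_recording(synth_scenario()), "seed")
  sc <- synth_scenario(duration = 0.15, silence = 0.1)
  b1 <- generate_recording(sc, seed = 5)
  b2 <- generate_recording(sc, seed = 5)
  expect_identical(b1$channels, b2$channels)
  expect_identical(b1$area$area_mm2, b2$area$area_mm2)
  expect_identical(b1$truth, b2$truth)
})

test_that("uncorrupted bundles decode to the truth block", {
  b <- fx_clean_bundle()
  fs <- b$fs_signal
  # IGP: calibrate, re-zero, per-cycle peaks match the truth within 0.5%
  igp <- zero_intraglottal(decode_channel(b, "IGP"), fs,
                           interval = c(b$truth$t_onset + 0.1,
                                        length(b$channels$IGP) / fs))$signal
  cyc <- detect_cycles(igp, fs)
  pk <- peak_collision_per_cycle(igp, fs, cyc)
  t_set <- b$truth$t_onset + 0.1
  keep <- pk$cycle_times > t_set
  pairs <- match_cycles(list(cycle_times = pk$cycle_times[keep],
                             peaks = pk$peaks[keep]),
                        truth_peaks_after(b, t_set))
  expect_gt(nrow(pairs), 30)
  expect_lt(max(abs(pairs$estimated - pairs$measured) / pairs$measured),
            0.005)
  # SGP: silence-zeroing recovers the configured mean subglottal pressure
  sgp <- zero_subglottal(decode_channel(b, "SGP"), fs, c(0, 0.25))
  expect_equal(sgp$offset, 3.4, tolerance = 0.01)
  post <- round((b$truth$t_onset + 0.1) * fs):length(sgp$signal)
  expect_equal(mean(sgp$signal[post]), 9.0, tolerance = 0.05)
  # f0 of the intraglottal signal matches the truth block
  expect_equal(as.numeric(estimate_f0(igp[post], fs)), b$truth$f0,
               tolerance = 0.5)
  # microphone channel is calibrated to the target SPL
  mic <- decode_channel(b, "MIC")[post]
  expect_equal(as.numeric(compute_spl(mic)), 81.4, tolerance = 0.1)
})

test_that("truth collision impulses align with the IGP channel at zero lag", {
  b <- fx_clean_bundle()
  fs <- b$fs_signal
  igp <- zero_intraglottal(decode_channel(b, "IGP"), fs,
                           interval = c(b$truth$t_onset + 0.1,
                                        length(b$channels$IGP) / fs))$signal
  cyc <- detect_cycles(igp, fs)
  tr <- truth_peaks_after(b, 0)
  pairs <- match_cycles(list(cycle_times = cyc, peaks = rep(1, length(cyc))),
                        list(cycle_times = tr$cycle_times,
                             peaks = rep(1, length(tr$cycle_times))))
  expect_lt(median(abs(pairs$dt)), 1.5 / fs)
})

test_that("configured DC offsets and drift are removable corruptions", {
  b <- fx_noisy_bundle()
  fs <- b$fs_signal
  sgp <- zero_subglottal(decode_channel(b, "SGP"), fs, c(0, 0.25))
  # offset = configured 3.4 cm H2O plus the slow drift at the silence window
  expect_equal(sgp$offset, 3.4, tolerance = 0.6)
  post <- round((b$truth$t_onset + 0.1) * fs):length(sgp$signal)
  expect_equal(mean(sgp$signal[post]), 9.0, tolerance = 0.5)
})

test_that("sinusoidal drift has the configured amplitude and stays below 5 Hz", {
  fs <- 2000
  n <- 30 * fs
  d <- add_dc_drift(numeric(n), fs, drift_spec("sinusoid", amplitude = 1,
                                               period = 10))
  expect_equal(max(d), 1, tolerance = 1e-6)
  sp <- Mod(fft(d))[1:(n / 2)]
  f <- (seq_len(n / 2) - 1) / 30
  expect_lt(sum(sp[f > 5]) / sum(sp), 1e-6)
  # amplitude 0 is the identity
  x <- rnorm(100)
  expect_identical(add_dc_drift(x, fs, drift_spec(amplitude = 0)), x)
  # random walks are reproducible under a fixed seed
  d1 <- add_dc_drift(numeric(1000), fs, drift_spec("random_walk", sd = 0.1,
                                                   seed = 3))
  d2 <- add_dc_drift(numeric(1000), fs, drift_spec("random_walk", sd = 0.1,
                                                   seed = 3))
  expect_identical(d1, d2)
})

test_that("16-bit codec round-trip is within one least significant bit", {
  set.seed(8)
  x <- cumsum(rnorm(4000)) / 50
  path <- withr::local_tempfile(fileext = ".wav")
  fsr <- write_wav(x, path, 8000)
  y <- read_wav(path, full_scale = fsr)
  expect_equal(y$fs, 8000)
  expect_lt(max(abs(y$x - x)), fsr / 32767 + 1e-12)
})

test_that("bundle writer and reader round-trip through WAV + side-car", {
  b <- fx_clean_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("ACC.wav", "EGG.wav",
                                               "IGP.wav", "MIC.wav",
                                               "SGP.wav", "bundle.json",
                                               "area.csv", "truth.json")))))
  b2 <- read_bundle(dir)
  lsb <- max(unlist(b$full_scale)) / 32767
  for (ch in names(b$channels)) {
    expect_lt(max(abs(b2$channels[[ch]] - b$channels[[ch]])),
              b$full_scale[[ch]] / 32767 + 1e-12)
  }
  expect_equal(b2$area$area_mm2, b$area$area_mm2, tolerance = 1e-6)
  expect_equal(b2$truth$p_sub_cmh2o, b$truth$p_sub_cmh2o)
  expect_equal(b2$calibration$IGP, 1.596)
})

test_that("stylized cycle parameters enforce their invariants", {
  expect_error(stylized_cycle_params(impulse_width = 0.7,
                                     open_quotient = 0.6), "impulse_width")
  expect_error(stylized_cycle_params(impulse_amp = -1))
  p <- stylized_cycle_params(jitter_sd = 0.01, seed = 2)
  s1 <- generate_stylized_igp(p, 0.3)
  s2 <- generate_stylized_igp(p, 0.3)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("occlusion scales the observed area by the configured fraction", {
  b <- fx_noisy_bundle()   # occlusion 0.10, no area noise
  truth_area <- b$truth$area_mm2
  corrected <- occlusion_correct(b$area$area_mm2, b$truth$occlusion)
  expect_lt(max(abs(corrected - truth_area) / pmax(truth_area, 1e-9)), 0.02)
})
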