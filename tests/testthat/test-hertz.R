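test_that("edge parabola fits exact data with zero residual", {
  s <- seq(0, 10, by = 1)
  x <- -0.05 * s * (s - 10) + 0.2 * s / 10
  fit <- fit_edge_parabola(data.frame(s = s, x = x), c(0, 0), c(10, 0.2))
  expect_lt(fit$residual_rms, 1e-12)
  expect_equal(unname(fit$coef["a"]), -0.05, tolerance = 1e-12)
})

test_that("symmetric edge points place the apex at the midline", {
  s <- c(2, 4, 6, 8)
  x <- c(1, 2.2, 2.2, 1)
  fit <- fit_edge_parabola(data.frame(s = s, x = x), c(0, 0), c(10, 0))
  expect_equal(fit$apex_s, 5, tolerance = 1e-9)
  expect_error(fit_edge_parabola(data.frame(s = s, x = x), c(3, 0), c(3, 1)),
               "degenerate")
})

test_that("noisy edge points keep the apex within 3 sigma of truth", {
  s <- seq(0.5, 9.5, by = 0.5)
  truth <- function(si) -0.08 * si * (si - 10)     # apex 2.0 at s = 5
  apexes <- vapply(1:100, function(k) {
    set.seed(k)
    pts <- data.frame(s = s, x = truth(s) + rnorm(length(s), 0, 0.1))
    fit_edge_parabola(pts, c(0, 0), c(10, 0))$apex_x
  }, numeric(1))
  expect_lt(abs(mean(apexes) - 2), 3 * sd(apexes) / sqrt(100))
  expect_lt(sd(apexes), 0.1)
})

test_that("Kalman edge tracking reproduces a noiseless 125 Hz sinusoid", {
  fs <- 2000
  t <- seq(0, 0.1, by = 1 / fs)
  A <- 5e-4
  obs <- A * sin(2 * pi * 125 * t)
  tr <- track_edge_kalman(obs, fs)
  post <- tr$t > 5 / 125            # after 5 cycles
  expect_lt(sqrt(mean((tr$x[post] - obs[post])^2)) / A, 0.02)
  # velocity phase error below 5 degrees vs the analytic derivative
  v_true <- A * 2 * pi * 125 * cos(2 * pi * 125 * t)
  phase <- function(y) Arg(sum(y[post] * exp(-2i * pi * 125 * t[post])))
  expect_lt(abs(phase(tr$v) - phase(v_true)) * 180 / pi, 5)
  # covariance contracts during steady observation
  expect_lt(tr$var_x[sum(post)], tr$var_x[5])
})

test_that("zero observation noise makes the tracker follow observations", {
  obs <- rnorm(50)
  tr <- track_edge_kalman(obs, 2000, obs_noise = 0)
  expect_equal(tr$x, obs, tolerance = 1e-9)
})

test_that("overlap estimation matches closed-form geometry", {
  fs <- 2000
  t <- seq(0, 0.05, by = 1 / fs)
  A <- 6e-4
  x <- A * sin(2 * pi * 125 * t)
  v <- A * 2 * pi * 125 * cos(2 * pi * 125 * t)
  track <- data.frame(t = t, x = x, v = v)
  # trajectory never reaching the plane: no overlap
  d0 <- estimate_overlap(track, hertz_config(contact_plane = -2 * A))
  expect_true(all(d0 == 0))
  # plane at half the amplitude: delta_max = A / 2
  d1 <- estimate_overlap(track, hertz_config(contact_plane = -A / 2))
  expect_equal(max(d1), A / 2, tolerance = 0.05 * A)
})

test_that("occluded-interval extrapolation is monotone in entry speed", {
  cfg <- hertz_config()
  mk <- function(v_in) {
    n <- 40
    track <- data.frame(t = (0:n) / 2000,
                        x = c(1e-4, rep(0, n)),
                        v = c(-v_in, rep(0, n)))
    occ <- c(FALSE, rep(TRUE, 8), rep(FALSE, n - 8))
    d <- estimate_overlap(track, cfg, occluded = occ)
    max(attr(d, "episodes")$delta_max)
  }
  expect_gt(mk(0.6), mk(0.3))
  expect_equal(mk(0.6) / mk(0.3), 2, tolerance = 1e-6)
})

test_that("overlap-to-pressure matches the brute-force contact oracle", {
  cfg <- hertz_config()
  deltas <- seq(0, 3e-4, length.out = 31)
  p_impl <- cmh2o_to_pa(hertz_peak_pressure(deltas, cfg))
  p_oracle <- vapply(deltas, oracle_hertz_p0, numeric(1),
                     E = cfg$E_eff, nu = cfg$nu, R = cfg$R_eff)
  rel <- abs(p_impl - p_oracle) / pmax(p_oracle, 1e-9)
  expect_lt(max(rel[deltas > 0]), 0.01)
  expect_equal(p_impl[1], 0)
})

test_that("contact pressure is monotone in overlap and moduli", {
  grid_d <- seq(1e-6, 3e-4, length.out = 20)
  cfg <- hertz_config()
  p <- hertz_peak_pressure(grid_d, cfg)
  expect_true(all(diff(p) > 0))
  # doubling E_eff doubles the plane-strain modulus and the pressure
  cfg2 <- hertz_config(E_eff = 2 * cfg$E_eff)
  expect_equal(hertz_peak_pressure(grid_d, cfg2) / p,
               rep(2, length(grid_d)))
  # larger contact radius spreads the load and lowers the peak
  cfg3 <- hertz_config(R_eff = 2 * cfg$R_eff)
  expect_true(all(hertz_peak_pressure(grid_d, cfg3) < p))
  expect_error(hertz_peak_pressure(-1e-6, cfg), "negative")
})

test_that("contact pressure analysis recovers simulated collision peaks", {
  b <- fx_clean_bundle()
  cpa <- run_cpa(b$truth$area_mm2, b$area$fs_video)
  t_set <- b$truth$t_onset + 0.15
  est <- list(cycle_times = cpa$cycle_times[cpa$cycle_times > t_set],
              peaks = cpa$p_est[cpa$cycle_times > t_set])
  pairs <- match_cycles(est, truth_peaks_after(b, t_set))
  st <- error_stats(pairs)
  expect_gt(st$n, 30)
  expect_lte(st$mape, 20)
})

test_that("per-cycle estimates track truth across driving pressures", {
  pools <- lapply(c(5, 7, 9, 12, 15, 18), function(psub) {
    b <- generate_recording(fx_clean_scenario(duration = 0.4, silence = 0,
                                              p_sub_cmh2o = psub),
                            seed = 21)
    cpa <- run_cpa(b$truth$area_mm2, b$area$fs_video)
    keep <- cpa$cycle_times > 0.15
    pairs <- match_cycles(list(cycle_times = cpa$cycle_times[keep],
                               peaks = cpa$p_est[keep]),
                          truth_peaks_after(b, 0.15))
    pairs
  })
  all_pairs <- do.call(rbind, pools)
  expect_gt(cor(all_pairs$measured, all_pairs$estimated), 0.95)
  # median estimate rises with the driving pressure
  med <- vapply(pools, function(p) median(p$estimated), numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("a non-colliding oscillation yields all-zero contact estimates", {
  p <- rules_to_params(activations(0.9, 0.1))
  s <- bcm_simulate(p, sim_config(duration = 0.5))
  expect_true(all(s$p_col == 0))
  area_mm2 <- s$area[seq(1, length(s$area), by = 4)] * 1e6
  cpa <- run_cpa(area_mm2, 2000)
  expect_gt(nrow(cpa), 0)
  expect_true(all(cpa$p_est == 0))
})
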