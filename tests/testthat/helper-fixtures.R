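# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, maker) {
  if (is.null(.fx[[name]])) assign(name, maker(), envir = .fx)
  get(name, envir = .fx)
}

# scenario with every corruption disabled (no noise, no drift, no occlusion)
fx_clean_scenario <- function(duration = 0.5, silence = 0.3, ...) {
  synth_scenario(duration = duration, silence = silence,
                 drift = drift_spec("sinusoid", amplitude = 0),
                 noise_sd = list(IGP = 0, SGP = 0, MIC = 0, EGG = 0,
                                 ACC = 0),
                 occlusion = 0, ...)
}

fx_clean_bundle <- function() {
  fx_cached("clean_bundle",
            function() generate_recording(fx_clean_scenario(), seed = 11))
}

fx_noisy_bundle <- function() {
  fx_cached("noisy_bundle",
            function() generate_recording(synth_scenario(duration = 0.5,
                                                         silence = 0.3),
                                          seed = 11))
}

fx_default_sim <- function() {
  fx_cached("default_sim", function() {
    bcm_simulate(rules_to_params(activations(0.5, 0.5)),
                 sim_config(duration = 0.5))
  })
}

# truth per-cycle collision peaks after a settle time
truth_peaks_after <- function(bundle, t_min) {
  keep <- bundle$truth$cycle_times > t_min
  list(cycle_times = bundle$truth$cycle_times[keep],
       peaks = bundle$truth$peak_p_col_cmh2o[keep])
}

# Independent numerical Hertz cylinder-contact oracle: bisection on the
# line load until the Hertz contact half-width matches the geometric
# interference half-width; peak pressure from the semi-elliptic profile.
oracle_hertz_p0 <- function(delta, E, nu, R) {
  Es <- E / (1 - nu^2)
  b_geom <- sqrt(2 * R * delta)
  lo <- 0
  hi <- 1e7
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sqrt(4 * mid * R / (pi * Es)) < b_geom) lo <- mid else hi <- mid
  }
  Fp <- (lo + hi) / 2
  if (Fp == 0) return(0)
  2 * Fp / (pi * sqrt(4 * Fp * R / (pi * Es)))   # Pa
}

# mean per-cycle collision peak of a simulation (Pa)
sim_mean_peak <- function(sim, t_min = 0.15) {
  post <- sim$t > t_min
  ep <- phonopress:::contact_episode_peaks(sim$p_col[post], sim$fs)
  if (length(ep$peaks) == 0) return(0)
  mean(ep$peaks)
}
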