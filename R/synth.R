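# Synthetic multichannel recording generator. Emulates the structure of
# an in vivo pressure-probe session: a body-cover simulation provides the
# physical truth; sensor channels are derived from it, encoded to volts
# through linear calibration slopes, corrupted by DC drift, Gaussian
# noise, and 16-bit quantization, and bundled with the ground truth.

#' DC drift specification
#'
#' Pressure sensors exhibit a slow additive baseline drift (attributed to
#' thermal fluctuation). Either a sinusoid of known amplitude and period
#' or a smoothed random walk.
#'
#' @param type `"sinusoid"` or `"random_walk"`.
#' @param amplitude sinusoid amplitude (cm H2O).
#' @param period sinusoid period (s); must be well below the phonation
#'   cycle rate in frequency.
#' @param phase sinusoid phase (rad).
#' @param sd random-walk step standard deviation (cm H2O) per knot
#'   (knots every 0.5 s, spline-interpolated).
#' @param seed seed for the random-walk realization.
#' @return an object of class `drift_spec`.
#' @export
drift_spec <- function(type = c("sinusoid", "random_walk"), amplitude = 0.5,
                       period = 20, phase = 0, sd = 0.02, seed = NULL) {
  type <- match.arg(type)
  if (type == "sinusoid" && period < 1)
    stop("drift period must be >= 1 s (drift bandwidth below 5 Hz)",
         call. = FALSE)
  structure(list(type = type, amplitude = amplitude, period = period,
                 phase = phase, sd = sd, seed = seed),
            class = "drift_spec")
}

#' Additive DC drift
#'
#' @param x signal (cm H2O).
#' @param fs sample rate (Hz).
#' @param spec a [drift_spec()].
#' @return drifted signal; `x + drift_signal(...)`.
#' @export
add_dc_drift <- function(x, fs, spec) {
  x + drift_signal(length(x), fs, spec)
}

drift_signal <- function(n, fs, spec) {
  stopifnot(inherits(spec, "drift_spec"))
  t <- (seq_len(n) - 1) / fs
  if (spec$type == "sinusoid") {
    if (spec$amplitude == 0) return(numeric(n))
    spec$amplitude * sin(2 * pi * t / spec$period + spec$phase)
  } else {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    knot_dt <- 0.5
    nk <- max(4L, ceiling(n / fs / knot_dt) + 2L)
    walk <- cumsum(rnorm(nk, 0, spec$sd))
    spline(x = (seq_len(nk) - 1) * knot_dt, y = walk, xout = t)$y
  }
}

#' Generate hydrostatic calibration points
#'
#' Emulates the bench calibration of a probe pressure sensor: the probe is
#' submerged at known depths in a water column and the output voltage is
#' noted; hydrostatic pressure in cm H2O equals the depth in cm.
#'
#' @param true_slope sensor scale factor ((cm H2O)/V).
#' @param depths_cm submergence depths (cm); positive and distinct.
#' @param noise_sd voltage noise standard deviation (V).
#' @param seed RNG seed.
#' @return data frame with columns `depth_cm`, `voltage`.
#' @export
generate_calibration_points <- function(true_slope, depths_cm = c(2, 4, 6, 8, 10),
                                        noise_sd = 0, seed = 1) {
  stopifnot(all(depths_cm > 0), !anyDuplicated(depths_cm), true_slope != 0)
  set.seed(seed)
  data.frame(depth_cm = depths_cm,
             voltage = depths_cm / true_slope + rnorm(length(depths_cm), 0,
                                                      noise_sd))
}

#' Stylized intraglottal cycle parameters
#'
#' Parameters of the stylized per-cycle intraglottal pressure waveform:
#' an impulsive collision peak at the start of the closed phase, a rounded
#' aerodynamic peak during the open phase, and a trough immediately
#' preceding the next impulse.
#'
#' @param f0 cycle rate (Hz).
#' @param impulse_amp impulsive peak amplitude (cm H2O).
#' @param impulse_width impulse half-height width as a fraction of the
#'   period.
#' @param rounded_amp rounded open-phase peak amplitude (cm H2O).
#' @param open_quotient open-phase fraction of the cycle.
#' @param trough_level baseline level before the impulse (cm H2O).
#' @param jitter_sd per-cycle period jitter (fractional sd).
#' @param noise_sd additive Gaussian noise sd (cm H2O).
#' @param seed RNG seed.
#' @return an object of class `stylized_cycle_params`.
#' @export
stylized_cycle_params <- function(f0 = 126.1, impulse_amp = 9.0,
                                  impulse_width = 0.08, rounded_amp = 4.0,
                                  open_quotient = 0.6, trough_level = 0,
                                  jitter_sd = 0, noise_sd = 0, seed = 1) {
  stopifnot(f0 > 0, impulse_amp >= 0, rounded_amp >= 0)
  if (!(impulse_width > 0 && impulse_width < open_quotient &&
        open_quotient < 1))
    stop("need 0 < impulse_width < open_quotient < 1", call. = FALSE)
  structure(list(f0 = f0, impulse_amp = impulse_amp,
                 impulse_width = impulse_width, rounded_amp = rounded_amp,
                 open_quotient = open_quotient, trough_level = trough_level,
                 jitter_sd = jitter_sd, noise_sd = noise_sd, seed = seed),
            class = "stylized_cycle_params")
}

#' Generate a stylized intraglottal pressure signal
#'
#' Builds the waveform cycle by cycle on a raised-cosine basis: each cycle
#' contains, in order, the impulsive collision peak, the rounded
#' aerodynamic peak centered in the open phase, and a return to
#' `trough_level` before the next impulse.
#'
#' @param p a [stylized_cycle_params()] object.
#' @param duration signal length (s).
#' @param fs sample rate (Hz).
#' @return numeric signal (cm H2O) with attribute `cycle_times` (s, the
#'   impulse peak times).
#' @export
generate_stylized_igp <- function(p, duration = 0.5, fs = 8000) {
  stopifnot(inherits(p, "stylized_cycle_params"), duration > 0)
  set.seed(p$seed)
  rc <- function(phi, c, w) {
    u <- (phi - c) / w
    ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
  }
  cq <- 1 - p$open_quotient
  c_imp <- 0.5 * p$impulse_width
  c_rnd <- cq + 0.45 * p$open_quotient
  w_rnd <- 0.45 * p$open_quotient
  sig <- numeric(0)
  cycle_times <- numeric(0)
  t_target <- 0
  n_emitted <- 0L
  while (t_target < duration) {
    T_i <- (1 / p$f0) * (1 + p$jitter_sd * rnorm(1))
    t_target <- t_target + T_i
    # fractional-sample cycle lengths accumulate so the mean period is exact
    n_i <- max(8L, round(t_target * fs) - n_emitted)
    phi <- (seq_len(n_i) - 1) / n_i
    cyc <- p$trough_level +
      p$impulse_amp * rc(phi, c_imp, p$impulse_width) +
      p$rounded_amp * rc(phi, c_rnd, w_rnd)
    cycle_times <- c(cycle_times, (n_emitted + c_imp * n_i) / fs)
    sig <- c(sig, cyc)
    n_emitted <- n_emitted + n_i
  }
  n <- round(duration * fs)
  sig <- sig[seq_len(min(n, length(sig)))]
  if (p$noise_sd > 0) sig <- sig + rnorm(length(sig), 0, p$noise_sd)
  attr(sig, "cycle_times") <- cycle_times[cycle_times < length(sig) / fs]
  sig
}

#' Synthetic recording scenario
#'
#' Settings for [generate_recording()]. Defaults parameterize the
#' reference regime of comfortable sustained phonation: cycle rate near
#' 126 Hz, mean subglottal pressure 9.0 cm H2O, mean peak collision
#' pressure of the same order, vocal SPL 81.4 dB re 15 cm, sensor
#' calibration slopes 1.596 (intraglottal) and 1.722 (subglottal)
#' (cm H2O)/V, DC offsets of -1.3 and +3.4 cm H2O, and a 0.5 cm H2O,
#' 20 s sinusoidal drift.
#'
#' @param act muscle [activations()].
#' @param baseline passive [bcm_params()].
#' @param p_sub_cmh2o mean subglottal pressure (cm H2O).
#' @param duration phonation duration (s).
#' @param silence silence lead-in before phonation onset (s).
#' @param fs_signal sensor channel sample rate (Hz).
#' @param fs_video glottal area frame rate (Hz); `fs_signal` must be 4
#'   times `fs_video`.
#' @param calibration named list of sensor scale factors (physical
#'   units per volt) for IGP, SGP, MIC, EGG, ACC.
#' @param dc_offset named list of additive sensor offsets (cm H2O) for
#'   IGP and SGP.
#' @param drift a [drift_spec()] applied to the two pressure channels.
#' @param noise_sd named list of additive voltage noise sd per channel.
#' @param occlusion fraction of the glottal area visually blocked by the
#'   probe, in `[0, 1)`.
#' @param area_noise_sd additive area observation noise (mm^2).
#' @param px_scale_mm spatial scale of the synthetic video (mm per pixel).
#' @param spl_db target vocal SPL of the microphone channel (dB re 20 uPa
#'   at 15 cm).
#' @param symmetric mirror condition for the simulated fold.
#' @return an object of class `synth_scenario`.
#' @export
synth_scenario <- function(act = activations(0.5, 0.5),
                           baseline = bcm_params(),
                           p_sub_cmh2o = 9.0, duration = 0.6, silence = 0.5,
                           fs_signal = 8000, fs_video = 2000,
                           calibration = list(IGP = 1.596, SGP = 1.722,
                                              MIC = 0.5, EGG = 1.0,
                                              ACC = 1.0),
                           dc_offset = list(IGP = -1.3, SGP = 3.4),
                           drift = drift_spec("sinusoid", amplitude = 0.5,
                                              period = 20),
                           noise_sd = list(IGP = 0.01, SGP = 0.01,
                                           MIC = 0.005, EGG = 0.005,
                                           ACC = 0.005),
                           occlusion = 0.10, area_noise_sd = 0,
                           px_scale_mm = 0.1, spl_db = 81.4,
                           symmetric = TRUE) {
  if (abs(fs_signal - 4 * fs_video) > 1e-9)
    stop("fs_signal must equal 4 * fs_video", call. = FALSE)
  if (occlusion < 0 || occlusion >= 1)
    stop("occlusion fraction must lie in [0, 1)", call. = FALSE)
  structure(list(act = act, baseline = baseline, p_sub_cmh2o = p_sub_cmh2o,
                 duration = duration, silence = silence,
                 fs_signal = fs_signal, fs_video = fs_video,
                 calibration = calibration, dc_offset = dc_offset,
                 drift = drift, noise_sd = noise_sd, occlusion = occlusion,
                 area_noise_sd = area_noise_sd, px_scale_mm = px_scale_mm,
                 spl_db = spl_db, symmetric = symmetric),
            class = "synth_scenario")
}

# Per-cycle collision peaks of a simulated pressure series: one peak per
# contiguous contact episode (p_col > 0).
contact_episode_peaks <- function(p_col, fs) {
  r <- rle(p_col > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= 2)
  if (length(keep) == 0)
    return(list(times = numeric(0), peaks = numeric(0)))
  times <- numeric(length(keep)); peaks <- numeric(length(keep))
  for (j in seq_along(keep)) {
    idx <- starts[keep[j]]:ends[keep[j]]
    peaks[j] <- max(p_col[idx])
    times[j] <- (idx[which.max(p_col[idx])] - 1) / fs
  }
  list(times = times, peaks = peaks)
}

#' Generate a synthetic multichannel recording
#'
#' Runs the body-cover simulator under the scenario and derives the five
#' sensor channels from it: IGP is the collision pressure plus the
#' open-phase aerodynamic (jet) pressure at the sensor; SGP is the
#' subglottal pressure with a small flow-coupled ripple; MIC is a scaled
#' glottal flow derivative; EGG is a contact proxy; ACC is a band-limited
#' flow-derivative proxy. Channels are encoded to volts through the
#' calibration slopes, with DC offsets, slow drift on the pressure
#' channels, Gaussian voltage noise, and 16-bit quantization. A silence
#' lead-in precedes phonation. The glottal area is emitted at the video
#' rate, partially occluded by the probe and coded in pixel units.
#'
#' @param scenario a [synth_scenario()].
#' @param seed integer seed; mandatory, for reproducibility.
#' @return an object of class `recording_bundle`: channels (volts, as
#'   acquired), full-scale ranges, calibration metadata, area block, and
#'   ground-truth block.
#' @export
generate_recording <- function(scenario = synth_scenario(), seed) {
  stopifnot(inherits(scenario, "synth_scenario"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required: synthetic recordings must be reproducible",
         call. = FALSE)
  set.seed(seed)
  sc <- scenario
  fs <- sc$fs_signal
  psub_pa <- cmh2o_to_pa(sc$p_sub_cmh2o)

  params <- rules_to_params(sc$act, sc$baseline)
  cfg <- sim_config(p_sub = psub_pa, duration = sc$duration, fs_out = fs,
                    symmetric = sc$symmetric)
  sim <- bcm_simulate(params, cfg)

  n_sil <- round(sc$silence * fs)
  n_pho <- length(sim$area)
  n <- n_sil + n_pho

  # --- physical channel truth -------------------------------------------
  igp_cm <- pa_to_cmh2o(sim$p_col + sim$p_drive)
  flow <- sim$area * sqrt(2 * psub_pa / 1.14)          # m^3/s, Bernoulli
  ripple <- flow / mean(flow) - 1
  sgp_cm <- sc$p_sub_cmh2o * (1 + 0.04 * ripple)
  dflow <- c(0, diff(flow)) * fs
  bw <- signal::butter(2, 3000 / (fs / 2), type = "low")
  mic_pa <- signal::filtfilt(bw, dflow)
  mic_pa <- mic_pa - mean(mic_pa)
  target_rms <- 20e-6 * 10^(sc$spl_db / 20)
  mic_pa <- mic_pa * target_rms / sqrt(mean(mic_pa^2))
  egg <- signal::filtfilt(bw, sim$p_col)
  egg <- egg - mean(egg)
  egg <- egg / max(abs(egg))
  acc <- signal::filtfilt(signal::butter(2, 2500 / (fs / 2), "low"), dflow)
  acc <- (acc - mean(acc)) / max(abs(acc))

  pad <- function(x) c(numeric(n_sil), x)
  phys <- list(IGP = pad(igp_cm), SGP = pad(sgp_cm), MIC = pad(mic_pa),
               EGG = pad(egg), ACC = pad(acc))

  # --- encode to volts: offsets, drift, noise, 16-bit codec -------------
  drift_phase <- stats::runif(2, 0, 2 * pi)
  channels <- list(); full_scale <- list()
  for (ch in names(phys)) {
    v <- phys[[ch]]
    if (ch %in% c("IGP", "SGP")) {
      off <- sc$dc_offset[[ch]]
      dsp <- sc$drift
      if (dsp$type == "sinusoid")
        dsp$phase <- drift_phase[match(ch, c("IGP", "SGP"))]
      v <- add_dc_drift(v + off, fs, dsp)
    }
    v <- v / sc$calibration[[ch]]
    nsd <- sc$noise_sd[[ch]]
    if (!is.null(nsd) && nsd > 0) v <- v + rnorm(n, 0, nsd)
    fsr <- 1.1 * max(abs(v))
    if (fsr == 0) fsr <- 1
    v <- round(v / fsr * 32767) / 32767 * fsr
    channels[[ch]] <- v
    full_scale[[ch]] <- fsr
  }

  # --- glottal area at the video rate -----------------------------------
  dec <- fs / sc$fs_video
  area_pho_mm2 <- sim$area[seq(1, n_pho, by = dec)] * 1e6
  rest_area_mm2 <- sim$area[1] * 1e6
  area_mm2 <- c(rep(rest_area_mm2, n_sil / dec), area_pho_mm2)
  area_obs <- area_mm2 * (1 - sc$occlusion)
  if (sc$area_noise_sd > 0)
    area_obs <- pmax(0, area_obs + rnorm(length(area_obs), 0,
                                         sc$area_noise_sd))
  area_px <- area_obs / sc$px_scale_mm^2

  # --- ground truth ------------------------------------------------------
  ep <- contact_episode_peaks(sim$p_col, fs)
  truth <- list(p_sub_cmh2o = sc$p_sub_cmh2o,
                cycle_times = ep$times + sc$silence,
                peak_p_col_cmh2o = pa_to_cmh2o(ep$peaks),
                f0 = as.numeric(estimate_f0(
                  sim$area[sim$t > min(0.15, 0.4 * max(sim$t))], fs)),
                a_ct = sc$act$a_ct, a_ta = sc$act$a_ta,
                a_pgo_mm2 = params$A_pgo * 1e6,
                occlusion = sc$occlusion, seed = seed,
                t_onset = sc$silence,
                area_mm2 = area_mm2)

  structure(list(channels = channels, fs_signal = fs,
                 full_scale = full_scale,
                 calibration = sc$calibration, dc_offset = sc$dc_offset,
                 area = list(t = (seq_along(area_obs) - 1) / sc$fs_video,
                             area_mm2 = area_obs, area_px = area_px,
                             px_scale_mm = sc$px_scale_mm,
                             probe_width_px = 4.4 / sc$px_scale_mm,
                             fs_video = sc$fs_video),
                 truth = truth, scenario = sc, sim = sim),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("Synthetic recording: %.2f s (%.2f s silence + %.2f s phonation) at %g Hz\n",
              length(x$channels$IGP) / x$fs_signal, x$truth$t_onset,
              length(x$channels$IGP) / x$fs_signal - x$truth$t_onset,
              x$fs_signal))
  cat(sprintf("  truth: P_sub %.1f cm H2O, f0 %.1f Hz, %d collision cycles\n",
              x$truth$p_sub_cmh2o, x$truth$f0, length(x$truth$cycle_times)))
  invisible(x)
}

#' Decode a bundle channel to physical units
#'
#' Applies the stored calibration slope to the voltage channel; the
#' result still carries the sensor DC offset and drift, which the zeroing
#' procedures remove.
#'
#' @param bundle a [generate_recording()] bundle.
#' @param channel channel name (`"IGP"`, `"SGP"`, ...).
#' @return numeric signal in physical units.
#' @export
decode_channel <- function(bundle, channel) {
  stopifnot(inherits(bundle, "recording_bundle"),
            channel %in% names(bundle$channels))
  bundle$channels[[channel]] * bundle$calibration[[channel]]
}

#' Write a recording bundle to disk
#'
#' One 16-bit PCM mono WAV file per channel (ACC, EGG, IGP, MIC, SGP),
#' full-scale ranges and calibration metadata in a JSON side-car (WAV
#' normalization destroys physical units), the area series as CSV, and
#' the truth block as JSON.
#'
#' @param bundle a `recording_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in c("ACC", "EGG", "IGP", "MIC", "SGP")) {
    write_wav(bundle$channels[[ch]], file.path(dir, paste0(ch, ".wav")),
              bundle$fs_signal, full_scale = bundle$full_scale[[ch]])
  }
  meta <- list(fs_signal = bundle$fs_signal,
               full_scale = bundle$full_scale,
               calibration = bundle$calibration,
               dc_offset = bundle$dc_offset,
               px_scale_mm = bundle$area$px_scale_mm,
               probe_width_px = bundle$area$probe_width_px,
               fs_video = bundle$area$fs_video)
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(t = bundle$area$t, area_mm2 = bundle$area$area_mm2,
                       area_px = bundle$area$area_px),
            file.path(dir, "area.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a recording bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a `recording_bundle` (without the simulation object; the truth
#'   block is restored from `truth.json` if present).
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  channels <- list()
  for (ch in c("ACC", "EGG", "IGP", "MIC", "SGP")) {
    w <- read_wav(file.path(dir, paste0(ch, ".wav")),
                  full_scale = meta$full_scale[[ch]])
    channels[[ch]] <- w$x
  }
  area_df <- read.csv(file.path(dir, "area.csv"))
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  structure(list(channels = channels, fs_signal = meta$fs_signal,
                 full_scale = as.list(meta$full_scale),
                 calibration = as.list(meta$calibration),
                 dc_offset = as.list(meta$dc_offset),
                 area = list(t = area_df$t, area_mm2 = area_df$area_mm2,
                             area_px = area_df$area_px,
                             px_scale_mm = meta$px_scale_mm,
                             probe_width_px = meta$probe_width_px,
                             fs_video = meta$fs_video),
                 truth = truth, scenario = NULL, sim = NULL),
            class = "recording_bundle")
}
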