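# Bayesian estimation over the body-cover model with the glottal area
# waveform as the only observation ("Case I"): an extended Kalman filter
# on the augmented state (6 mechanical states + subglottal pressure +
# posterior glottal opening area + the two muscle activations), with
# random-walk dynamics for the slowly varying parameters, finite-
# difference Jacobians of the simulator transition, and delta-method
# propagation of uncertainty into the collision pressure.

.ekf_names <- c("x_u", "x_l", "x_b", "v_u", "v_l", "v_b",
                "p_sub", "a_pgo", "a_ct", "a_ta")

#' Priors for the Case-I estimator
#'
#' @param p_sub,a_pgo,a_ct,a_ta lists with `mean` and `sd`; `p_sub` in Pa,
#'   `a_pgo` in m^2, activations dimensionless.
#' @return an object of class `ekf_priors`.
#' @export
ekf_priors <- function(p_sub = list(mean = 600, sd = 250),
                       a_pgo = list(mean = 1.0e-6, sd = 1.5e-6),
                       a_ct = list(mean = 0.3, sd = 0.25),
                       a_ta = list(mean = 0.3, sd = 0.25)) {
  pr <- list(p_sub = p_sub, a_pgo = a_pgo, a_ct = a_ct, a_ta = a_ta)
  for (nm in names(pr)) {
    if (!is.finite(pr[[nm]]$sd) || pr[[nm]]$sd <= 0)
      stop("prior sd for '", nm, "' must be > 0 (the filter requires ",
           "nonzero prior uncertainty)", call. = FALSE)
  }
  structure(pr, class = "ekf_priors")
}

#' Filter tuning constants
#'
#' Per-observation-step process noise standard deviations. The mechanical
#' states receive a small noise floor (the process model is the simulator
#' itself); the parameters follow a random walk whose step size trades
#' tracking speed against steady-state variance.
#'
#' @param sd_x,sd_v state noise sd (m, m/s) per step.
#' @param sd_psub,sd_apgo,sd_act random-walk step sd for subglottal
#'   pressure (Pa), PGO area (m^2), activations.
#' @param r_obs area observation variance (m^4).
#' @param n_sub internal prediction substeps per observation step.
#' @return list of class `ekf_control`.
#' @export
ekf_control <- function(sd_x = 2e-6, sd_v = 2e-3, sd_psub = 4,
                        sd_apgo = 4e-9, sd_act = 2e-3,
                        r_obs = (0.3e-6)^2, n_sub = 8) {
  structure(list(sd_x = sd_x, sd_v = sd_v, sd_psub = sd_psub,
                 sd_apgo = sd_apgo, sd_act = sd_act, r_obs = r_obs,
                 n_sub = as.integer(n_sub)),
            class = "ekf_control")
}

#' Initialize the augmented state
#'
#' The mechanical state starts at the rest posture of the prior-mean
#' parameters. The covariance is diagonal; the parameter-block variances
#' are multiplied by `inflation^2` so that the initial confidence
#' intervals of the estimated outputs are `inflation` times the nominal
#' prior width (large initial uncertainty, letting the data drive early
#' convergence). The mechanical state keeps its nominal uncertainty: the
#' fold is known to start near rest, and inflating it only destabilizes
#' the first updates.
#'
#' @param priors an [ekf_priors()] object.
#' @param baseline passive [bcm_params()].
#' @param inflation initial-uncertainty inflation factor (>= 1 typical).
#' @param sd_x0,sd_v0 nominal initial sd of displacements (m) and
#'   velocities (m/s).
#' @return an object of class `augmented_state` with `mean` (named
#'   10-vector), `cov` (10 x 10), `baseline`, `t`.
#' @export
ekf_init <- function(priors = ekf_priors(), baseline = bcm_params(),
                     inflation = 1, sd_x0 = 2e-4, sd_v0 = 0.05) {
  stopifnot(inherits(priors, "ekf_priors"), inflation > 0)
  th <- c(priors$p_sub$mean, priors$a_pgo$mean, priors$a_ct$mean,
          priors$a_ta$mean)
  params <- rules_to_params(activations(th[3], th[4]), baseline)
  params$A_pgo <- max(0, th[2])
  m <- c(rest_state(params), th)
  names(m) <- .ekf_names
  sds <- c(rep(sd_x0, 3), rep(sd_v0, 3),
           inflation * c(priors$p_sub$sd, priors$a_pgo$sd,
                         priors$a_ct$sd, priors$a_ta$sd))
  structure(list(mean = m, cov = diag(sds^2),
                 baseline = baseline, t = 0),
            class = "augmented_state")
}

# parameters implied by the augmented state's theta block
theta_params <- function(z, baseline) {
  a_ct <- min(1, max(0, z[9])); a_ta <- min(1, max(0, z[10]))
  p <- rules_to_params(activations(a_ct, a_ta), baseline)
  p$A_pgo <- max(0, z[8])
  p
}

# observation function: glottal area (m^2) from the augmented state
ekf_area_h <- function(z, baseline, symmetric = TRUE) {
  p <- theta_params(z, baseline)
  mult <- if (symmetric) 2 else 1
  max(0, mult * p$L_g * min(z[1], z[2])) + p$A_pgo
}

ekf_pcol <- function(z, baseline) {
  p <- theta_params(z, baseline)
  collision_pressure(list(x_u = z[1], x_l = z[2]), p)
}

reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' One extended Kalman filter step
#'
#' Predicts the augmented state through the body-cover dynamics (the
#' parameter block follows a random walk), then updates with the scalar
#' glottal area observation. A missing observation (`NA`) gives a pure
#' prediction step. The covariance is kept symmetric positive
#' semidefinite (Joseph-form update, symmetrization, eigenvalue floor).
#'
#' @param state an `augmented_state`.
#' @param area_obs glottal area observation (m^2), or `NA`.
#' @param dt observation step (s).
#' @param ctrl an [ekf_control()].
#' @param symmetric mirror condition of the observation model.
#' @return the updated `augmented_state`; attribute `"innovation"` holds
#'   the (normalized) innovation of the update.
#' @export
ekf_step <- function(state, area_obs, dt, ctrl = ekf_control(),
                     symmetric = TRUE) {
  stopifnot(inherits(state, "augmented_state"))
  z <- state$mean; P <- state$cov; base <- state$baseline
  nz <- length(z)

  # --- predict ----------------------------------------------------------
  hx <- c(rep(1e-6, 3), rep(1e-4, 3))   # FD steps for mechanical states
  h_psub <- 1.0; h_act <- 1e-3

  par_center <- params_to_vec(theta_params(z, base), symmetric)
  # rows: 1 center, 12 state perturbations, 2 psub, 4 activations
  a_ct0 <- min(1, max(0, z[9])); a_ta0 <- min(1, max(0, z[10]))
  act_pert <- list(
    ct_p = min(1, a_ct0 + h_act), ct_m = max(0, a_ct0 - h_act),
    ta_p = min(1, a_ta0 + h_act), ta_m = max(0, a_ta0 - h_act))
  par_act <- lapply(list(c(act_pert$ct_p, a_ta0), c(act_pert$ct_m, a_ta0),
                         c(a_ct0, act_pert$ta_p), c(a_ct0, act_pert$ta_m)),
                    function(a) {
                      p <- rules_to_params(activations(a[1], a[2]), base)
                      p$A_pgo <- max(0, z[8])
                      params_to_vec(p, symmetric)
                    })
  n_rows <- 1 + 12 + 2 + 4
  S0 <- matrix(rep(z[1:6], each = n_rows), n_rows, 6)
  PM <- matrix(rep(par_center, each = n_rows), n_rows, length(par_center))
  psub0 <- max(0, z[7])
  PS <- rep(psub0, n_rows)
  r <- 2
  for (i in 1:6) {
    S0[r, i] <- z[i] + hx[i]; S0[r + 1, i] <- z[i] - hx[i]
    r <- r + 2
  }
  PS[r] <- psub0 + h_psub; PS[r + 1] <- max(0, psub0 - h_psub)
  i_psub <- r; r <- r + 2
  for (j in 1:4) PM[r + j - 1, ] <- par_act[[j]]
  i_act <- r

  prop <- bcm_propagate_cpp(S0, PM, PS, dt, ctrl$n_sub)

  Fm <- diag(nz)
  for (i in 1:6) {
    Fm[1:6, i] <- (prop[2 * i, ] - prop[2 * i + 1, ]) / (2 * hx[i])
  }
  Fm[1:6, 7] <- (prop[i_psub, ] - prop[i_psub + 1, ]) /
    (PS[i_psub] - PS[i_psub + 1])
  dct <- act_pert$ct_p - act_pert$ct_m
  dta <- act_pert$ta_p - act_pert$ta_m
  if (dct > 0) Fm[1:6, 9] <- (prop[i_act, ] - prop[i_act + 1, ]) / dct
  if (dta > 0) Fm[1:6, 10] <- (prop[i_act + 2, ] - prop[i_act + 3, ]) / dta
  # column 8 (A_pgo): dynamics do not depend on the leak area

  z_pred <- z
  z_pred[1:6] <- prop[1, ]
  Q <- diag(c(rep(ctrl$sd_x^2, 3), rep(ctrl$sd_v^2, 3), ctrl$sd_psub^2,
              ctrl$sd_apgo^2, rep(ctrl$sd_act^2, 2)))
  P <- Fm %*% P %*% t(Fm) + Q

  innov_norm <- NA_real_
  innov_raw <- NA_real_
  if (!is.na(area_obs)) {
    h0 <- ekf_area_h(z_pred, base, symmetric)
    H <- matrix(0, 1, nz)
    hz <- c(rep(1e-6, 2), 0, 0, 0, 0, 0, 1e-9, 1e-3, 1e-3)
    for (i in c(1, 2, 8, 9, 10)) {
      zp <- z_pred; zm <- z_pred
      zp[i] <- zp[i] + hz[i]; zm[i] <- zm[i] - hz[i]
      H[1, i] <- (ekf_area_h(zp, base, symmetric) -
                    ekf_area_h(zm, base, symmetric)) / (zp[i] - zm[i])
    }
    S <- as.numeric(H %*% P %*% t(H)) + ctrl$r_obs
    K <- (P %*% t(H)) / S
    innov <- area_obs - h0
    innov_raw <- innov
    innov_norm <- innov / sqrt(S)
    z_pred <- z_pred + as.numeric(K) * innov
    IKH <- diag(nz) - K %*% H
    P <- IKH %*% P %*% t(IKH) + K %*% t(K) * ctrl$r_obs
  }

  # physical range constraints; the displacement/velocity clamps are
  # safeguards against unphysical excursions of the linearized update
  # (centimeter-scale penetrations would blow up the collision spring)
  z_pred[1:3] <- pmin(5e-3, pmax(-2e-3, z_pred[1:3]))
  z_pred[4:6] <- pmin(20, pmax(-20, z_pred[4:6]))
  z_pred[7] <- max(0, z_pred[7])
  z_pred[8] <- max(0, z_pred[8])
  z_pred[9] <- reflect01(z_pred[9])
  z_pred[10] <- reflect01(z_pred[10])
  if (any(!is.finite(z_pred)) || any(!is.finite(P)))
    stop("numerical error: non-finite filter state at t = ",
         round(state$t + dt, 5), " s", call. = FALSE)
  P <- (P + t(P)) / 2
  dP <- diag(P)
  if (any(dP < 0)) {
    ev <- eigen(P, symmetric = TRUE)
    P <- ev$vectors %*% diag(pmax(ev$values, 1e-20)) %*% t(ev$vectors)
    P <- (P + t(P)) / 2
  }
  out <- structure(list(mean = z_pred, cov = P, baseline = base,
                        t = state$t + dt),
                   class = "augmented_state")
  attr(out, "innovation") <- innov_norm
  attr(out, "innovation_raw") <- innov_raw
  out
}

#' Case-I estimation from the glottal area waveform
#'
#' Runs the extended Kalman filter over a calibrated glottal area
#' waveform (the only observation signal) and returns time-varying
#' posterior means with 95% confidence bands (mean +/- 1.96 posterior sd)
#' for subglottal pressure, posterior glottal opening area, the
#' cricothyroid and thyroarytenoid activations, and the vocal fold
#' collision pressure (delta-method first-order propagation through the
#' collision law). Persistent innovation failures flag divergence and
#' return the partial series.
#'
#' @param area_mm2 calibrated glottal area waveform (mm^2), >= 100 ms.
#' @param fs_video frame rate (Hz), typically 2000.
#' @param priors an [ekf_priors()].
#' @param baseline passive [bcm_params()].
#' @param ctrl an [ekf_control()].
#' @param inflation initial-uncertainty inflation (see [ekf_init()]).
#' @param symmetric mirror condition.
#' @return an object of class `posterior_series`: data frame with `t` and
#'   mean/lower/upper columns for `psub` (cm H2O), `apgo` (mm^2), `act`,
#'   `ata`, `pcol` (cm H2O), plus `area_obs_mm2` and `area_pred_mm2`.
#'   Attribute `"diagnostics"` holds innovation statistics and the
#'   divergence flag.
#' @export
run_case1 <- function(area_mm2, fs_video = 2000, priors = ekf_priors(),
                      baseline = bcm_params(), ctrl = ekf_control(),
                      inflation = 10, symmetric = TRUE) {
  stopifnot(is.numeric(area_mm2))
  n <- length(area_mm2)
  if (n < 0.1 * fs_video)
    stop("need at least 100 ms of area data", call. = FALSE)
  dt <- 1 / fs_video
  st <- ekf_init(priors, baseline, inflation = inflation)
  area_m2 <- area_mm2 * 1e-6

  cols <- c("psub", "apgo", "act", "ata", "pcol")
  M <- matrix(NA_real_, n, 2 * length(cols) + 2)
  innovs <- numeric(n)
  diverged <- FALSE
  bad_run <- 0
  h_pc <- c(1e-6, 1e-6, 1e-3, 1e-3)   # FD steps for the p_col gradient

  pcol_fine <- numeric(n * ctrl$n_sub)
  for (i in seq_len(n)) {
    # substep-resolved collision pressure along the predicted mean
    # trajectory (the 2000 Hz grid undersamples the impulsive peak)
    z_prev <- st$mean
    path <- bcm_path_cpp(z_prev[1:6],
                         params_to_vec(theta_params(z_prev, baseline),
                                       symmetric),
                         max(0, z_prev[7]), dt, ctrl$n_sub)
    pcol_fine[((i - 1) * ctrl$n_sub + 1):(i * ctrl$n_sub)] <- path$p_col
    st <- ekf_step(st, area_m2[i], dt, ctrl, symmetric)
    innovs[i] <- attr(st, "innovation")
    z <- st$mean; P <- st$cov
    # delta-method mean/sd of the collision pressure
    pc0 <- ekf_pcol(z, baseline)
    g <- numeric(10)
    idx <- c(1, 2, 9, 10)
    for (k in seq_along(idx)) {
      zp <- z; zm <- z
      zp[idx[k]] <- zp[idx[k]] + h_pc[k]
      zm[idx[k]] <- zm[idx[k]] - h_pc[k]
      g[idx[k]] <- (ekf_pcol(zp, baseline) - ekf_pcol(zm, baseline)) /
        (zp[idx[k]] - zm[idx[k]])
    }
    v_pc <- max(0, as.numeric(t(g) %*% P %*% g))
    sds <- sqrt(pmax(0, diag(P)))
    M[i, ] <- c(pa_to_cmh2o(z[7]), pa_to_cmh2o(1.96 * sds[7]),
                z[8] * 1e6, 1.96 * sds[8] * 1e6,
                z[9], 1.96 * sds[9],
                z[10], 1.96 * sds[10],
                pa_to_cmh2o(pc0), pa_to_cmh2o(1.96 * sqrt(v_pc)),
                area_mm2[i],
                ekf_area_h(z, baseline, symmetric) * 1e6)
    if (is.finite(innovs[i]) && abs(innovs[i]) > 8) bad_run <- bad_run + 1
    else bad_run <- 0
    if (bad_run > 0.05 * fs_video) {   # > 100 ms of persistent failure
      diverged <- TRUE
      warning("EKF divergence flagged at t = ", round(i * dt, 4),
              " s; returning partial output", call. = FALSE)
      M <- M[1:i, , drop = FALSE]
      innovs <- innovs[1:i]
      pcol_fine <- pcol_fine[1:(i * ctrl$n_sub)]
      break
    }
  }
  nn <- nrow(M)
  out <- data.frame(t = (seq_len(nn) - 1) * dt)
  for (j in seq_along(cols)) {
    mu <- M[, 2 * j - 1]; hw <- M[, 2 * j]
    out[[paste0(cols[j], "_mean")]] <- mu
    out[[paste0(cols[j], "_lo")]] <- mu - hw
    out[[paste0(cols[j], "_hi")]] <- mu + hw
  }
  out$area_obs_mm2 <- M[, 11]
  out$area_pred_mm2 <- M[, 12]
  class(out) <- c("posterior_series", "data.frame")
  attr(out, "pcol_fine") <- list(p_col_cmh2o = pa_to_cmh2o(pcol_fine),
                                 fs = fs_video * ctrl$n_sub)
  attr(out, "diagnostics") <- list(
    innovation_rms = sqrt(mean(innovs^2, na.rm = TRUE)),
    diverged = diverged,
    final_state = st)
  out
}

#' @export
print.posterior_series <- function(x, ...) {
  post <- x$t >= 0.1
  if (!any(post)) post <- rep(TRUE, nrow(x))
  cat(sprintf("Case-I posterior series: %.3f s (%d samples)\n", max(x$t),
              nrow(x)))
  cat(sprintf("  post-transient P_sub %.2f cm H2O [%.2f, %.2f]\n",
              mean(x$psub_mean[post]), mean(x$psub_lo[post]),
              mean(x$psub_hi[post])))
  cat(sprintf("  a_CT %.2f, a_TA %.2f, PGO %.2f mm^2\n",
              mean(x$act_mean[post]), mean(x$ata_mean[post]),
              mean(x$apgo_mean[post])))
  invisible(x)
}

#' Per-cycle peaks of the estimated collision pressure
#'
#' Extracts per-cycle peak collision pressures from the substep-resolved
#' collision-pressure track of a [run_case1()] posterior series: one peak
#' per contiguous contact episode after `t_min`.
#'
#' @param ps a `posterior_series`.
#' @param t_min discard the initial transient before this time (s).
#' @return a `cycle_peaks` object (times in the posterior time base).
#' @export
posterior_collision_peaks <- function(ps, t_min = 0.1) {
  fine <- attr(ps, "pcol_fine")
  if (is.null(fine)) stop("posterior series lacks the fine collision track",
                          call. = FALSE)
  x <- fine$p_col_cmh2o
  i0 <- max(1L, floor(t_min * fine$fs) + 1L)
  ep <- contact_episode_peaks(x[i0:length(x)], fine$fs)
  if (length(ep$peaks) == 0)
    stop("no collision episodes in the estimated series", call. = FALSE)
  structure(list(cycle_times = ep$times + t_min, peaks = ep$peaks,
                 f0_mean = if (length(ep$times) > 1)
                   1 / mean(diff(ep$times)) else NA_real_),
            class = "cycle_peaks")
}

#' Spatial calibration of a pixel-coded area waveform
#'
#' The known probe-tip width serves as an imaging ruler: the scale is
#' `probe_width_mm / probe_width_px` (mm per pixel), and areas scale with
#' its square.
#'
#' @param area_px area series in pixel^2.
#' @param probe_width_px apparent probe-tip width in pixels (> 0).
#' @param probe_width_mm physical probe-tip width (mm); 4.4 mm.
#' @return area in mm^2, with attribute `scale_mm_per_px`.
#' @export
spatial_calibrate <- function(area_px, probe_width_px, probe_width_mm = 4.4) {
  if (!is.finite(probe_width_px) || probe_width_px <= 0)
    stop("probe width in pixels must be positive", call. = FALSE)
  scale <- probe_width_mm / probe_width_px
  structure(area_px * scale^2, scale_mm_per_px = scale)
}

#' Correct the glottal area for probe occlusion
#'
#' Part of the glottal area is visually blocked by the probe; under a
#' constant-fraction occlusion model the full area is the observed area
#' divided by `1 - fraction`.
#'
#' @param area observed area series.
#' @param fraction occluded fraction in `[0, 1)`.
#' @return corrected area.
#' @export
occlusion_correct <- function(area, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1)
    stop("occlusion fraction must lie in [0, 1)", call. = FALSE)
  area / (1 - fraction)
}
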