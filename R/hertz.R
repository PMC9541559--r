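# Contact pressure analysis: parabolic edge representation, Kalman-
# filtered edge kinematics, lumped-mass estimation of the non-physical
# overlap of two colliding cylinders, and Hertzian conversion of overlap
# to peak contact pressure. Point estimates only.

#' Hertzian contact analysis configuration
#'
#' @param E_eff effective Young's modulus of the vocal fold tissue (Pa).
#' @param nu Poisson ratio (0.5 = incompressible).
#' @param R_eff effective radius of the contact cylinder (m), of the
#'   order of the cover-mass thickness.
#' @param contact_plane medial position of the rigid counter-surface (m)
#'   in edge-displacement coordinates; contact when the edge drops to or
#'   below this plane.
#' @param L_contact axial length of the colliding tissue (m); the
#'   mid-membranous portion of the fold.
#' @param m_eff lumped mass of the cover-layer tissue engaged in the
#'   collision (kg); together with the linearized cylinder-contact
#'   stiffness it sets the contact time-scale used to extrapolate the
#'   overlap through the occluded interval. The default corresponds to a
#'   tissue ribbon of density 1040 kg/m^3, length `L_contact`, and
#'   roughly 0.65 mm x 0.65 mm cross-section.
#' @param T_plate inferior-superior height (m) of the loaded contact
#'   surface over which the Hertz line load is spread when reporting a
#'   plate-referenced (sensor-equivalent) contact pressure.
#' @param anchor_a,anchor_p optional anterior/posterior anchor points
#'   (`c(s, x)` pairs) for the edge parabola.
#' @return an object of class `hertz_config`.
#' @export
hertz_config <- function(E_eff = 24750, nu = 0.5, R_eff = 2e-3,
                         contact_plane = 0, L_contact = 8e-3,
                         m_eff = 3.5e-6, T_plate = 2.5e-3,
                         anchor_a = NULL, anchor_p = NULL) {
  stopifnot(E_eff > 0, nu > 0, nu <= 0.5, R_eff > 0, L_contact > 0,
            m_eff > 0, T_plate > 0)
  structure(list(E_eff = E_eff, nu = nu, R_eff = R_eff,
                 contact_plane = contact_plane, L_contact = L_contact,
                 m_eff = m_eff, T_plate = T_plate,
                 anchor_a = anchor_a, anchor_p = anchor_p),
            class = "hertz_config")
}

e_star <- function(cfg) cfg$E_eff / (1 - cfg$nu^2)

#' Fit a parabola to vocal fold edge points
#'
#' The vibrating tissue of a vocal fold edge is represented by a parabola
#' constrained to pass through the anterior and posterior anchor points;
#' the single remaining curvature coefficient is fitted by least squares
#' to the edge points. The apex (extremal medial excursion) is the
#' kinematic observable.
#'
#' @param edge_points data frame with columns `s` (axial position) and
#'   `x` (medial position); at least 3 points.
#' @param anchor_a,anchor_p anchors as `c(s, x)`; must have distinct `s`.
#' @return list with `coef` (`c(a, b, c)` of `x = a s^2 + b s + c`),
#'   `apex_s`, `apex_x`, and `residual_rms`.
#' @export
fit_edge_parabola <- function(edge_points, anchor_a, anchor_p) {
  stopifnot(is.data.frame(edge_points),
            all(c("s", "x") %in% names(edge_points)),
            nrow(edge_points) >= 3)
  s_a <- anchor_a[1]; x_a <- anchor_a[2]
  s_p <- anchor_p[1]; x_p <- anchor_p[2]
  if (abs(s_a - s_p) < .Machine$double.eps^0.5)
    stop("degenerate anchors: anterior and posterior coincide",
         call. = FALSE)
  s <- edge_points$s; x <- edge_points$x
  # line through the anchors + a * (s - s_a)(s - s_p)
  line <- x_a + (x_p - x_a) * (s - s_a) / (s_p - s_a)
  basis <- (s - s_a) * (s - s_p)
  if (sum(basis^2) < .Machine$double.eps)
    stop("edge points coincide with the anchors: curvature undetermined",
         call. = FALSE)
  a <- sum((x - line) * basis) / sum(basis^2)
  b <- (x_p - x_a) / (s_p - s_a) - a * (s_a + s_p)
  c0 <- x_a - a * s_a^2 - b * s_a
  apex_s <- if (abs(a) > .Machine$double.eps) -b / (2 * a)
            else 0.5 * (s_a + s_p)
  apex_x <- a * apex_s^2 + b * apex_s + c0
  fitted <- a * s^2 + b * s + c0
  list(coef = c(a = a, b = b, c = c0), apex_s = apex_s, apex_x = apex_x,
       residual_rms = sqrt(mean((x - fitted)^2)))
}

#' Kalman-filtered edge kinematics
#'
#' Constant-acceleration kinematic Kalman filter over the apex
#' displacement observations, returning smoothed displacement and
#' velocity with per-step covariance.
#'
#' @param obs apex displacement observations (m).
#' @param fs_video frame rate (Hz).
#' @param process_noise white jerk spectral density driving the
#'   constant-acceleration model.
#' @param obs_noise observation variance (m^2); 0 makes the filter track
#'   the observations exactly.
#' @return an object of class `edge_track`: data frame `t`, `x`, `v`,
#'   `acc`, `var_x`, `var_v`, plus the covariance array in attribute
#'   `"P"`.
#' @export
track_edge_kalman <- function(obs, fs_video, process_noise = 1e8,
                              obs_noise = 1e-10) {
  stopifnot(is.numeric(obs), length(obs) >= 10)
  if (any(!is.finite(obs))) stop("non-finite edge observation", call. = FALSE)
  dt <- 1 / fs_video
  F_ <- matrix(c(1, 0, 0, dt, 1, 0, dt^2 / 2, dt, 1), 3, 3)
  q <- process_noise
  Q <- q * matrix(c(dt^5 / 20, dt^4 / 8, dt^3 / 6,
                    dt^4 / 8,  dt^3 / 3, dt^2 / 2,
                    dt^3 / 6,  dt^2 / 2, dt), 3, 3)
  H <- matrix(c(1, 0, 0), 1, 3)
  m <- c(obs[1], 0, 0)
  P <- diag(c((10 * sd(obs) + 1e-12)^2, 1e2, 1e6))
  n <- length(obs)
  out <- matrix(0, n, 3)
  Parr <- array(0, c(n, 3, 3))
  for (i in seq_len(n)) {
    if (i > 1) {
      m <- as.numeric(F_ %*% m)
      P <- F_ %*% P %*% t(F_) + Q
    }
    S <- as.numeric(H %*% P %*% t(H)) + obs_noise
    K <- (P %*% t(H)) / S
    m <- m + as.numeric(K) * (obs[i] - m[1])
    IKH <- diag(3) - K %*% H
    P <- IKH %*% P %*% t(IKH) + K %*% t(K) * obs_noise
    P <- (P + t(P)) / 2
    out[i, ] <- m
    Parr[i, , ] <- P
  }
  df <- data.frame(t = (seq_len(n) - 1) * dt, x = out[, 1], v = out[, 2],
                   acc = out[, 3], var_x = Parr[, 1, 1], var_v = Parr[, 2, 2])
  attr(df, "P") <- Parr
  class(df) <- c("edge_track", "data.frame")
  df
}

#' Estimate the non-physical contact overlap
#'
#' Overlap of the undeformed edge trajectory past the rigid contact
#' plane. Where the edge is directly observed past the plane the overlap
#' is the geometric penetration. Where the edge is occluded (the glottis
#' is closed and the edge position is unobservable), a lumped-mass
#' contact oscillator — mass `m_eff` against the linearized
#' cylinder-contact stiffness `(pi/2) E* L_contact` — continues the
#' motion from the entry velocity: `delta(tau) = (v_in / omega) sin(omega
#' tau)`.
#'
#' @param track an [track_edge_kalman()] edge track (or data frame with
#'   `t`, `x`, `v`).
#' @param cfg a [hertz_config()].
#' @param occluded optional logical vector marking frames where the edge
#'   is not observable; default none.
#' @return numeric overlap series `delta` (m, `>= 0`) with attribute
#'   `episodes`: data frame of per-contact-episode `t_start`, `v_in`,
#'   `delta_max`.
#' @export
estimate_overlap <- function(track, cfg, occluded = NULL) {
  stopifnot(inherits(cfg, "hertz_config"))
  x <- track$x; v <- track$v; t <- track$t
  n <- length(x)
  if (is.null(occluded)) occluded <- rep(FALSE, n)
  stopifnot(length(occluded) == n)
  delta <- pmax(0, cfg$contact_plane - x)
  omega <- sqrt(pi / 2 * e_star(cfg) * cfg$L_contact / cfg$m_eff)
  # replace occluded stretches by the lumped-mass extrapolation
  r <- rle(occluded)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  eps_rows <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    i_in <- max(1, i0 - 1)
    v_in <- max(0, -v[i_in])           # approach speed toward the plane
    tau <- t[i0:i1] - t[i_in]
    delta[i0:i1] <- ifelse(tau <= pi / omega,
                           (v_in / omega) * sin(omega * pmin(tau, pi / omega)),
                           0)
    eps_rows[[length(eps_rows) + 1]] <-
      data.frame(t_start = t[i0], v_in = v_in, delta_max = v_in / omega)
  }
  # direct-penetration episodes (observed crossings)
  if (!any(occluded)) {
    rr <- rle(delta > 0)
    e2 <- cumsum(rr$lengths); s2 <- e2 - rr$lengths + 1
    for (j in which(rr$values)) {
      idx <- s2[j]:e2[j]
      i_in <- max(1, s2[j] - 1)
      eps_rows[[length(eps_rows) + 1]] <-
        data.frame(t_start = t[s2[j]], v_in = max(0, -v[i_in]),
                   delta_max = max(delta[idx]))
    }
  }
  episodes <- if (length(eps_rows)) do.call(rbind, eps_rows)
              else data.frame(t_start = numeric(0), v_in = numeric(0),
                              delta_max = numeric(0))
  episodes <- episodes[order(episodes$t_start), , drop = FALSE]
  attr(delta, "episodes") <- episodes
  delta
}

#' Hertzian peak contact pressure from overlap
#'
#' Peak pressure at the center of the contact strip for a Hertzian
#' contact between a cylinder of radius `R_eff` and a rigid plane. With
#' the plane-strain modulus `E* = E_eff / (1 - nu^2)`, geometric
#' interference gives the contact half-width `b = sqrt(2 R delta)`, the
#' Hertz half-width relation gives the line load `F' = (pi/2) E* delta`,
#' and the peak of the semi-elliptic pressure profile is
#' `p0 = 2 F' / (pi b) = E* sqrt(delta / (2 R))`.
#'
#' @param delta_max overlap (m); vectorized, `>= 0`.
#' @param cfg a [hertz_config()].
#' @return peak contact pressure in cm H2O; 0 at zero overlap, strictly
#'   increasing in `delta_max` and `E_eff`, decreasing in `R_eff`.
#' @export
hertz_peak_pressure <- function(delta_max, cfg) {
  stopifnot(inherits(cfg, "hertz_config"))
  if (any(delta_max < 0)) stop("negative overlap", call. = FALSE)
  pa_to_cmh2o(e_star(cfg) * sqrt(delta_max / (2 * cfg$R_eff)))
}

#' Contact pressure analysis of a glottal area waveform
#'
#' End-to-end pipeline: the mid-membranous edge displacement is derived
#' from the calibrated glottal area (or taken from a supplied edge
#' track), Kalman filtered, extrapolated through the occluded contact
#' intervals with the lumped-mass contact model, and converted per cycle
#' to a peak collision pressure by the Hertzian relation. Point estimates
#' only; no confidence intervals.
#'
#' @param area_mm2 calibrated glottal area waveform (mm^2).
#' @param fs_video frame rate (Hz).
#' @param cfg a [hertz_config()].
#' @param L_g membranous fold length (m) used to convert area to edge
#'   displacement.
#' @param symmetric if `TRUE` both folds move (half-gap = area / (2 L));
#'   `FALSE` for the hemilarynx configuration.
#' @param track optional pre-computed edge track; bypasses the
#'   area-to-edge conversion.
#' @param closure_frac closure detection threshold as a fraction of the
#'   95th percentile of the membranous area.
#' @param closure_min_frames minimum number of consecutive sub-threshold
#'   frames that counts as a contact episode; shorter dips are smooth
#'   passages through the area minimum of a non-colliding cycle.
#' @param warmup_s initial interval (s) excluded from the episode list
#'   while the edge-tracking filter settles.
#' @return an object of class `contact_estimate`: data frame
#'   `cycle_times`, `delta_max` (m), `p_est` (cm H2O, plate-referenced:
#'   Hertz line load `(pi/2) E* delta` spread over the `T_plate` plate
#'   height, the quantity a flush-mounted sensor reports), `p_peak`
#'   (cm H2O, [hertz_peak_pressure()] at the contact-strip center), and
#'   `v_in` (m/s).
#' @export
run_cpa <- function(area_mm2, fs_video, cfg = hertz_config(),
                    L_g = 0.016, symmetric = TRUE, track = NULL,
                    closure_frac = 0.05, closure_min_frames = 3L,
                    warmup_s = 0.02) {
  stopifnot(is.numeric(area_mm2), all(is.finite(area_mm2)))
  area_m2 <- area_mm2 * 1e-6
  leak <- min(area_m2)
  memb <- pmax(0, area_m2 - leak)
  mult <- if (symmetric) 2 else 1
  if (is.null(track)) {
    x_obs <- memb / (mult * L_g)       # mid-membranous half-gap (m)
    track <- track_edge_kalman(x_obs, fs_video)
  }
  occluded <- memb < closure_frac * quantile(memb, 0.95)
  # drop sub-threshold dips too short to be true closed phases
  r <- rle(occluded)
  r$values[r$values & r$lengths < closure_min_frames] <- FALSE
  occluded <- inverse.rle(r)
  delta <- estimate_overlap(track, cfg, occluded = occluded)
  ep <- attr(delta, "episodes")
  ep <- ep[ep$t_start >= warmup_s & ep$delta_max > 0, , drop = FALSE]
  if (nrow(ep) > 0) {
    line_load <- pi / 2 * e_star(cfg) * ep$delta_max   # N/m
    est <- data.frame(cycle_times = ep$t_start,
                      delta_max = ep$delta_max,
                      p_est = pa_to_cmh2o(line_load / cfg$T_plate),
                      p_peak = hertz_peak_pressure(ep$delta_max, cfg),
                      v_in = ep$v_in)
  } else {
    # no contact anywhere: report zero estimates at the area minima cycles
    f0 <- estimate_f0(area_mm2, fs_video)
    if (is.na(f0)) {
      est <- data.frame(cycle_times = numeric(0), delta_max = numeric(0),
                        p_est = numeric(0), p_peak = numeric(0),
                        v_in = numeric(0))
    } else {
      cyc <- detect_cycles(max(area_mm2) - area_mm2, fs_video)
      est <- data.frame(cycle_times = cyc, delta_max = 0, p_est = 0,
                        p_peak = 0, v_in = 0)
    }
  }
  structure(est, class = c("contact_estimate", "data.frame"),
            config = cfg)
}
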