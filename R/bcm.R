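# Three-mass body-cover vocal fold model: two superficial cover masses
# (upper/lower) and one deep body mass per fold, coupled by springs and
# dampers, driven by quasi-steady Bernoulli jet pressure on the lower mass.
# Only one fold is simulated; the contralateral side is a mirror image
# (symmetric condition) or a rigid plane (hemilarynx configuration).

.bcm_par_order <- c(
  "m_u", "m_l", "m_b", "k_u", "k_l", "k_b", "k_c", "d_u", "d_l", "d_b",
  "k_col", "eta_col", "L_g", "T_u", "T_l", "x0_u", "x0_l", "x0_b", "A_pgo",
  "mult"
)

#' Body-cover model parameters
#'
#' Constructs the physical parameter set of the three-mass body-cover
#' vocal fold model. Defaults are generic adult-male values chosen so that
#' the passive fold oscillates near 95 Hz and, under mid-range muscle
#' activation ([rules_to_params()] at `a_ct = a_ta = 0.5`), sustains
#' oscillation near 125 Hz at a subglottal pressure of 9 cm H2O with
#' per-cycle peak collision pressures of the same order as the subglottal
#' pressure.
#'
#' Displacements are medial positions of the mass faces relative to the
#' glottal midline: positive is open, zero is the contact plane. The rest
#' posture is slightly convergent (lower margin more open than the upper),
#' which is required for aerodynamic energy transfer into the oscillation.
#'
#' @param m_u,m_l,m_b masses of the upper cover, lower cover, and body
#'   elements (kg).
#' @param k_u,k_l,k_b spring stiffnesses anchoring each mass (N/m); cover
#'   springs attach to the body mass, the body spring to the rigid wall.
#' @param k_c cover coupling stiffness between upper and lower mass (N/m).
#' @param d_u,d_l,d_b damping coefficients (N s/m); defaults give
#'   damping ratios of 0.6, 0.1, and 0.15.
#' @param k_col collision spring stiffness (N/m), engaged one-sidedly when
#'   a cover mass crosses the contact plane.
#' @param eta_col dimensionless cubic hardening coefficient of the
#'   collision spring (penetration normalized by mass thickness).
#' @param L_g membranous vocal fold length (m).
#' @param T_u,T_l thicknesses of the upper and lower cover masses (m).
#' @param x0_u,x0_l,x0_b rest displacements (m).
#' @param A_pgo posterior glottal opening area (m^2), a constant leak added
#'   to the membranous glottal area.
#' @return an object of class `bcm_params` (a validated named list).
#' @seealso [rules_to_params()], [bcm_simulate()]
#' @export
bcm_params <- function(m_u = 2.5e-5, m_l = 1.25e-4, m_b = 2.0e-4,
                       k_u = 5.8, k_l = 58, k_b = 385, k_c = 18,
                       d_u = NULL, d_l = NULL, d_b = NULL,
                       k_col = 3.6 * k_l, eta_col = 1.0,
                       L_g = 0.016, T_u = 0.002, T_l = 0.003,
                       x0_u = 1.5e-4, x0_l = 3.0e-4, x0_b = 3.0e-3,
                       A_pgo = 2.0e-6) {
  # default dampings correspond to damping ratios 0.6 / 0.1 / 0.15
  if (is.null(d_u)) d_u <- 2 * 0.6 * sqrt(max(k_u * m_u, 0))
  if (is.null(d_l)) d_l <- 2 * 0.1 * sqrt(max(k_l * m_l, 0))
  if (is.null(d_b)) d_b <- 2 * 0.15 * sqrt(max(k_b * m_b, 0))
  p <- list(m_u = m_u, m_l = m_l, m_b = m_b, k_u = k_u, k_l = k_l,
            k_b = k_b, k_c = k_c, d_u = d_u, d_l = d_l, d_b = d_b,
            k_col = k_col, eta_col = eta_col, L_g = L_g, T_u = T_u,
            T_l = T_l, x0_u = x0_u, x0_l = x0_l, x0_b = x0_b,
            A_pgo = A_pgo)
  validate_bcm_params(p)
  structure(p, class = "bcm_params")
}

validate_bcm_params <- function(p) {
  pos <- c("m_u", "m_l", "m_b", "k_u", "k_l", "k_b", "k_c", "d_u", "d_l",
           "d_b", "k_col", "L_g", "T_u", "T_l")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("bcm_params: '", nm, "' must be a positive finite scalar",
           call. = FALSE)
    }
  }
  if (!is.finite(p$A_pgo) || p$A_pgo < 0)
    stop("bcm_params: 'A_pgo' must be >= 0", call. = FALSE)
  if (!is.finite(p$eta_col) || p$eta_col < 0)
    stop("bcm_params: 'eta_col' must be >= 0", call. = FALSE)
  for (nm in c("x0_u", "x0_l", "x0_b")) {
    if (!is.finite(p[[nm]])) stop("bcm_params: '", nm, "' must be finite",
                                  call. = FALSE)
  }
  invisible(p)
}

#' @export
print.bcm_params <- function(x, ...) {
  cat("Body-cover model parameters\n")
  cat(sprintf("  masses (mg):      m_u %.3g, m_l %.3g, m_b %.3g\n",
              x$m_u * 1e6, x$m_l * 1e6, x$m_b * 1e6))
  cat(sprintf("  stiffness (N/m):  k_u %.3g, k_l %.3g, k_b %.3g, k_c %.3g, k_col %.3g\n",
              x$k_u, x$k_l, x$k_b, x$k_c, x$k_col))
  cat(sprintf("  geometry (mm):    L_g %.3g, T_u %.3g, T_l %.3g, rest gaps %.3g/%.3g\n",
              x$L_g * 1e3, x$T_u * 1e3, x$T_l * 1e3, x$x0_u * 1e3, x$x0_l * 1e3))
  cat(sprintf("  PGO area (mm^2):  %.3g\n", x$A_pgo * 1e6))
  invisible(x)
}

#' Normalized laryngeal muscle activations
#'
#' @param a_ct normalized cricothyroid activation in \[0, 1\]; raises
#'   cover fiber tension and hence pitch.
#' @param a_ta normalized thyroarytenoid activation in \[0, 1\]; shortens
#'   the fold and stiffens the body layer.
#' @return an object of class `activations`.
#' @export
activations <- function(a_ct, a_ta) {
  if (!is.numeric(a_ct) || !is.numeric(a_ta) || length(a_ct) != 1 ||
      length(a_ta) != 1 || !is.finite(a_ct) || !is.finite(a_ta))
    stop("activations must be finite scalars", call. = FALSE)
  if (a_ct < 0 || a_ct > 1 || a_ta < 0 || a_ta > 1)
    stop("activations must lie in [0, 1]", call. = FALSE)
  structure(list(a_ct = a_ct, a_ta = a_ta), class = "activations")
}

#' Map muscle activations to body-cover model parameters
#'
#' Implements an activation-to-parameter rule set in the spirit of the
#' standard rules for low-dimensional vocal fold models: cricothyroid
#' activation elongates the fold and raises cover fiber tension,
#' thyroarytenoid activation shortens the fold and stiffens the body
#' layer. The elongation strain is `eps = G (R a_ct - a_ta)` with
#' `G = 0.2`, `R = 3`. Cover stiffnesses (including the collision spring)
#' scale as `exp(2.2 eps)`, the body stiffness as `1 + 3 a_ta`, dampings by
#' the square root of the corresponding stiffness ratio (constant damping
#' ratios), length as `1 + eps`, and thicknesses as `1 / (1 + eps)`
#' (tissue volume conservation; masses unchanged). At
#' `a_ct = a_ta = 0` the baseline passive parameters are returned
#' unchanged.
#'
#' @param act an [activations()] object (or numeric length-2 vector
#'   `c(a_ct, a_ta)`).
#' @param baseline passive baseline parameters ([bcm_params()]).
#' @return a `bcm_params` object.
#' @export
rules_to_params <- function(act, baseline = bcm_params()) {
  if (is.numeric(act) && length(act) == 2) act <- activations(act[1], act[2])
  if (!inherits(act, "activations"))
    stop("'act' must be an activations object", call. = FALSE)
  stopifnot(inherits(baseline, "bcm_params"))
  G <- 0.2; R <- 3.0
  eps <- G * (R * act$a_ct - act$a_ta)
  if (1 + eps <= 0.2)
    stop("activation-induced strain out of admissible range", call. = FALSE)
  q_cov <- exp(2.2 * eps)        # cover fiber-tension multiplier
  q_bod <- 1 + 3 * act$a_ta    # active body stiffening
  p <- unclass(baseline)
  p$k_u <- baseline$k_u * q_cov
  p$k_l <- baseline$k_l * q_cov
  p$k_c <- baseline$k_c * q_cov
  p$k_col <- baseline$k_col * q_cov
  p$k_b <- baseline$k_b * q_bod
  p$d_u <- baseline$d_u * sqrt(q_cov)
  p$d_l <- baseline$d_l * sqrt(q_cov)
  p$d_b <- baseline$d_b * sqrt(q_bod)
  p$L_g <- baseline$L_g * (1 + eps)
  p$T_u <- baseline$T_u / (1 + eps)
  p$T_l <- baseline$T_l / (1 + eps)
  validate_bcm_params(p)
  structure(p, class = "bcm_params")
}

#' Simulation configuration
#'
#' @param p_sub subglottal pressure (Pa).
#' @param duration simulated time (s).
#' @param fs_out output sample rate (Hz).
#' @param solver_step fixed Runge-Kutta step (s); must divide `1/fs_out`.
#' @param seed optional integer recorded with the output (the simulator
#'   itself is deterministic and draws no random numbers).
#' @param symmetric if `TRUE` the single simulated fold is mirrored, so the
#'   membranous glottal width is twice the fold displacement; if `FALSE`
#'   the contralateral surface is a rigid plane at the midline (hemilarynx
#'   configuration) and the width equals the displacement.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(p_sub = cmh2o_to_pa(9), duration = 0.5,
                       fs_out = 8000, solver_step = 1 / 80000,
                       seed = NULL, symmetric = TRUE) {
  if (!is.finite(p_sub) || p_sub < 0) stop("p_sub must be >= 0", call. = FALSE)
  if (!is.finite(fs_out) || fs_out <= 0) stop("fs_out must be > 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (!is.finite(solver_step) || solver_step <= 0 ||
      solver_step > 1 / fs_out + 1e-15)
    stop("solver_step must be positive and <= 1/fs_out", call. = FALSE)
  decim <- 1 / (fs_out * solver_step)
  if (abs(decim - round(decim)) > 1e-8)
    stop("solver_step must divide 1/fs_out", call. = FALSE)
  structure(list(p_sub = p_sub, duration = duration, fs_out = fs_out,
                 solver_step = solver_step, seed = seed,
                 symmetric = isTRUE(symmetric), decim = as.integer(round(decim))),
            class = "sim_config")
}

params_to_vec <- function(params, symmetric = TRUE) {
  v <- unlist(params[setdiff(.bcm_par_order, "mult")])
  c(v, mult = if (symmetric) 2 else 1)[.bcm_par_order]
}

rest_state <- function(params) {
  c(x_u = params$x0_u, x_l = params$x0_l, x_b = params$x0_b,
    v_u = 0, v_l = 0, v_b = 0)
}

#' Simulate the body-cover model
#'
#' Integrates the three-mass system with a fixed-step 4th-order
#' Runge-Kutta scheme from the rest posture, recording the state, the
#' glottal area, the collision pressure, and the driving (jet) pressure at
#' `fs_out`. The simulation is fully deterministic: identical parameters
#' and configuration give bit-identical output.
#'
#' @param params a [bcm_params()] object.
#' @param cfg a [sim_config()] object.
#' @return an object of class `bcm_sim`: a list with `t` (s), `states`
#'   (data frame `x_u, x_l, x_b, v_u, v_l, v_b`), `area` (m^2), `p_col`
#'   (Pa, nonzero only during contact), `p_drive` (Pa), `fs`, and the
#'   inputs.
#' @export
bcm_simulate <- function(params, cfg = sim_config()) {
  stopifnot(inherits(params, "bcm_params"), inherits(cfg, "sim_config"))
  n_out <- as.integer(round(cfg$duration * cfg$fs_out))
  pv <- params_to_vec(params, cfg$symmetric)
  raw <- bcm_simulate_cpp(pv, cfg$p_sub, n_out, cfg$solver_step, cfg$decim,
                          rest_state(params))
  states <- as.data.frame(raw$states)
  names(states) <- c("x_u", "x_l", "x_b", "v_u", "v_l", "v_b")
  structure(list(t = (seq_len(n_out) - 1) / cfg$fs_out,
                 states = states,
                 area = raw$area, p_col = raw$p_col, p_drive = raw$p_drive,
                 fs = cfg$fs_out, params = params, config = cfg),
            class = "bcm_sim")
}

#' @export
print.bcm_sim <- function(x, ...) {
  cat(sprintf("Body-cover simulation: %.3f s at %g Hz (P_sub = %.1f cm H2O)\n",
              max(x$t) + 1 / x$fs, x$fs, pa_to_cmh2o(x$config$p_sub)))
  cat(sprintf("  area range %.2f-%.2f mm^2, max collision pressure %.1f cm H2O\n",
              min(x$area) * 1e6, max(x$area) * 1e6,
              pa_to_cmh2o(max(x$p_col))))
  invisible(x)
}

#' Glottal area readout
#'
#' Projected glottal area for a given model state: the membranous
#' contribution is the fold length times the minimum of the upper and
#' lower gaps (doubled under the symmetric mirror condition), floored at
#' zero, plus the posterior glottal opening leak `A_pgo`.
#'
#' @param state a list or data frame with elements `x_u`, `x_l`
#'   (vectorized).
#' @param params a [bcm_params()] object.
#' @param symmetric mirror the single fold (default `TRUE`).
#' @return glottal area (m^2), never below `A_pgo`.
#' @export
glottal_area <- function(state, params, symmetric = TRUE) {
  mult <- if (symmetric) 2 else 1
  g <- pmin(state$x_u, state$x_l)
  pmax(0, mult * params$L_g * g) + params$A_pgo
}

#' Collision pressure readout
#'
#' Contact force from the one-sided collision spring law divided by the
#' instantaneous contact area (fold length times the thickness of each
#' mass in contact). Zero when the glottis is open; continuous at contact
#' onset.
#'
#' @inheritParams glottal_area
#' @return collision pressure (Pa), `>= 0`.
#' @export
collision_pressure <- function(state, params) {
  x_u <- state$x_u; x_l <- state$x_l
  f_one <- function(x, Tm) ifelse(x < 0, -params$k_col * x *
                                    (1 + params$eta_col * (x / Tm)^2), 0)
  Fc <- f_one(x_u, params$T_u) + f_one(x_l, params$T_l)
  Ac <- params$L_g * (params$T_u * (x_u < 0) + params$T_l * (x_l < 0))
  ifelse(Ac > 0, Fc / Ac, 0)
}
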