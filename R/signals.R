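# Measurement procedures applied to pressure-probe recordings: hydrostatic
# calibration, zero-offset corrections, cycle detection, per-cycle peak
# collision pressure, fundamental frequency, SPL, strike-zone waveform
# criteria, and the two-sensor co-location test.

#' Fit a hydrostatic calibration line
#'
#' Pressure sensors are calibrated by submerging the probe in a water
#' column and noting the output voltage at known depths; the hydrostatic
#' pressure in cm H2O equals the submergence depth in cm. An ordinary
#' least-squares line of pressure on voltage gives the calibration slope.
#'
#' @param points data frame with columns `depth_cm` and `voltage`.
#' @return an object of class `calibration_fit` with elements `slope`
#'   ((cm H2O)/V), `intercept` (cm H2O), and `r_squared`.
#' @export
fit_hydrostatic_calibration <- function(points) {
  stopifnot(is.data.frame(points), all(c("depth_cm", "voltage") %in%
                                         names(points)))
  if (length(unique(points$depth_cm)) < 2)
    stop("calibration underdetermined: need at least 2 distinct depths",
         call. = FALSE)
  fit <- lm(depth_cm ~ voltage, data = points)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((points$depth_cm - mean(points$depth_cm))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Hydrostatic calibration: slope %.4g (cm H2O)/V, intercept %.4g cm H2O, R^2 = %.6g\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Zero the subglottal pressure signal
#'
#' Zero subglottal pressure is defined during the silence period prior to
#' phonation onset: the mean over that interval is subtracted from the
#' whole signal.
#'
#' @param x subglottal pressure signal (cm H2O).
#' @param fs sample rate (Hz).
#' @param silence_interval numeric length-2 vector `c(t0, t1)` in seconds,
#'   at least 50 ms long and within the signal extent.
#' @return list with `signal` (corrected) and `offset` (cm H2O).
#' @export
zero_subglottal <- function(x, fs, silence_interval) {
  stopifnot(is.numeric(x), length(silence_interval) == 2)
  t0 <- silence_interval[1]; t1 <- silence_interval[2]
  if (t1 - t0 < 0.05)
    stop("silence interval must be at least 50 ms", call. = FALSE)
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(length(x), ceiling(t1 * fs))
  if (i0 >= i1) stop("silence interval outside signal extent", call. = FALSE)
  offset <- mean(x[i0:i1])
  list(signal = x - offset, offset = offset)
}

#' Zero the intraglottal pressure signal
#'
#' When the intraglottal sensor sits in the plane of vocal fold collision,
#' the zero pressure level is defined at the most-negative per-cycle peak
#' pressure value: the signal is shifted so that this trough reads zero.
#' Ties between equally negative troughs are broken by first occurrence
#' (the offset is the same either way).
#'
#' @param x intraglottal pressure signal (cm H2O).
#' @param fs sample rate (Hz).
#' @param interval optional `c(t0, t1)` analysis window (s); default whole
#'   signal. Must contain at least 3 cycles.
#' @param f_range f0 search range (Hz) passed to cycle detection.
#' @return list with `signal` (corrected), `offset` (cm H2O), and
#'   `cycle_minima`.
#' @export
zero_intraglottal <- function(x, fs, interval = NULL, f_range = c(70, 300)) {
  stopifnot(is.numeric(x))
  if (!is.null(interval)) {
    i0 <- max(1L, floor(interval[1] * fs) + 1L)
    i1 <- min(length(x), ceiling(interval[2] * fs))
    seg <- x[i0:i1]
  } else seg <- x
  cyc <- detect_cycles(seg, fs, f_range)  # errors if no oscillation
  period <- median(diff(cyc))
  # per-cycle minima between consecutive impulse anchors
  anchors <- c(cyc - 0.2 * period, max(cyc) + 0.8 * period)
  mins <- vapply(seq_len(length(anchors) - 1), function(i) {
    j0 <- max(1L, floor(anchors[i] * fs) + 1L)
    j1 <- min(length(seg), ceiling(anchors[i + 1] * fs))
    min(seg[j0:j1])
  }, numeric(1))
  offset <- -min(mins)
  list(signal = x + offset, offset = offset, cycle_minima = mins)
}

#' Detect phonatory cycles from impulsive peaks
#'
#' Locates one impulsive peak per phonatory cycle in an intraglottal (or
#' collision) pressure signal. The period is first estimated by the
#' autocorrelation method; local maxima are then selected greedily by
#' amplitude under a minimum-spacing constraint of 0.6 periods.
#'
#' @param x signal.
#' @param fs sample rate (Hz).
#' @param f_range search range for the cycle rate (Hz).
#' @return numeric vector of peak timestamps (s), strictly increasing.
#' @export
detect_cycles <- function(x, fs, f_range = c(70, 300)) {
  stopifnot(is.numeric(x), fs > 0)
  f0 <- estimate_f0(x, fs, f_range)
  if (is.na(f0))
    stop("no oscillation detected in the requested range", call. = FALSE)
  period <- fs / f0
  xc <- x - median(x)
  # local maxima
  dx <- diff(xc)
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  thr <- 0.4 * quantile(xc[cand], 0.95)
  cand <- cand[xc[cand] > thr]
  if (length(cand) < 3)
    stop("fewer than 3 cycle peaks detected", call. = FALSE)
  # greedy selection by descending amplitude with spacing >= 0.6 periods
  ord <- cand[order(xc[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(i - keep) >= 0.6 * period)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 3)
    stop("fewer than 3 cycle peaks detected", call. = FALSE)
  (keep - 1) / fs
}

#' Per-cycle peak collision pressure
#'
#' The peak collision pressure is the maximum pressure value within each
#' phonatory cycle. Cycle windows are anchored 0.2 periods before each
#' impulse timestamp so that an impulse and the trough preceding it fall
#' in adjacent cycles consistently.
#'
#' @param x corrected intraglottal pressure signal (cm H2O).
#' @param fs sample rate (Hz).
#' @param cycles impulse timestamps (s), e.g. from [detect_cycles()].
#' @param anchor_frac cycle anchor offset as a fraction of the period.
#' @return an object of class `cycle_peaks`: list with `cycle_times`,
#'   `peaks` (cm H2O), and `f0_mean` (Hz).
#' @export
peak_collision_per_cycle <- function(x, fs, cycles, anchor_frac = 0.2) {
  stopifnot(is.numeric(x), length(cycles) >= 1, !is.unsorted(cycles))
  period <- if (length(cycles) > 1) median(diff(cycles)) else length(x) / fs
  anchors <- c(cycles - anchor_frac * period,
               max(cycles) + (1 - anchor_frac) * period)
  peaks <- vapply(seq_along(cycles), function(i) {
    j0 <- max(1L, floor(anchors[i] * fs) + 1L)
    j1 <- min(length(x), ceiling(anchors[i + 1] * fs))
    max(x[j0:j1])
  }, numeric(1))
  structure(list(cycle_times = cycles, peaks = peaks,
                 f0_mean = if (length(cycles) > 1) 1 / mean(diff(cycles))
                           else NA_real_),
            class = "cycle_peaks")
}

#' @export
print.cycle_peaks <- function(x, ...) {
  cat(sprintf("Per-cycle peaks: %d cycles, mean peak %.2f cm H2O, f0 %.1f Hz\n",
              length(x$peaks), mean(x$peaks), x$f0_mean))
  invisible(x)
}

#' Autocorrelation-based fundamental frequency
#'
#' Normalized autocorrelation over the full analysis segment; the highest
#' peak within the search range is refined by parabolic interpolation. If
#' the best normalized autocorrelation falls below the voicing threshold
#' the segment is declared unvoiced and `NA` is returned (with the peak
#' value in attribute `"voicing"`), which is distinct from an error.
#'
#' @param x signal (any amplitude scale; the estimate is amplitude
#'   invariant).
#' @param fs sample rate (Hz).
#' @param f_range search range `c(lo, hi)` in Hz.
#' @param voicing_threshold minimum normalized autocorrelation for a
#'   voiced decision.
#' @return f0 in Hz, or `NA` if unvoiced.
#' @export
estimate_f0 <- function(x, fs, f_range = c(70, 300),
                        voicing_threshold = 0.3) {
  stopifnot(is.numeric(x), fs > 0, length(f_range) == 2,
            f_range[1] < f_range[2])
  n <- length(x)
  k_max <- floor(fs / f_range[1])
  k_min <- max(2L, ceiling(fs / f_range[2]))
  if (n < 2 * k_max)
    stop("signal too short for the requested search range", call. = FALSE)
  xc <- x - mean(x)
  if (all(xc == 0)) return(structure(NA_real_, voicing = 0))
  # normalized autocorrelation r(k) = sum x_t x_{t+k} / sqrt(E0k * Ek)
  r <- vapply((k_min - 1):(k_max + 1), function(k) {
    a <- xc[1:(n - k)]; b <- xc[(k + 1):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }, numeric(1))
  ks <- (k_min - 1):(k_max + 1)
  inside <- ks >= k_min & ks <= k_max
  i_best <- which(inside)[which.max(r[inside])]
  if (r[i_best] < voicing_threshold)
    return(structure(NA_real_, voicing = r[i_best]))
  # parabolic interpolation around the peak
  k0 <- ks[i_best]
  y1 <- r[i_best - 1]; y2 <- r[i_best]; y3 <- r[i_best + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  structure(fs / (k0 + delta), voicing = r[i_best])
}

#' Sound pressure level
#'
#' @param x calibrated acoustic signal (Pa).
#' @param p_ref reference pressure (Pa), 20 micropascal by default.
#' @return level in dB SPL; `-Inf` with attribute `silence = TRUE` for an
#'   all-zero signal.
#' @export
compute_spl <- function(x, p_ref = 20e-6) {
  stopifnot(is.numeric(x), length(x) > 0)
  r <- sqrt(mean(x^2))
  if (r == 0) return(structure(-Inf, silence = TRUE))
  20 * log10(r / p_ref)
}

#' Strike-zone waveform criteria
#'
#' Evaluates, cycle by cycle, the three waveform characteristics expected
#' of an intraglottal pressure sensor positioned in the strike zone of
#' vocal fold collision: (c1) an impulsive peak at the start of the closed
#' phase (half-height width below `w_max` periods), (c2) a later,
#' more-rounded peak during the open phase (width at least `rho` times the
#' impulse width, with non-negligible prominence), and (c3) a minimum
#' value around zero immediately preceding the next impulse (magnitude
#' below `eps` times the impulse height). The overall verdict is the
#' conjunction of the three criteria on at least a `majority` fraction of
#' cycles.
#'
#' @param x corrected intraglottal pressure signal (cm H2O).
#' @param fs sample rate (Hz).
#' @param cycles impulse timestamps (s); detected from `x` if `NULL`.
#' @param w_max,rho,eps,majority criterion thresholds (see above).
#' @return an object of class `strike_zone_report`: flags
#'   `in_strike_zone`, `c1_impulsive`, `c2_rounded`, `c3_trough`, and a
#'   per-cycle diagnostics data frame.
#' @export
strike_zone_check <- function(x, fs, cycles = NULL, w_max = 0.25, rho = 2,
                              eps = 0.10, majority = 0.8) {
  if (is.null(cycles)) cycles <- detect_cycles(x, fs)
  if (length(cycles) < 5)
    stop("need at least 5 cycles for the strike-zone check", call. = FALSE)
  period <- median(diff(cycles))
  np <- period * fs

  half_width <- function(seg, i_pk) {
    lev <- min(seg) + 0.5 * (seg[i_pk] - min(seg))
    lo <- i_pk; while (lo > 1 && seg[lo - 1] >= lev) lo <- lo - 1
    hi <- i_pk; while (hi < length(seg) && seg[hi + 1] >= lev) hi <- hi + 1
    hi - lo + 1
  }
  # cycle windows start 0.2 periods before each impulse so the impulse,
  # its preceding trough, and the open-phase peak are all interior
  rows <- lapply(2:(length(cycles) - 1), function(i) {
    i0 <- max(1L, round((cycles[i] - 0.2 * period) * fs) + 1L)
    i1 <- min(length(x), i0 + round(period * fs) - 1L)
    seg <- x[i0:i1]
    if (length(seg) < 12) return(NULL)
    n <- length(seg)
    # c1: impulsive peak near the anchor (must be an interior local max
    # of the search region, with half-height width < w_max periods)
    a0 <- max(1L, round(0.08 * n)); a1 <- round(0.45 * n)
    i_imp <- a0 - 1L + which.max(seg[a0:a1])
    wi <- half_width(seg, i_imp)
    c1 <- i_imp > a0 && i_imp < a1 && (wi / np) < w_max
    # c2: a later rounded peak with width >= rho * impulse width and
    # non-negligible prominence
    j0 <- min(n - 1L, max(i_imp + wi, round(0.45 * n)))
    j1 <- max(j0 + 1L, round(0.97 * n))
    i_rnd <- j0 - 1L + which.max(seg[j0:j1])
    prominence <- seg[i_rnd] - min(seg)
    wr <- half_width(seg, i_rnd)
    local_max <- i_rnd > j0 && i_rnd < j1
    c2 <- local_max && prominence > 0.05 * max(seg[i_imp] - min(seg), 1e-12) &&
      wr >= rho * wi
    # c3: trough immediately preceding the impulse
    k0 <- max(1L, round(0.02 * n)); k1 <- max(k0 + 1L, round(0.13 * n))
    trough <- min(seg[k0:k1])
    c3 <- abs(trough) < eps * max(abs(seg[i_imp]), 1e-12)
    data.frame(cycle = i, t = cycles[i], imp_height = seg[i_imp],
               imp_width = wi / fs, rnd_width = wr / fs, trough = trough,
               c1 = c1, c2 = c2, c3 = c3)
  })
  diag <- do.call(rbind, rows)
  frac <- function(v) mean(v)
  all3 <- diag$c1 & diag$c2 & diag$c3
  structure(list(in_strike_zone = frac(all3) >= majority,
                 c1_impulsive = frac(diag$c1) >= majority,
                 c2_rounded = frac(diag$c2) >= majority,
                 c3_trough = frac(diag$c3) >= majority,
                 per_cycle = diag),
            class = "strike_zone_report")
}

#' @export
print.strike_zone_report <- function(x, ...) {
  cat(sprintf("Strike zone: %s (impulsive %s, rounded %s, trough %s; %d cycles)\n",
              if (x$in_strike_zone) "YES" else "no",
              x$c1_impulsive, x$c2_rounded, x$c3_trough, nrow(x$per_cycle)))
  invisible(x)
}

#' Two-sensor co-location test
#'
#' If the signals captured by two adjacent pressure sensors are in phase
#' and strongly correlated, both sensors sit in the same region
#' (subglottal, intraglottal, or supraglottal); distinct waveshapes at a
#' shared cycle rate indicate the desired placement in different regions.
#' The test is amplitude invariant.
#'
#' @param sig_a,sig_b equal-length signals.
#' @param fs sample rate (Hz).
#' @param r_same zero-lag correlation threshold for a "same" verdict.
#' @param max_lag_s lag search extent (s).
#' @return list with `verdict` (`"same"` or `"different"`),
#'   `zero_lag_correlation`, `best_lag` (s), `best_correlation`, and the
#'   normalized waveshape distance.
#' @export
colocation_test <- function(sig_a, sig_b, fs, r_same = 0.9,
                            max_lag_s = 0.02) {
  stopifnot(length(sig_a) == length(sig_b), length(sig_a) > 8)
  a <- sig_a - mean(sig_a); b <- sig_b - mean(sig_b)
  if (sd(a) == 0 || sd(b) == 0)
    stop("constant signal: co-location test undefined", call. = FALSE)
  r0 <- unname(stats::cor(a, b))
  max_lag <- min(length(a) - 2, round(max_lag_s * fs))
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE)
  best <- which.max(cc$acf)
  an <- a / sqrt(mean(a^2)); bn <- b / sqrt(mean(b^2))
  dist <- sqrt(mean((an - bn)^2))
  list(verdict = if (r0 >= r_same) "same" else "different",
       zero_lag_correlation = r0,
       best_lag = cc$lag[best] / fs,
       best_correlation = unname(cc$acf[best]),
       shape_distance = dist)
}
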