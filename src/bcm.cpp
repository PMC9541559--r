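#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout shared with R (see .bcm_par_order in R/bcm.R).
enum par_index {
  P_MU, P_ML, P_MB, P_KU, P_KL, P_KB, P_KC, P_DU, P_DL, P_DB,
  P_KCOL, P_ETA, P_LG, P_TU, P_TL, P_X0U, P_X0L, P_X0B, P_APGO, P_MULT,
  NPAR
};

// One-sided collision spring with cubic hardening; x < 0 is penetration
// past the contact plane, normalized by the mass thickness T.
static inline double collision_force(const double* p, double x, double T) {
  if (x >= 0.0) return 0.0;
  double r = x / T;
  return -p[P_KCOL] * x * (1.0 + p[P_ETA] * r * r);
}

// Quasi-steady Bernoulli jet pressure on the lower mass: full stagnation
// pressure when the flow detaches below the upper mass, zero supraglottal
// recovery, zero when the lower margin itself is closed.
static inline double jet_pressure(const double* p, double x_u, double x_l,
                                  double psub) {
  double a_l = p[P_MULT] * p[P_LG] * x_l;
  double a_u = p[P_MULT] * p[P_LG] * x_u;
  if (a_l <= 0.0) return 0.0;
  double a_min = a_l < a_u ? a_l : a_u;
  if (a_min <= 0.0) return psub;
  double r = a_min / a_l;
  return psub * (1.0 - r * r);
}

static inline void derivs(const double* p, const double* s, double psub,
                          double* ds) {
  const double x_u = s[0], x_l = s[1], x_b = s[2];
  const double v_u = s[3], v_l = s[4], v_b = s[5];
  const double F_ku = -p[P_KU] * ((x_u - x_b) - (p[P_X0U] - p[P_X0B]));
  const double F_kl = -p[P_KL] * ((x_l - x_b) - (p[P_X0L] - p[P_X0B]));
  const double F_kc = -p[P_KC] * ((x_u - x_l) - (p[P_X0U] - p[P_X0L]));
  const double F_du = -p[P_DU] * (v_u - v_b);
  const double F_dl = -p[P_DL] * (v_l - v_b);
  const double F_cu = collision_force(p, x_u, p[P_TU]);
  const double F_cl = collision_force(p, x_l, p[P_TL]);
  const double F_al = jet_pressure(p, x_u, x_l, psub) * p[P_LG] * p[P_TL];
  ds[0] = v_u;
  ds[1] = v_l;
  ds[2] = v_b;
  ds[3] = (F_ku + F_kc + F_du + F_cu) / p[P_MU];
  ds[4] = (F_kl - F_kc + F_dl + F_cl + F_al) / p[P_ML];
  ds[5] = (-F_ku - F_kl - F_du - F_dl
           - p[P_KB] * (s[2] - p[P_X0B]) - p[P_DB] * v_b) / p[P_MB];
}

static inline void rk4_step(const double* p, double* s, double psub,
                            double h) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  derivs(p, s, psub, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
  derivs(p, tmp, psub, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
  derivs(p, tmp, psub, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = s[i] + h * k3[i];
  derivs(p, tmp, psub, k4);
  for (int i = 0; i < 6; ++i)
    s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static inline double area_of(const double* p, const double* s) {
  double g = s[0] < s[1] ? s[0] : s[1];
  double a = p[P_MULT] * p[P_LG] * g;
  return (a > 0.0 ? a : 0.0) + p[P_APGO];
}

static inline double pcol_of(const double* p, const double* s) {
  double F = 0.0, A = 0.0;
  if (s[0] < 0.0) { F += collision_force(p, s[0], p[P_TU]); A += p[P_LG] * p[P_TU]; }
  if (s[1] < 0.0) { F += collision_force(p, s[1], p[P_TL]); A += p[P_LG] * p[P_TL]; }
  return A > 0.0 ? F / A : 0.0;
}

// [[Rcpp::export]]
List bcm_simulate_cpp(NumericVector par, double psub, int n_out,
                      double solver_step, int decim, NumericVector init) {
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  if (init.size() != 6) stop("initial state must have length 6");
  const double* p = par.begin();
  double s[6];
  for (int i = 0; i < 6; ++i) s[i] = init[i];

  NumericMatrix states(n_out, 6);
  NumericVector area(n_out), p_col(n_out), p_drive(n_out);

  for (int i = 0; i < n_out; ++i) {
    if (i > 0) {
      for (int j = 0; j < decim; ++j) rk4_step(p, s, psub, solver_step);
    }
    for (int k = 0; k < 6; ++k) {
      if (!R_finite(s[k])) {
        double t_bad = (double)i * decim * solver_step;
        stop("numerical instability: non-finite state at t = %f s", t_bad);
      }
      states(i, k) = s[k];
    }
    area[i] = area_of(p, s);
    p_col[i] = pcol_of(p, s);
    p_drive[i] = jet_pressure(p, s[0], s[1], psub);
  }
  return List::create(_["states"] = states, _["area"] = area,
                      _["p_col"] = p_col, _["p_drive"] = p_drive);
}

// Batch propagation used by the extended Kalman filter: each row of
// `states` is advanced by n_sub RK4 substeps of size dt/n_sub under the
// matching row of `pars` and element of `psub`.
// [[Rcpp::export]]
NumericMatrix bcm_propagate_cpp(NumericMatrix states, NumericMatrix pars,
                                NumericVector psub, double dt, int n_sub) {
  const int n = states.nrow();
  if (pars.nrow() != n || psub.size() != n)
    stop("states, pars and psub must have matching rows");
  if (pars.ncol() != NPAR) stop("parameter matrix has wrong width");
  NumericMatrix out(n, 6);
  const double h = dt / n_sub;
  std::vector<double> p(NPAR);
  double s[6];
  for (int r = 0; r < n; ++r) {
    for (int k = 0; k < NPAR; ++k) p[k] = pars(r, k);
    for (int k = 0; k < 6; ++k) s[k] = states(r, k);
    for (int j = 0; j < n_sub; ++j) rk4_step(p.data(), s, psub[r], h);
    for (int k = 0; k < 6; ++k) {
      if (!R_finite(s[k]))
        stop("numerical instability: non-finite state in propagation row %d",
             r + 1);
      out(r, k) = s[k];
    }
  }
  return out;
}

// Substep-resolved trajectory for one state: returns the state, area,
// and collision pressure at each of the n_sub RK4 substeps across dt.
// [[Rcpp::export]]
List bcm_path_cpp(NumericVector state, NumericVector par, double psub,
                  double dt, int n_sub) {
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  if (state.size() != 6) stop("state must have length 6");
  const double* p = par.begin();
  double s[6];
  for (int i = 0; i < 6; ++i) s[i] = state[i];
  const double h = dt / n_sub;
  NumericMatrix states(n_sub, 6);
  NumericVector area(n_sub), p_col(n_sub);
  for (int j = 0; j < n_sub; ++j) {
    rk4_step(p, s, psub, h);
    for (int k = 0; k < 6; ++k) states(j, k) = s[k];
    area[j] = area_of(p, s);
    p_col[j] = pcol_of(p, s);
  }
  return List::create(_["states"] = states, _["area"] = area,
                      _["p_col"] = p_col);
}
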