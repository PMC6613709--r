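// Exact solution of the linear gadoxetate compartment system.
// State x = (C_hep, C_p, C_ees); dx/dt = A x + b(t) with b a rectangular
// infusion pulse into plasma. Spectral decomposition gives the solution on
// each constant-input segment; a singular A (no elimination pathways)
// falls back to an augmented matrix exponential for the pulse segment.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// constants: V_l, V_p, V_ees, Alb, v_h, CLr
// dose: t_start, duration, rate_mmol_s
// times must be ascending; concentrations before t_start are zero.
// [[Rcpp::export]]
arma::mat gf_sim_conc(double k_diff, double k_ph, double k_hp, double k_hb,
                      const arma::vec& constants, const arma::vec& dose,
                      const arma::vec& times) {
  const double V_l = constants(0), V_p = constants(1), V_ees = constants(2),
               Alb = constants(3), v_h = constants(4), CLr = constants(5);
  const double t0 = dose(0), dur = dose(1), rate = dose(2);
  const double t1 = t0 + dur;

  mat A(3, 3, fill::zeros);
  A(0, 0) = -(k_hp + k_hb);
  A(0, 1) = k_ph * Alb;
  A(1, 0) = k_hp * V_l * v_h / V_p;
  A(1, 1) = -(k_ph * Alb * V_l * v_h + CLr * Alb + k_diff * Alb * V_ees) / V_p;
  A(1, 2) = k_diff * V_ees / V_p;
  A(2, 1) = k_diff * Alb;
  A(2, 2) = -k_diff;

  cx_vec lam;
  cx_mat V;
  if (!eig_gen(lam, V, A)) Rcpp::stop("spectral decomposition failed");
  cx_mat W;
  if (!inv(W, V)) Rcpp::stop("defective system matrix");
  if (norm(V, "inf") * norm(W, "inf") > 1e12)
    Rcpp::stop("ill-conditioned eigenvector basis");

  vec b = {0.0, rate / V_p, 0.0};
  vec xss(3);
  bool have_ss = solve(xss, A, -b, solve_opts::no_approx + solve_opts::fast);
  if (have_ss && !xss.is_finite()) have_ss = false;
  if (have_ss && norm(A * xss + b) > 1e-10 * (norm(b) + 1.0))
    have_ss = false;  // singular A (no elimination): solve "succeeded" badly

  // pulse-segment state at offset dt from t0 (x(t0) = 0)
  mat Maug(4, 4, fill::zeros);
  if (!have_ss) {
    Maug.submat(0, 0, 2, 2) = A;
    Maug(0, 3) = b(0); Maug(1, 3) = b(1); Maug(2, 3) = b(2);
  }
  auto pulse_state = [&](double dt) -> vec {
    if (have_ss) {
      cx_vec co = W * cx_vec(-xss, vec(3, fill::zeros));
      cx_vec x = V * (exp(lam * dt) % co);
      return xss + real(x);
    }
    mat E = expmat(Maug * dt);
    return E.submat(0, 3, 2, 3);
  };

  const uword T = times.n_elem;
  mat out(3, T, fill::zeros);
  vec x1;
  bool have_x1 = false;
  for (uword i = 0; i < T; ++i) {
    double t = times(i);
    if (t <= t0) continue;
    if (t < t1) {
      out.col(i) = pulse_state(t - t0);
    } else {
      if (!have_x1) { x1 = pulse_state(dur); have_x1 = true; }
      cx_vec co = W * cx_vec(x1, vec(3, fill::zeros));
      out.col(i) = real(V * (exp(lam * (t - t1)) % co));
    }
  }
  return out;
}
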