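// Fixed-step integrators for the whole-cell circuit and two-domain
// stimulation models.  Scheme: Lie splitting per substep — gating advanced
// by the exact matrix exponential of the generator at the frozen membrane
// voltage, then the node voltages advanced by the exact solution of the
// linear circuit ODE with conductances frozen.  Both sub-updates share the
// steady state of the coupled system as an exact fixed point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int NS = 5;  // gating states C0..C3, O

struct RatePar {
  double alpha1, m, beta1, n, A, B;
};

static inline void check_exp_arg(double x) {
  if (std::abs(x) > 700.0)
    Rcpp::stop("rate-law exponent overflow: |V/slope| = %g > 700", std::abs(x));
}

static inline double fwd(double V, const RatePar& rp) {
  check_exp_arg(V / rp.m);
  return rp.alpha1 * std::exp(V / rp.m);
}
static inline double bwd(double V, const RatePar& rp) {
  check_exp_arg(-V / rp.n);
  return rp.beta1 * std::exp(-V / rp.n);
}

// infinitesimal generator, Q(i,j) = rate i -> j
static mat gating_Q(double V, const RatePar& rp) {
  double a = fwd(V, rp), b = bwd(V, rp);
  mat Q(NS, NS, fill::zeros);
  for (int i = 0; i < 3; ++i) { Q(i, i + 1) = a; Q(i + 1, i) = b; }
  Q(3, 4) = rp.A; Q(4, 3) = rp.B;
  Q.diag() = -sum(Q, 1);
  return Q;
}

// expm of a 5x5 matrix by scaling-and-squaring of a truncated Taylor
// series; specialised for the small gating generators (norms of order
// |Q| h ~ 1-10 after scaling), accurate to ~1e-13 with 12 terms
static void expm5(const double* A, double* E) {
  double nrm = 0.0;
  for (int i = 0; i < NS; ++i) {
    double rs = 0.0;
    for (int j = 0; j < NS; ++j) rs += std::fabs(A[i * NS + j]);
    if (rs > nrm) nrm = rs;
  }
  int sq = 0;
  double sc = 1.0;
  while (nrm * sc > 0.5) { sc *= 0.5; ++sq; }
  double As[25], X[25], T[25];
  for (int i = 0; i < 25; ++i) As[i] = A[i] * sc;
  for (int i = 0; i < 25; ++i) { E[i] = (i % 6 == 0) ? 1.0 : 0.0; X[i] = E[i]; }
  double fac = 1.0;
  for (int q = 1; q <= 12; ++q) {
    fac *= q;
    // X <- X * As
    for (int i = 0; i < NS; ++i)
      for (int j = 0; j < NS; ++j) {
        double s = 0.0;
        for (int k = 0; k < NS; ++k) s += X[i * NS + k] * As[k * NS + j];
        T[i * NS + j] = s;
      }
    for (int i = 0; i < 25; ++i) { X[i] = T[i]; E[i] += X[i] / fac; }
  }
  for (int r = 0; r < sq; ++r) {
    for (int i = 0; i < NS; ++i)
      for (int j = 0; j < NS; ++j) {
        double s = 0.0;
        for (int k = 0; k < NS; ++k) s += E[i * NS + k] * E[k * NS + j];
        T[i * NS + j] = s;
      }
    for (int i = 0; i < 25; ++i) E[i] = T[i];
  }
}

// p <- expm(Q^T h) p, exact for frozen V
static inline void gating_step(vec& p, double V, const RatePar& rp, double h) {
  double a = fwd(V, rp), b = bwd(V, rp);
  // Q^T h, row-major: QT[i][j] = Q(j,i) * h
  double QT[25] = {0};
  auto at = [&](int i, int j) -> double& { return QT[i * NS + j]; };
  for (int i = 0; i < 3; ++i) { at(i + 1, i) = a * h; at(i, i + 1) = b * h; }
  at(4, 3) = rp.A * h; at(3, 4) = rp.B * h;
  at(0, 0) = -a * h;
  at(1, 1) = -(a + b) * h; at(2, 2) = -(a + b) * h;
  at(3, 3) = -(b + rp.A) * h;
  at(4, 4) = -rp.B * h;
  double E[25];
  expm5(QT, E);
  double pn[NS];
  for (int i = 0; i < NS; ++i) {
    double s = 0.0;
    for (int j = 0; j < NS; ++j) s += E[i * NS + j] * p(j);
    pn[i] = s;
  }
  for (int i = 0; i < NS; ++i) p(i) = pn[i];
}

static RatePar rates_from_list(const Rcpp::List& rp) {
  RatePar r;
  r.alpha1 = rp["alpha1"]; r.m = rp["m"]; r.beta1 = rp["beta1"];
  r.n = rp["n"]; r.A = rp["A"]; r.B = rp["B"];
  return r;
}

// scalar linear update dV/dt = a - b V over h (exact, b >= 0)
static inline double lin1_step(double V, double a, double b, double h) {
  if (b * h < 1e-12) return V + (a - b * V) * h;
  double Vss = a / b;
  return Vss + (V - Vss) * std::exp(-b * h);
}

// ---------------------------------------------------------------------------
// single-domain whole-cell circuit
// mode: 0 = voltage clamp (u = command voltage), 1 = current clamp (u = I_inj)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_simulate_single(const arma::vec& t, const arma::vec& u, int mode,
                               const Rcpp::List& rates, double Ng, double EK,
                               double CM, double RS, double Rseal, double GB,
                               double EV, const arma::vec& p0, double V0,
                               int n_sub) {
  const int nt = t.n_elem;
  if ((int)u.n_elem != nt) Rcpp::stop("input trace length != time grid length");
  RatePar rp = rates_from_list(rates);
  bool has_ch = Ng > 0.0;

  vec p = p0;
  double V = V0;
  mat P(nt, NS);
  vec Vout(nt), Iout(nt);

  for (int k = 0; k < nt; ++k) {
    P.row(k) = p.t();
    Vout(k) = V;
    if (mode == 0)
      Iout(k) = (u(k) - V) / RS + u(k) / Rseal;
    else
      Iout(k) = u(k);
    if (k == nt - 1) break;
    double h = (t(k + 1) - t(k)) / n_sub;
    for (int s = 0; s < n_sub; ++s) {
      if (has_ch) gating_step(p, V, rp, h);
      double G = has_ch ? Ng * p(4) : 0.0;
      double a, b;
      if (mode == 0) {
        a = (u(k) / RS + GB * EV + G * EK) / CM;
        b = (1.0 / RS + GB + G) / CM;
      } else {
        a = (u(k) + GB * EV + G * EK) / CM;
        b = (GB + G) / CM;
      }
      V = lin1_step(V, a, b, h);
    }
  }
  return Rcpp::List::create(Rcpp::Named("V") = Vout,
                            Rcpp::Named("p") = P,
                            Rcpp::Named("I_out") = Iout);
}

// Equivalent clamp voltage: given the raw output current of the single-domain
// circuit, recover the command voltage step by step (algebraic inversion of
// the output relation, then the same state advance as the forward scheme).
// [[Rcpp::export]]
Rcpp::List cpp_invert_single(const arma::vec& t, const arma::vec& iout,
                             const Rcpp::List& rates, double Ng, double EK,
                             double CM, double RS, double Rseal, double GB,
                             double EV, const arma::vec& p0, double V0,
                             int n_sub) {
  const int nt = t.n_elem;
  RatePar rp = rates_from_list(rates);
  bool has_ch = Ng > 0.0;
  double kout = 1.0 / RS + 1.0 / Rseal;

  vec p = p0;
  double V = V0;
  vec Vc(nt), Vm(nt);
  for (int k = 0; k < nt; ++k) {
    Vc(k) = (iout(k) + V / RS) / kout;
    Vm(k) = V;
    if (k == nt - 1) break;
    double h = (t(k + 1) - t(k)) / n_sub;
    for (int s = 0; s < n_sub; ++s) {
      if (has_ch) gating_step(p, V, rp, h);
      double G = has_ch ? Ng * p(4) : 0.0;
      double a = (Vc(k) / RS + GB * EV + G * EK) / CM;
      double b = (1.0 / RS + GB + G) / CM;
      V = lin1_step(V, a, b, h);
    }
  }
  return Rcpp::List::create(Rcpp::Named("V_C") = Vc, Rcpp::Named("V_I") = Vm);
}

// ---------------------------------------------------------------------------
// two-domain (attached/free) model
// mode: 0 = voltage clamp, 1 = current clamp I = 0
// stim_mode: 0 = none, 1 = voltage source V_in behind C_E, 2 = photocurrent
// vin/dvin/iph sampled on the output grid (linearly interpolated to substeps)
// ---------------------------------------------------------------------------

// exact update of M x' = -K x + c over h via 3x3 augmented matrix exponential
static inline void lin2_step(vec& x, const mat& M, const mat& K, const vec& c,
                             double h) {
  mat W = solve(M, K);
  vec d = solve(M, c);
  mat Aug(3, 3, fill::zeros);
  Aug.submat(0, 0, 1, 1) = -W;
  Aug(0, 2) = d(0); Aug(1, 2) = d(1);
  mat E = expmat(Aug * h);
  vec xn = E.submat(0, 0, 1, 1) * x;
  x(0) = xn(0) + E(0, 2);
  x(1) = xn(1) + E(1, 2);
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate_two(const arma::vec& t, const arma::vec& u, int mode,
                            const Rcpp::List& rates,
                            double Ng_att, double Ng_free, double EK,
                            double cm_att, double cm_free,
                            double gb_att, double gb_free, double EV,
                            double RS, double Rseal, double RJ, double CE,
                            int stim_mode, const arma::vec& vin,
                            const arma::vec& dvin, const arma::vec& iph,
                            const arma::vec& p0_att, const arma::vec& p0_free,
                            double VI0, double VJ0, int n_sub) {
  const int nt = t.n_elem;
  RatePar rp = rates_from_list(rates);

  // M x' = -K x + c with x = (V_I, V_J); entries derived from KCL at the
  // cell and cleft nodes (free membrane to bath, attached membrane to cleft,
  // cleft to bath through R_J, stimulus into the cleft node).
  const double Ca = cm_att, Cf = cm_free;
  const double CEeff = (stim_mode == 1) ? CE : 0.0;
  mat M(2, 2);
  M(0, 0) = Cf + Ca;  M(0, 1) = -Ca;
  M(1, 0) = Ca;       M(1, 1) = -(Ca + CEeff);

  vec p_att = p0_att, p_free = p0_free;
  vec x = {VI0, VJ0};
  mat Patt(nt, NS), Pfree(nt, NS);
  vec VI(nt), VJ(nt), Iout(nt), Gatt(nt), Gfree(nt), Iatt(nt), Istim(nt);

  auto interp = [&](const arma::vec& v, int k, double f) -> double {
    if (v.n_elem == 0) return 0.0;
    if (k >= nt - 1) return v(nt - 1);
    return v(k) * (1.0 - f) + v(k + 1) * f;
  };

  for (int k = 0; k < nt; ++k) {
    Patt.row(k) = p_att.t(); Pfree.row(k) = p_free.t();
    VI(k) = x(0); VJ(k) = x(1);
    double Gma = Ng_att * p_att(4), Gmf = Ng_free * p_free(4);
    Gatt(k) = Gma; Gfree(k) = Gmf;

    // instantaneous derivatives for the output bookkeeping
    {
      double s = (stim_mode == 1) ? CE * interp(dvin, k, 0.0)
               : (stim_mode == 2) ? interp(iph, k, 0.0) : 0.0;
      double k11 = gb_free + Gmf + gb_att + Gma + ((mode == 0) ? 1.0 / RS : 0.0);
      double k12 = -(gb_att + Gma);
      double c1 = gb_free * EV + Gmf * EK + gb_att * EV + Gma * EK +
                  ((mode == 0) ? u(k) / RS : u(k));
      double k21 = gb_att + Gma;
      double k22 = -(1.0 / RJ + gb_att + Gma);
      double c2 = gb_att * EV + Gma * EK - s;
      mat K = {{k11, k12}, {k21, k22}};
      vec c = {c1, c2};
      vec xd = solve(M, -K * x + c);
      double VM = x(0) - x(1);
      Iatt(k) = Ca * (xd(0) - xd(1)) + gb_att * (VM - EV) + Gma * (VM - EK);
      Istim(k) = (stim_mode == 1) ? CE * (interp(dvin, k, 0.0) - xd(1))
               : (stim_mode == 2) ? interp(iph, k, 0.0) : 0.0;
    }
    Iout(k) = (mode == 0) ? (u(k) - x(0)) / RS + u(k) / Rseal : 0.0;
    if (k == nt - 1) break;

    double h = (t(k + 1) - t(k)) / n_sub;
    for (int s2 = 0; s2 < n_sub; ++s2) {
      double fmid = (s2 + 0.5) / n_sub;
      if (Ng_att > 0) gating_step(p_att, x(0) - x(1), rp, h);
      if (Ng_free > 0) gating_step(p_free, x(0), rp, h);
      double Gma = Ng_att * p_att(4), Gmf = Ng_free * p_free(4);
      double s = (stim_mode == 1) ? CE * interp(dvin, k, fmid)
               : (stim_mode == 2) ? interp(iph, k, fmid) : 0.0;
      double k11 = gb_free + Gmf + gb_att + Gma + ((mode == 0) ? 1.0 / RS : 0.0);
      double k12 = -(gb_att + Gma);
      double c1 = gb_free * EV + Gmf * EK + gb_att * EV + Gma * EK +
                  ((mode == 0) ? u(k) / RS : u(k));
      double k21 = gb_att + Gma;
      double k22 = -(1.0 / RJ + gb_att + Gma);
      double c2 = gb_att * EV + Gma * EK - s;
      mat K = {{k11, k12}, {k21, k22}};
      vec c = {c1, c2};
      lin2_step(x, M, K, c, h);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("V_I") = VI, Rcpp::Named("V_J") = VJ,
      Rcpp::Named("I_out") = Iout,
      Rcpp::Named("p_att") = Patt, Rcpp::Named("p_free") = Pfree,
      Rcpp::Named("G_att") = Gatt, Rcpp::Named("G_free") = Gfree,
      Rcpp::Named("i_att") = Iatt, Rcpp::Named("i_stim") = Istim);
}

// gating-only propagation under piecewise-constant voltage (exact per
// interval; the propagator for each distinct (V, dt) is cached)
// [[Rcpp::export]]
arma::mat cpp_propagate_pc(const arma::vec& t, const arma::vec& V,
                           const arma::vec& p0, const Rcpp::List& rates) {
  const int nt = t.n_elem;
  RatePar rp = rates_from_list(rates);
  mat P(nt, NS);
  vec p = p0;
  double lastV = datum::nan, lasth = datum::nan;
  mat E;
  for (int k = 0; k < nt; ++k) {
    P.row(k) = p.t();
    if (k == nt - 1) break;
    double h = t(k + 1) - t(k);
    if (V(k) != lastV || h != lasth) {
      E = expmat(gating_Q(V(k), rp).t() * h);
      lastV = V(k); lasth = h;
    }
    p = E * p;
  }
  return P;
}
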