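// Core numerical kernels: three-compartment disposition eigensystem,
// transit-absorption concentration profiles, and the FOCE-I per-subject
// conditional likelihood with Gauss-Newton inner optimisation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Disposition eigensystem
//
// Rate matrix (amounts; central, P1, P2):
//   [ -(k10+k12+k13)  k21   k31 ]
//   [  k12           -k21    0  ]
//   [  k13             0   -k31 ]
// Eigenvalues are -lambda_i with lambda_i >= 0 the roots of
//   L^3 - a2 L^2 + a1 L - a0 = 0,
//   a2 = k10+k12+k13+k21+k31
//   a1 = k10*k21 + k10*k31 + k12*k31 + k13*k21 + k21*k31
//   a0 = k10*k21*k31
// Unit-bolus (into central) amount response: h(t) = sum_i c_i exp(-lambda_i t),
//   c_i = (k21-lambda_i)(k31-lambda_i) / prod_{j!=i}(lambda_j-lambda_i).
// ---------------------------------------------------------------------------

struct Disp {
  double lam[3];
  double c[3];
  bool ok;
};

static void cubic_roots(double a2, double a1, double a0, double* r) {
  // All-real-roots cubic x^3 - a2 x^2 + a1 x - a0 via the trigonometric method
  double p = a1 - a2 * a2 / 3.0;
  double q = -2.0 * a2 * a2 * a2 / 27.0 + a1 * a2 / 3.0 - a0;
  double shift = a2 / 3.0;
  if (p > -1e-300) {  // triple/degenerate root region
    r[0] = r[1] = r[2] = shift;
    return;
  }
  double m = 2.0 * std::sqrt(-p / 3.0);
  double arg = 3.0 * q / (p * m);
  if (arg > 1.0) arg = 1.0;
  if (arg < -1.0) arg = -1.0;
  double th = std::acos(arg);
  for (int k = 0; k < 3; ++k)
    r[k] = m * std::cos((th - 2.0 * M_PI * k) / 3.0) + shift;
}

static Disp disposition(double CL, double Vc, double Q1, double Vp1,
                        double Q2, double Vp2) {
  Disp d;
  d.ok = (CL > 0 && Vc > 0 && Q1 >= 0 && Vp1 > 0 && Q2 >= 0 && Vp2 > 0);
  if (!d.ok) return d;
  double k10 = CL / Vc, k12 = Q1 / Vc, k21 = Q1 / Vp1;
  double k13 = Q2 / Vc, k31 = Q2 / Vp2;
  double a2 = k10 + k12 + k13 + k21 + k31;
  double a1 = k10 * k21 + k10 * k31 + k12 * k31 + k13 * k21 + k21 * k31;
  double a0 = k10 * k21 * k31;
  double lam[3];
  cubic_roots(a2, a1, a0, lam);
  // sort descending; separate near-coincident roots so residues stay finite
  std::sort(lam, lam + 3, std::greater<double>());
  double scale = std::max(lam[0], 1e-12);
  for (int i = 1; i < 3; ++i)
    if (lam[i - 1] - lam[i] < 1e-10 * scale) lam[i] = lam[i - 1] - 1e-10 * scale;
  for (int i = 0; i < 3; ++i) {
    if (lam[i] < 0) lam[i] = 0.0;
    d.lam[i] = lam[i];
  }
  for (int i = 0; i < 3; ++i) {
    double num = (k21 - lam[i]) * (k31 - lam[i]);
    double den = 1.0;
    for (int j = 0; j < 3; ++j)
      if (j != i) den *= (lam[j] - lam[i]);
    d.c[i] = num / den;
  }
  return d;
}

// [[Rcpp::export]]
List cpp_disp_eigen(double CL, double Vc, double Q1, double Vp1, double Q2,
                    double Vp2) {
  Disp d = disposition(CL, Vc, Q1, Vp1, Q2, Vp2);
  if (!d.ok) stop("invalid disposition parameters");
  return List::create(_["lambda"] = NumericVector::create(d.lam[0], d.lam[1], d.lam[2]),
                      _["coef"] = NumericVector::create(d.c[0], d.c[1], d.c[2]));
}

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// e^{-lambda dt} * integral_0^dt s^{m-1} e^{-b s} ds  with b = ktr - lambda.
// Explicit finite-sum form (any sign of b); power series near b*dt = 0.
// E2 = exp(-ktr dt) is shared across the three eigenterms and passed in.
static double conv_term(double dt, double lam, double ktr, double E2, int m,
                        double factm1) {
  double b = ktr - lam;
  double bt = b * dt;
  if (std::fabs(bt) < 1e-3) {
    double s = 0.0, cj = 1.0;  // cj = (-b)^j / j!
    for (int j = 0; j < 16; ++j) {
      double term = cj * std::pow(dt, m + j) / (m + j);
      s += term;
      if (std::fabs(term) < 1e-17 * std::fabs(s)) break;
      cj *= (-b) / (j + 1);
    }
    return std::exp(-lam * dt) * s;
  }
  double E1 = std::exp(-lam * dt);
  double S = 0.0, u = 1.0;
  for (int k = 0; k < m; ++k) {
    S += u;
    u *= bt / (k + 1);
  }
  return factm1 / ipow(b, m) * (E1 - E2 * S);
}

// Central amount at dt after a unit bioavailable bolus through an
// (n_transit+1)-stage chain at rate ktr, i.e. Erlang(m, ktr) input.
static double erlang_central(double dt, double ktr, int m, double factm1,
                             const Disp& d) {
  double E2 = std::exp(-ktr * dt);
  double acc = 0.0;
  for (int i = 0; i < 3; ++i)
    acc += d.c[i] * conv_term(dt, d.lam[i], ktr, E2, m, factm1);
  double out = ipow(ktr, m) / factm1 * acc;
  return out > 0 ? out : 0.0;
}

static double factorial(int n) {
  double f = 1.0;
  for (int i = 2; i <= n; ++i) f *= i;
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_profile_conc(NumericVector times, NumericVector dose_time,
                               NumericVector dose_mass, NumericVector dose_ktr,
                               int n_transit, double CL, double Vc, double Q1,
                               double Vp1, double Q2, double Vp2) {
  Disp d = disposition(CL, Vc, Q1, Vp1, Q2, Vp2);
  if (!d.ok) stop("invalid disposition parameters");
  int m = n_transit + 1;
  double factm1 = factorial(m - 1);
  int nt = times.size(), nd = dose_time.size();
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    double A = 0.0;
    for (int j = 0; j < nd; ++j) {
      double dt = times[i] - dose_time[j];
      if (dt > 0)
        A += dose_mass[j] * erlang_central(dt, dose_ktr[j], m, factm1, d);
    }
    out[i] = A / Vc * 1000.0;  // mg, L -> ng/ml
  }
  return out;
}

// ---------------------------------------------------------------------------
// Model / subject plumbing for the FOCE-I engine
// ---------------------------------------------------------------------------

// eta layout (full): 0..4 BSV on CL, Vc, Vp1, Q2, MTT;
//                    5..4+n_occ IOV on F per occasion;
//                    5+n_occ..4+2*n_occ IOV on MTT per occasion.
struct Model {
  double th[8];  // CL Vc Q1 Vp1 Q2 Vp2 MTT F
  double dose_slope;
  std::vector<int> rel_param, rel_cov, rel_form;
  std::vector<double> rel_ref, rel_th1, rel_th2;
  double omega_full[32];  // variance per eta slot
  double sigma;
  double ref_wt, allo_cl, allo_v;
  int n_transit, n_occ, q_full;
  double lloq;
};

static Model parse_model(const List& ml) {
  Model M;
  NumericVector th = ml["theta"];
  for (int i = 0; i < 8; ++i) M.th[i] = th[i];
  M.dose_slope = as<double>(ml["dose_slope"]);
  IntegerVector rp = ml["rel_param"], rc = ml["rel_cov"], rf = ml["rel_form"];
  NumericVector rr = ml["rel_ref"], r1 = ml["rel_th1"], r2 = ml["rel_th2"];
  for (int i = 0; i < rp.size(); ++i) {
    M.rel_param.push_back(rp[i]);
    M.rel_cov.push_back(rc[i]);
    M.rel_form.push_back(rf[i]);
    M.rel_ref.push_back(rr[i]);
    M.rel_th1.push_back(r1[i]);
    M.rel_th2.push_back(r2[i]);
  }
  NumericVector om = ml["omega2"];  // CL Vc Vp1 Q2 MTT F_IOV MTT_IOV
  M.sigma = as<double>(ml["sigma"]);
  M.ref_wt = as<double>(ml["ref_wt"]);
  M.allo_cl = as<double>(ml["allo_cl"]);
  M.allo_v = as<double>(ml["allo_v"]);
  M.n_transit = as<int>(ml["n_transit"]);
  M.n_occ = as<int>(ml["n_occ"]);
  M.lloq = as<double>(ml["lloq"]);
  M.q_full = 5 + 2 * M.n_occ;
  for (int i = 0; i < 5; ++i) M.omega_full[i] = om[i];
  for (int o = 0; o < M.n_occ; ++o) {
    M.omega_full[5 + o] = om[5];
    M.omega_full[5 + M.n_occ + o] = om[6];
  }
  return M;
}

struct Subj {
  arma::vec tobs, y;        // y = log observed conc (NA-free; blq rows carry 0)
  arma::ivec blq;
  arma::vec dose_time, dose_amt;  // amt = mg base
  arma::ivec dose_occ;            // 1-based
  double wt;
  arma::vec covs;
};

static Subj parse_subj(const List& sl) {
  Subj s;
  s.tobs = as<arma::vec>(sl["tobs"]);
  s.y = as<arma::vec>(sl["y"]);
  s.blq = as<arma::ivec>(sl["blq"]);
  s.dose_time = as<arma::vec>(sl["dose_time"]);
  s.dose_amt = as<arma::vec>(sl["dose_amt"]);
  s.dose_occ = as<arma::ivec>(sl["dose_occ"]);
  s.wt = as<double>(sl["wt"]);
  s.covs = as<arma::vec>(sl["covs"]);
  return s;
}

static bool rel_multiplier(const Model& M, const Subj& s, int param, double* mult) {
  double m = 1.0;
  for (size_t i = 0; i < M.rel_param.size(); ++i) {
    if (M.rel_param[i] != param) continue;
    double x = s.covs[M.rel_cov[i]];
    double r = M.rel_ref[i];
    double f;
    switch (M.rel_form[i]) {
      case 1: f = 1.0 + M.rel_th1[i] * (x - r); break;          // linear
      case 2: f = std::pow(x / r, M.rel_th1[i]); break;         // power
      case 3: f = std::exp(M.rel_th1[i] * (x - r)); break;      // exponential
      case 4: f = (x < r) ? 1.0 + M.rel_th1[i] * (x - r)        // piecewise
                          : 1.0 + M.rel_th2[i] * (x - r); break;
      default: f = 1.0;
    }
    if (!(f > 0) || !std::isfinite(f)) return false;
    m *= f;
  }
  *mult = m;
  return true;
}

struct IndivPars {
  double CL, Vc, Q1, Vp1, Q2, Vp2;
  std::vector<double> Focc, ktrocc;
  bool ok;
};

static IndivPars build_individual(const Model& M, const Subj& s,
                                  const double* eta) {
  IndivPars p;
  p.ok = true;
  double wtr = s.wt / M.ref_wt;
  double acl = std::pow(wtr, M.allo_cl), av = std::pow(wtr, M.allo_v);
  double mult;
  if (!rel_multiplier(M, s, 1, &mult)) { p.ok = false; return p; }
  p.CL = M.th[0] * acl * mult * std::exp(eta[0]);
  if (!rel_multiplier(M, s, 2, &mult)) { p.ok = false; return p; }
  p.Vc = M.th[1] * av * mult * std::exp(eta[1]);
  if (!rel_multiplier(M, s, 3, &mult)) { p.ok = false; return p; }
  p.Q1 = M.th[2] * acl * mult;
  if (!rel_multiplier(M, s, 4, &mult)) { p.ok = false; return p; }
  p.Vp1 = M.th[3] * av * mult * std::exp(eta[2]);
  if (!rel_multiplier(M, s, 5, &mult)) { p.ok = false; return p; }
  p.Q2 = M.th[4] * acl * mult * std::exp(eta[3]);
  if (!rel_multiplier(M, s, 6, &mult)) { p.ok = false; return p; }
  p.Vp2 = M.th[5] * av * mult;
  double multMTT, multF;
  if (!rel_multiplier(M, s, 7, &multMTT) || !rel_multiplier(M, s, 8, &multF)) {
    p.ok = false; return p;
  }
  p.Focc.resize(M.n_occ);
  p.ktrocc.resize(M.n_occ);
  for (int o = 0; o < M.n_occ; ++o) {
    double occ_eff = 1.0 + M.dose_slope * o;
    if (!(occ_eff > 0)) { p.ok = false; return p; }
    p.Focc[o] = M.th[7] * occ_eff * multF * std::exp(eta[5 + o]);
    double MTT = M.th[6] * multMTT * std::exp(eta[4] + eta[5 + M.n_occ + o]);
    if (!(MTT > 0)) { p.ok = false; return p; }
    p.ktrocc[o] = (M.n_transit + 1) / MTT;
  }
  if (!(p.CL > 0 && p.Vc > 0 && p.Q1 >= 0 && p.Vp1 > 0 && p.Q2 >= 0 &&
        p.Vp2 > 0))
    p.ok = false;
  return p;
}

// Per-dose concentration contributions (obs x dose) and their log-sum.
struct PredWork {
  IndivPars p;
  Disp d;
  arma::mat C;
  arma::vec tot, f;
};

static void fill_cols(const Model& M, const Subj& s, const IndivPars& p,
                      const Disp& d, const std::vector<int>& cols,
                      arma::mat& C) {
  int m = M.n_transit + 1;
  double factm1 = factorial(m - 1);
  int nt = s.tobs.n_elem;
  for (size_t jj = 0; jj < cols.size(); ++jj) {
    int j = cols[jj];
    int o = s.dose_occ[j] - 1;
    double scale = s.dose_amt[j] * p.Focc[o] / p.Vc * 1000.0;
    for (int i = 0; i < nt; ++i) {
      double dt = s.tobs[i] - s.dose_time[j];
      C(i, j) = dt > 0
        ? scale * erlang_central(dt, p.ktrocc[o], m, factm1, d) : 0.0;
    }
  }
}

static bool pred_contrib(const Model& M, const Subj& s, const double* eta,
                         PredWork& w) {
  w.p = build_individual(M, s, eta);
  if (!w.p.ok) return false;
  w.d = disposition(w.p.CL, w.p.Vc, w.p.Q1, w.p.Vp1, w.p.Q2, w.p.Vp2);
  if (!w.d.ok) return false;
  int nt = s.tobs.n_elem, nd = s.dose_time.n_elem;
  w.C.set_size(nt, nd);
  std::vector<int> all(nd);
  for (int j = 0; j < nd; ++j) all[j] = j;
  fill_cols(M, s, w.p, w.d, all, w.C);
  w.tot = arma::sum(w.C, 1);
  w.f.set_size(nt);
  for (int i = 0; i < nt; ++i)
    w.f[i] = std::log(std::max(w.tot[i], 1e-250));
  return true;
}

// log predicted concentration at the subject's observation times
static bool pred_log_conc(const Model& M, const Subj& s, const double* eta,
                          arma::vec& f) {
  PredWork w;
  if (!pred_contrib(M, s, eta, w)) return false;
  f = w.f;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_pred_subject(List subject, List model, NumericVector eta_full) {
  Model M = parse_model(model);
  Subj s = parse_subj(subject);
  if ((int)eta_full.size() != M.q_full) stop("eta length mismatch");
  arma::vec f;
  if (!pred_log_conc(M, s, REAL(eta_full), f))
    stop("invalid individual parameters");
  return wrap(f);
}

// ---------------------------------------------------------------------------
// FOCE-I conditional objective for one subject
// G(eta) = sum_obs [log(2 pi s^2) + (y-f)^2/s^2]
//        + sum_blq  -2 log Phi((log lloq - f)/s)
//        + sum_act  eta^2 / omega^2
// iOFV   = G(eta_hat) + sum_act log omega^2 + log det(Omega^-1 + J' W J)
// ---------------------------------------------------------------------------

static double G_of_f(const Model& M, const Subj& s, const double* eta,
                     const arma::vec& f, const std::vector<int>& act) {
  double s2 = M.sigma * M.sigma;
  double llq = std::log(M.lloq);
  double G = 0.0;
  for (size_t j = 0; j < f.n_elem; ++j) {
    if (s.blq[j]) {
      double h = (llq - f[j]) / M.sigma;
      G += -2.0 * R::pnorm(h, 0.0, 1.0, 1, 1);
    } else {
      double r = s.y[j] - f[j];
      G += std::log(2.0 * M_PI * s2) + r * r / s2;
    }
  }
  for (size_t k = 0; k < act.size(); ++k) {
    double e = eta[act[k]];
    G += e * e / M.omega_full[act[k]];
  }
  return G;
}

static double subj_G(const Model& M, const Subj& s, const double* eta,
                     PredWork& w, const std::vector<int>& act) {
  if (!pred_contrib(M, s, eta, w)) return R_PosInf;
  return G_of_f(M, s, eta, w.f, act);
}

// Jacobian of f wrt active etas.  Bioavailability occasion etas enter each
// dose contribution multiplicatively, so their columns are exact
// (share-of-total); occasion-level MTT etas only touch that occasion's
// dose columns; the remaining etas use forward differences with a full
// profile recomputation.
static bool subj_J(const Model& M, const Subj& s, const double* eta,
                   const PredWork& w0, const std::vector<int>& act,
                   arma::mat& J) {
  int q = act.size(), n = w0.f.n_elem, nd = s.dose_time.n_elem;
  J.set_size(n, q);
  double h = 1e-5;
  std::vector<double> e2(eta, eta + M.q_full);
  for (int k = 0; k < q; ++k) {
    int idx = act[k];
    if (idx >= 5 && idx < 5 + M.n_occ) {           // F IOV: analytic
      int o = idx - 5;
      for (int i = 0; i < n; ++i) {
        double part = 0.0;
        for (int j = 0; j < nd; ++j)
          if (s.dose_occ[j] - 1 == o) part += w0.C(i, j);
        J(i, k) = w0.tot[i] > 1e-250 ? part / w0.tot[i] : 0.0;
      }
    } else if (idx >= 5 + M.n_occ) {               // MTT IOV: partial FD
      int o = idx - 5 - M.n_occ;
      e2[idx] = eta[idx] + h;
      IndivPars pk = build_individual(M, s, e2.data());
      e2[idx] = eta[idx];
      if (!pk.ok) return false;
      std::vector<int> cols;
      for (int j = 0; j < nd; ++j)
        if (s.dose_occ[j] - 1 == o) cols.push_back(j);
      arma::mat Ck = w0.C;
      fill_cols(M, s, pk, w0.d, cols, Ck);
      for (int i = 0; i < n; ++i) {
        double tot = w0.tot[i];
        for (size_t jj = 0; jj < cols.size(); ++jj)
          tot += Ck(i, cols[jj]) - w0.C(i, cols[jj]);
        J(i, k) = (std::log(std::max(tot, 1e-250)) - w0.f[i]) / h;
      }
    } else if (idx == 4) {                         // MTT BSV: same disposition
      e2[idx] = eta[idx] + h;
      IndivPars pk = build_individual(M, s, e2.data());
      e2[idx] = eta[idx];
      if (!pk.ok) return false;
      arma::mat Ck(n, nd);
      std::vector<int> all(nd);
      for (int j = 0; j < nd; ++j) all[j] = j;
      fill_cols(M, s, pk, w0.d, all, Ck);
      arma::vec tot = arma::sum(Ck, 1);
      for (int i = 0; i < n; ++i)
        J(i, k) = (std::log(std::max(tot[i], 1e-250)) - w0.f[i]) / h;
    } else {                                       // disposition etas: full FD
      e2[idx] = eta[idx] + h;
      arma::vec fk;
      if (!pred_log_conc(M, s, e2.data(), fk)) return false;
      e2[idx] = eta[idx];
      J.col(k) = (fk - w0.f) / h;
    }
  }
  return true;
}

// gradient of G/2 and Gauss-Newton Hessian of G/2 at eta
static void grad_hess(const Model& M, const Subj& s, const double* eta,
                      const arma::vec& f, const arma::mat& J,
                      const std::vector<int>& act, arma::vec& g, arma::mat& H) {
  int q = act.size(), n = f.n_elem;
  double s2 = M.sigma * M.sigma;
  double llq = std::log(M.lloq);
  arma::vec w(n), u(n);
  for (int j = 0; j < n; ++j) {
    if (s.blq[j]) {
      double h = (llq - f[j]) / M.sigma;
      double lphi = R::dnorm(h, 0.0, 1.0, 1);
      double lPhi = R::pnorm(h, 0.0, 1.0, 1, 1);
      double mills = std::exp(lphi - lPhi);
      u[j] = mills / M.sigma;                       // d(-logPhi)/df
      w[j] = mills * (h + mills) / s2;              // d2(-logPhi)/df2 > 0
    } else {
      u[j] = -(s.y[j] - f[j]) / s2;
      w[j] = 1.0 / s2;
    }
  }
  g = J.t() * u;
  H = J.t() * (J.each_col() % w);
  for (int k = 0; k < q; ++k) {
    double om = M.omega_full[act[k]];
    g[k] += eta[act[k]] / om;
    H(k, k) += 1.0 / om;
  }
}

struct InnerResult {
  double iofv;
  arma::vec eta_full;
  bool converged;
  bool ok;
};

static InnerResult inner_fit(const Model& M, const Subj& s,
                             const std::vector<int>& act,
                             const arma::vec& eta_start) {
  InnerResult res;
  int q = act.size();
  res.eta_full = eta_start;  // full-length; inactive stay 0
  std::vector<double> eta(res.eta_full.begin(), res.eta_full.end());
  PredWork w;
  double G = subj_G(M, s, eta.data(), w, act);
  if (!std::isfinite(G)) {
    // fall back to eta = 0
    std::fill(eta.begin(), eta.end(), 0.0);
    G = subj_G(M, s, eta.data(), w, act);
    if (!std::isfinite(G)) { res.ok = false; res.converged = false; res.iofv = R_PosInf; return res; }
  }
  res.ok = true;
  res.converged = (q == 0);
  arma::mat J, H;
  arma::vec g;
  if (q > 0) {
    for (int iter = 0; iter < 60; ++iter) {
      if (!subj_J(M, s, eta.data(), w, act, J)) break;
      grad_hess(M, s, eta.data(), w.f, J, act, g, H);
      if (arma::norm(g, "inf") < 1e-7 * (1.0 + std::fabs(G))) {
        res.converged = true;
        break;
      }
      arma::vec step;
      bool solved = arma::solve(step, H, -g, arma::solve_opts::likely_sympd +
                                                 arma::solve_opts::no_approx);
      if (!solved) {
        arma::mat Hr = H + arma::eye(q, q) * (1e-6 + arma::trace(H) / q * 1e-6);
        if (!arma::solve(step, Hr, -g)) break;
      }
      double alpha = 1.0;
      bool improved = false;
      std::vector<double> etry(eta);
      PredWork wtry;
      for (int ls = 0; ls < 14; ++ls) {
        for (int k = 0; k < q; ++k) etry[act[k]] = eta[act[k]] + alpha * step[k];
        double Gt = subj_G(M, s, etry.data(), wtry, act);
        if (std::isfinite(Gt) && Gt < G + 1e-12) {
          eta = etry;
          w = wtry;
          double dec = G - Gt;
          G = Gt;
          improved = true;
          if (dec < 1e-10 * (1.0 + std::fabs(G))) {
            // recheck gradient next loop; tiny decrease usually means done
          }
          break;
        }
        alpha *= 0.5;
      }
      if (!improved) {
        // stuck; accept current point if gradient smallish
        res.converged = (arma::norm(g, "inf") < 1e-3 * (1.0 + std::fabs(G)));
        break;
      }
    }
    // final curvature at the mode
    if (!subj_J(M, s, eta.data(), w, act, J)) {
      res.ok = false;
      res.iofv = R_PosInf;
      return res;
    }
    grad_hess(M, s, eta.data(), w.f, J, act, g, H);
    if (arma::norm(g, "inf") < 1e-5 * (1.0 + std::fabs(G))) res.converged = true;
  }
  double iofv = G;
  if (q > 0) {
    double ld, sign;
    arma::log_det(ld, sign, H);
    if (sign <= 0 || !std::isfinite(ld)) {
      res.ok = false;
      res.iofv = R_PosInf;
      return res;
    }
    for (int k = 0; k < q; ++k) iofv += std::log(M.omega_full[act[k]]);
    iofv += ld;
  }
  for (int k = 0; k < M.q_full; ++k) res.eta_full[k] = eta[k];
  res.iofv = iofv;
  return res;
}

// [[Rcpp::export]]
List cpp_focei(List subjects, List model, NumericMatrix eta_warm) {
  Model M = parse_model(model);
  std::vector<int> act;
  for (int k = 0; k < M.q_full; ++k)
    if (M.omega_full[k] > 0) act.push_back(k);
  int ns = subjects.size();
  if (eta_warm.nrow() != ns || eta_warm.ncol() != M.q_full)
    stop("eta_warm dimension mismatch");
  NumericVector iofv(ns);
  NumericMatrix eta_out(ns, M.q_full);
  LogicalVector conv(ns), ok(ns);
  double total = 0.0;
  for (int i = 0; i < ns; ++i) {
    Subj s = parse_subj(subjects[i]);
    arma::vec e0(M.q_full, arma::fill::zeros);
    for (int k = 0; k < M.q_full; ++k) e0[k] = eta_warm(i, k);
    InnerResult r = inner_fit(M, s, act, e0);
    iofv[i] = r.iofv;
    conv[i] = r.converged;
    ok[i] = r.ok;
    for (int k = 0; k < M.q_full; ++k) eta_out(i, k) = r.eta_full[k];
    total += r.iofv;
  }
  return List::create(_["ofv"] = total, _["iofv"] = iofv, _["eta"] = eta_out,
                      _["converged"] = conv, _["ok"] = ok);
}

// [[Rcpp::export]]
double cpp_subject_G(List subject, List model, NumericVector eta_full) {
  // conditional -2 log-likelihood + eta prior quadratic form (test hook)
  Model M = parse_model(model);
  Subj s = parse_subj(subject);
  std::vector<int> act;
  for (int k = 0; k < M.q_full; ++k)
    if (M.omega_full[k] > 0) act.push_back(k);
  PredWork w;
  return subj_G(M, s, REAL(eta_full), w, act);
}
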