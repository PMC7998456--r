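#include <Rcpp.h>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Batched FOCE-I inner problems for the two model stages. For each subject
// the joint -2 log posterior over its random effects
//   g(eta) = sum_j [ log(2 pi v_j) + (y_j - f_j)^2 / v_j ]
//            + q log(2 pi) + log|Omega| + eta' Omega^-1 eta
// is minimized by damped Gauss-Newton with finite-difference prediction
// Jacobians, and the Laplace/FOCE-I marginal contribution
//   ofv_i = g(etahat) - q log(2 pi) + log det(H/2),  H = 2 J'DJ + 2 Oinv
// is returned. Omega is diagonal. The caller retries non-converged
// subjects on a slower, more forgiving path.
// ---------------------------------------------------------------------------

typedef std::function<bool(const double*, double*)> PredFn;  // eta -> f

static const double TWOPI = 6.283185307179586;

// Cholesky of symmetric q x q (row-major), in place; returns false if not PD.
static bool chol_small(std::vector<double>& A, int q) {
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * q + j];
      for (int k = 0; k < j; ++k) s -= A[i * q + k] * A[j * q + k];
      if (i == j) {
        if (s <= 0 || !R_finite(s)) return false;
        A[i * q + i] = std::sqrt(s);
      } else {
        A[i * q + j] = s / A[j * q + j];
      }
    }
  }
  return true;
}

static void chol_solve(const std::vector<double>& L, int q,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> z(q);
  for (int i = 0; i < q; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * q + k] * z[k];
    z[i] = s / L[i * q + i];
  }
  for (int i = q - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < q; ++k) s -= L[k * q + i] * x[k];
    x[i] = s / L[i * q + i];
  }
}

struct InnerResult {
  std::vector<double> eta;
  double ofv;
  bool ok;
};

// g evaluation; returns 1e10 on invalid predictions
static double eval_g(const PredFn& pred, const double* y, int n, int q,
                     const double* eta, double sigma2, bool prop,
                     const double* oinv, double logdetO,
                     std::vector<double>& f, std::vector<double>& v,
                     std::vector<double>& e, bool& valid) {
  valid = false;
  if (!pred(eta, f.data())) return 1e10;
  double g = 0;
  for (int j = 0; j < n; ++j) {
    if (!R_finite(f[j])) return 1e10;
    double vj = prop ? sigma2 * f[j] * f[j] : sigma2;
    if (prop && f[j] <= 0) return 1e10;
    e[j] = y[j] - f[j];
    v[j] = vj;
    g += std::log(TWOPI * vj) + e[j] * e[j] / vj;
  }
  for (int k = 0; k < q; ++k) g += oinv[k] * eta[k] * eta[k];
  g += q * std::log(TWOPI) + logdetO;
  if (!R_finite(g)) return 1e10;
  valid = true;
  return g;
}

struct GnState {
  std::vector<double> eta, f, v, e;
  double g;
  double gmax;   // inf-norm of the gradient at exit
  bool stationary;
};

// One damped-GN descent from a given start; returns the reached state.
static bool gn_descend(const PredFn& pred, const double* y, int n, int q,
                       double sigma2, bool prop, const double* oinv,
                       double logdetO, const std::vector<double>& start,
                       int maxit, GnState& st) {
  st.eta = start;
  st.f.assign(n, 0.0); st.v.assign(n, 0.0); st.e.assign(n, 0.0);
  st.gmax = R_PosInf;
  st.stationary = false;
  bool valid;
  st.g = eval_g(pred, y, n, q, st.eta.data(), sigma2, prop, oinv, logdetO,
                st.f, st.v, st.e, valid);
  if (!valid) return false;
  const double h = 1e-4;
  double lam = 1e-8;
  std::vector<double> J(n * q), grad(q), H(q * q), L(q * q), delta(q),
      etry(q), fp(n), fm(n), fw(n), vtmp(n), etmp(n);
  bool done = false;
  for (int it = 0; it < maxit && !done; ++it) {
    bool jok = true;
    for (int k = 0; k < q && jok; ++k) {
      std::vector<double> ep(st.eta), em(st.eta);
      ep[k] += h; em[k] -= h;
      jok = pred(ep.data(), fp.data()) && pred(em.data(), fm.data());
      if (jok)
        for (int j = 0; j < n; ++j) {
          double d = (fp[j] - fm[j]) / (2 * h);
          if (!R_finite(d)) { jok = false; break; }
          J[j * q + k] = d;
        }
    }
    if (!jok) return false;
    double gmax = 0;
    for (int k = 0; k < q; ++k) {
      double s = 2 * oinv[k] * st.eta[k];
      for (int j = 0; j < n; ++j) {
        double w = prop
          ? 2 / st.f[j] - 2 * st.e[j] / st.v[j]
            - 2 * st.e[j] * st.e[j] / (st.v[j] * st.f[j])
          : -2 * st.e[j] / st.v[j];
        s += J[j * q + k] * w;
      }
      grad[k] = s;
      gmax = std::max(gmax, std::fabs(s));
    }
    st.gmax = gmax;
    if (gmax < 1e-6 * (1 + std::fabs(st.g))) { done = true; break; }
    for (int a = 0; a < q; ++a)
      for (int b = 0; b <= a; ++b) {
        double s = 0;
        for (int j = 0; j < n; ++j)
          s += J[j * q + a] * J[j * q + b] / st.v[j];
        H[a * q + b] = H[b * q + a] = 2 * s + (a == b ? 2 * oinv[a] : 0.0);
      }
    bool accepted = false;
    for (int t = 0; t < 6 && !accepted; ++t) {
      L = H;
      for (int a = 0; a < q; ++a) L[a * q + a] += lam;
      if (chol_small(L, q)) {
        std::vector<double> ng(q);
        for (int a = 0; a < q; ++a) ng[a] = -grad[a];
        chol_solve(L, q, ng, delta);
        double step = 1.0;
        for (int bt = 0; bt < 6; ++bt) {
          double smax = 0;
          for (int a = 0; a < q; ++a) {
            etry[a] = st.eta[a] + step * delta[a];
            smax = std::max(smax, std::fabs(step * delta[a]));
          }
          bool v2;
          double gnew = eval_g(pred, y, n, q, etry.data(), sigma2, prop,
                               oinv, logdetO, fw, vtmp, etmp, v2);
          if (v2 && gnew <= st.g + 1e-12) {
            accepted = true;
            if (smax < 1e-7) done = true;
            st.eta = etry;
            st.g = gnew;
            st.f = fw; st.v = vtmp; st.e = etmp;
            lam = std::max(lam * 0.3, 1e-10);
            break;
          }
          step /= 4;
        }
      }
      if (!accepted) lam *= 30;
    }
    if (!accepted) break;
  }
  st.stationary = done || st.gmax < 1e-4 * (1 + std::fabs(st.g));
  return true;
}

static InnerResult inner_solve(const PredFn& pred, const double* y, int n,
                               int q, double sigma2, bool prop,
                               const double* oinv, double logdetO,
                               const double* eta0, int maxit,
                               bool exact_hess) {
  InnerResult res;
  res.eta.assign(q, 0.0);
  res.ok = false;
  res.ofv = 1e10;
  GnState st;
  std::vector<double> warm(eta0, eta0 + q);
  bool have = gn_descend(pred, y, n, q, sigma2, prop, oinv, logdetO, warm,
                         maxit, st) && st.stationary;
  bool warm_zero = true;
  for (int k = 0; k < q; ++k) if (warm[k] != 0.0) warm_zero = false;
  if (!have && !warm_zero) {
    // cold restart: warm starts inherited from a different theta can sit in
    // a bad region
    have = gn_descend(pred, y, n, q, sigma2, prop, oinv, logdetO,
                      std::vector<double>(q, 0.0), maxit, st) &&
           st.stationary;
  }
  if (!have) return res;
  res.eta = st.eta;
  // Gauss-Newton (FOCE-I) curvature at the mode
  const double h = 1e-4;
  std::vector<double> J(n * q), fp(n), fm(n), H(q * q), L(q * q);
  for (int k = 0; k < q; ++k) {
    std::vector<double> ep(st.eta), em(st.eta);
    ep[k] += h; em[k] -= h;
    if (!pred(ep.data(), fp.data()) || !pred(em.data(), fm.data())) {
      res.ofv = st.g;
      return res;
    }
    for (int j = 0; j < n; ++j)
      J[j * q + k] = (fp[j] - fm[j]) / (2 * h);
  }
  for (int a = 0; a < q; ++a)
    for (int b = 0; b <= a; ++b) {
      double s = 0;
      for (int j = 0; j < n; ++j)
        s += J[j * q + a] * J[j * q + b] / st.v[j];
      H[a * q + b] = H[b * q + a] = 2 * s + (a == b ? 2 * oinv[a] : 0.0);
    }
  if (exact_hess) {
    // true Laplace: exact Hessian of g by central second differences;
    // keeps the residual-curvature terms the GN form drops (they matter
    // when residual noise is large). Falls back to GN if not PD.
    const double h2 = 1e-3;
    std::vector<double> fw(n), vt(n), et(n), He(q * q);
    bool v2, ok2 = true;
    double g0 = st.g;
    std::vector<double> gp(q), gm(q);
    for (int k = 0; k < q && ok2; ++k) {
      std::vector<double> e1(st.eta), e2(st.eta);
      e1[k] += h2; e2[k] -= h2;
      gp[k] = eval_g(pred, y, n, q, e1.data(), sigma2, prop, oinv, logdetO,
                     fw, vt, et, v2);
      ok2 = ok2 && v2;
      gm[k] = eval_g(pred, y, n, q, e2.data(), sigma2, prop, oinv, logdetO,
                     fw, vt, et, v2);
      ok2 = ok2 && v2;
      if (ok2) He[k * q + k] = (gp[k] - 2 * g0 + gm[k]) / (h2 * h2);
    }
    for (int a = 0; a < q && ok2; ++a)
      for (int b = 0; b < a && ok2; ++b) {
        double gpp, gpm, gmp, gmm;
        std::vector<double> e(st.eta);
        e[a] += h2; e[b] += h2;
        gpp = eval_g(pred, y, n, q, e.data(), sigma2, prop, oinv, logdetO,
                     fw, vt, et, v2); ok2 = ok2 && v2;
        e[b] -= 2 * h2;
        gpm = eval_g(pred, y, n, q, e.data(), sigma2, prop, oinv, logdetO,
                     fw, vt, et, v2); ok2 = ok2 && v2;
        e[a] -= 2 * h2;
        gmm = eval_g(pred, y, n, q, e.data(), sigma2, prop, oinv, logdetO,
                     fw, vt, et, v2); ok2 = ok2 && v2;
        e[b] += 2 * h2;
        gmp = eval_g(pred, y, n, q, e.data(), sigma2, prop, oinv, logdetO,
                     fw, vt, et, v2); ok2 = ok2 && v2;
        if (ok2)
          He[a * q + b] = He[b * q + a] =
            (gpp - gpm - gmp + gmm) / (4 * h2 * h2);
      }
    if (ok2) {
      L = He;
      for (int a = 0; a < q * q; ++a) L[a] *= 0.5;
      if (chol_small(L, q)) {
        double ld = 0;
        for (int a = 0; a < q; ++a) ld += 2 * std::log(L[a * q + a]);
        res.ofv = st.g - q * std::log(TWOPI) + ld;
        res.ok = R_finite(res.ofv);
        if (res.ok) return res;
      }
    }
  }
  L = H;
  for (int a = 0; a < q * q; ++a) L[a] *= 0.5;
  if (!chol_small(L, q)) { res.ofv = st.g; return res; }
  double ld = 0;
  for (int a = 0; a < q; ++a) ld += 2 * std::log(L[a * q + a]);
  res.ofv = st.g - q * std::log(TWOPI) + ld;
  res.ok = R_finite(res.ofv);
  return res;
}

// closed-form 2-compartment infusion concentration into out[(n)]
static bool conc2(const double* t, const int* tgrp, int n, const double* ds,
                  const double* da, const double* dd, const int* dgrp, int m,
                  double CLp, double CLt, double Vc, double Vt, double* out) {
  if (!(R_finite(CLp) && R_finite(CLt) && R_finite(Vc) && R_finite(Vt)) ||
      CLp <= 0 || CLt <= 0 || Vc <= 0 || Vt <= 0)
    return false;
  const double k10 = CLp / Vc, k12 = CLt / Vc, k21 = CLt / Vt;
  const double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  if (disc < 0) disc = 0;
  disc = std::sqrt(disc);
  double l1 = (s + disc) / 2.0, l2 = (s - disc) / 2.0;
  if (l1 - l2 < 1e-10 * l1) l1 = l2 * (1.0 + 1e-8);
  const double c1 = (l1 - k21) / (Vc * (l1 - l2));
  const double c2 = (k21 - l2) / (Vc * (l1 - l2));
  for (int i = 0; i < n; ++i) out[i] = 0;
  for (int j = 0; j < m; ++j) {
    if (da[j] <= 0) continue;
    const double rate = da[j] / dd[j];
    for (int i = 0; i < n; ++i) {
      if (tgrp[i] != dgrp[j]) continue;
      const double te = t[i] - ds[j];
      if (te <= 0) continue;
      const double tp = te > dd[j] ? te - dd[j] : 0.0;
      out[i] += 1000.0 * rate *
        (c1 / l1 * (std::exp(-l1 * tp) - std::exp(-l1 * te)) +
         c2 / l2 * (std::exp(-l2 * tp) - std::exp(-l2 * te)));
    }
  }
  return true;
}

// [[Rcpp::export]]
List foce_pk_batch_cpp(NumericVector t, IntegerVector tgrp, NumericVector y,
                       IntegerVector obs_off, NumericVector dstart,
                       NumericVector damt, NumericVector ddur,
                       IntegerVector dgrp, IntegerVector dose_off,
                       NumericVector CLp_b, NumericVector CLt_b,
                       NumericVector Vc_b, NumericVector Vt_b,
                       IntegerVector bsv_idx, NumericVector omega,
                       double sigma, NumericMatrix eta0, int maxit,
                       bool exact_hess) {
  const int S = obs_off.size() - 1;
  const int q = bsv_idx.size();
  std::vector<double> oinv(q);
  double logdetO = 0;
  for (int k = 0; k < q; ++k) {
    oinv[k] = 1.0 / (omega[k] * omega[k]);
    logdetO += 2 * std::log(omega[k]);
  }
  const double sigma2 = sigma * sigma;
  NumericVector ofv(S);
  NumericMatrix etas(S, q);
  LogicalVector ok(S);
  for (int s = 0; s < S; ++s) {
    const int o0 = obs_off[s], n = obs_off[s + 1] - o0;
    const int d0 = dose_off[s], m = dose_off[s + 1] - d0;
    double base[4] = { CLp_b[s], CLt_b[s], Vc_b[s], Vt_b[s] };
    PredFn pred = [&](const double* eta, double* f) -> bool {
      double p[4] = { base[0], base[1], base[2], base[3] };
      for (int k = 0; k < q; ++k) {
        double ee = std::exp(eta[k]);
        if (!R_finite(ee)) return false;
        p[bsv_idx[k]] *= ee;
      }
      return conc2(&t[o0], &tgrp[o0], n, &dstart[d0], &damt[d0], &ddur[d0],
                   &dgrp[d0], m, p[0], p[1], p[2], p[3], f);
    };
    std::vector<double> e0(q);
    for (int k = 0; k < q; ++k) e0[k] = eta0(s, k);
    InnerResult r = inner_solve(pred, &y[o0], n, q, sigma2, true,
                                oinv.data(), logdetO, e0.data(), maxit,
                                exact_hess);
    ofv[s] = r.ofv;
    ok[s] = r.ok;
    for (int k = 0; k < q; ++k) etas(s, k) = r.eta[k];
  }
  return List::create(_["ofv"] = ofv, _["etas"] = etas, _["ok"] = ok);
}

// [[Rcpp::export]]
List foce_pd_batch_cpp(NumericVector cp_mid, NumericVector f_mid,
                       IntegerVector grid_off, NumericVector dt,
                       IntegerVector occ_off, NumericVector y,
                       IntegerVector obs_i0, NumericVector obs_w,
                       NumericVector obs_tmod, IntegerVector obs_occ_off,
                       double kdeg_b, double kd_b, double kout_b,
                       double hbase, double fe4, double fe10, double kfe,
                       IntegerVector bsv_idx, NumericVector omega,
                       double sigma, NumericMatrix eta0, int maxit,
                       bool exact_hess) {
  // occasions are global: occasion j has grid segment
  // [grid_off[j], grid_off[j+1]) and observations
  // [obs_occ_off[j], obs_occ_off[j+1]); subject s owns occasions
  // [occ_off[s], occ_off[s+1]).
  const int S = occ_off.size() - 1;
  const int q = bsv_idx.size();
  std::vector<double> oinv(q);
  double logdetO = 0;
  for (int k = 0; k < q; ++k) {
    oinv[k] = 1.0 / (omega[k] * omega[k]);
    logdetO += 2 * std::log(omega[k]);
  }
  const double sigma2 = sigma * sigma;
  // meal dilution at the observation times (eta-independent)
  const int nobs_all = y.size();
  std::vector<double> Fe(nobs_all);
  for (int j = 0; j < nobs_all; ++j) {
    double td = obs_tmod[j];
    if (td < 4) Fe[j] = 1.0;
    else if (td < 10) Fe[j] = 1.0 / (1.0 + fe4 * std::exp(-kfe * (td - 4)));
    else Fe[j] = 1.0 / (1.0 + fe4 * std::exp(-kfe * (td - 4)) +
                        fe10 * std::exp(-kfe * (td - 10)));
  }
  NumericVector ofv(S);
  NumericMatrix etas(S, q);
  LogicalVector ok(S);
  std::vector<double> E, H;
  for (int s = 0; s < S; ++s) {
    const int oc0 = occ_off[s], oc1 = occ_off[s + 1];
    const int y0 = obs_occ_off[oc0], y1 = obs_occ_off[oc1];
    const int n = y1 - y0;
    PredFn pred = [&](const double* eta, double* f) -> bool {
      double p[3] = { kdeg_b, kd_b, kout_b };
      for (int k = 0; k < q; ++k) {
        double ee = std::exp(eta[k]);
        if (!R_finite(ee)) return false;
        p[bsv_idx[k]] *= ee;
      }
      const double kdeg = p[0], kd = p[1], kout = p[2];
      if (!(R_finite(kdeg) && R_finite(kd) && R_finite(kout)) ||
          kdeg <= 0 || kout <= 0 || kd < 0)
        return false;
      for (int oc = oc0; oc < oc1; ++oc) {
        const int g0 = grid_off[oc], ng = grid_off[oc + 1] - g0;
        const double ddt = dt[oc];
        E.assign(ng + 1, 1.0);
        H.assign(ng + 1, hbase);
        const double dh = std::exp(-kout * ddt);
        for (int i = 0; i < ng; ++i) {
          const double k1 = kdeg + kd * cp_mid[g0 + i];
          const double ess = kdeg / k1;
          E[i + 1] = ess + (E[i] - ess) * std::exp(-k1 * ddt);
          const double em = 0.5 * (E[i] + E[i + 1]);
          const double hss = hbase * f_mid[g0 + i] * em;
          H[i + 1] = hss + (H[i] - hss) * dh;
        }
        for (int j = obs_occ_off[oc]; j < obs_occ_off[oc + 1]; ++j) {
          const int i0 = obs_i0[j];  // 0-based node index within occasion
          const double w = obs_w[j];
          const double hh = (H[i0] * (1 - w) + H[i0 + 1] * w) * Fe[j];
          if (!(hh > 0) || !R_finite(hh)) return false;
          f[j - y0] = -std::log10(hh);
        }
      }
      return true;
    };
    std::vector<double> e0(q);
    for (int k = 0; k < q; ++k) e0[k] = eta0(s, k);
    InnerResult r = inner_solve(pred, &y[y0], n, q, sigma2, false,
                                oinv.data(), logdetO, e0.data(), maxit,
                                exact_hess);
    ofv[s] = r.ofv;
    ok[s] = r.ok;
    for (int k = 0; k < q; ++k) etas(s, k) = r.eta[k];
  }
  return List::create(_["ofv"] = ofv, _["etas"] = etas, _["ok"] = ok);
}
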