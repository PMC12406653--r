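// Per-subject Laplace approximation to the marginal -2 log-likelihood of the
// one-compartment infusion model with lognormal random effects on CL, V, D1
// and combined additive + proportional residual error. The inner optimization
// (conditional mode of the random effects) runs here, in compiled code, with
// a damped finite-difference Newton method; the outer optimization over the
// population parameters stays in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// concentration at time t under superposed zero-order infusions
static double conc_at(double t, const double *dose_t, const double *dose_amt,
                      int n_dose, double CL, double V, double D1) {
  double k = CL / V;
  double c = 0.0;
  for (int d = 0; d < n_dose; ++d) {
    double td = t - dose_t[d];
    if (td < 0) continue;
    double R0 = dose_amt[d] / D1;
    if (td <= D1) {
      c += R0 / CL * (1.0 - std::exp(-k * td));
    } else {
      c += R0 / CL * (1.0 - std::exp(-k * D1)) * std::exp(-k * (td - D1));
    }
  }
  return c;
}

struct SubjData {
  const double *t, *y;
  int n_obs;
  const double *dose_t, *dose_amt;
  int n_dose;
  double tcl, tv, td1;
  double sa2, sp2;       // sigma_add^2, sigma_prop^2
  const double *omega;   // length 3 (SDs; <=0 means eta fixed at 0)
  const int *free_idx;   // indices (0..2) of free etas
  int k_free;
};

static const double LOG2PI = 1.8378770664093453;

// q(eta) = -2 log p(y|eta) - 2 log p(eta_free)   (includes constants)
static double qfun(const SubjData &s, const double *eta_full) {
  double CL = s.tcl * std::exp(eta_full[0]);
  double V = s.tv * std::exp(eta_full[1]);
  double D1 = s.td1 * std::exp(eta_full[2]);
  if (!std::isfinite(CL) || !std::isfinite(V) || !std::isfinite(D1) ||
      CL <= 0 || V <= 0 || D1 <= 0) return 1e30;
  double q = 0.0;
  for (int j = 0; j < s.n_obs; ++j) {
    double f = conc_at(s.t[j], s.dose_t, s.dose_amt, s.n_dose, CL, V, D1);
    double g = s.sa2 + s.sp2 * f * f;
    if (g <= 1e-14 || !std::isfinite(g)) return 1e30;
    double r = s.y[j] - f;
    q += std::log(2.0 * M_PI * g) + r * r / g;
  }
  for (int m = 0; m < s.k_free; ++m) {
    int i = s.free_idx[m];
    double w2 = s.omega[i] * s.omega[i];
    q += LOG2PI + std::log(w2) + eta_full[i] * eta_full[i] / w2;
  }
  return q;
}

// log-determinant of a symmetric positive-definite k x k matrix (k <= 3) via
// Cholesky; adds a ridge until positive definite.
static double logdet_spd(double H[3][3], int k) {
  double ridge = 0.0;
  for (int attempt = 0; attempt < 60; ++attempt) {
    double L[3][3] = {{0}};
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) {
      for (int j = 0; j <= i && ok; ++j) {
        double sum = H[i][j] + (i == j ? ridge : 0.0);
        for (int m = 0; m < j; ++m) sum -= L[i][m] * L[j][m];
        if (i == j) {
          if (sum <= 0) { ok = false; break; }
          L[i][i] = std::sqrt(sum);
        } else {
          L[i][j] = sum / L[j][j];
        }
      }
    }
    if (ok) {
      double ld = 0.0;
      for (int i = 0; i < k; ++i) ld += 2.0 * std::log(L[i][i]);
      return ld;
    }
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 10.0;
  }
  return 1e30;
}

// Laplace -2 log marginal likelihood contribution of one subject; eta is
// updated in place to the conditional mode (over its free components).
static double subject_ofv(const SubjData &s, double *eta) {
  const int k = s.k_free;
  for (int i = 0; i < 3; ++i) if (s.omega[i] <= 0) eta[i] = 0.0;
  if (k == 0) return qfun(s, eta);

  const double h = 1e-4;
  double x[3];
  for (int m = 0; m < k; ++m) x[m] = eta[s.free_idx[m]];

  double ef[3] = {eta[0], eta[1], eta[2]};
  // local helper: q as a function of the free components
  auto qx = [&](const double *xv) {
    for (int m = 0; m < k; ++m) ef[s.free_idx[m]] = xv[m];
    return qfun(s, ef);
  };

  double q0 = qx(x);
  double grad[3], H[3][3];
  double lambda = 1e-3;
  for (int iter = 0; iter < 60; ++iter) {
    // finite-difference gradient and Hessian of q
    double xp[3], fp[3], fm[3];
    for (int m = 0; m < k; ++m) {
      for (int j = 0; j < k; ++j) xp[j] = x[j];
      xp[m] = x[m] + h; fp[m] = qx(xp);
      xp[m] = x[m] - h; fm[m] = qx(xp);
      grad[m] = (fp[m] - fm[m]) / (2 * h);
      H[m][m] = (fp[m] - 2 * q0 + fm[m]) / (h * h);
    }
    for (int m = 0; m < k; ++m) {
      for (int j = m + 1; j < k; ++j) {
        for (int i2 = 0; i2 < k; ++i2) xp[i2] = x[i2];
        xp[m] += h; xp[j] += h; double fpp = qx(xp);
        xp[j] -= 2 * h; double fpm = qx(xp);
        xp[m] -= 2 * h; double fmm = qx(xp);
        xp[j] += 2 * h; double fmp = qx(xp);
        H[m][j] = H[j][m] = (fpp - fpm - fmp + fmm) / (4 * h * h);
      }
    }
    double gnorm = 0.0;
    for (int m = 0; m < k; ++m) gnorm = std::max(gnorm, std::fabs(grad[m]));
    if (gnorm < 1e-7) break;

    // damped Newton step: solve (H + lambda I) delta = -grad
    bool accepted = false;
    for (int tries = 0; tries < 25 && !accepted; ++tries) {
      double A[3][3], b[3];
      for (int m = 0; m < k; ++m) {
        b[m] = -grad[m];
        for (int j = 0; j < k; ++j)
          A[m][j] = H[m][j] + (m == j ? lambda * (1.0 + std::fabs(H[m][m])) : 0.0);
      }
      // Gaussian elimination (k <= 3)
      double delta[3] = {0, 0, 0};
      bool solved = true;
      {
        double M[3][4];
        for (int m = 0; m < k; ++m) {
          for (int j = 0; j < k; ++j) M[m][j] = A[m][j];
          M[m][k] = b[m];
        }
        for (int c = 0; c < k && solved; ++c) {
          int piv = c;
          for (int r2 = c + 1; r2 < k; ++r2)
            if (std::fabs(M[r2][c]) > std::fabs(M[piv][c])) piv = r2;
          if (std::fabs(M[piv][c]) < 1e-300) { solved = false; break; }
          if (piv != c) for (int j = 0; j <= k; ++j) std::swap(M[piv][j], M[c][j]);
          for (int r2 = 0; r2 < k; ++r2) {
            if (r2 == c) continue;
            double fac = M[r2][c] / M[c][c];
            for (int j = c; j <= k; ++j) M[r2][j] -= fac * M[c][j];
          }
        }
        if (solved) for (int m = 0; m < k; ++m) delta[m] = M[m][k] / M[m][m];
      }
      if (!solved) { lambda *= 10; continue; }
      double xn[3];
      double steplen = 0.0;
      for (int m = 0; m < k; ++m) {
        xn[m] = x[m] + delta[m];
        steplen = std::max(steplen, std::fabs(delta[m]));
      }
      double qn = qx(xn);
      if (qn <= q0 + 1e-12) {
        for (int m = 0; m < k; ++m) x[m] = xn[m];
        bool converged = (q0 - qn < 1e-10 && steplen < 1e-6);
        q0 = qn;
        lambda = std::max(lambda * 0.3, 1e-10);
        accepted = true;
        if (converged) iter = 1000;  // exit outer loop
      } else {
        lambda *= 10;
      }
    }
    if (!accepted) break;  // cannot improve further
  }

  // final Hessian of m(eta) = q/2 at the mode, for the Laplace determinant
  double Hm[3][3];
  {
    double xp[3];
    for (int m = 0; m < k; ++m) {
      for (int j = 0; j < k; ++j) xp[j] = x[j];
      xp[m] = x[m] + h; double fp = qx(xp);
      xp[m] = x[m] - h; double fm = qx(xp);
      Hm[m][m] = 0.5 * (fp - 2 * q0 + fm) / (h * h);
    }
    for (int m = 0; m < k; ++m) {
      for (int j = m + 1; j < k; ++j) {
        for (int i2 = 0; i2 < k; ++i2) xp[i2] = x[i2];
        xp[m] += h; xp[j] += h; double fpp = qx(xp);
        xp[j] -= 2 * h; double fpm = qx(xp);
        xp[m] -= 2 * h; double fmm = qx(xp);
        xp[j] += 2 * h; double fmp = qx(xp);
        Hm[m][j] = Hm[j][m] = 0.5 * (fpp - fpm - fmp + fmm) / (4 * h * h);
      }
    }
  }
  double ld = logdet_spd(Hm, k);
  for (int m = 0; m < k; ++m) eta[s.free_idx[m]] = x[m];
  return q0 - k * LOG2PI + ld;
}

// [[Rcpp::export]]
List ofv_laplace_cpp(IntegerVector obs_start, IntegerVector obs_end,
                     NumericVector obs_t, NumericVector obs_y,
                     IntegerVector dose_start, IntegerVector dose_end,
                     NumericVector dose_t, NumericVector dose_amt,
                     NumericVector tcl, NumericVector tv, NumericVector td1,
                     NumericVector omega, double sigma_add, double sigma_prop,
                     NumericMatrix eta_start) {
  int n_sub = tcl.size();
  NumericMatrix eta(clone(eta_start));
  NumericVector ofv_i(n_sub);
  double om[3] = {omega[0], omega[1], omega[2]};
  int free_idx[3], k_free = 0;
  for (int i = 0; i < 3; ++i) if (om[i] > 0) free_idx[k_free++] = i;

  double total = 0.0;
  for (int s = 0; s < n_sub; ++s) {
    SubjData sd;
    sd.t = &obs_t[obs_start[s]];
    sd.y = &obs_y[obs_start[s]];
    sd.n_obs = obs_end[s] - obs_start[s];
    sd.dose_t = &dose_t[dose_start[s]];
    sd.dose_amt = &dose_amt[dose_start[s]];
    sd.n_dose = dose_end[s] - dose_start[s];
    sd.tcl = tcl[s]; sd.tv = tv[s]; sd.td1 = td1[s];
    sd.sa2 = sigma_add * sigma_add;
    sd.sp2 = sigma_prop * sigma_prop;
    sd.omega = om;
    sd.free_idx = free_idx;
    sd.k_free = k_free;
    // the inner problem is multimodal in the infusion-duration effect (the
    // end-of-infusion kink moves across sample times), so the Newton search
    // is multi-started: warm start, prior mean, and shifted eta_D1.
    double starts[4][3] = {
      {eta(s, 0), eta(s, 1), eta(s, 2)},
      {0.0, 0.0, 0.0},
      {0.0, 0.0, -0.75},
      {0.0, 0.0, 0.75}
    };
    int n_starts = (om[2] > 0) ? 4 : 2;
    double v = R_PosInf, e[3] = {0, 0, 0};
    for (int st = 0; st < n_starts; ++st) {
      double es[3] = {starts[st][0], starts[st][1], starts[st][2]};
      double vs = subject_ofv(sd, es);
      if (vs < v) {
        v = vs;
        e[0] = es[0]; e[1] = es[1]; e[2] = es[2];
      }
    }
    eta(s, 0) = e[0]; eta(s, 1) = e[1]; eta(s, 2) = e[2];
    ofv_i[s] = v;
    total += v;
  }
  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i, _["eta"] = eta);
}

// [[Rcpp::export]]
NumericVector conc_profile_cpp(NumericVector t, NumericVector dose_t,
                               NumericVector dose_amt, double CL, double V,
                               double D1) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = conc_at(t[i], &dose_t[0], &dose_amt[0], dose_t.size(), CL, V, D1);
  return out;
}
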