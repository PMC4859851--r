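// Adaptive Gauss-Hermite marginal log-likelihood and score for a GLMM
// with a single random intercept. Mirrors the R reference backend in
// R/glmm.R; rows must be sorted by group. Families: 0 = binomial(logit),
// 1 = negative binomial(log), 2 = zero-truncated NB(log), 3 = gaussian.

#include <Rcpp.h>
using namespace Rcpp;

static const double ETA_CLAMP = 30.0;

static inline double clamp_eta(double e) {
  return std::max(-ETA_CLAMP, std::min(ETA_CLAMP, e));
}

// d log f / d eta (used by the inner Newton iteration)
static inline double f_d1(int fam, double disp, double y, double eta) {
  switch (fam) {
  case 0:
    return y - 1.0 / (1.0 + std::exp(-eta));
  case 1: {
    double mu = std::exp(clamp_eta(eta));
    return (y - mu) * disp / (disp + mu);
  }
  case 2: {
    double mu = std::exp(clamp_eta(eta));
    double p0 = std::exp(-disp * std::log1p(mu / disp));
    return (y - mu) * disp / (disp + mu) -
      p0 * disp * mu / ((disp + mu) * (1.0 - p0));
  }
  default:
    return (y - eta) / (disp * disp);
  }
}

// d^2 log f / d eta^2
static inline double f_d2(int fam, double disp, double y, double eta) {
  switch (fam) {
  case 0: {
    double p = 1.0 / (1.0 + std::exp(-eta));
    return -p * (1.0 - p);
  }
  case 1: {
    double mu = std::exp(clamp_eta(eta));
    return -disp * mu * (disp + y) / ((disp + mu) * (disp + mu));
  }
  case 2: {
    double mu = std::exp(clamp_eta(eta));
    double th = disp;
    double p0 = std::exp(-th * std::log1p(mu / th));
    double F = p0 * th * th * mu / ((th + mu) * (th + mu) * (1.0 - p0));
    return -th * mu * (th + y) / ((th + mu) * (th + mu)) -
      F * (1.0 - mu / (1.0 - p0));
  }
  default:
    return -1.0 / (disp * disp);
  }
}

// [[Rcpp::export(name = ".agq_core_cpp")]]
List agq_core_cpp(const NumericMatrix& X, const NumericVector& y,
                  const IntegerVector& gstart, int fam,
                  const NumericVector& zk, const NumericVector& lwk,
                  const NumericVector& par, NumericVector bwarm,
                  bool want_grad) {
  const int n = X.nrow(), p = X.ncol(), G = gstart.size() - 1,
            K = zk.size();
  const bool has_disp = fam != 0;
  const double disp = has_disp ? std::exp(par[p]) : 0.0;
  const double sig = std::exp(par[p + (has_disp ? 1 : 0)]);
  const double inv_s2 = 1.0 / (sig * sig);
  const double SQRT2 = 1.4142135623730951;
  const double LOG2PI_HALF = 0.918938533204672742;
  const double lth = has_disp ? std::log(disp) : 0.0;

  // per-row constants of the NB families
  std::vector<double> lgconst, dgconst;
  if (fam == 1 || fam == 2) {
    lgconst.resize(n);
    dgconst.resize(n);
    const double lgth = R::lgammafn(disp), dgth = R::digamma(disp);
    for (int i = 0; i < n; ++i) {
      lgconst[i] = R::lgammafn(y[i] + disp) - lgth - R::lgammafn(y[i] + 1.0);
      dgconst[i] = R::digamma(y[i] + disp) - dgth;
    }
  }

  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * par[j];
    eta0[i] = s;
  }

  // inner Newton for the per-group posterior modes (warm-started)
  std::vector<double> b(bwarm.begin(), bwarm.end());
  std::vector<double> tau(G);
  for (int it = 0; it < 30; ++it) {
    double maxstep = 0.0;
    for (int g = 0; g < G; ++g) {
      double hp = -b[g] * inv_s2, hpp = -inv_s2;
      for (int i = gstart[g]; i < gstart[g + 1]; ++i) {
        double e = eta0[i] + b[g];
        hp += f_d1(fam, disp, y[i], e);
        hpp += f_d2(fam, disp, y[i], e);
      }
      double step = hp / hpp;
      if (step > 4.0) step = 4.0;
      if (step < -4.0) step = -4.0;
      b[g] -= step;
      if (std::fabs(step) > maxstep) maxstep = std::fabs(step);
    }
    if (maxstep < 1e-8) break;
  }
  for (int g = 0; g < G; ++g) {
    double hpp = -inv_s2;
    for (int i = gstart[g]; i < gstart[g + 1]; ++i)
      hpp += f_d2(fam, disp, y[i], eta0[i] + b[g]);
    tau[g] = 1.0 / std::sqrt(-hpp);
  }

  double ll = 0.0;
  NumericVector grad(par.size());
  std::vector<double> hk(K), bk(K), pk(K);
  // caches reused between the likelihood and gradient passes (one group
  // at a time): derivative wrt eta and wrt log(disp) for each (row, node)
  int maxrows = 0;
  for (int g = 0; g < G; ++g)
    maxrows = std::max(maxrows, gstart[g + 1] - gstart[g]);
  std::vector<double> c_d1, c_dd;
  if (want_grad) {
    c_d1.resize((size_t)maxrows * K);
    if (has_disp) c_dd.resize((size_t)maxrows * K);
  }

  for (int g = 0; g < G; ++g) {
    const int r0 = gstart[g], nr = gstart[g + 1] - r0;
    double hmax = -1e300;
    for (int k = 0; k < K; ++k) {
      const double bgk = b[g] + SQRT2 * tau[g] * zk[k];
      bk[k] = bgk;
      double s = -bgk * bgk * inv_s2 / 2.0 - std::log(sig) - LOG2PI_HALF +
        lwk[k];
      for (int i = 0; i < nr; ++i) {
        const int r = r0 + i;
        const double eta = eta0[r] + bgk, yy = y[r];
        double lf, d1v = 0.0, ddv = 0.0;
        switch (fam) {
        case 0: {
          // one exp serves logf and d1: log(1+e^x) = max(x,0)+log1p(e^-|x|)
          const double q = std::exp(-std::fabs(eta));
          const double l1pe = std::max(eta, 0.0) + std::log1p(q);
          lf = yy * eta - l1pe;
          const double pr = (eta >= 0) ? 1.0 / (1.0 + q) : q / (1.0 + q);
          d1v = yy - pr;
          break;
        }
        case 1: {
          const double mu = std::exp(clamp_eta(eta));
          const double ltm = std::log(disp + mu);
          lf = lgconst[r] + disp * (lth - ltm) + yy * (clamp_eta(eta) - ltm);
          d1v = (yy - mu) * disp / (disp + mu);
          ddv = disp * (dgconst[r] + lth + 1.0 - ltm -
                        (yy + disp) / (disp + mu));
          break;
        }
        case 2: {
          const double mu = std::exp(clamp_eta(eta));
          const double ltm = std::log(disp + mu);
          const double lp0 = disp * (lth - ltm);
          const double l1m = (lp0 > -0.6931472)
            ? std::log(-std::expm1(lp0)) : std::log1p(-std::exp(lp0));
          const double p0 = std::exp(lp0);
          lf = lgconst[r] + lp0 + yy * (clamp_eta(eta) - ltm) - l1m;
          d1v = (yy - mu) * disp / (disp + mu) -
            p0 * disp * mu / ((disp + mu) * (1.0 - p0));
          ddv = disp * (dgconst[r] + lth + 1.0 - ltm -
                        (yy + disp) / (disp + mu)) +
            disp * p0 * ((lth - ltm) + mu / (disp + mu)) / (1.0 - p0);
          break;
        }
        default: {
          const double resid = yy - eta;
          lf = -LOG2PI_HALF - std::log(disp) -
            resid * resid / (2.0 * disp * disp);
          d1v = resid / (disp * disp);
          ddv = -1.0 + resid * resid / (disp * disp);
        }
        }
        s += lf;
        if (want_grad) {
          c_d1[(size_t)i * K + k] = d1v;
          if (has_disp) c_dd[(size_t)i * K + k] = ddv;
        }
      }
      hk[k] = s;
      if (s > hmax) hmax = s;
    }
    double se = 0.0;
    for (int k = 0; k < K; ++k) se += std::exp(hk[k] - hmax);
    const double lse = hmax + std::log(se);
    ll += std::log(SQRT2 * tau[g]) + lse;

    if (want_grad) {
      for (int k = 0; k < K; ++k) pk[k] = std::exp(hk[k] - lse);
      for (int i = 0; i < nr; ++i) {
        const int r = r0 + i;
        double w1 = 0.0, wd = 0.0;
        for (int k = 0; k < K; ++k) {
          w1 += pk[k] * c_d1[(size_t)i * K + k];
          if (has_disp) wd += pk[k] * c_dd[(size_t)i * K + k];
        }
        for (int j = 0; j < p; ++j) grad[j] += X(r, j) * w1;
        if (has_disp) grad[p] += wd;
      }
      double gs = 0.0;
      for (int k = 0; k < K; ++k)
        gs += pk[k] * (bk[k] * bk[k] * inv_s2 - 1.0);
      grad[p + (has_disp ? 1 : 0)] += gs;
    }
  }

  NumericVector bout(b.begin(), b.end());
  return List::create(_["ll"] = ll, _["grad"] = grad, _["b"] = bout);
}
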