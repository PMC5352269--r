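#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// The IRF profile is a piecewise-constant density on a uniform grid:
// bin j (0-based) covers [lo + j*dt, lo + (j+1)*dt] and carries mass m[j],
// sum(m) = 1. Convolution with exp(-t/tau) is integrated exactly per bin,
// so the model matches quadrature of the same density to machine precision:
//   B(d) = sum_j m[j]/dt * tau * (exp(-(d-b_j)/tau) - exp(-(d-a_j)/tau))
// over bins with a_j < d (b_j truncated at d for the partial bin).
// For full bins this factorises through prefix sums of m[j]*exp(b_j/tau),
// making evaluation O(1) per gate after an O(nbins) setup per tau.

namespace {

struct Irf {
  double lo, dt;
  const double* mass;
  int n;
};

void irf_prefix(double tau, const Irf& irf, std::vector<double>& G) {
  G.resize(irf.n + 1);
  G[0] = 0.0;
  for (int j = 0; j < irf.n; ++j) {
    double b = irf.lo + (j + 1) * irf.dt;
    G[j + 1] = G[j] + irf.mass[j] * std::exp(b / tau);
  }
}

// convolved basis at delay d; shifting the IRF by +s = evaluation at d - s
double conv_at(double d, double tau, const Irf& irf,
               const std::vector<double>& G) {
  double x = d - irf.lo;
  if (x <= 0.0) return 0.0;
  int k = (int)std::floor(x / irf.dt);
  if (k > irf.n) k = irf.n;
  double out = (1.0 - std::exp(-irf.dt / tau)) * std::exp(-d / tau) * G[k];
  if (k < irf.n) {
    double a = irf.lo + k * irf.dt;
    if (d > a) out += irf.mass[k] * (1.0 - std::exp(-(d - a) / tau));
  }
  return out * (tau / irf.dt);
}

// ---------- linear (weighted LS) solvers for the projected problem ----------

// y ~ a0*X0 + ... + a_{K-1}*X_{K-1}, weights w; gaussian elimination, K <= 3
double wls_solve(const std::vector<const double*>& X, const double* y,
                 const std::vector<double>& w, int n, int K, double* a) {
  double M[3][3] = {{0}}, v[3] = {0};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      v[k] += w[i] * X[k][i] * y[i];
      for (int l = k; l < K; ++l) M[k][l] += w[i] * X[k][i] * X[l][i];
    }
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < k; ++l) M[k][l] = M[l][k];
  double aug[3][4];
  for (int k = 0; k < K; ++k) {
    for (int l = 0; l < K; ++l) aug[k][l] = M[k][l];
    aug[k][K] = v[k];
  }
  for (int col = 0; col < K; ++col) {
    int piv = col;
    for (int r = col + 1; r < K; ++r)
      if (std::abs(aug[r][col]) > std::abs(aug[piv][col])) piv = r;
    if (std::abs(aug[piv][col]) < 1e-300) {
      for (int k = 0; k < K; ++k) a[k] = 0;
      return 1e300;
    }
    if (piv != col)
      for (int j = 0; j <= K; ++j) std::swap(aug[piv][j], aug[col][j]);
    for (int r = col + 1; r < K; ++r) {
      double f = aug[r][col] / aug[col][col];
      for (int j = col; j <= K; ++j) aug[r][j] -= f * aug[col][j];
    }
  }
  for (int r = K - 1; r >= 0; --r) {
    double s = aug[r][K];
    for (int j = r + 1; j < K; ++j) s -= aug[r][j] * a[j];
    a[r] = s / aug[r][r];
  }
  double rss = 0;
  for (int i = 0; i < n; ++i) {
    double pred = 0;
    for (int k = 0; k < K; ++k) pred += a[k] * X[k][i];
    double r = y[i] - pred;
    rss += w[i] * r * r;
  }
  return rss;
}

// ---------- Poisson maximum likelihood for the projected problem ----------
// y_i ~ Poisson( sum_k a_k X_ki + base_i ); the first `namp` coefficients are
// amplitudes constrained >= 0 (active-set clamping); objective is the
// deviance 2*sum(mu - y + y log(y/mu)). Newton with step damping keeping
// mu > 0. Returns the deviance; sets bound=1 when an amplitude is clamped.

double pois_deviance(const std::vector<const double*>& X, const double* y,
                     const double* base, int n, int K, const double* a) {
  double D = 0;
  for (int i = 0; i < n; ++i) {
    double mu = base[i];
    for (int k = 0; k < K; ++k) mu += a[k] * X[k][i];
    if (mu < 1e-12) mu = 1e-12;
    D += mu - y[i];
    if (y[i] > 0) D += y[i] * std::log(y[i] / mu);
  }
  return 2.0 * D;
}

double pois_fit(const std::vector<const double*>& X, const double* y,
                const double* base, int n, int K, int namp, double* a,
                int* bound) {
  // start from weighted LS on (y - base)
  std::vector<double> w(n), yc(n);
  for (int i = 0; i < n; ++i) {
    w[i] = 1.0 / std::max(y[i], 1.0);
    yc[i] = y[i] - base[i];
  }
  wls_solve(X, yc.data(), w, n, K, a);
  std::vector<char> clamped(K, 0);
  for (int k = 0; k < namp; ++k)
    if (a[k] < 0) { a[k] = 0; clamped[k] = 1; }

  std::vector<double> mu(n);
  for (int iter = 0; iter < 40; ++iter) {
    for (int i = 0; i < n; ++i) {
      double m = base[i];
      for (int k = 0; k < K; ++k) m += a[k] * X[k][i];
      mu[i] = std::max(m, 1e-12);
    }
    // release clamped coefficients whose gradient wants them positive
    for (int k = 0; k < namp; ++k)
      if (clamped[k]) {
        double g = 0;
        for (int i = 0; i < n; ++i) g += X[k][i] * (1.0 - y[i] / mu[i]);
        if (g < 0) clamped[k] = 0;  // deviance decreases for a_k > 0
      }
    // free-parameter index map
    std::vector<int> idx;
    for (int k = 0; k < K; ++k) if (!clamped[k]) idx.push_back(k);
    int F = idx.size();
    if (F == 0) break;
    double g[3] = {0, 0, 0}, H[3][3] = {{0}};
    for (int i = 0; i < n; ++i) {
      double r = 1.0 - y[i] / mu[i];
      double q = y[i] / (mu[i] * mu[i]);
      for (int p = 0; p < F; ++p) {
        g[p] += X[idx[p]][i] * r;
        for (int q2 = p; q2 < F; ++q2)
          H[p][q2] += X[idx[p]][i] * X[idx[q2]][i] * q;
      }
    }
    for (int p = 0; p < F; ++p)
      for (int q2 = 0; q2 < p; ++q2) H[p][q2] = H[q2][p];
    // ridge guard
    double tr = 0;
    for (int p = 0; p < F; ++p) tr += H[p][p];
    for (int p = 0; p < F; ++p) H[p][p] += 1e-12 * (tr > 0 ? tr : 1.0);
    // solve H step = -g
    double aug[3][4];
    for (int p = 0; p < F; ++p) {
      for (int q2 = 0; q2 < F; ++q2) aug[p][q2] = H[p][q2];
      aug[p][F] = -g[p];
    }
    bool ok = true;
    for (int col = 0; col < F && ok; ++col) {
      int piv = col;
      for (int r2 = col + 1; r2 < F; ++r2)
        if (std::abs(aug[r2][col]) > std::abs(aug[piv][col])) piv = r2;
      if (std::abs(aug[piv][col]) < 1e-300) { ok = false; break; }
      if (piv != col)
        for (int j = 0; j <= F; ++j) std::swap(aug[piv][j], aug[col][j]);
      for (int r2 = col + 1; r2 < F; ++r2) {
        double f = aug[r2][col] / aug[col][col];
        for (int j = col; j <= F; ++j) aug[r2][j] -= f * aug[col][j];
      }
    }
    if (!ok) break;
    double step[3] = {0, 0, 0};
    for (int r2 = F - 1; r2 >= 0; --r2) {
      double s = aug[r2][F];
      for (int j = r2 + 1; j < F; ++j) s -= aug[r2][j] * step[j];
      step[r2] = s / aug[r2][r2];
    }
    // damping: keep amplitudes >= 0 (clamp on crossing) and mu > 0
    double lam = 1.0, norm = 0;
    for (int p = 0; p < F; ++p) norm += std::abs(step[p]);
    for (int p = 0; p < F; ++p) {
      int k = idx[p];
      if (k < namp && step[p] < 0 && a[k] + step[p] < 0)
        lam = std::min(lam, a[k] > 0 ? -a[k] / step[p] : 0.0);
    }
    double D0 = pois_deviance(X, y, base, n, K, a);
    double anew[3];
    double Dn = D0;
    bool accepted = false;
    for (int half = 0; half < 14 && !accepted; ++half) {
      for (int k = 0; k < K; ++k) anew[k] = a[k];
      for (int p = 0; p < F; ++p) anew[idx[p]] += lam * step[p];
      bool pos = true;
      for (int i = 0; i < n && pos; ++i) {
        double m = base[i];
        for (int k = 0; k < K; ++k) m += anew[k] * X[k][i];
        if (m < 0 && y[i] > 0) pos = false;
      }
      if (pos) {
        Dn = pois_deviance(X, y, base, n, K, anew);
        if (Dn <= D0 + 1e-12) accepted = true;
      }
      if (!accepted) lam *= 0.5;
    }
    if (!accepted) break;  // no improving step: converged (or stuck)
    bool moved = false;
    for (int k = 0; k < K; ++k) {
      if (std::abs(anew[k] - a[k]) > 1e-10 * (std::abs(a[k]) + 1e-6))
        moved = true;
      a[k] = anew[k];
    }
    for (int k = 0; k < namp; ++k)
      if (a[k] <= 0) { a[k] = 0; clamped[k] = 1; }
    if (!moved || std::abs(D0 - Dn) < 1e-10 * (std::abs(D0) + 1)) break;
  }
  *bound = 0;
  for (int k = 0; k < namp; ++k) if (clamped[k]) *bound = 1;
  return pois_deviance(X, y, base, n, K, a);
}

void weights_from(const std::vector<double>& mu, const double* base,
                  std::vector<double>& w, double floorv, int n) {
  for (int i = 0; i < n; ++i)
    w[i] = 1.0 / std::max(mu[i] + base[i], floorv);
}

// golden-section minimization of f over [lo, hi] in log-tau
template <class F>
double golden_log(F f, double lo, double hi, int iters = 32) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = f(std::exp(c)), fd = f(std::exp(d));
  for (int it = 0; it < iters; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = f(std::exp(c));
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = f(std::exp(d));
    }
  }
  return std::exp((a + b) / 2);
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_conv_basis(NumericVector taus, NumericVector delays,
                             double irf_lo, double irf_dt,
                             NumericVector irf_mass, double shift) {
  Irf irf{irf_lo + shift, irf_dt, irf_mass.begin(), (int)irf_mass.size()};
  int ng = delays.size(), nt = taus.size();
  NumericMatrix out(ng, nt);
  std::vector<double> G;
  for (int t = 0; t < nt; ++t) {
    irf_prefix(taus[t], irf, G);
    for (int g = 0; g < ng; ++g)
      out(g, t) = conv_at(delays[g], taus[t], irf, G);
  }
  return out;
}

// Pixel-wise monoexponential fit by variable projection over tau.
// counts: ngates x npix raw counts (camera background removed);
// baseline: ngates x npix known additive background (TVB), zeros if none;
// mode: 0 unweighted LS, 1 Poisson-weighted LS (model weights, n_reweight
// passes), 2 Poisson MLE (deviance; the default for low-count pixels).
// Grid search over tau (linear parameters profiled out per candidate)
// followed by golden-section refinement between the grid neighbours.
// flag: 0 ok, 1 tau at grid edge, 2 amplitude clamped at zero.
//' @noRd
// [[Rcpp::export]]
List cpp_fit_mono_px(NumericMatrix counts, NumericMatrix baseline,
                     NumericVector delays, double irf_lo, double irf_dt,
                     NumericVector irf_mass, NumericVector shifts,
                     NumericVector tau_grid, bool fit_offset, int mode,
                     int n_reweight, double w_floor) {
  int ng = counts.nrow(), npix = counts.ncol(), ntau = tau_grid.size();
  Irf irf{irf_lo, irf_dt, irf_mass.begin(), (int)irf_mass.size()};
  std::vector<std::vector<double> > Gs(ntau);
  for (int t = 0; t < ntau; ++t) irf_prefix(tau_grid[t], irf, Gs[t]);
  int K = fit_offset ? 2 : 1;

  NumericVector tau_out(npix), amp_out(npix), off_out(npix), obj_out(npix);
  IntegerVector flag_out(npix);
  std::vector<double> b(ng), ones(ng, 1.0), w(ng), yc(ng), mu(ng), objg(ntau);

  for (int px = 0; px < npix; ++px) {
    const double* y = &counts(0, px);
    const double* base = &baseline(0, px);
    double s = shifts[px];
    std::vector<const double*> X{b.data(), ones.data()};
    double a[3] = {0, 0, 0};
    int bnd = 0;

    auto eval_tau = [&](double tau, const std::vector<double>* Gp) -> double {
      std::vector<double> Gloc;
      if (!Gp) { irf_prefix(tau, irf, Gloc); Gp = &Gloc; }
      for (int g = 0; g < ng; ++g)
        b[g] = conv_at(delays[g] - s, tau, irf, *Gp);
      if (mode == 2) return pois_fit(X, y, base, ng, K, 1, a, &bnd);
      return wls_solve(X, yc.data(), w, ng, K, a);
    };

    if (mode != 2) {
      for (int g = 0; g < ng; ++g) yc[g] = y[g] - base[g];
      if (mode == 1) for (int g = 0; g < ng; ++g)
        w[g] = 1.0 / std::max(y[g], w_floor);
      else std::fill(w.begin(), w.end(), 1.0);
    }

    int best = 0;
    for (int pass = 0; pass <= (mode == 1 ? n_reweight : 0); ++pass) {
      double bestv = R_PosInf;
      for (int t = 0; t < ntau; ++t) {
        objg[t] = eval_tau(tau_grid[t], &Gs[t]);
        if (objg[t] < bestv) { bestv = objg[t]; best = t; }
      }
      if (mode == 1 && pass < n_reweight) {
        eval_tau(tau_grid[best], &Gs[best]);
        for (int g = 0; g < ng; ++g)
          mu[g] = a[0] * b[g] + (fit_offset ? a[1] : 0.0);
        weights_from(mu, base, w, w_floor, ng);
      }
    }
    double tau_hat;
    int flag = 0;
    if (best == 0 || best == ntau - 1) {
      flag = 1;
      tau_hat = tau_grid[best];
    } else {
      tau_hat = golden_log([&](double t) { return eval_tau(t, nullptr); },
                           tau_grid[best - 1], tau_grid[best + 1]);
    }
    double obj = eval_tau(tau_hat, nullptr);
    if (mode != 2 && a[0] < 0) flag = 2;
    if (mode == 2 && bnd) flag = 2;
    tau_out[px] = tau_hat;
    amp_out[px] = a[0];
    off_out[px] = fit_offset ? a[1] : 0.0;
    obj_out[px] = obj;
    flag_out[px] = flag;
  }
  return List::create(_["tau"] = tau_out, _["amplitude"] = amp_out,
                      _["offset"] = off_out, _["objective"] = obj_out,
                      _["flag"] = flag_out);
}

// Pixel-wise linear fit with both lifetimes fixed:
// y ~ A1*B(tau1) + A2*B(tau2) (+ offset) + baseline.
// Amplitudes are constrained non-negative (beta = A2/(A1+A2)) unless
// constrain = false: the unconstrained solve is used inside the global-fit
// objective, where clamping would bias the profiled lifetimes.
// at_bound: 1 when an amplitude was clamped at zero.
//' @noRd
// [[Rcpp::export]]
List cpp_fit_fraction_px(NumericMatrix counts, NumericMatrix baseline,
                         NumericVector delays, double irf_lo, double irf_dt,
                         NumericVector irf_mass, NumericVector shifts,
                         double tau1, double tau2, bool fit_offset, int mode,
                         int n_reweight, double w_floor,
                         bool constrain = true) {
  int ng = counts.nrow(), npix = counts.ncol();
  Irf irf{irf_lo, irf_dt, irf_mass.begin(), (int)irf_mass.size()};
  std::vector<double> G1, G2;
  irf_prefix(tau1, irf, G1);
  irf_prefix(tau2, irf, G2);
  int K = fit_offset ? 3 : 2;

  NumericVector a1_out(npix), a2_out(npix), off_out(npix), beta_out(npix),
      obj_out(npix);
  IntegerVector bound_out(npix);
  std::vector<double> b1(ng), b2(ng), ones(ng, 1.0), w(ng), yc(ng), mu(ng);

  for (int px = 0; px < npix; ++px) {
    const double* y = &counts(0, px);
    const double* base = &baseline(0, px);
    double s = shifts[px];
    for (int g = 0; g < ng; ++g) {
      b1[g] = conv_at(delays[g] - s, tau1, irf, G1);
      b2[g] = conv_at(delays[g] - s, tau2, irf, G2);
    }
    std::vector<const double*> X{b1.data(), b2.data(), ones.data()};
    double a[3] = {0, 0, 0};
    int bnd = 0;
    double obj;
    if (mode == 2) {
      obj = pois_fit(X, y, base, ng, K, constrain ? 2 : 0, a, &bnd);
    } else {
      for (int g = 0; g < ng; ++g) yc[g] = y[g] - base[g];
      if (mode == 1) for (int g = 0; g < ng; ++g)
        w[g] = 1.0 / std::max(y[g], w_floor);
      else std::fill(w.begin(), w.end(), 1.0);
      for (int pass = 0; pass <= (mode == 1 ? n_reweight : 0); ++pass) {
        obj = wls_solve(X, yc.data(), w, ng, K, a);
        // clamp negative amplitudes by refitting without that basis
        bnd = 0;
        if (constrain && (a[0] < 0 || a[1] < 0)) {
          bnd = 1;
          int drop = a[0] < 0 ? 0 : 1;
          std::vector<const double*> X1{X[1 - drop], ones.data()};
          double a1[3] = {0, 0, 0};
          obj = wls_solve(X1, yc.data(), w, ng, fit_offset ? 2 : 1, a1);
          a[drop] = 0; a[1 - drop] = a1[0];
          a[2] = fit_offset ? a1[1] : 0.0;
          if (a[1 - drop] < 0) a[1 - drop] = 0;
        }
        if (mode == 1 && pass < n_reweight) {
          for (int g = 0; g < ng; ++g)
            mu[g] = a[0] * b1[g] + a[1] * b2[g] + (fit_offset ? a[2] : 0.0);
          weights_from(mu, base, w, w_floor, ng);
        }
      }
    }
    double I0 = a[0] + a[1];
    beta_out[px] = I0 > 0 ? a[1] / I0 : NA_REAL;
    a1_out[px] = a[0]; a2_out[px] = a[1];
    off_out[px] = fit_offset ? a[2] : 0.0;
    obj_out[px] = obj;
    bound_out[px] = bnd;
  }
  return List::create(_["a1"] = a1_out, _["a2"] = a2_out,
                      _["offset"] = off_out, _["beta"] = beta_out,
                      _["objective"] = obj_out, _["at_bound"] = bound_out);
}
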