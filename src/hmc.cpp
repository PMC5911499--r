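#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive Hamiltonian Monte Carlo for a hierarchical Bayesian logistic
// regression with partially pooled participant intercepts:
//
//   logit P(y_i = 1) = x_i' beta + sigma_u * u_raw[g_i]     (non-centered)
//   beta_k  ~ Student-t(prior_df, 0, prior_scale[k])
//   u_raw_j ~ Normal(0, 1)
//   sigma_u ~ half-Student-t(sigma_df, 0, sigma_scale), sampled as
//             log(sigma_u) with the Jacobian term included.
//
// Warmup: dual-averaged step size (Nesterov/Hoffman-Gelman) targeting
// `target_accept`, with a diagonal mass matrix estimated from the middle
// warmup window. Trajectory lengths are jittered to avoid periodicity.
// Uses R's RNG so results are reproducible under set.seed().

static inline double inv_logit(double x) {
  return x > 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}
static inline double pd_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

namespace {

struct HLogit {
  int n, p, J, dim;
  std::vector<double> X;  // column-major n*p
  std::vector<int> y, g;
  std::vector<double> pscale;
  double pdf, sscale, sdf;
  mutable std::vector<double> eta, gsum;

  HLogit(const NumericMatrix& Xm, const IntegerVector& yv,
         const IntegerVector& gv, int J_, const NumericVector& ps,
         double prior_df, double sigma_scale, double sigma_df)
      : n(Xm.nrow()), p(Xm.ncol()), J(J_), dim(Xm.ncol() + J_ + 1),
        X(Xm.begin(), Xm.end()), y(yv.begin(), yv.end()),
        g(gv.begin(), gv.end()), pscale(ps.begin(), ps.end()),
        pdf(prior_df), sscale(sigma_scale), sdf(sigma_df),
        eta(n), gsum(J_) {}

  // log posterior and gradient; theta = (beta[p], u_raw[J], log_sigma)
  double lp_grad(const std::vector<double>& th, std::vector<double>& gr) const {
    const double ls = th[p + J];
    const double sigma = std::exp(ls);
    double lp = 0.0;
    std::fill(gr.begin(), gr.end(), 0.0);
    std::fill(eta.begin(), eta.end(), 0.0);
    std::fill(gsum.begin(), gsum.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double b = th[j];
      if (b != 0.0) {
        const double* col = &X[(size_t)j * n];
        for (int i = 0; i < n; ++i) eta[i] += col[i] * b;
      }
    }
    double su_r = 0.0;  // sum_i r_i * u_raw[g_i]
    for (int i = 0; i < n; ++i) {
      const double u = (J > 0) ? th[p + g[i]] : 0.0;
      const double e = eta[i] + sigma * u;
      lp += (y[i] ? e : 0.0) - pd_log1pexp(e);
      const double r = y[i] - inv_logit(e);
      eta[i] = r;  // reuse buffer as residual
      if (J > 0) { gsum[g[i]] += r; su_r += r * u; }
    }
    for (int j = 0; j < p; ++j) {
      const double* col = &X[(size_t)j * n];
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += col[i] * eta[i];
      gr[j] = s;
    }
    for (int j = 0; j < p; ++j) {  // Student-t prior on beta
      const double b = th[j], s2 = pscale[j] * pscale[j];
      lp += -0.5 * (pdf + 1.0) * std::log1p(b * b / (pdf * s2));
      gr[j] += -(pdf + 1.0) * b / (pdf * s2 + b * b);
    }
    for (int j = 0; j < J; ++j) {  // standard normal on u_raw
      const double u = th[p + j];
      lp += -0.5 * u * u;
      gr[p + j] = sigma * gsum[j] - u;
    }
    // half-t prior on sigma plus log-Jacobian of the exp transform
    const double ss2 = sscale * sscale;
    lp += -0.5 * (sdf + 1.0) * std::log1p(sigma * sigma / (sdf * ss2)) + ls;
    gr[p + J] = sigma * su_r
        - (sdf + 1.0) * sigma * sigma / (sdf * ss2 + sigma * sigma) + 1.0;
    return lp;
  }
};

struct DualAvg {
  double mu, log_eps, log_eps_bar, Hbar, gamma, t0, kappa, delta;
  int t;
  void init(double eps, double target) {
    mu = std::log(10.0 * eps);
    log_eps = std::log(eps);
    log_eps_bar = std::log(eps);
    Hbar = 0.0; t = 0;
    gamma = 0.05; t0 = 10.0; kappa = 0.75; delta = target;
  }
  void update(double accept) {
    ++t;
    const double w = 1.0 / (t + t0);
    Hbar = (1.0 - w) * Hbar + w * (delta - accept);
    log_eps = mu - std::sqrt((double)t) / gamma * Hbar;
    const double w2 = std::pow((double)t, -kappa);
    log_eps_bar = w2 * log_eps + (1.0 - w2) * log_eps_bar;
  }
};

struct Sampler {
  const HLogit& mod;
  int dim;
  std::vector<double> inv_mass, th, grad, p, th_prop, grad_prop;
  double lp_cur;
  double max_dh;  // divergence threshold on Hamiltonian error
  int divergences;

  explicit Sampler(const HLogit& m)
      : mod(m), dim(m.dim), inv_mass(m.dim, 1.0), th(m.dim), grad(m.dim),
        p(m.dim), th_prop(m.dim), grad_prop(m.dim), lp_cur(0.0),
        max_dh(1000.0), divergences(0) {}

  double kinetic(const std::vector<double>& mom) const {
    double k = 0.0;
    for (int i = 0; i < dim; ++i) k += mom[i] * mom[i] * inv_mass[i];
    return 0.5 * k;
  }

  // One HMC transition; returns acceptance statistic in [0, 1].
  double transition(double eps, int L) {
    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(inv_mass[i]);
    const double H0 = -lp_cur + kinetic(p);
    th_prop = th;
    grad_prop = grad;
    double lp = lp_cur;
    std::vector<double>& mom = p;
    for (int i = 0; i < dim; ++i) mom[i] += 0.5 * eps * grad_prop[i];
    bool bad = false;
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < dim; ++i) th_prop[i] += eps * inv_mass[i] * mom[i];
      lp = mod.lp_grad(th_prop, grad_prop);
      if (!std::isfinite(lp)) { bad = true; break; }
      const double half = (l == L - 1) ? 0.5 : 1.0;
      for (int i = 0; i < dim; ++i) mom[i] += half * eps * grad_prop[i];
    }
    double astat = 0.0;
    if (!bad) {
      const double H1 = -lp + kinetic(mom);
      const double dh = H0 - H1;
      if (std::isfinite(dh)) {
        if (-dh > max_dh) ++divergences;
        astat = dh > 0 ? 1.0 : std::exp(dh);
        if (unif_rand() < astat) {
          th = th_prop;
          grad = grad_prop;
          lp_cur = lp;
        }
      }
    }
    return astat;
  }

  double find_eps(double target) {
    double eps = 0.1 / std::sqrt((double)dim);
    // crude bisection on one-step acceptance, capped iterations
    for (int it = 0; it < 30; ++it) {
      const double a = probe(eps);
      if (a > 0.9) eps *= 1.6;
      else if (a < 0.25) eps *= 0.5;
      else break;
    }
    (void)target;
    return eps;
  }

  // acceptance statistic of a single leapfrog step from current state
  double probe(double eps) {
    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(inv_mass[i]);
    const double H0 = -lp_cur + kinetic(p);
    th_prop = th;
    grad_prop = grad;
    std::vector<double> mom = p;
    for (int i = 0; i < dim; ++i) mom[i] += 0.5 * eps * grad_prop[i];
    for (int i = 0; i < dim; ++i) th_prop[i] += eps * inv_mass[i] * mom[i];
    const double lp = mod.lp_grad(th_prop, grad_prop);
    if (!std::isfinite(lp)) return 0.0;
    for (int i = 0; i < dim; ++i) mom[i] += 0.5 * eps * grad_prop[i];
    const double dh = H0 - (-lp + kinetic(mom));
    if (!std::isfinite(dh)) return 0.0;
    return dh > 0 ? 1.0 : std::exp(dh);
  }
};

}  // namespace

// [[Rcpp::export(name = ".hmc_fit_cpp")]]
List hmc_fit_cpp(NumericMatrix X, IntegerVector y, IntegerVector g, int J,
                 NumericVector prior_scale, double prior_df,
                 double sigma_scale, double sigma_df, int chains, int warmup,
                 int iter, double target_accept, double init_sd,
                 int max_leapfrog, double int_time) {
  HLogit mod(X, y, g, J, prior_scale, prior_df, sigma_scale, sigma_df);
  const int dim = mod.dim;
  List out(chains);
  NumericVector eps_used(chains), accept_rate(chains);
  IntegerVector div_count(chains);

  for (int c = 0; c < chains; ++c) {
    Sampler s(mod);
    for (int i = 0; i < mod.p; ++i) s.th[i] = norm_rand() * init_sd;
    for (int i = 0; i < J; ++i) s.th[mod.p + i] = norm_rand() * 0.5;
    s.th[dim - 1] = norm_rand() * 0.3;  // log sigma
    s.lp_cur = mod.lp_grad(s.th, s.grad);

    double eps = s.find_eps(target_accept);
    DualAvg da;
    da.init(eps, target_accept);

    const int w_lo = (int)std::floor(0.25 * warmup);
    const int w_hi = (int)std::floor(0.75 * warmup);
    std::vector<double> msum(dim, 0.0), msq(dim, 0.0);
    int mcount = 0;

    for (int it = 0; it < warmup; ++it) {
      eps = std::exp(da.log_eps);
      int Lb = (int)std::lround(int_time / eps);
      if (Lb < 1) Lb = 1;
      if (Lb > max_leapfrog) Lb = max_leapfrog;
      const int L = 1 + (int)std::floor(unif_rand() * Lb);
      const double a = s.transition(eps, L);
      da.update(a);
      if (it >= w_lo && it < w_hi) {
        ++mcount;
        for (int i = 0; i < dim; ++i) {
          msum[i] += s.th[i];
          msq[i] += s.th[i] * s.th[i];
        }
      }
      if (it == w_hi && mcount > 4) {
        for (int i = 0; i < dim; ++i) {
          const double mu = msum[i] / mcount;
          double v = msq[i] / mcount - mu * mu;
          if (!(v > 0.0)) v = 1e-3;
          // regularize toward unit as Stan does
          s.inv_mass[i] =
              v * mcount / (mcount + 5.0) + 1e-3 * 5.0 / (mcount + 5.0);
        }
        eps = s.find_eps(target_accept);
        da.init(eps, target_accept);
      }
    }

    eps = std::exp(da.log_eps_bar);
    if (!std::isfinite(eps) || eps <= 0) eps = std::exp(da.log_eps);
    eps_used[c] = eps;
    int Lb = (int)std::lround(int_time / eps);
    if (Lb < 1) Lb = 1;
    if (Lb > max_leapfrog) Lb = max_leapfrog;

    NumericMatrix draws(iter, dim);
    double asum = 0.0;
    for (int it = 0; it < iter; ++it) {
      const int L = 1 + (int)std::floor(unif_rand() * Lb);
      asum += s.transition(eps, L);
      for (int i = 0; i < dim; ++i) draws(it, i) = s.th[i];
      if ((it & 255) == 0) Rcpp::checkUserInterrupt();
    }
    accept_rate[c] = asum / iter;
    div_count[c] = s.divergences;
    out[c] = draws;
  }
  return List::create(_["draws"] = out, _["eps"] = eps_used,
                      _["accept_rate"] = accept_rate,
                      _["divergences"] = div_count);
}
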