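#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// negative-binomial trend model
//
//   y[i] ~ NegBin(mu[i], theta),  Var = mu + mu^2/theta
//   log mu[i] = alpha + u[reg(i)] + v[prov(i)] + beta * x[t(i)] + gamma[t(i)]
//
// with x[t] the year index centred at the first training year, gamma a
// first-order random walk anchored at gamma[0] = 0, and u, v exchangeable
// Gaussian deviations with half-Normal sd hyperpriors. alpha, u, v are
// sampled unconstrained (proper priors keep the posterior proper); draws are
// reported under the sum-to-zero identification (u, v centred, their means
// folded into alpha), which leaves every linear predictor unchanged.
//
// Ridge-exchange moves (shift alpha against u or v; trade beta slope against
// random-walk drift) keep the weakly identified directions mixing; each is a
// likelihood-invariant proposal accepted on the prior ratio alone.

static inline double ll_eta_term(double y, double eta, double th) {
  // cell log-likelihood terms that depend on eta (theta fixed)
  return y * eta - (th + y) * std::log(th + std::exp(eta));
}

static inline double dnorm_l(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * z * z - std::log(s);
}

// conditional log-density of a log-sd given the centred effects it governs:
// sum of Normal(0, s) terms, a half-Normal(scale) prior on s, and the
// log-scale Jacobian
static inline double logsd_cond(double ls, const double* x, int n,
                                double scale) {
  double s = std::exp(ls);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += x[i] * x[i];
  return -n * ls - 0.5 * ss / (s * s) - 0.5 * s * s / (scale * scale) + ls;
}

// univariate slice sampler (Neal 2003, stepping out + shrinkage) for the
// log-sd conditionals; exact, tuning-free, and cheap since the conditional
// involves only the handful of effects the sd governs
template <typename F>
static double slice_sample(double x0, F logf, double w = 1.0,
                           int max_steps = 30) {
  double f0 = logf(x0);
  double logy = f0 + std::log(R::unif_rand());
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  int j = max_steps;
  while (j-- > 0 && logf(L) > logy) L -= w;
  j = max_steps;
  while (j-- > 0 && logf(Rr) > logy) Rr += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = L + (Rr - L) * R::unif_rand();
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List nb_mwg_sampler(IntegerVector y, IntegerVector prov, IntegerVector reg,
                    IntegerVector tidx, int nP, int nR, int nT,
                    bool use_linear, bool use_rw, bool use_u, bool use_v,
                    List priors, int n_iter, int n_warmup, int thin,
                    List inits) {
  const int n = y.size();
  const double alpha_mean = priors["alpha_mean"];
  const double alpha_sd   = priors["alpha_sd"];
  const double beta_sd    = priors["beta_sd"];
  const double su_scale   = priors["sigma_u_scale"];
  const double sv_scale   = priors["sigma_v_scale"];
  const double sg_scale   = priors["sigma_gamma_scale"];
  const double theta_rate = priors["theta_rate"];

  // state
  double alpha = inits["alpha"];
  double beta  = inits["beta"];
  std::vector<double> u(nR, 0.0), v(nP, 0.0), gam(nT, 0.0);
  double log_su = std::log((double)inits["sigma_u"]);
  double log_sv = std::log((double)inits["sigma_v"]);
  double log_sg = std::log((double)inits["sigma_gamma"]);
  double log_th = std::log((double)inits["theta"]);

  std::vector<double> eta(n), yv(n);
  for (int i = 0; i < n; ++i) yv[i] = (double)y[i];

  std::vector< std::vector<int> > by_reg(nR), by_prov(nP), by_year(nT);
  for (int i = 0; i < n; ++i) {
    by_reg[reg[i]].push_back(i);
    by_prov[prov[i]].push_back(i);
    by_year[tidx[i]].push_back(i);
  }
  std::vector< std::vector<int> > prov_in_reg(nR);
  {
    std::vector<int> reg_of_prov(nP, -1);
    for (int i = 0; i < n; ++i) reg_of_prov[prov[i]] = reg[i];
    for (int p = 0; p < nP; ++p)
      if (reg_of_prov[p] >= 0) prov_in_reg[reg_of_prov[p]].push_back(p);
  }
  std::vector<double> xt(nT);
  for (int t = 0; t < nT; ++t) xt[t] = (double)t;

  auto recompute_eta = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = alpha;
      if (use_u) e += u[reg[i]];
      if (use_v) e += v[prov[i]];
      if (use_linear) e += beta * xt[tidx[i]];
      if (use_rw) e += gam[tidx[i]];
      eta[i] = e;
    }
  };
  recompute_eta();

  // adaptive proposal log-sds: [alpha, beta, u.., v.., gamma(1..nT-1),
  //  exch_u, exch_v, exch_trend, log_su, log_sv, log_sg, log_theta]
  const int off_u = 2, off_v = off_u + nR, off_g = off_v + nP;
  const int off_ex = off_g + nT, off_exr = off_ex + 3, off_h = off_exr + nR;
  const int off_lvl = off_h + 4;
  const int n_ls = off_h + 5;
  std::vector<double> ls(n_ls, std::log(0.1));
  ls[0] = std::log(0.02); // alpha: full-data likelihood is sharp
  ls[1] = std::log(0.01);
  for (int t = 0; t < nT; ++t) ls[off_g + t] = std::log(0.05);
  std::vector<double> acc(n_ls, 0.0), tries(n_ls, 0.0);

  auto adapt = [&](int k, bool accepted, int iter) {
    if (iter >= n_warmup) return;
    double rate = std::min(0.25, 3.0 / std::sqrt((double)(iter + 1)));
    ls[k] += accepted ? rate * 0.56 : -rate * 0.44;
    if (ls[k] > 3.0) ls[k] = 3.0;
    if (ls[k] < -12.0) ls[k] = -12.0;
  };

  auto full_theta_terms = [&](double th) {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += R::lgammafn(yv[i] + th) - (th + yv[i]) * std::log(th + std::exp(eta[i]));
    s += -n * R::lgammafn(th) + n * th * std::log(th);
    return s;
  };

  int n_keep = n_iter / thin;
  int ncol = 2 + nR + nP + nT + 4;
  NumericMatrix draws(n_keep, ncol);
  int keep = 0;

  for (int iter = 0; iter < n_warmup + n_iter; ++iter) {
    double th = std::exp(log_th);

    // alpha
    {
      double d = R::norm_rand() * std::exp(ls[0]);
      double dl = 0.0;
      for (int i = 0; i < n; ++i)
        dl += ll_eta_term(yv[i], eta[i] + d, th) - ll_eta_term(yv[i], eta[i], th);
      dl += dnorm_l(alpha + d, alpha_mean, alpha_sd) - dnorm_l(alpha, alpha_mean, alpha_sd);
      bool ok = std::log(R::unif_rand()) < dl;
      if (ok) { alpha += d; for (int i = 0; i < n; ++i) eta[i] += d; }
      adapt(0, ok, iter); tries[0]++; acc[0] += ok;
    }

    // beta
    if (use_linear) {
      double d = R::norm_rand() * std::exp(ls[1]);
      double dl = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = d * xt[tidx[i]];
        dl += ll_eta_term(yv[i], eta[i] + de, th) - ll_eta_term(yv[i], eta[i], th);
      }
      dl += dnorm_l(beta + d, 0.0, beta_sd) - dnorm_l(beta, 0.0, beta_sd);
      bool ok = std::log(R::unif_rand()) < dl;
      if (ok) { beta += d; for (int i = 0; i < n; ++i) eta[i] += d * xt[tidx[i]]; }
      adapt(1, ok, iter); tries[1]++; acc[1] += ok;
    }

    // region effects
    if (use_u) {
      double su = std::exp(log_su);
      for (int r = 0; r < nR; ++r) {
        double d = R::norm_rand() * std::exp(ls[off_u + r]);
        double dl = 0.0;
        for (int idx : by_reg[r])
          dl += ll_eta_term(yv[idx], eta[idx] + d, th) - ll_eta_term(yv[idx], eta[idx], th);
        dl += dnorm_l(u[r] + d, 0.0, su) - dnorm_l(u[r], 0.0, su);
        bool ok = std::log(R::unif_rand()) < dl;
        if (ok) { u[r] += d; for (int idx : by_reg[r]) eta[idx] += d; }
        adapt(off_u + r, ok, iter);
      }
      // exchange alpha <-> u (likelihood-invariant)
      double d = R::norm_rand() * std::exp(ls[off_ex]);
      double dl = dnorm_l(alpha + d, alpha_mean, alpha_sd) - dnorm_l(alpha, alpha_mean, alpha_sd);
      for (int r = 0; r < nR; ++r)
        dl += dnorm_l(u[r] - d, 0.0, su) - dnorm_l(u[r], 0.0, su);
      bool ok = std::log(R::unif_rand()) < dl;
      if (ok) { alpha += d; for (int r = 0; r < nR; ++r) u[r] -= d; }
      adapt(off_ex, ok, iter);
    }

    // province effects
    if (use_v) {
      double sv = std::exp(log_sv);
      for (int p = 0; p < nP; ++p) {
        double d = R::norm_rand() * std::exp(ls[off_v + p]);
        double dl = 0.0;
        for (int idx : by_prov[p])
          dl += ll_eta_term(yv[idx], eta[idx] + d, th) - ll_eta_term(yv[idx], eta[idx], th);
        dl += dnorm_l(v[p] + d, 0.0, sv) - dnorm_l(v[p], 0.0, sv);
        bool ok = std::log(R::unif_rand()) < dl;
        if (ok) { v[p] += d; for (int idx : by_prov[p]) eta[idx] += d; }
        adapt(off_v + p, ok, iter);
      }
      double d = R::norm_rand() * std::exp(ls[off_ex + 1]);
      double dl = dnorm_l(alpha + d, alpha_mean, alpha_sd) - dnorm_l(alpha, alpha_mean, alpha_sd);
      for (int p = 0; p < nP; ++p)
        dl += dnorm_l(v[p] - d, 0.0, sv) - dnorm_l(v[p], 0.0, sv);
      bool ok = std::log(R::unif_rand()) < dl;
      if (ok) { alpha += d; for (int p = 0; p < nP; ++p) v[p] -= d; }
      adapt(off_ex + 1, ok, iter);
      // per-region exchange u[r] <-> {v[p] : p in region r} (likelihood-invariant)
      if (use_u) {
        double su = std::exp(log_su);
        for (int r = 0; r < nR; ++r) {
          double dr = R::norm_rand() * std::exp(ls[off_exr + r]);
          double dlr = dnorm_l(u[r] + dr, 0.0, su) - dnorm_l(u[r], 0.0, su);
          for (int p : prov_in_reg[r])
            dlr += dnorm_l(v[p] - dr, 0.0, sv) - dnorm_l(v[p], 0.0, sv);
          bool okr = std::log(R::unif_rand()) < dlr;
          if (okr) { u[r] += dr; for (int p : prov_in_reg[r]) v[p] -= dr; }
          adapt(off_exr + r, okr, iter);
        }
      }
    }

    // random-walk year effects (gamma[0] anchored at 0)
    if (use_rw) {
      double sg = std::exp(log_sg);
      for (int t = 1; t < nT; ++t) {
        double d = R::norm_rand() * std::exp(ls[off_g + t]);
        double dl = 0.0;
        for (int idx : by_year[t])
          dl += ll_eta_term(yv[idx], eta[idx] + d, th) - ll_eta_term(yv[idx], eta[idx], th);
        dl += dnorm_l(gam[t] + d, gam[t - 1], sg) - dnorm_l(gam[t], gam[t - 1], sg);
        if (t + 1 < nT)
          dl += dnorm_l(gam[t + 1], gam[t] + d, sg) - dnorm_l(gam[t + 1], gam[t], sg);
        bool ok = std::log(R::unif_rand()) < dl;
        if (ok) { gam[t] += d; for (int idx : by_year[t]) eta[idx] += d; }
        adapt(off_g + t, ok, iter);
      }
      // level exchange alpha <-> gamma: alpha + d, all gamma[t>=1] - d.
      // Only the anchor-year cells see a changed linear predictor (they get
      // +d); the affected priors are alpha's and the first RW increment's.
      if (nT > 1) {
        double d = R::norm_rand() * std::exp(ls[off_lvl]);
        double dl = dnorm_l(alpha + d, alpha_mean, alpha_sd) -
                    dnorm_l(alpha, alpha_mean, alpha_sd);
        dl += dnorm_l(gam[1] - d, 0.0, sg) - dnorm_l(gam[1], 0.0, sg);
        for (int idx : by_year[0])
          dl += ll_eta_term(yv[idx], eta[idx] + d, th) - ll_eta_term(yv[idx], eta[idx], th);
        bool ok = std::log(R::unif_rand()) < dl;
        if (ok) {
          alpha += d;
          for (int t = 1; t < nT; ++t) gam[t] -= d;
          for (int idx : by_year[0]) eta[idx] += d;
        }
        adapt(off_lvl, ok, iter);
      }
      // exchange beta slope <-> random-walk drift (likelihood-invariant)
      if (use_linear && nT > 1) {
        double d = R::norm_rand() * std::exp(ls[off_ex + 2]);
        double dl = dnorm_l(beta + d, 0.0, beta_sd) - dnorm_l(beta, 0.0, beta_sd);
        for (int t = 1; t < nT; ++t) {
          double inc = gam[t] - gam[t - 1];
          dl += dnorm_l(inc - d, 0.0, sg) - dnorm_l(inc, 0.0, sg);
        }
        bool ok = std::log(R::unif_rand()) < dl;
        if (ok) { beta += d; for (int t = 1; t < nT; ++t) gam[t] -= d * xt[t]; }
        adapt(off_ex + 2, ok, iter);
      }
    }

    // sd hyperparameters (log-scale RW, half-Normal priors + Jacobian)
    if (use_u) {
      log_su = slice_sample(log_su, [&](double ls_) {
        return logsd_cond(ls_, u.data(), nR, su_scale);
      });

      // joint rescale (u, sigma_u); prior ratio and Jacobian cancel
      double d2 = R::norm_rand() * std::exp(ls[off_h]);
      double c = std::exp(d2);
      double th2 = std::exp(log_th);
      double dl2 = 0.0;
      for (int r = 0; r < nR; ++r) {
        double de = (c - 1.0) * u[r];
        for (int idx : by_reg[r])
          dl2 += ll_eta_term(yv[idx], eta[idx] + de, th2) - ll_eta_term(yv[idx], eta[idx], th2);
      }
      double su0 = std::exp(log_su), su1 = std::exp(log_su + d2);
      dl2 += -0.5 * (su1 * su1 - su0 * su0) / (su_scale * su_scale) + d2;
      bool ok2 = std::log(R::unif_rand()) < dl2;
      if (ok2) {
        log_su += d2;
        for (int r = 0; r < nR; ++r) {
          double de = (c - 1.0) * u[r];
          u[r] *= c;
          for (int idx : by_reg[r]) eta[idx] += de;
        }
      }
      adapt(off_h, ok2, iter);
    }
    if (use_v) {
      log_sv = slice_sample(log_sv, [&](double ls_) {
        return logsd_cond(ls_, v.data(), nP, sv_scale);
      });

      // joint rescale (v, sigma_v)
      double d2 = R::norm_rand() * std::exp(ls[off_h + 1]);
      double c = std::exp(d2);
      double th2 = std::exp(log_th);
      double dl2 = 0.0;
      for (int p = 0; p < nP; ++p) {
        double de = (c - 1.0) * v[p];
        for (int idx : by_prov[p])
          dl2 += ll_eta_term(yv[idx], eta[idx] + de, th2) - ll_eta_term(yv[idx], eta[idx], th2);
      }
      double sv0 = std::exp(log_sv), sv1 = std::exp(log_sv + d2);
      dl2 += -0.5 * (sv1 * sv1 - sv0 * sv0) / (sv_scale * sv_scale) + d2;
      bool ok2 = std::log(R::unif_rand()) < dl2;
      if (ok2) {
        log_sv += d2;
        for (int p = 0; p < nP; ++p) {
          double de = (c - 1.0) * v[p];
          v[p] *= c;
          for (int idx : by_prov[p]) eta[idx] += de;
        }
      }
      adapt(off_h + 1, ok2, iter);
    }
    if (use_rw && nT > 1) {
      std::vector<double> inc(nT - 1);
      for (int t = 1; t < nT; ++t) inc[t - 1] = gam[t] - gam[t - 1];
      log_sg = slice_sample(log_sg, [&](double ls_) {
        return logsd_cond(ls_, inc.data(), nT - 1, sg_scale);
      });

      // joint rescale of (gamma, sigma_gamma): gamma' = c*gamma, log_sg' += d.
      // The increment-prior ratio and the transform Jacobian cancel, leaving
      // the likelihood change plus the sigma prior ratio and log-scale
      // Jacobian; this decouples the funnel between the states and their sd.
      double d2 = R::norm_rand() * std::exp(ls[off_h + 2]);
      double c = std::exp(d2);
      double th2 = std::exp(log_th);
      double dl2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = (c - 1.0) * gam[tidx[i]];
        if (de != 0.0)
          dl2 += ll_eta_term(yv[i], eta[i] + de, th2) - ll_eta_term(yv[i], eta[i], th2);
      }
      double sg0 = std::exp(log_sg), sg1 = std::exp(log_sg + d2);
      dl2 += -0.5 * (sg1 * sg1 - sg0 * sg0) / (sg_scale * sg_scale) + d2;
      bool ok2 = std::log(R::unif_rand()) < dl2;
      if (ok2) {
        log_sg += d2;
        for (int t = 1; t < nT; ++t) {
          double de = (c - 1.0) * gam[t];
          gam[t] *= c;
          for (int idx : by_year[t]) eta[idx] += de;
        }
      }
      adapt(off_h + 2, ok2, iter);
    }

    // dispersion theta
    {
      double d = R::norm_rand() * std::exp(ls[off_h + 3]);
      double th0 = std::exp(log_th), th1 = std::exp(log_th + d);
      double dl = full_theta_terms(th1) - full_theta_terms(th0);
      // Exponential(theta_rate) prior on 1/theta, with the change of
      // variables to log theta: log p(x) = -rate*exp(-x) - x + const
      dl += -theta_rate * (1.0 / th1 - 1.0 / th0) - d;
      bool ok = std::log(R::unif_rand()) < dl;
      if (ok) log_th += d;
      adapt(off_h + 3, ok, iter);
    }

    if (iter >= n_warmup && ((iter - n_warmup) % thin == 0) && keep < n_keep) {
      double mu_u = 0.0, mu_v = 0.0;
      if (use_u) { for (int r = 0; r < nR; ++r) mu_u += u[r]; mu_u /= nR; }
      if (use_v) { for (int p = 0; p < nP; ++p) mu_v += v[p]; mu_v /= nP; }
      int c = 0;
      draws(keep, c++) = alpha + mu_u + mu_v;
      draws(keep, c++) = beta;
      for (int r = 0; r < nR; ++r) draws(keep, c++) = use_u ? u[r] - mu_u : 0.0;
      for (int p = 0; p < nP; ++p) draws(keep, c++) = use_v ? v[p] - mu_v : 0.0;
      for (int t = 0; t < nT; ++t) draws(keep, c++) = gam[t];
      draws(keep, c++) = std::exp(log_su);
      draws(keep, c++) = std::exp(log_sv);
      draws(keep, c++) = std::exp(log_sg);
      draws(keep, c++) = std::exp(log_th);
      keep++;
    }
  }

  return List::create(_["draws"] = draws,
                      _["accept_alpha"] = tries[0] > 0 ? acc[0] / tries[0] : NA_REAL);
}
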