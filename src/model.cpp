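// Joint hierarchical model of response accuracy (bi-factor 2PL) and response
// time (bi-factor lognormal), with nested reductions, on the unconstrained
// scale used by the NUTS sampler.
//
// Unconstrained parameter layout (length D), sizes N persons, m items,
// K specific dimensions, flags has_general / rt_unidim:
//   [0]        la_s      m   log a_s            (specific RA discrimination)
//   [1]        lalpha_s  m   log alpha_s        (specific/unidim RT slope)
//   [2]        w         m   log (1/sigma)      (log time discrimination)
//   [3]        zd        m   raw d              (non-centered)
//   [4]        zb        m   raw beta           (non-centered)
//   [5]        la_g      m   log a_g            (only if has_general)
//   [6]        lalpha_g  m   log alpha_g        (only if has_general)
//   [7]        hyper     5   mu_d, mu_beta, log sigma_d, log sigma_beta,
//                            atanh rho_d_beta
//   [8]        yg        1   atanh rho_g        (only if has_general)
//   [9]        ys        K   atanh rho_s[k]     (only if !rt_unidim)
//              u         K   ball-parameterized speed-ability correlations
//                            (only if rt_unidim)
//   [10]       ths       N*K theta_s (person-major within dimension)
//   [11]       zs        N*K raw tau_s          (only if !rt_unidim)
//              zu        N   raw tau            (only if rt_unidim)
//   [12]       thg       N   theta_g            (only if has_general)
//   [13]       zg        N   raw tau_g          (only if has_general)
//
// Missing cells: U = -1 (int), L = NaN; they contribute nothing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Layout {
  int N, m, K;
  bool hasG, rtUni;
  int la_s, lalpha_s, w, zd, zb, la_g, lalpha_g, hyper, yg, ycor, ths, ztau,
      thg, zg;
  int D;
};

Layout make_layout(int N, int m, int K, bool hasG, bool rtUni) {
  Layout L;
  L.N = N; L.m = m; L.K = K; L.hasG = hasG; L.rtUni = rtUni;
  int pos = 0;
  L.la_s = pos; pos += m;
  L.lalpha_s = pos; pos += m;
  L.w = pos; pos += m;
  L.zd = pos; pos += m;
  L.zb = pos; pos += m;
  L.la_g = hasG ? pos : -1; if (hasG) pos += m;
  L.lalpha_g = hasG ? pos : -1; if (hasG) pos += m;
  L.hyper = pos; pos += 5;
  L.yg = hasG ? pos : -1; if (hasG) pos += 1;
  L.ycor = pos; pos += K;  // ys if !rtUni, u if rtUni
  L.ths = pos; pos += N * K;
  L.ztau = pos; pos += rtUni ? N : N * K;
  L.thg = hasG ? pos : -1; if (hasG) pos += N;
  L.zg = hasG ? pos : -1; if (hasG) pos += N;
  L.D = pos;
  return L;
}

struct Priors {
  double mu_d_mean, mu_d_sd, mu_b_mean, mu_b_sd, eta;
};

Priors make_priors(const Rcpp::NumericVector& pr) {
  Priors p;
  p.mu_d_mean = pr["mu_d_mean"];
  p.mu_d_sd = pr["mu_d_sd"];
  p.mu_b_mean = pr["mu_b_mean"];
  p.mu_b_sd = pr["mu_b_sd"];
  p.eta = pr["eta"];
  return p;
}

// Derived (constrained) quantities shared by value/gradient, transform and
// pointwise log-likelihood.
struct Derived {
  vec a_s, alpha_s, isig, sig, d, b, a_g, alpha_g;
  double mu_d, mu_b, sd_d, sd_b, rho_db, q_db;
  double rho_g, c_g;        // general pair
  vec rho_s, c_s;           // per-dimension pairs (!rtUni)
  vec r_u; double c_u, s_u; // ball parameterization (rtUni)
  mat Ths;                  // N x K
  mat Taus;                 // N x K (!rtUni)
  vec tau_u;                // N (rtUni)
  vec thg, taug, zg;        // general
  mat Zs;                   // raw tau_s
  vec zu;
  vec zd, zb;
};

Derived derive(const vec& x, const Layout& L) {
  Derived d;
  const int N = L.N, m = L.m, K = L.K;
  d.a_s = exp(x.subvec(L.la_s, L.la_s + m - 1));
  d.alpha_s = exp(x.subvec(L.lalpha_s, L.lalpha_s + m - 1));
  d.isig = exp(x.subvec(L.w, L.w + m - 1));
  d.sig = 1.0 / d.isig;
  d.zd = x.subvec(L.zd, L.zd + m - 1);
  d.zb = x.subvec(L.zb, L.zb + m - 1);
  d.mu_d = x[L.hyper + 0];
  d.mu_b = x[L.hyper + 1];
  d.sd_d = std::exp(x[L.hyper + 2]);
  d.sd_b = std::exp(x[L.hyper + 3]);
  const double ydb = x[L.hyper + 4];
  d.rho_db = std::tanh(ydb);
  d.q_db = 1.0 / std::cosh(ydb);
  d.d = d.mu_d + d.sd_d * d.zd;
  d.b = d.mu_b + d.sd_b * (d.rho_db * d.zd + d.q_db * d.zb);
  if (L.hasG) {
    d.a_g = exp(x.subvec(L.la_g, L.la_g + m - 1));
    d.alpha_g = exp(x.subvec(L.lalpha_g, L.lalpha_g + m - 1));
    const double yg = x[L.yg];
    d.rho_g = std::tanh(yg);
    d.c_g = 1.0 / std::cosh(yg);
    d.thg = x.subvec(L.thg, L.thg + N - 1);
    d.zg = x.subvec(L.zg, L.zg + N - 1);
    d.taug = d.rho_g * d.thg + d.c_g * d.zg;
  }
  d.Ths = reshape(x.subvec(L.ths, L.ths + N * K - 1), N, K);
  if (!L.rtUni) {
    d.rho_s.set_size(K); d.c_s.set_size(K);
    for (int k = 0; k < K; ++k) {
      const double yk = x[L.ycor + k];
      d.rho_s[k] = std::tanh(yk);
      d.c_s[k] = 1.0 / std::cosh(yk);
    }
    d.Zs = reshape(x.subvec(L.ztau, L.ztau + N * K - 1), N, K);
    d.Taus = d.Ths.each_row() % d.rho_s.t() + d.Zs.each_row() % d.c_s.t();
  } else {
    const vec u = x.subvec(L.ycor, L.ycor + K - 1);
    d.s_u = std::sqrt(1.0 + dot(u, u));
    d.r_u = u / d.s_u;
    d.c_u = 1.0 / d.s_u;
    d.zu = x.subvec(L.ztau, L.ztau + N - 1);
    d.tau_u = (d.Ths * u + d.zu) / d.s_u;
  }
  return d;
}

// Linear predictors, N x m.
mat ra_eta(const Derived& dv, const Layout& L, const uvec& grp) {
  mat E(L.N, L.m);
  for (int j = 0; j < L.m; ++j) {
    E.col(j) = dv.d[j] + dv.a_s[j] * dv.Ths.col(grp[j]);
    if (L.hasG) E.col(j) += dv.a_g[j] * dv.thg;
  }
  return E;
}

mat rt_mu(const Derived& dv, const Layout& L, const uvec& grp) {
  mat M(L.N, L.m);
  for (int j = 0; j < L.m; ++j) {
    if (L.rtUni) M.col(j) = dv.b[j] - dv.alpha_s[j] * dv.tau_u;
    else M.col(j) = dv.b[j] - dv.alpha_s[j] * dv.Taus.col(grp[j]);
    if (L.hasG) M.col(j) -= dv.alpha_g[j] * dv.taug;
  }
  return M;
}

inline double stable_log1pexp(double z) {
  // log(1 + exp(z)), stable
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

}  // namespace

// Value and (optionally) gradient of the log posterior. lik_weight = 0 gives
// the prior alone (used for prior-predictive checks); prior_weight = 0 gives
// the likelihood alone (used to validate against the R pointwise routines).
static double value_grad(const vec& x, const imat& U, const mat& Lt,
                         const uvec& grp, const Layout& L, const Priors& pr,
                         double lik_weight, double prior_weight,
                         vec* grad_out) {
  const int N = L.N, m = L.m, K = L.K;
  Derived dv = derive(x, L);
  const bool want_grad = grad_out != nullptr;
  vec grad;
  if (want_grad) grad = zeros<vec>(L.D);

  double lp = 0.0;

  // ---- Priors -------------------------------------------------------------
  auto halfnorm_block = [&](int off, const vec& v) {
    // v = exp(y), half-normal(0,1) prior on v plus Jacobian
    lp += prior_weight * accu(-0.5 * square(v) + log(v));
    if (want_grad)
      for (int j = 0; j < (int)v.n_elem; ++j)
        grad[off + j] += prior_weight * (1.0 - v[j] * v[j]);
  };
  halfnorm_block(L.la_s, dv.a_s);
  halfnorm_block(L.lalpha_s, dv.alpha_s);
  halfnorm_block(L.w, dv.isig);
  if (L.hasG) {
    halfnorm_block(L.la_g, dv.a_g);
    halfnorm_block(L.lalpha_g, dv.alpha_g);
  }
  // raw normals
  auto stdnorm_block = [&](int off, int len) {
    for (int j = 0; j < len; ++j) {
      lp += prior_weight * (-0.5 * x[off + j] * x[off + j]);
      if (want_grad) grad[off + j] += prior_weight * (-x[off + j]);
    }
  };
  stdnorm_block(L.zd, m);
  stdnorm_block(L.zb, m);
  stdnorm_block(L.ths, N * K);
  stdnorm_block(L.ztau, L.rtUni ? N : N * K);
  if (L.hasG) { stdnorm_block(L.thg, N); stdnorm_block(L.zg, N); }

  // hyper-priors
  {
    const double vd = (dv.mu_d - pr.mu_d_mean) / pr.mu_d_sd;
    const double vb = (dv.mu_b - pr.mu_b_mean) / pr.mu_b_sd;
    lp += prior_weight * (-0.5 * vd * vd - 0.5 * vb * vb);
    lp += prior_weight * (-0.5 * dv.sd_d * dv.sd_d + x[L.hyper + 2]);
    lp += prior_weight * (-0.5 * dv.sd_b * dv.sd_b + x[L.hyper + 3]);
    // LKJ(eta) on rho_d_beta plus tanh Jacobian: eta * log(1 - rho^2)
    lp += prior_weight * (2.0 * pr.eta * std::log(dv.q_db));
    if (want_grad) {
      grad[L.hyper + 0] += prior_weight * (-vd / pr.mu_d_sd);
      grad[L.hyper + 1] += prior_weight * (-vb / pr.mu_b_sd);
      grad[L.hyper + 2] += prior_weight * (1.0 - dv.sd_d * dv.sd_d);
      grad[L.hyper + 3] += prior_weight * (1.0 - dv.sd_b * dv.sd_b);
      grad[L.hyper + 4] += prior_weight * (-2.0 * pr.eta * dv.rho_db);
    }
  }
  if (L.hasG) {
    lp += prior_weight * (2.0 * pr.eta * std::log(dv.c_g));
    if (want_grad) grad[L.yg] += prior_weight * (-2.0 * pr.eta * dv.rho_g);
  }
  if (!L.rtUni) {
    for (int k = 0; k < K; ++k) {
      lp += prior_weight * (2.0 * pr.eta * std::log(dv.c_s[k]));
      if (want_grad)
        grad[L.ycor + k] += prior_weight * (-2.0 * pr.eta * dv.rho_s[k]);
    }
  } else {
    // uniform prior over the unit ball of correlations
    const vec u = x.subvec(L.ycor, L.ycor + K - 1);
    const double s2 = 1.0 + dot(u, u);
    lp += prior_weight * (-0.5 * (K + 2) * std::log(s2));
    if (want_grad)
      for (int k = 0; k < K; ++k)
        grad[L.ycor + k] += prior_weight * (-(K + 2) * u[k] / s2);
  }

  if (lik_weight == 0.0) {
    if (want_grad) *grad_out = grad;
    return lp;
  }

  // ---- Likelihood ---------------------------------------------------------
  const double LOG_SQRT_2PI = 0.9189385332046727;  // log(sqrt(2*pi))
  mat E = ra_eta(dv, L, grp);
  mat M = rt_mu(dv, L, grp);
  mat R(N, m, fill::zeros);    // u - p, zero where missing
  mat Emat(N, m, fill::zeros); // (lnT - mu)/sigma^2, zero where missing
  vec g_w_lik(m, fill::zeros);
  double ll = 0.0;
  for (int j = 0; j < m; ++j) {
    const double sj = dv.sig[j], inv_s2 = 1.0 / (sj * sj);
    const double log_sj = std::log(sj);
    for (int i = 0; i < N; ++i) {
      const int u = U(i, j);
      if (u >= 0) {
        // one exp per cell: p, log(1+exp(e)) share exp(-|e|)
        const double e = E(i, j);
        if (e > 0) {
          const double q = (e < 35.0) ? std::exp(-e) : 0.0;
          ll += u * e - e - std::log1p(q);
          R(i, j) = u - 1.0 / (1.0 + q);
        } else {
          const double q = (e > -35.0) ? std::exp(e) : 0.0;
          ll += u * e - std::log1p(q);
          R(i, j) = u - q / (1.0 + q);
        }
      }
      const double lt = Lt(i, j);
      if (std::isfinite(lt)) {
        const double res = lt - M(i, j);
        ll += -log_sj - 0.5 * res * res * inv_s2 - LOG_SQRT_2PI;
        Emat(i, j) = res * inv_s2;
        g_w_lik[j] += 1.0 - res * res * inv_s2;
      }
    }
  }
  lp += lik_weight * ll;
  if (!want_grad) return lp;

  // RA gradients
  vec g_d = sum(R, 0).t();                       // m
  vec g_as(m);
  for (int j = 0; j < m; ++j) g_as[j] = dot(R.col(j), dv.Ths.col(grp[j]));
  mat As(m, K, fill::zeros);
  for (int j = 0; j < m; ++j) As(j, grp[j]) = dv.a_s[j];
  mat G_ths = R * As;                            // N x K
  vec g_ag, g_thg_ra;
  if (L.hasG) {
    g_ag = R.t() * dv.thg;
    g_thg_ra = R * dv.a_g;
  }

  // RT gradients
  vec g_b = sum(Emat, 0).t();
  vec g_alphas(m);
  mat G_taus;
  vec g_tauu;
  if (L.rtUni) {
    g_alphas = -(Emat.t() * dv.tau_u);
    g_tauu = -(Emat * dv.alpha_s);
  } else {
    for (int j = 0; j < m; ++j)
      g_alphas[j] = -dot(Emat.col(j), dv.Taus.col(grp[j]));
    mat Aal(m, K, fill::zeros);
    for (int j = 0; j < m; ++j) Aal(j, grp[j]) = dv.alpha_s[j];
    G_taus = -(Emat * Aal);
  }
  vec g_alphag, g_taug;
  if (L.hasG) {
    g_alphag = -(Emat.t() * dv.taug);
    g_taug = -(Emat * dv.alpha_g);
  }

  // chain rules into unconstrained gradient
  const double lw = lik_weight;
  for (int j = 0; j < m; ++j) {
    grad[L.la_s + j] += lw * g_as[j] * dv.a_s[j];
    grad[L.lalpha_s + j] += lw * g_alphas[j] * dv.alpha_s[j];
    grad[L.w + j] += lw * g_w_lik[j];
    grad[L.zd + j] += lw * (g_d[j] * dv.sd_d + g_b[j] * dv.sd_b * dv.rho_db);
    grad[L.zb + j] += lw * g_b[j] * dv.sd_b * dv.q_db;
    if (L.hasG) {
      grad[L.la_g + j] += lw * g_ag[j] * dv.a_g[j];
      grad[L.lalpha_g + j] += lw * g_alphag[j] * dv.alpha_g[j];
    }
  }
  grad[L.hyper + 0] += lw * accu(g_d);
  grad[L.hyper + 1] += lw * accu(g_b);
  grad[L.hyper + 2] += lw * dv.sd_d * dot(g_d, dv.zd);
  grad[L.hyper + 3] += lw * dot(g_b, dv.b - dv.mu_b);
  {
    // d b_j / d y_db = sd_b * (zd_j - sinh(y) * zb_j) * q^2 ; with
    // rho = tanh(y), q = sech(y): d rho/dy = q^2, d q/dy = -rho q.
    const double sinh_y = dv.rho_db / dv.q_db;
    double acc = 0.0;
    for (int j = 0; j < m; ++j)
      acc += g_b[j] * dv.sd_b * (dv.zd[j] - sinh_y * dv.zb[j]) *
             (dv.q_db * dv.q_db);
    grad[L.hyper + 4] += lw * acc;
  }

  // persons
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < N; ++i) {
      double g = G_ths(i, k);
      if (!L.rtUni) g += G_taus(i, k) * dv.rho_s[k];
      else g += g_tauu[i] * dv.r_u[k];
      grad[L.ths + i + N * k] += lw * g;
      if (!L.rtUni) grad[L.ztau + i + N * k] += lw * G_taus(i, k) * dv.c_s[k];
    }
  }
  if (L.rtUni) {
    for (int i = 0; i < N; ++i) grad[L.ztau + i] += lw * g_tauu[i] * dv.c_u;
    const vec u = x.subvec(L.ycor, L.ycor + K - 1);
    const double s = dv.s_u;
    // d tau_i / d u_l = ths_il / s - tau_i * u_l / s^2
    vec gT = dv.Ths.t() * g_tauu;            // K
    const double gtau_tau = dot(g_tauu, dv.tau_u);
    for (int k = 0; k < K; ++k)
      grad[L.ycor + k] += lw * (gT[k] / s - gtau_tau * u[k] / (s * s));
  } else {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      const double sinh_y = dv.rho_s[k] / dv.c_s[k];
      for (int i = 0; i < N; ++i)
        acc += G_taus(i, k) * (dv.Ths(i, k) - sinh_y * dv.Zs(i, k)) *
               (dv.c_s[k] * dv.c_s[k]);
      grad[L.ycor + k] += lw * acc;
    }
  }
  if (L.hasG) {
    for (int i = 0; i < N; ++i) {
      grad[L.thg + i] += lw * (g_thg_ra[i] + g_taug[i] * dv.rho_g);
      grad[L.zg + i] += lw * g_taug[i] * dv.c_g;
    }
    const double sinh_y = dv.rho_g / dv.c_g;
    double acc = 0.0;
    for (int i = 0; i < N; ++i)
      acc += g_taug[i] * (dv.thg[i] - sinh_y * dv.zg[i]) *
             (dv.c_g * dv.c_g);
    grad[L.yg] += lw * acc;
  }

  *grad_out = grad;
  return lp;
}

// [[Rcpp::export(name = ".bf_logpost")]]
double bf_logpost(const arma::vec& x, const arma::imat& U, const arma::mat& L,
                  const arma::uvec& group0, int K, bool has_general,
                  bool rt_unidim, Rcpp::NumericVector priors,
                  double lik_weight = 1.0, double prior_weight = 1.0) {
  Layout lay = make_layout(U.n_rows, U.n_cols, K, has_general, rt_unidim);
  if ((int)x.n_elem != lay.D) Rcpp::stop("parameter vector has wrong length");
  return value_grad(x, U, L, group0, lay, make_priors(priors), lik_weight,
                    prior_weight, nullptr);
}

// [[Rcpp::export(name = ".bf_grad")]]
arma::vec bf_grad(const arma::vec& x, const arma::imat& U, const arma::mat& L,
                  const arma::uvec& group0, int K, bool has_general,
                  bool rt_unidim, Rcpp::NumericVector priors,
                  double lik_weight = 1.0, double prior_weight = 1.0) {
  Layout lay = make_layout(U.n_rows, U.n_cols, K, has_general, rt_unidim);
  if ((int)x.n_elem != lay.D) Rcpp::stop("parameter vector has wrong length");
  vec g;
  value_grad(x, U, L, group0, lay, make_priors(priors), lik_weight,
             prior_weight, &g);
  return g;
}

// [[Rcpp::export(name = ".bf_dim")]]
int bf_dim(int N, int m, int K, bool has_general, bool rt_unidim) {
  return make_layout(N, m, K, has_general, rt_unidim).D;
}

// ---------------------------------------------------------------------------
// NUTS (Hoffman & Gelman 2014, Algorithm 6) with diagonal mass matrix and
// dual-averaging step-size adaptation; one mass-matrix update mid-warmup.
// ---------------------------------------------------------------------------

namespace {

struct NutsCtx {
  const imat* U; const mat* Lt; const uvec* grp;
  Layout lay; Priors pr; double lik_weight;
  vec inv_mass;  // 1 / M_ii
  int n_grad = 0;
  double logp_grad(const vec& q, vec& grad) {
    ++n_grad;
    return value_grad(q, *U, *Lt, *grp, lay, pr, lik_weight, 1.0, &grad);
  }
  double kinetic(const vec& p) const { return 0.5 * dot(square(p), inv_mass); }
};

struct TreeState {
  vec q, p, grad;
  double logp;
};

void leapfrog(NutsCtx& ctx, TreeState& s, double eps) {
  s.p += 0.5 * eps * s.grad;
  s.q += eps * (ctx.inv_mass % s.p);
  s.logp = ctx.logp_grad(s.q, s.grad);
  s.p += 0.5 * eps * s.grad;
}

struct BuildResult {
  TreeState minus, plus, prop;
  int n_valid;
  bool ok;         // no u-turn / divergence inside subtree
  double alpha_sum;
  int n_alpha;
  bool divergent;
};

bool no_uturn(const NutsCtx& ctx, const TreeState& minus,
              const TreeState& plus) {
  vec dq = plus.q - minus.q;
  return dot(dq, ctx.inv_mass % minus.p) >= 0 &&
         dot(dq, ctx.inv_mass % plus.p) >= 0;
}

void build_tree(NutsCtx& ctx, const TreeState& s, double log_u, int dir,
                int depth, double eps, double H0, BuildResult& out) {
  if (depth == 0) {
    TreeState s1 = s;
    leapfrog(ctx, s1, dir * eps);
    double H = -s1.logp + ctx.kinetic(s1.p);
    if (!std::isfinite(H)) H = std::numeric_limits<double>::infinity();
    out.minus = s1; out.plus = s1; out.prop = s1;
    out.n_valid = (log_u <= -H) ? 1 : 0;
    out.divergent = (log_u - 1000.0) > -H;
    out.ok = !out.divergent;
    double a = std::exp(std::min(0.0, H0 - H));
    out.alpha_sum = std::isfinite(a) ? a : 0.0;
    out.n_alpha = 1;
    return;
  }
  build_tree(ctx, s, log_u, dir, depth - 1, eps, H0, out);
  if (!out.ok) return;
  BuildResult second;
  if (dir == -1) build_tree(ctx, out.minus, log_u, dir, depth - 1, eps, H0, second);
  else build_tree(ctx, out.plus, log_u, dir, depth - 1, eps, H0, second);
  if (dir == -1) out.minus = second.minus; else out.plus = second.plus;
  const int n_tot = out.n_valid + second.n_valid;
  if (second.n_valid > 0 &&
      R::runif(0.0, 1.0) < (double)second.n_valid / n_tot)
    out.prop = second.prop;
  out.alpha_sum += second.alpha_sum;
  out.n_alpha += second.n_alpha;
  out.n_valid = n_tot;
  out.divergent = out.divergent || second.divergent;
  out.ok = second.ok && !out.divergent && no_uturn(ctx, out.minus, out.plus);
}

double find_epsilon(NutsCtx& ctx, const vec& q0) {
  double eps = 0.1;
  TreeState s;
  s.q = q0;
  s.logp = ctx.logp_grad(s.q, s.grad);
  vec p(q0.n_elem);
  for (uword i = 0; i < p.n_elem; ++i)
    p[i] = R::norm_rand() / std::sqrt(ctx.inv_mass[i]);
  s.p = p;
  const double H0 = -s.logp + ctx.kinetic(s.p);
  TreeState s1 = s;
  leapfrog(ctx, s1, eps);
  double H1 = -s1.logp + ctx.kinetic(s1.p);
  if (!std::isfinite(H1)) H1 = H0 + 1000.0;
  double a = (H0 - H1 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= std::pow(2.0, a);
    s1 = s;
    leapfrog(ctx, s1, eps);
    H1 = -s1.logp + ctx.kinetic(s1.p);
    if (!std::isfinite(H1)) H1 = H0 + 1000.0;
    if (a * (H0 - H1) <= a * std::log(0.5)) break;
  }
  return eps;
}

}  // namespace

// [[Rcpp::export(name = ".bf_nuts")]]
Rcpp::List bf_nuts(const arma::vec& init, const arma::imat& U,
                   const arma::mat& L, const arma::uvec& group0, int K,
                   bool has_general, bool rt_unidim,
                   Rcpp::NumericVector priors, int n_warmup, int n_sample,
                   int thin, int max_treedepth, double adapt_delta,
                   double lik_weight = 1.0) {
  NutsCtx ctx;
  ctx.U = &U; ctx.Lt = &L; ctx.grp = &group0;
  ctx.lay = make_layout(U.n_rows, U.n_cols, K, has_general, rt_unidim);
  ctx.pr = make_priors(priors);
  ctx.lik_weight = lik_weight;
  const int D = ctx.lay.D;
  if ((int)init.n_elem != D) Rcpp::stop("init has wrong length");
  ctx.inv_mass = ones<vec>(D);

  const int n_keep = n_sample / thin;
  mat draws(n_keep, D);
  vec accept_stat(n_keep), energy(n_keep);
  ivec treedepth(n_keep), divergent(n_keep);
  int n_divergent_total = 0;

  // dual averaging state
  double eps = find_epsilon(ctx, init);
  double mu_da = std::log(10.0 * eps);
  double log_eps_bar = 0.0, H_bar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // mass-matrix accumulation (Welford) over the middle of warmup
  const int mass_start = std::max(25, n_warmup / 5);
  const int mass_end = n_warmup / 2;
  vec mw_mean = zeros<vec>(D), mw_m2 = zeros<vec>(D);
  int mw_n = 0;

  TreeState cur;
  cur.q = init;
  cur.logp = ctx.logp_grad(cur.q, cur.grad);
  if (!std::isfinite(cur.logp)) Rcpp::stop("initial point has zero density");

  const int total = n_warmup + n_sample;
  int kept = 0;
  for (int iter = 1; iter <= total; ++iter) {
    const bool warm = iter <= n_warmup;
    // momentum
    vec p(D);
    for (int i = 0; i < D; ++i)
      p[i] = R::norm_rand() / std::sqrt(ctx.inv_mass[i]);
    const double H0 = -cur.logp + ctx.kinetic(p);
    const double log_u = std::log(R::runif(0.0, 1.0)) - H0;

    TreeState s_minus = cur, s_plus = cur, prop = cur;
    s_minus.p = p; s_plus.p = p;
    int n_valid = 1, depth = 0;
    bool keep_going = true, div_iter = false;
    double alpha_sum = 0.0;
    int n_alpha = 0;
    while (keep_going && depth < max_treedepth) {
      const int dir = (R::unif_rand() < 0.5) ? -1 : 1;
      BuildResult res;
      if (dir == -1) build_tree(ctx, s_minus, log_u, dir, depth, eps, H0, res);
      else build_tree(ctx, s_plus, log_u, dir, depth, eps, H0, res);
      if (dir == -1) s_minus = res.minus; else s_plus = res.plus;
      alpha_sum += res.alpha_sum;
      n_alpha += res.n_alpha;
      div_iter = div_iter || res.divergent;
      if (res.ok && res.n_valid > 0 &&
          R::unif_rand() < std::min(1.0, (double)res.n_valid / n_valid))
        prop = res.prop;
      n_valid += res.n_valid;
      keep_going = res.ok && no_uturn(ctx, s_minus, s_plus);
      ++depth;
    }
    cur.q = prop.q; cur.grad = prop.grad; cur.logp = prop.logp;
    if (div_iter) ++n_divergent_total;

    const double accept = n_alpha > 0 ? alpha_sum / n_alpha : 0.0;
    if (warm) {
      // dual averaging
      ++da_count;
      const double eta = 1.0 / (da_count + t0);
      H_bar = (1.0 - eta) * H_bar + eta * (adapt_delta - accept);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma_da * H_bar;
      const double weight = std::pow((double)da_count, -kappa);
      log_eps_bar = weight * log_eps + (1.0 - weight) * log_eps_bar;
      eps = std::exp(log_eps);
      // mass accumulation
      if (iter > mass_start && iter <= mass_end) {
        ++mw_n;
        vec delta = cur.q - mw_mean;
        mw_mean += delta / mw_n;
        mw_m2 += delta % (cur.q - mw_mean);
      }
      if (iter == mass_end && mw_n > 10) {
        vec v = mw_m2 / (mw_n - 1);
        const double shrink = (double)mw_n / (mw_n + 5.0);
        ctx.inv_mass = shrink * v + (1.0 - shrink) * 1e-3 * ones<vec>(D);
        ctx.inv_mass = clamp(ctx.inv_mass, 1e-8, 1e8);
        // restart step-size adaptation around the current value
        eps = find_epsilon(ctx, cur.q);
        mu_da = std::log(10.0 * eps);
        log_eps_bar = 0.0; H_bar = 0.0; da_count = 0;
      }
      if (iter == n_warmup) eps = std::exp(log_eps_bar);
    } else {
      const int post = iter - n_warmup;
      if (post % thin == 0 && kept < n_keep) {
        draws.row(kept) = cur.q.t();
        accept_stat[kept] = accept;
        treedepth[kept] = depth;
        divergent[kept] = div_iter ? 1 : 0;
        energy[kept] = H0;
        ++kept;
      }
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("accept_stat") = accept_stat,
      Rcpp::Named("treedepth") = treedepth,
      Rcpp::Named("divergent") = divergent,
      Rcpp::Named("energy") = energy,
      Rcpp::Named("step_size") = eps,
      Rcpp::Named("inv_mass") = ctx.inv_mass,
      Rcpp::Named("n_divergent") = n_divergent_total,
      Rcpp::Named("n_grad_evals") = ctx.n_grad);
}

// ---------------------------------------------------------------------------
// Transform unconstrained draws to the constrained reporting scale, and
// compute pointwise log-likelihood matrices.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".bf_transform")]]
arma::mat bf_transform(const arma::mat& draws, int N, int m, int K,
                       bool has_general, bool rt_unidim) {
  Layout lay = make_layout(N, m, K, has_general, rt_unidim);
  if ((int)draws.n_cols != lay.D) Rcpp::stop("draws have wrong width");
  const int S = draws.n_rows;
  // constrained layout: a_s, alpha_s, sigma, d, beta [, a_g, alpha_g], hyper
  // (mu_d, mu_beta, sigma_d, sigma_beta, rho_d_beta) [, rho_g],
  // rho_s/rho_tau (K), theta_s (N*K), tau_s (N*K) or tau (N)
  // [, theta_g (N), tau_g (N)]
  int P = 5 * m + (has_general ? 2 * m : 0) + 5 + (has_general ? 1 : 0) + K +
          N * K + (rt_unidim ? N : N * K) + (has_general ? 2 * N : 0);
  mat out(S, P);
  for (int s = 0; s < S; ++s) {
    vec x = draws.row(s).t();
    Derived dv = derive(x, lay);
    int pos = 0;
    out(s, span(pos, pos + m - 1)) = dv.a_s.t(); pos += m;
    out(s, span(pos, pos + m - 1)) = dv.alpha_s.t(); pos += m;
    out(s, span(pos, pos + m - 1)) = dv.sig.t(); pos += m;
    out(s, span(pos, pos + m - 1)) = dv.d.t(); pos += m;
    out(s, span(pos, pos + m - 1)) = dv.b.t(); pos += m;
    if (has_general) {
      out(s, span(pos, pos + m - 1)) = dv.a_g.t(); pos += m;
      out(s, span(pos, pos + m - 1)) = dv.alpha_g.t(); pos += m;
    }
    out(s, pos++) = dv.mu_d;
    out(s, pos++) = dv.mu_b;
    out(s, pos++) = dv.sd_d;
    out(s, pos++) = dv.sd_b;
    out(s, pos++) = dv.rho_db;
    if (has_general) out(s, pos++) = dv.rho_g;
    if (!rt_unidim) {
      out(s, span(pos, pos + K - 1)) = dv.rho_s.t(); pos += K;
    } else {
      out(s, span(pos, pos + K - 1)) = dv.r_u.t(); pos += K;
    }
    out(s, span(pos, pos + N * K - 1)) = vectorise(dv.Ths).t(); pos += N * K;
    if (!rt_unidim) {
      out(s, span(pos, pos + N * K - 1)) = vectorise(dv.Taus).t();
      pos += N * K;
    } else {
      out(s, span(pos, pos + N - 1)) = dv.tau_u.t(); pos += N;
    }
    if (has_general) {
      out(s, span(pos, pos + N - 1)) = dv.thg.t(); pos += N;
      out(s, span(pos, pos + N - 1)) = dv.taug.t(); pos += N;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bf_pointwise")]]
Rcpp::List bf_pointwise(const arma::mat& draws, const arma::imat& U,
                        const arma::mat& L, const arma::uvec& group0, int K,
                        bool has_general, bool rt_unidim) {
  Layout lay = make_layout(U.n_rows, U.n_cols, K, has_general, rt_unidim);
  if ((int)draws.n_cols != lay.D) Rcpp::stop("draws have wrong width");
  const int S = draws.n_rows, N = lay.N, m = lay.m;
  const double LOG_SQRT_2PI = 0.9189385332046727;
  mat ra(S, N * m), rt(S, N * m);
  for (int s = 0; s < S; ++s) {
    vec x = draws.row(s).t();
    Derived dv = derive(x, lay);
    mat E = ra_eta(dv, lay, group0);
    mat M = rt_mu(dv, lay, group0);
    for (int j = 0; j < m; ++j) {
      const double log_sj = std::log(dv.sig[j]);
      const double inv_s2 = 1.0 / (dv.sig[j] * dv.sig[j]);
      for (int i = 0; i < N; ++i) {
        const int cell = i + N * j;
        const int u = U(i, j);
        ra(s, cell) = (u >= 0) ? u * E(i, j) - stable_log1pexp(E(i, j)) : NA_REAL;
        const double lt = L(i, j);
        if (std::isfinite(lt)) {
          const double res = lt - M(i, j);
          rt(s, cell) = -log_sj - 0.5 * res * res * inv_s2 - LOG_SQRT_2PI;
        } else {
          rt(s, cell) = NA_REAL;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("ra") = ra, Rcpp::Named("rt") = rt);
}
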