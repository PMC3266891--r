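#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Bernoulli log-likelihood term, stable for large |eta|
static inline double bern_ll(int d, double eta) {
  if (eta > 0.0)
    return d * eta - eta - std::log1p(std::exp(-eta));
  return d * eta - std::log1p(std::exp(eta));
}

struct Graph {
  int H;
  std::vector<std::vector<int> > nb;    // neighbour ids (0-based)
  std::vector<std::vector<double> > wt; // matching weights
  double total_weight;
  bool integral;                        // all weights nonnegative integers
  int max_site_weight;                  // max over sites of summed weights
  Graph(int H_, const IntegerVector& ei, const IntegerVector& ej,
        const NumericVector& ew) : H(H_), nb(H_), wt(H_), total_weight(0.0) {
    integral = true;
    for (int e = 0; e < ei.size(); ++e) {
      int a = ei[e] - 1, b = ej[e] - 1;
      nb[a].push_back(b); wt[a].push_back(ew[e]);
      nb[b].push_back(a); wt[b].push_back(ew[e]);
      total_weight += ew[e];
      if (ew[e] < 0 || ew[e] != std::floor(ew[e])) integral = false;
    }
    max_site_weight = 0;
    for (int h = 0; h < H_; ++h) {
      double s = 0;
      for (size_t t = 0; t < wt[h].size(); ++t) s += wt[h][t];
      if ((int) std::ceil(s) > max_site_weight)
        max_site_weight = (int) std::ceil(s);
    }
  }
};

// Potts sufficient statistic U(z) = sum_{h<h'} w * I(z_h == z_h')
static double suff_stat(const std::vector<int>& z, const Graph& g) {
  double u = 0.0;
  for (int h = 0; h < g.H; ++h)
    for (size_t t = 0; t < g.nb[h].size(); ++t) {
      int hp = g.nb[h][t];
      if (hp > h && z[hp] == z[h]) u += g.wt[h][t];
    }
  return u;
}

// neighbour-weight sums u_{hk} for one site
static inline void site_weights(const std::vector<int>& z, const Graph& g,
                                int h, int K, std::vector<double>& u) {
  std::fill(u.begin(), u.begin() + K, 0.0);
  for (size_t t = 0; t < g.nb[h].size(); ++t)
    u[z[g.nb[h][t]]] += g.wt[h][t];
}

static int sample_cat_log(const std::vector<double>& logp, int K) {
  double mx = logp[0];
  for (int k = 1; k < K; ++k) if (logp[k] > mx) mx = logp[k];
  double tot = 0.0;
  std::vector<double> p(K);
  for (int k = 0; k < K; ++k) { p[k] = std::exp(logp[k] - mx); tot += p[k]; }
  double r = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) { c += p[k]; if (r <= c) return k; }
  return K - 1;
}

// one full prior-only Gibbs sweep at coupling psi; when the graph has
// integral weights an exp(psi * u) lookup table avoids per-site exp calls
struct PriorSampler {
  const Graph& g;
  int K;
  double psi;
  std::vector<double> tab;    // exp(psi * u), u = 0..max_site_weight
  std::vector<double> u, logp, p;
  PriorSampler(const Graph& g_, int K_, double psi_)
      : g(g_), K(K_), psi(psi_), u(K_), logp(K_), p(K_) {
    if (g.integral) {
      tab.resize(g.max_site_weight + 1);
      for (int v = 0; v <= g.max_site_weight; ++v)
        tab[v] = std::exp(psi * v);
    }
  }
  void sweep(std::vector<int>& z) {
    for (int h = 0; h < g.H; ++h) {
      site_weights(z, g, h, K, u);
      if (!tab.empty()) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { p[k] = tab[(int) u[k]]; tot += p[k]; }
        double r = unif_rand() * tot, c = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) { c += p[k]; if (r <= c) { pick = k; break; } }
        z[h] = pick;
      } else {
        for (int k = 0; k < K; ++k) logp[k] = psi * u[k];
        z[h] = sample_cat_log(logp, K);
      }
    }
  }
};

// [[Rcpp::export]]
double potts_suff_stat_cpp(IntegerVector z, int H, IntegerVector ei,
                           IntegerVector ej, NumericVector ew) {
  Graph g(H, ei, ej, ew);
  std::vector<int> zz(H);
  for (int h = 0; h < H; ++h) zz[h] = z[h] - 1;
  return suff_stat(zz, g);
}

// Gibbs draws from the Potts prior: fresh uniform start per draw,
// `sweeps` full single-site sweeps each.
// [[Rcpp::export]]
IntegerMatrix sample_potts_cpp(double psi, int H, IntegerVector ei,
                               IntegerVector ej, NumericVector ew, int K,
                               int n_samples, int sweeps) {
  Graph g(H, ei, ej, ew);
  PriorSampler ps(g, K, psi);
  IntegerMatrix out(n_samples, H);
  std::vector<int> z(H);
  for (int s = 0; s < n_samples; ++s) {
    for (int h = 0; h < H; ++h)
      z[h] = (int) std::floor(unif_rand() * K) % K;
    for (int sw = 0; sw < sweeps; ++sw) ps.sweep(z);
    for (int h = 0; h < H; ++h) out(s, h) = z[h] + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full posterior chain.
//
// Blocks per iteration, in order:
//   1. random-walk MH on each intercept alpha_k, each exposure slope beta
//      (per cluster under the interaction form, shared otherwise) and each
//      covariate coefficient gamma_j, against likelihood x prior;
//   2. Metropolized-Gibbs single-site update of the allocation vector z;
//   3. (every psi_every iterations) MCMH update of the Potts coupling psi:
//      the intractable normalizing-constant ratio is replaced by an
//      importance-sampling estimate from m auxiliary draws of a prior-only
//      Gibbs chain started at the current allocation state.
//
// When the exposure is binary and there are no covariates, the Bernoulli
// likelihood factorizes through per-genotype and per-cluster counts of the
// four (D, E) cells, and all likelihood evaluations reduce to O(K) table
// arithmetic; the general per-subject path covers continuous exposure and
// covariate adjustment.
//
// prior_type: 0 = normal(0, prior_sd^2), 1 = uniform[-prior_bound, prior_bound]
// [[Rcpp::export]]
List run_chain_cpp(IntegerVector D, NumericVector E, NumericMatrix X,
                   IntegerVector cid, int H,
                   IntegerVector ei, IntegerVector ej, NumericVector ew,
                   int K, bool interaction,
                   int iterations, int burn_in, int thinning,
                   int m_aux, int aux_sweeps, int psi_every,
                   double sd_alpha, double sd_beta, double sd_gamma,
                   double sd_psi,
                   int prior_type, double prior_sd, double prior_bound,
                   double psi_max, bool adapt,
                   IntegerVector z_init, double psi_init,
                   NumericVector alpha_init, NumericVector beta_init,
                   NumericVector gamma_init) {
  const int n = D.size(), p = X.ncol();
  const int nbeta = interaction ? K : 1;
  Graph g(H, ei, ej, ew);

  std::vector<int> z(H);
  for (int h = 0; h < H; ++h) z[h] = z_init[h] - 1;
  double psi = psi_init;

  std::vector<double> alpha(K, 0.0), beta(nbeta, 0.0), gamma(p, 0.0);
  for (int k = 0; k < K && k < alpha_init.size(); ++k) alpha[k] = alpha_init[k];
  for (int k = 0; k < nbeta && k < beta_init.size(); ++k) beta[k] = beta_init[k];
  for (int j = 0; j < p && j < gamma_init.size(); ++j) gamma[j] = gamma_init[j];

  std::vector<double> off(n, 0.0);            // covariate part of eta
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) off[i] += gamma[j] * X(i, j);
  std::vector<int> ki(n);                     // subject's current cluster
  for (int i = 0; i < n; ++i) ki[i] = z[cid[i] - 1];

  // subjects carrying each distinct genotype
  std::vector<std::vector<int> > subj(H);
  for (int i = 0; i < n; ++i) subj[cid[i] - 1].push_back(i);

  // ---- sufficient-statistic fast path (binary E, no covariates) --------
  bool fast = (p == 0);
  for (int i = 0; i < n && fast; ++i)
    if (E[i] != 0.0 && E[i] != 1.0) fast = false;
  // cell index de = 2*D + E
  std::vector<std::array<double, 4> > cnt_h;   // per-genotype cell counts
  std::vector<std::array<double, 4> > N_k;     // per-cluster cell counts
  std::vector<std::array<double, 4> > val_k;   // bern_ll(d, alpha_k+beta_k*e)
  auto refresh_val = [&](int k) {
    double bk = interaction ? beta[k] : beta[0];
    val_k[k][0] = bern_ll(0, alpha[k]);
    val_k[k][1] = bern_ll(0, alpha[k] + bk);
    val_k[k][2] = bern_ll(1, alpha[k]);
    val_k[k][3] = bern_ll(1, alpha[k] + bk);
  };
  if (fast) {
    cnt_h.assign(H, {0, 0, 0, 0});
    N_k.assign(K, {0, 0, 0, 0});
    val_k.assign(K, {0, 0, 0, 0});
    for (int i = 0; i < n; ++i) {
      int de = 2 * D[i] + (int) E[i];
      cnt_h[cid[i] - 1][de] += 1;
    }
    for (int h = 0; h < H; ++h)
      for (int de = 0; de < 4; ++de) N_k[z[h]][de] += cnt_h[h][de];
    for (int k = 0; k < K; ++k) refresh_val(k);
  }

  double U = suff_stat(z, g);

  std::vector<double> s_alpha(K, sd_alpha), s_beta(nbeta, sd_beta),
      s_gamma(p, sd_gamma);
  double s_psi = sd_psi;

  double acc_alpha = 0, try_alpha = 0, acc_beta = 0, try_beta = 0,
         acc_gamma = 0, try_gamma = 0, acc_z = 0, try_z = 0,
         acc_psi = 0, try_psi = 0;
  std::vector<double> win_try_a(K, 0), win_acc_a(K, 0),
      win_try_b(nbeta, 0), win_acc_b(nbeta, 0),
      win_try_g(p, 0), win_acc_g(p, 0);
  double win_try_psi = 0, win_acc_psi = 0;
  const int adapt_window = 100;

  auto lp_coef = [&](double v) -> double {
    if (prior_type == 0) return -0.5 * v * v / (prior_sd * prior_sd);
    return (std::fabs(v) <= prior_bound) ? 0.0 : R_NegInf;
  };
  auto eta_of = [&](int i, int k) -> double {
    return alpha[k] + (interaction ? beta[k] : beta[0]) * E[i] + off[i];
  };

  const int n_draws = (iterations - burn_in) / thinning;
  IntegerMatrix z_out(n_draws, H);
  NumericMatrix a_out(n_draws, K), b_out(n_draws, nbeta), g_out(n_draws, p);
  NumericVector psi_out(n_draws), ll_out(n_draws);

  std::vector<double> u(K), logp(K), prob(K);
  std::vector<int> aux(H);
  int stored = 0;

  for (int it = 1; it <= iterations; ++it) {
    // --- 1. coefficients ------------------------------------------------
    for (int k = 0; k < K; ++k) {                       // alpha_k
      double d = s_alpha[k] * norm_rand();
      double dll = lp_coef(alpha[k] + d) - lp_coef(alpha[k]);
      if (R_finite(dll)) {
        if (fast) {
          double bk = interaction ? beta[k] : beta[0];
          double a2 = alpha[k] + d;
          dll += N_k[k][0] * (bern_ll(0, a2) - val_k[k][0])
               + N_k[k][1] * (bern_ll(0, a2 + bk) - val_k[k][1])
               + N_k[k][2] * (bern_ll(1, a2) - val_k[k][2])
               + N_k[k][3] * (bern_ll(1, a2 + bk) - val_k[k][3]);
        } else {
          for (int i = 0; i < n; ++i) if (ki[i] == k) {
            double e0 = eta_of(i, k);
            dll += bern_ll(D[i], e0 + d) - bern_ll(D[i], e0);
          }
        }
      }
      ++try_alpha; ++win_try_a[k];
      if (R_finite(dll) && std::log(unif_rand()) < dll) {
        alpha[k] += d; ++acc_alpha; ++win_acc_a[k];
        if (fast) refresh_val(k);
      }
    }
    for (int k = 0; k < nbeta; ++k) {                   // beta
      double d = s_beta[k] * norm_rand();
      double dll = lp_coef(beta[k] + d) - lp_coef(beta[k]);
      if (R_finite(dll)) {
        if (fast) {
          if (interaction) {
            double b2 = beta[k] + d;
            dll += N_k[k][1] * (bern_ll(0, alpha[k] + b2) - val_k[k][1])
                 + N_k[k][3] * (bern_ll(1, alpha[k] + b2) - val_k[k][3]);
          } else {
            double b2 = beta[0] + d;
            for (int kk = 0; kk < K; ++kk)
              dll += N_k[kk][1] * (bern_ll(0, alpha[kk] + b2) - val_k[kk][1])
                   + N_k[kk][3] * (bern_ll(1, alpha[kk] + b2) - val_k[kk][3]);
          }
        } else {
          for (int i = 0; i < n; ++i) if (!interaction || ki[i] == k) {
            double e0 = eta_of(i, ki[i]);
            dll += bern_ll(D[i], e0 + d * E[i]) - bern_ll(D[i], e0);
          }
        }
      }
      ++try_beta; ++win_try_b[k];
      if (R_finite(dll) && std::log(unif_rand()) < dll) {
        beta[k] += d; ++acc_beta; ++win_acc_b[k];
        if (fast) {
          if (interaction) refresh_val(k);
          else for (int kk = 0; kk < K; ++kk) refresh_val(kk);
        }
      }
    }
    for (int j = 0; j < p; ++j) {                       // gamma_j
      double d = s_gamma[j] * norm_rand();
      double dll = lp_coef(gamma[j] + d) - lp_coef(gamma[j]);
      if (R_finite(dll)) {
        for (int i = 0; i < n; ++i) {
          double e0 = eta_of(i, ki[i]);
          dll += bern_ll(D[i], e0 + d * X(i, j)) - bern_ll(D[i], e0);
        }
      }
      ++try_gamma; ++win_try_g[j];
      if (R_finite(dll) && std::log(unif_rand()) < dll) {
        gamma[j] += d; ++acc_gamma; ++win_acc_g[j];
        for (int i = 0; i < n; ++i) off[i] += d * X(i, j);
      }
    }

    // --- 2. allocations (Metropolized Gibbs) ----------------------------
    if (K > 1) {
      for (int h = 0; h < H; ++h) {
        site_weights(z, g, h, K, u);
        bool has_subj = !subj[h].empty();
        for (int k = 0; k < K; ++k) {
          double lp = psi * u[k];
          if (has_subj) {
            if (fast) {
              lp += cnt_h[h][0] * val_k[k][0] + cnt_h[h][1] * val_k[k][1]
                  + cnt_h[h][2] * val_k[k][2] + cnt_h[h][3] * val_k[k][3];
            } else {
              for (size_t t = 0; t < subj[h].size(); ++t) {
                int i = subj[h][t];
                lp += bern_ll(D[i], alpha[k] +
                              (interaction ? beta[k] : beta[0]) * E[i] + off[i]);
              }
            }
          }
          logp[k] = lp;
        }
        double mx = logp[0];
        for (int k = 1; k < K; ++k) if (logp[k] > mx) mx = logp[k];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { prob[k] = std::exp(logp[k] - mx); tot += prob[k]; }
        for (int k = 0; k < K; ++k) prob[k] /= tot;
        int k0 = z[h];
        double rest = 1.0 - prob[k0];
        ++try_z;
        if (rest > 1e-300) {
          double r = unif_rand() * rest, c = 0.0;
          int kp = -1;
          for (int k = 0; k < K; ++k) {
            if (k == k0) continue;
            c += prob[k];
            if (r <= c) { kp = k; break; }
          }
          if (kp < 0) kp = (k0 == K - 1) ? K - 2 : K - 1;
          double a = rest / (1.0 - prob[kp]);      // Liu's acceptance ratio
          if (a >= 1.0 || unif_rand() < a) {
            U += (u[kp] - u[k0]);
            z[h] = kp;
            for (size_t t = 0; t < subj[h].size(); ++t) ki[subj[h][t]] = kp;
            if (fast)
              for (int de = 0; de < 4; ++de) {
                N_k[k0][de] -= cnt_h[h][de];
                N_k[kp][de] += cnt_h[h][de];
              }
            ++acc_z;
          }
        }
      }
    }

    // --- 3. regulating parameter via MCMH -------------------------------
    if (K > 1 && psi_every > 0 && it % psi_every == 0 && psi_max > 0) {
      double prop = psi + s_psi * norm_rand();
      for (int guard = 0; guard < 64 && (prop < 0 || prop > psi_max); ++guard) {
        if (prop < 0) prop = -prop;
        if (prop > psi_max) prop = 2 * psi_max - prop;
      }
      double dpsi = prop - psi;
      double mx = R_NegInf;
      std::vector<double> lw(m_aux);
      aux = z;
      PriorSampler ps(g, K, psi);
      for (int s = 0; s < m_aux; ++s) {
        for (int sw = 0; sw < aux_sweeps; ++sw) ps.sweep(aux);
        lw[s] = dpsi * suff_stat(aux, g);
        if (lw[s] > mx) mx = lw[s];
      }
      double sum = 0.0;
      for (int s = 0; s < m_aux; ++s) sum += std::exp(lw[s] - mx);
      double log_est = mx + std::log(sum / m_aux);
      double log_acc = dpsi * U - log_est;     // uniform prior on [0, psi_max]
      ++try_psi; ++win_try_psi;
      if (std::log(unif_rand()) < log_acc) {
        psi = prop; ++acc_psi; ++win_acc_psi;
      }
    }

    // --- burn-in proposal-scale adaptation ------------------------------
    if (adapt && it <= burn_in && it % adapt_window == 0) {
      for (int k = 0; k < K; ++k) if (win_try_a[k] > 0) {
        double r = win_acc_a[k] / win_try_a[k];
        if (r > 0.45) s_alpha[k] *= 1.15; else if (r < 0.20) s_alpha[k] /= 1.15;
        win_try_a[k] = win_acc_a[k] = 0;
      }
      for (int k = 0; k < nbeta; ++k) if (win_try_b[k] > 0) {
        double r = win_acc_b[k] / win_try_b[k];
        if (r > 0.45) s_beta[k] *= 1.15; else if (r < 0.20) s_beta[k] /= 1.15;
        win_try_b[k] = win_acc_b[k] = 0;
      }
      for (int j = 0; j < p; ++j) if (win_try_g[j] > 0) {
        double r = win_acc_g[j] / win_try_g[j];
        if (r > 0.45) s_gamma[j] *= 1.15; else if (r < 0.20) s_gamma[j] /= 1.15;
        win_try_g[j] = win_acc_g[j] = 0;
      }
      if (win_try_psi > 0) {
        double r = win_acc_psi / win_try_psi;
        if (r > 0.45) s_psi = std::min(s_psi * 1.15, psi_max);
        else if (r < 0.20) s_psi /= 1.15;
        win_try_psi = win_acc_psi = 0;
      }
    }

    // --- storage --------------------------------------------------------
    if (it > burn_in && (it - burn_in) % thinning == 0 && stored < n_draws) {
      double ll = 0.0;
      if (fast) {
        for (int k = 0; k < K; ++k)
          for (int de = 0; de < 4; ++de) ll += N_k[k][de] * val_k[k][de];
      } else {
        for (int i = 0; i < n; ++i) ll += bern_ll(D[i], eta_of(i, ki[i]));
      }
      for (int h = 0; h < H; ++h) z_out(stored, h) = z[h] + 1;
      for (int k = 0; k < K; ++k) a_out(stored, k) = alpha[k];
      for (int k = 0; k < nbeta; ++k) b_out(stored, k) = beta[k];
      for (int j = 0; j < p; ++j) g_out(stored, j) = gamma[j];
      psi_out[stored] = psi;
      ll_out[stored] = ll;
      ++stored;
    }
    if (it % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["z"] = z_out, _["alpha"] = a_out, _["beta"] = b_out,
      _["gamma"] = g_out, _["psi"] = psi_out, _["loglik"] = ll_out,
      _["acceptance"] = NumericVector::create(
          _["alpha"] = try_alpha > 0 ? acc_alpha / try_alpha : NA_REAL,
          _["beta"] = try_beta > 0 ? acc_beta / try_beta : NA_REAL,
          _["gamma"] = try_gamma > 0 ? acc_gamma / try_gamma : NA_REAL,
          _["z"] = try_z > 0 ? acc_z / try_z : NA_REAL,
          _["psi"] = try_psi > 0 ? acc_psi / try_psi : NA_REAL));
}

// co-assignment proportion matrix over stored allocation draws
// [[Rcpp::export]]
NumericMatrix coassign_cpp(IntegerMatrix zdraws) {
  const int T = zdraws.nrow(), H = zdraws.ncol();
  NumericMatrix pi(H, H);
  for (int t = 0; t < T; ++t)
    for (int a = 0; a < H; ++a)
      for (int b = a; b < H; ++b)
        if (zdraws(t, a) == zdraws(t, b)) { pi(a, b) += 1.0; }
  for (int a = 0; a < H; ++a)
    for (int b = a; b < H; ++b) {
      pi(a, b) /= T;
      pi(b, a) = pi(a, b);
    }
  return pi;
}

// ---------------------------------------------------------------------------
// PAM (k-medoids): BUILD followed by SWAP using the standard delta formula
// with nearest / second-nearest medoid distances. Deterministic: all ties
// broken by the lowest index.
// [[Rcpp::export]]
List pam_cpp(NumericMatrix d, int k) {
  const int H = d.nrow();
  std::vector<bool> is_med(H, false);
  std::vector<int> med;

  // BUILD: first medoid minimizes total dissimilarity
  {
    int best = 0; double bestv = R_PosInf;
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int j = 0; j < H; ++j) s += d(j, i);
      if (s < bestv - 1e-12) { bestv = s; best = i; }
    }
    med.push_back(best); is_med[best] = true;
  }
  std::vector<double> d1(H);   // distance to nearest medoid
  for (int i = 0; i < H; ++i) d1[i] = d(i, med[0]);
  while ((int) med.size() < k) {
    int best = -1; double bestgain = -1;
    for (int c = 0; c < H; ++c) {
      if (is_med[c]) continue;
      double gain = 0;
      for (int i = 0; i < H; ++i) {
        double diff = d1[i] - d(i, c);
        if (diff > 0) gain += diff;
      }
      if (gain > bestgain + 1e-12) { bestgain = gain; best = c; }
    }
    med.push_back(best); is_med[best] = true;
    for (int i = 0; i < H; ++i) if (d(i, best) < d1[i]) d1[i] = d(i, best);
  }

  // SWAP
  const int kk = (int) med.size();
  std::vector<double> d2(H);
  std::vector<int> a1(H);      // index (into med) of nearest medoid
  auto refresh = [&]() {
    for (int i = 0; i < H; ++i) {
      double b1 = R_PosInf, b2 = R_PosInf; int w = -1;
      for (int m = 0; m < kk; ++m) {
        double v = d(i, med[m]);
        if (v < b1) { b2 = b1; b1 = v; w = m; }
        else if (v < b2) b2 = v;
      }
      d1[i] = b1; d2[i] = b2; a1[i] = w;
    }
  };
  refresh();
  bool improved = true;
  int guard = 0;
  while (improved && ++guard <= 500) {
    improved = false;
    int bm = -1, bc = -1; double bdelta = -1e-12;
    for (int m = 0; m < kk; ++m) {
      for (int c = 0; c < H; ++c) {
        if (is_med[c]) continue;
        double delta = 0;
        for (int i = 0; i < H; ++i) {
          double dic = d(i, c);
          if (a1[i] != m) {
            if (dic < d1[i]) delta += dic - d1[i];
          } else {
            double alt = dic < d2[i] ? dic : d2[i];
            delta += alt - d1[i];
          }
        }
        if (delta < bdelta) { bdelta = delta; bm = m; bc = c; }
      }
    }
    if (bm >= 0) {
      is_med[med[bm]] = false;
      med[bm] = bc; is_med[bc] = true;
      refresh();
      improved = true;
    }
  }

  std::sort(med.begin(), med.end());
  IntegerVector medoids(kk), labels(H);
  for (int m = 0; m < kk; ++m) medoids[m] = med[m] + 1;
  double obj = 0;
  for (int i = 0; i < H; ++i) {
    double b1 = R_PosInf; int w = 0;
    for (int m = 0; m < kk; ++m) {
      double v = d(i, med[m]);
      if (v < b1) { b1 = v; w = m; }
    }
    labels[i] = w + 1; obj += b1;
  }
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["objective"] = obj);
}
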