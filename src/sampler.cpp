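// Adaptive MCMC sampler for the two hierarchical models:
//
//   family 0: y_i ~ Poisson(exp(eta_i)),  eta_i = x_i'beta + u_loc + u_hh +
//             u_part + e_i, with an observation-level normal deviate e_i
//             (lognormal-Poisson overdispersion);
//   family 1: y_i ~ Bernoulli(1 - (1 - p_i)^{m_i}), logit p_i = x_i'beta +
//             u_loc + u_hh + u_part  (group-aware any-of-m likelihood).
//
// Fixed effects use component-wise random walks for a short initial
// stretch of warmup, then Hamiltonian (leapfrog) updates of the whole
// beta block with a diagonal mass matrix and step size adapted during
// warmup. Random effects are updated unit-by-unit (centered), and each RE
// scale gets both a centered update and a non-centered interweaving move
// that rescales the whole effect vector, which keeps mixing healthy when
// sigma is near zero.
// Priors: beta_j ~ N(0, prior_sd_beta_j), sigma ~ half-Normal(0,
// prior_sd_sigma). All randomness comes from one seeded mt19937_64 stream,
// so chains are bit-reproducible.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm{0.0, 1.0};
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(unsigned long long seed) : gen(seed) {}
  double rnorm() { return norm(gen); }
  double runif() { return unif(gen); }
};

inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log P(y | eta) for one observation
inline double point_ll(int family, double y, double m, double eta,
                       double lgamma_y1) {
  if (family == 0) {
    double e = eta > 50.0 ? 50.0 : eta;
    return y * e - std::exp(e) - lgamma_y1;
  }
  double s = m * softplus(eta);  // -m * log(1 - p) > 0
  if (y > 0.5) {
    if (s < 1e-12) s = 1e-12;  // guards log(0) when p underflows
    return std::log(-std::expm1(-s));
  }
  return -s;
}

// derivative of the observation log-likelihood wrt eta
inline double point_dll(int family, double y, double m, double eta) {
  if (family == 0) {
    double e = eta > 50.0 ? 50.0 : eta;
    return y - std::exp(e);
  }
  double p = 1.0 / (1.0 + std::exp(-eta));
  if (y < 0.5) return -m * p;
  double s = m * softplus(eta);
  if (s < 1e-12) s = 1e-12;
  return m * p / std::expm1(s);
}

struct Level {
  int n_units = 0;
  std::vector<std::vector<int>> rows;
  std::vector<int> unit_of_row;  // -1 when absent
  std::vector<double> u;
  std::vector<double> lstep_u;
  double log_sigma = std::log(0.3);
  double lstep_sigma = std::log(0.3);
  double lstep_sigma_nc = std::log(0.2);
  double lstep_rc = std::log(0.1);
  bool present = false;
};

void build_level(Level& lv, const IntegerVector& idx, int N) {
  lv.unit_of_row.assign(N, -1);
  if (idx.size() == 0) return;
  int mx = 0;
  for (int i = 0; i < N; ++i) mx = std::max(mx, idx[i]);
  lv.n_units = mx;
  lv.rows.assign(mx, {});
  for (int i = 0; i < N; ++i) {
    lv.unit_of_row[i] = idx[i] - 1;
    lv.rows[idx[i] - 1].push_back(i);
  }
  lv.u.assign(mx, 0.0);
  lv.lstep_u.assign(mx, std::log(0.2));
  lv.present = true;
}

// Cholesky of a small SPD matrix (row-major), jittered if needed.
bool chol_lower(std::vector<double>& A, int P) {
  for (int j = 0; j < P; ++j) {
    double d = A[j * P + j];
    for (int k = 0; k < j; ++k) d -= A[j * P + k] * A[j * P + k];
    if (d <= 0) return false;
    d = std::sqrt(d);
    A[j * P + j] = d;
    for (int i = j + 1; i < P; ++i) {
      double s = A[i * P + j];
      for (int k = 0; k < j; ++k) s -= A[i * P + k] * A[j * P + k];
      A[i * P + j] = s / d;
    }
    for (int i = 0; i < j; ++i) A[i * P + j] = 0.0;
  }
  return true;
}

inline double half_normal_lp(double sigma, double sd) {
  return -0.5 * (sigma / sd) * (sigma / sd);
}

}  // namespace

// [[Rcpp::export]]
List et_run_chain(NumericMatrix X, NumericVector y, NumericVector m,
                  int family, IntegerVector loc_idx, IntegerVector hh_idx,
                  IntegerVector part_idx, NumericVector beta_init,
                  NumericVector prior_sd_beta, double prior_sd_sigma,
                  int n_iter, int n_warmup, int seed, bool store_loglik) {
  const int N = X.nrow(), P = X.ncol();
  Rng rng(static_cast<unsigned long long>(seed));

  std::vector<double> lgam(N, 0.0);
  if (family == 0) {
    for (int i = 0; i < N; ++i) lgam[i] = std::lgamma(y[i] + 1.0);
  }

  Level levels[3];
  build_level(levels[0], loc_idx, N);
  build_level(levels[1], hh_idx, N);
  build_level(levels[2], part_idx, N);
  const bool has_obs = (family == 0);
  std::vector<double> e_obs(has_obs ? N : 0, 0.0);
  std::vector<double> lstep_obs(has_obs ? N : 0, std::log(0.5));
  double log_sigma_obs = std::log(0.3);
  double lstep_sigma_obs = std::log(0.3), lstep_sigma_obs_nc = std::log(0.2);
  double lstep_obs_rc = std::log(0.1);

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> eta(N), ll(N);
  auto recompute_eta = [&]() {
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int j = 0; j < P; ++j) s += X(i, j) * beta[j];
      for (auto& lv : levels) {
        if (lv.present) s += lv.u[lv.unit_of_row[i]];
      }
      if (has_obs) s += e_obs[i];
      eta[i] = s;
    }
  };
  recompute_eta();
  double ll_sum = 0.0;
  for (int i = 0; i < N; ++i) {
    ll[i] = point_ll(family, y[i], m[i], eta[i], lgam[i]);
    ll_sum += ll[i];
  }
  auto beta_prior = [&](const std::vector<double>& b) {
    double s = 0.0;
    for (int j = 0; j < P; ++j) {
      s += -0.5 * (b[j] / prior_sd_beta[j]) * (b[j] / prior_sd_beta[j]);
    }
    return s;
  };

  // component-wise beta steps (early warmup) and HMC state for the beta
  // block: diagonal mass from the running warmup variances, leapfrog step
  // size adapted towards 0.8 acceptance.
  std::vector<double> lstep_beta(P, std::log(0.1));
  std::vector<double> bmean(P, 0.0), bvarM2(P, 0.0);
  long bcount = 0;
  std::vector<double> mass(P, 100.0);  // ~ 1 / var(beta_j)
  double leps = std::log(0.05);
  const int phase1_end = std::min(60, std::max(20, n_warmup / 5));

  const int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, P + 3 + (has_obs ? 1 : 0));
  NumericMatrix llmat(store_loglik ? n_keep : 0, store_loglik ? N : 0);
  std::vector<double> new_eta(N), new_ll(N);
  long acc_joint = 0, try_joint = 0;

  // gradient of the log posterior wrt beta at the state in new_eta
  std::vector<double> grow(N), gbeta(P);
  auto beta_grad = [&](const std::vector<double>& b,
                       const std::vector<double>& et) {
    for (int i = 0; i < N; ++i) {
      grow[i] = point_dll(family, y[i], m[i], et[i]);
    }
    for (int j = 0; j < P; ++j) {
      const double* col = &X(0, j);
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += col[i] * grow[i];
      gbeta[j] = s - b[j] / (prior_sd_beta[j] * prior_sd_beta[j]);
    }
  };

  for (int t = 1; t <= n_iter; ++t) {
    const bool warm = t <= n_warmup;
    const double gam = std::pow((double)t, -0.6);

    // ---- fixed effects ----
    if (t <= phase1_end) {
      for (int j = 0; j < P; ++j) {
        double d = std::exp(lstep_beta[j]) * rng.rnorm();
        double bj_new = beta[j] + d;
        double new_sum = 0.0;
        for (int i = 0; i < N; ++i) {
          new_eta[i] = eta[i] + X(i, j) * d;
          new_ll[i] = point_ll(family, y[i], m[i], new_eta[i], lgam[i]);
          new_sum += new_ll[i];
        }
        double dprior = -0.5 * (bj_new * bj_new - beta[j] * beta[j]) /
                        (prior_sd_beta[j] * prior_sd_beta[j]);
        bool acc = std::log(rng.runif()) < new_sum - ll_sum + dprior;
        if (acc) {
          beta[j] = bj_new;
          eta.swap(new_eta);
          ll.swap(new_ll);
          ll_sum = new_sum;
        }
        if (warm) lstep_beta[j] += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
    } else {
      // Hamiltonian update of the whole beta block
      std::vector<double> bq = beta, mom(P);
      double kin0 = 0.0;
      for (int j = 0; j < P; ++j) {
        mom[j] = rng.rnorm() * std::sqrt(mass[j]);
        kin0 += 0.5 * mom[j] * mom[j] / mass[j];
      }
      const double H0 = -(ll_sum + beta_prior(beta)) + kin0;
      const double eps = std::exp(leps);
      const int L = 6 + (int)(rng.runif() * 6.0);  // 6..11 leapfrog steps
      std::copy(eta.begin(), eta.end(), new_eta.begin());
      beta_grad(bq, new_eta);
      bool diverged = false;
      double new_sum = 0.0;
      for (int l = 0; l < L; ++l) {
        for (int j = 0; j < P; ++j) mom[j] += 0.5 * eps * gbeta[j];
        for (int j = 0; j < P; ++j) {
          const double dq = eps * mom[j] / mass[j];
          bq[j] += dq;
          const double* col = &X(0, j);
          for (int i = 0; i < N; ++i) new_eta[i] += col[i] * dq;
        }
        beta_grad(bq, new_eta);
        for (int j = 0; j < P; ++j) mom[j] += 0.5 * eps * gbeta[j];
        for (int j = 0; j < P; ++j) {
          if (!std::isfinite(bq[j]) || !std::isfinite(mom[j])) {
            diverged = true;
            break;
          }
        }
        if (diverged) break;
      }
      double acc_prob = 0.0;
      if (!diverged) {
        new_sum = 0.0;
        for (int i = 0; i < N; ++i) {
          new_ll[i] = point_ll(family, y[i], m[i], new_eta[i], lgam[i]);
          new_sum += new_ll[i];
        }
        double kin1 = 0.0;
        for (int j = 0; j < P; ++j) kin1 += 0.5 * mom[j] * mom[j] / mass[j];
        double H1 = -(new_sum + beta_prior(bq)) + kin1;
        if (!std::isfinite(H1) || H1 - H0 > 1000.0) {
          diverged = true;
        } else {
          acc_prob = std::min(1.0, std::exp(H0 - H1));
        }
      }
      bool acc = !diverged && rng.runif() < acc_prob;
      ++try_joint;
      if (acc) {
        ++acc_joint;
        beta.swap(bq);
        eta.swap(new_eta);
        ll.swap(new_ll);
        ll_sum = new_sum;
      }
      if (warm) leps += 4.0 * gam * (acc_prob - 0.8);
    }
    if (warm) {
      // running per-component variance of beta -> diagonal mass matrix
      ++bcount;
      for (int j = 0; j < P; ++j) {
        double delta = beta[j] - bmean[j];
        bmean[j] += delta / bcount;
        bvarM2[j] += delta * (beta[j] - bmean[j]);
      }
      if (bcount >= 40 && t % 25 == 0) {
        for (int j = 0; j < P; ++j) {
          double v = bvarM2[j] / (bcount - 1);
          if (v < 1e-8) v = 1e-8;
          mass[j] = 1.0 / v;
        }
      }
    }

    // ---- random-effect levels ----
    for (auto& lv : levels) {
      if (!lv.present) continue;
      double sigma = std::exp(lv.log_sigma);
      for (int k = 0; k < lv.n_units; ++k) {
        double d = std::exp(lv.lstep_u[k]) * rng.rnorm();
        double u_new = lv.u[k] + d;
        double dll = 0.0;
        for (int i : lv.rows[k]) {
          double nll = point_ll(family, y[i], m[i], eta[i] + d, lgam[i]);
          dll += nll - ll[i];
        }
        double dprior = -0.5 * (u_new * u_new - lv.u[k] * lv.u[k]) /
                        (sigma * sigma);
        bool acc = std::log(rng.runif()) < dll + dprior;
        if (acc) {
          lv.u[k] = u_new;
          for (int i : lv.rows[k]) {
            eta[i] += d;
            double nll = point_ll(family, y[i], m[i], eta[i], lgam[i]);
            ll_sum += nll - ll[i];
            ll[i] = nll;
          }
        }
        if (warm) lv.lstep_u[k] += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
      // recentering: shift the intercept against the whole effect vector;
      // the likelihood is invariant, only the priors move, so this frees
      // the intercept from the random-effect means
      {
        double d = std::exp(lv.lstep_rc) * rng.rnorm();
        double b0_new = beta[0] + d;
        double dprior = -0.5 * (b0_new * b0_new - beta[0] * beta[0]) /
                        (prior_sd_beta[0] * prior_sd_beta[0]);
        double sig2 = sigma * sigma;
        for (double u : lv.u) {
          dprior += -0.5 * ((u - d) * (u - d) - u * u) / sig2;
        }
        bool acc = std::log(rng.runif()) < dprior;
        if (acc) {
          beta[0] = b0_new;
          for (auto& u : lv.u) u -= d;
        }
        if (warm) lv.lstep_rc += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
      // centered scale update (prior of u only)
      for (int rep = 0; rep < 3; ++rep) {
        double ls_new = lv.log_sigma + std::exp(lv.lstep_sigma) * rng.rnorm();
        double s_old = std::exp(lv.log_sigma), s_new = std::exp(ls_new);
        double usq = 0.0;
        for (double u : lv.u) usq += u * u;
        double lp_new = -lv.n_units * ls_new - 0.5 * usq / (s_new * s_new) +
                        half_normal_lp(s_new, prior_sd_sigma) + ls_new;
        double lp_old = -lv.n_units * lv.log_sigma -
                        0.5 * usq / (s_old * s_old) +
                        half_normal_lp(s_old, prior_sd_sigma) + lv.log_sigma;
        bool acc = std::log(rng.runif()) < lp_new - lp_old;
        if (acc) lv.log_sigma = ls_new;
        if (warm) lv.lstep_sigma += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
      // interweaving: rescale u holding u/sigma fixed (likelihood moves)
      {
        double ls_new =
            lv.log_sigma + std::exp(lv.lstep_sigma_nc) * rng.rnorm();
        double r = std::exp(ls_new - lv.log_sigma);
        double new_sum = 0.0;
        for (int i = 0; i < N; ++i) {
          new_eta[i] = eta[i] + (r - 1.0) * lv.u[lv.unit_of_row[i]];
          new_ll[i] = point_ll(family, y[i], m[i], new_eta[i], lgam[i]);
          new_sum += new_ll[i];
        }
        double s_old = std::exp(lv.log_sigma), s_new = std::exp(ls_new);
        double dprior = half_normal_lp(s_new, prior_sd_sigma) + ls_new -
                        half_normal_lp(s_old, prior_sd_sigma) -
                        lv.log_sigma;
        bool acc = std::log(rng.runif()) < new_sum - ll_sum + dprior;
        if (acc) {
          lv.log_sigma = ls_new;
          for (auto& u : lv.u) u *= r;
          eta.swap(new_eta);
          ll.swap(new_ll);
          ll_sum = new_sum;
        }
        if (warm) lv.lstep_sigma_nc += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // ---- observation-level deviates (count family) ----
    if (has_obs) {
      double sig = std::exp(log_sigma_obs);
      for (int i = 0; i < N; ++i) {
        double d = std::exp(lstep_obs[i]) * rng.rnorm();
        double e_new = e_obs[i] + d;
        double nll = point_ll(family, y[i], m[i], eta[i] + d, lgam[i]);
        double dprior =
            -0.5 * (e_new * e_new - e_obs[i] * e_obs[i]) / (sig * sig);
        bool acc = std::log(rng.runif()) < nll - ll[i] + dprior;
        if (acc) {
          e_obs[i] = e_new;
          eta[i] += d;
          ll_sum += nll - ll[i];
          ll[i] = nll;
        }
        if (warm) lstep_obs[i] += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
      {
        // recentering against the intercept (likelihood invariant)
        double d = std::exp(lstep_obs_rc) * rng.rnorm();
        double b0_new = beta[0] + d;
        double dprior = -0.5 * (b0_new * b0_new - beta[0] * beta[0]) /
                        (prior_sd_beta[0] * prior_sd_beta[0]);
        double sig2 = sig * sig;
        for (double e : e_obs) {
          dprior += -0.5 * ((e - d) * (e - d) - e * e) / sig2;
        }
        bool acc = std::log(rng.runif()) < dprior;
        if (acc) {
          beta[0] = b0_new;
          for (auto& e : e_obs) e -= d;
        }
        if (warm) lstep_obs_rc += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
      for (int rep = 0; rep < 3; ++rep) {
        double ls_new =
            log_sigma_obs + std::exp(lstep_sigma_obs) * rng.rnorm();
        double s_old = std::exp(log_sigma_obs), s_new = std::exp(ls_new);
        double esq = 0.0;
        for (double e : e_obs) esq += e * e;
        double lp_new = -N * ls_new - 0.5 * esq / (s_new * s_new) +
                        half_normal_lp(s_new, prior_sd_sigma) + ls_new;
        double lp_old = -N * log_sigma_obs - 0.5 * esq / (s_old * s_old) +
                        half_normal_lp(s_old, prior_sd_sigma) +
                        log_sigma_obs;
        bool acc = std::log(rng.runif()) < lp_new - lp_old;
        if (acc) log_sigma_obs = ls_new;
        if (warm) lstep_sigma_obs += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
      {
        double ls_new =
            log_sigma_obs + std::exp(lstep_sigma_obs_nc) * rng.rnorm();
        double r = std::exp(ls_new - log_sigma_obs);
        double new_sum = 0.0;
        for (int i = 0; i < N; ++i) {
          new_eta[i] = eta[i] + (r - 1.0) * e_obs[i];
          new_ll[i] = point_ll(family, y[i], m[i], new_eta[i], lgam[i]);
          new_sum += new_ll[i];
        }
        double s_old = std::exp(log_sigma_obs), s_new = std::exp(ls_new);
        double dprior = half_normal_lp(s_new, prior_sd_sigma) + ls_new -
                        half_normal_lp(s_old, prior_sd_sigma) -
                        log_sigma_obs;
        bool acc = std::log(rng.runif()) < new_sum - ll_sum + dprior;
        if (acc) {
          log_sigma_obs = ls_new;
          for (auto& e : e_obs) e *= r;
          eta.swap(new_eta);
          ll.swap(new_ll);
          ll_sum = new_sum;
        }
        if (warm) lstep_sigma_obs_nc += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // refresh the accumulated total to kill floating drift
    if (t % 200 == 0) {
      ll_sum = 0.0;
      for (int i = 0; i < N; ++i) ll_sum += ll[i];
    }

    if (!warm) {
      int r = t - n_warmup - 1;
      for (int j = 0; j < P; ++j) draws(r, j) = beta[j];
      for (int l = 0; l < 3; ++l) {
        draws(r, P + l) = levels[l].present ? std::exp(levels[l].log_sigma)
                                            : NA_REAL;
      }
      if (has_obs) draws(r, P + 3) = std::exp(log_sigma_obs);
      if (store_loglik) {
        for (int i = 0; i < N; ++i) llmat(r, i) = ll[i];
      }
    }
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["loglik"] = llmat,
      _["accept_joint"] = try_joint > 0 ? (double)acc_joint / try_joint
                                        : NA_REAL);
}
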