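// MCMC kernel for the integrated population model.
//
// Joint target: multistate CMR likelihood (latent state paths z augmented,
// sampled by forward-filtering backward-sampling) x census state-space
// density (latent abundances N_juv/N_ad/N_imm and the juvenile-origin
// survivor split) x hierarchical priors (link-scale year effects with
// Normal hyper-means and Uniform year-effect SDs).
//
// Rate order (fixed, matches R's .rate_names):
//   0 phi_juv_W  1 phi_ad_W  2 phi_ad_E  3 psi_juv_WE  4 psi_ad_WE
//   5 psi_ad_EW  6 p_W  7 p_E  8 beta (log)  9 omega (log)
// Latent CMR states: 0 juv_W, 1 ad_W, 2 ad_E, 3 dead.

#include <Rcpp.h>
using namespace Rcpp;

static const int N_RATE = 10;

static inline double inv_link(int r, double l) {
  return (r < 8) ? 1.0 / (1.0 + std::exp(-l)) : std::exp(l);
}

// binomial log-likelihood kernel (no choose term; used only in MH ratios
// where the constant cancels)
static inline double lbin(int s, int n, double p) {
  if (n == 0) return (s == 0) ? 0.0 : R_NegInf;
  if (s < 0 || s > n) return R_NegInf;
  if (p <= 0.0) return (s == 0) ? 0.0 : R_NegInf;
  if (p >= 1.0) return (s == n) ? 0.0 : R_NegInf;
  return s * std::log(p) + (n - s) * std::log1p(-p);
}

// Poisson log-likelihood kernel (no factorial term)
static inline double lpois(int x, double mu) {
  if (mu <= 0.0) return (x == 0) ? 0.0 : R_NegInf;
  return x * std::log(mu) - mu;
}

// full binomial log-pmf (constants kept; used for latent-count updates where
// n changes between current and proposal)
static inline double lbin_full(int s, int n, double p) {
  if (s < 0 || n < 0 || s > n) return R_NegInf;
  return R::dbinom(s, n, p, 1);
}

static inline double lpois_full(int x, double mu) {
  if (x < 0) return R_NegInf;
  if (mu <= 0.0) return (x == 0) ? 0.0 : R_NegInf;
  return R::dpois(x, mu, 1);
}

// discrete-uniform prior on round(c(1-w)) .. round(c(1+w))
static inline double ldunif_int(int x, int centre, double w) {
  int lo = (int)std::lround(centre * (1.0 - w));
  int hi = (int)std::lround(centre * (1.0 + w));
  if (hi < lo) hi = lo;
  return (x < lo || x > hi) ? R_NegInf : -std::log((double)(hi - lo + 1));
}

struct Counts {
  // per transition t: cohort bookkeeping of the augmented latent paths
  std::vector<int> nJ, sJ, mJ;    // juveniles at W: present, survived, moved
  std::vector<int> nAW, sAW, mAW; // adults at W
  std::vector<int> nAE, sAE, rAE; // adults at E (r = returned to W)
  std::vector<int> nW, dW, nE, dE; // detection pools/successes at occ t+1
  Counts(int nt) : nJ(nt), sJ(nt), mJ(nt), nAW(nt), sAW(nt), mAW(nt),
                   nAE(nt), sAE(nt), rAE(nt), nW(nt), dW(nt), nE(nt), dE(nt) {}
  void reset() {
    for (auto v : {&nJ, &sJ, &mJ, &nAW, &sAW, &mAW, &nAE, &sAE, &rAE,
                   &nW, &dW, &nE, &dE})
      std::fill(v->begin(), v->end(), 0);
  }
};

// transition probabilities out of state j for transition t, given natural
// rates v (column t)
static inline void trans_row(const double* vt, int j, double* out) {
  // vt indexed by rate
  if (j == 0) {
    out[0] = 0.0;
    out[1] = vt[0] * (1.0 - vt[3]);
    out[2] = vt[0] * vt[3];
    out[3] = 1.0 - vt[0];
  } else if (j == 1) {
    out[0] = 0.0;
    out[1] = vt[1] * (1.0 - vt[4]);
    out[2] = vt[1] * vt[4];
    out[3] = 1.0 - vt[1];
  } else if (j == 2) {
    out[0] = 0.0;
    out[1] = vt[2] * vt[5];
    out[2] = vt[2] * (1.0 - vt[5]);
    out[3] = 1.0 - vt[2];
  } else {
    out[0] = out[1] = out[2] = 0.0; out[3] = 1.0;
  }
}

// emission probability of observed code (0/1/2) at occasion t+1 for state k
static inline double emit(const double* vt, int k, int code) {
  double pW = vt[6], pE = vt[7];
  if (k == 0 || k == 1) {          // at W
    if (code == 1) return pW;
    if (code == 0) return 1.0 - pW;
    return 0.0;
  }
  if (k == 2) {                    // at E
    if (code == 2) return pE;
    if (code == 0) return 1.0 - pE;
    return 0.0;
  }
  return (code == 0) ? 1.0 : 0.0;  // dead
}

// [[Rcpp::export(name = ".ipm_mcmc_chain")]]
List ipm_mcmc_chain(IntegerMatrix ch, IntegerVector release,
                    IntegerVector J, IntegerVector A,
                    int n_iter, int n_burn, int thin,
                    bool immigration, bool obs_normal,
                    double mu0_sd, double sigma_upper, double init_width,
                    NumericVector mu_init, NumericVector sigma_init,
                    IntegerVector Nj_init, IntegerVector Na_init,
                    IntegerVector Ni_init, IntegerVector s_init) {
  const int n_ind = ch.nrow();
  const int T = J.size();
  const int nt = T - 1;
  if (ch.ncol() != T && n_ind > 0)
    stop("capture histories and census span different occasion counts");

  // --- parameter state ---------------------------------------------------
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> sigma(sigma_init.begin(), sigma_init.end());
  // link-scale year values l[r][t] and natural values v[t*N_RATE + r]
  std::vector<std::vector<double>> l(N_RATE, std::vector<double>(nt));
  std::vector<double> v(nt * N_RATE);
  for (int r = 0; r < N_RATE; ++r)
    for (int t = 0; t < nt; ++t) {
      l[r][t] = mu[r] + 0.1 * norm_rand();
      if (r == 9 && !immigration) l[r][t] = R_NegInf;  // omega == 0
      v[t * N_RATE + r] = (r == 9 && !immigration) ? 0.0 : inv_link(r, l[r][t]);
    }

  // --- latent abundances --------------------------------------------------
  std::vector<int> Nj(Nj_init.begin(), Nj_init.end());
  std::vector<int> Na(Na_init.begin(), Na_init.end());
  std::vector<int> Ni(Ni_init.begin(), Ni_init.end());
  std::vector<int> s(s_init.begin(), s_init.end());
  if (!immigration) std::fill(Ni.begin(), Ni.end(), 0);

  // --- latent CMR state paths ---------------------------------------------
  IntegerMatrix z(n_ind, T);   // 0-based states; -1 before release
  std::fill(z.begin(), z.end(), -1);
  Counts cnt(nt > 0 ? nt : 1);

  // --- adaptation ----------------------------------------------------------
  std::vector<std::vector<double>> lstep(N_RATE,
                                         std::vector<double>(nt, std::log(0.5)));
  // integer step sizes (log scale) for Nj, Na, Ni, s
  std::vector<double> stepNj(T, std::log(4.0)), stepNa(T, std::log(4.0)),
      stepNi(T, std::log(4.0)), stepS(nt > 0 ? nt : 1, std::log(4.0)),
      stepSwap(T, std::log(8.0)), stepJoint(T, std::log(8.0));
  std::vector<double> lstepMu(N_RATE, std::log(0.3)),
      lstepSig(N_RATE, std::log(0.3));

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out_rates(n_keep, N_RATE * nt);
  IntegerMatrix out_latent(n_keep, 3 * T);
  NumericMatrix out_hyper(n_keep, 2 * N_RATE);
  NumericMatrix out_obs_sd(n_keep, 2);

  std::vector<double> alpha(4 * T);

  // census observation variances (Gaussian law only; Poisson otherwise)
  double meanJ = 0.0, meanA = 0.0;
  for (int t = 0; t < T; ++t) { meanJ += J[t]; meanA += A[t]; }
  meanJ /= T; meanA /= T;
  double sdJ = std::sqrt(meanJ + 1.0), sdA = std::sqrt(meanA + 1.0);
  auto lobs = [&](int x, double m, double sdv) {
    if (obs_normal) return R::dnorm((double)x, m, sdv, 1);
    if (m <= 0.0) return (x == 0) ? 0.0 : R_NegInf;
    return R::dpois(x, m, 1);
  };

  auto qj = [&](int t) { return v[t * N_RATE + 0] * (1.0 - v[t * N_RATE + 3]); };
  auto qa = [&](int t) { return v[t * N_RATE + 1] * (1.0 - v[t * N_RATE + 4]); };
  auto om = [&](int t) { return v[t * N_RATE + 9]; };
  auto be = [&](int t) { return v[t * N_RATE + 8]; };
  auto tot = [&](int t) { return Nj[t] + Na[t] + Ni[t]; };

  // local log-density pieces around one latent count ------------------------
  auto ll_Nj = [&](int t) {
    double ll = (t == 0) ? ldunif_int(Nj[0], J[0], init_width)
                         : lpois_full(Nj[t], be(t - 1) * Na[t - 1]);
    if (t < nt) {
      ll += lbin_full(s[t], Nj[t], qj(t));
      if (immigration) ll += lpois_full(Ni[t + 1], om(t) * tot(t));
    }
    ll += lobs(J[t], (double)Nj[t], sdJ);
    return ll;
  };
  auto ll_Na = [&](int t) {
    double ll = (t == 0) ? ldunif_int(Na[0], A[0], init_width)
                         : lbin_full(Na[t] - s[t - 1], Na[t - 1] + Ni[t - 1],
                                     qa(t - 1));
    if (t < nt) {
      ll += lpois_full(Nj[t + 1], be(t) * Na[t]);
      ll += lbin_full(Na[t + 1] - s[t], Na[t] + Ni[t], qa(t));
      if (immigration) ll += lpois_full(Ni[t + 1], om(t) * tot(t));
    }
    ll += lobs(A[t], (double)(Na[t] + Ni[t]), sdA);
    return ll;
  };
  auto ll_Ni = [&](int t) {
    double ll = (t == 0) ? ((Ni[0] == 0) ? 0.0 : R_NegInf)
                         : lpois_full(Ni[t], om(t - 1) * tot(t - 1));
    if (t < nt) {
      ll += lbin_full(Na[t + 1] - s[t], Na[t] + Ni[t], qa(t));
      ll += lpois_full(Ni[t + 1], om(t) * tot(t));
    }
    ll += lobs(A[t], (double)(Na[t] + Ni[t]), sdA);
    return ll;
  };
  auto ll_s = [&](int t) {
    return lbin_full(s[t], Nj[t], qj(t)) +
           lbin_full(Na[t + 1] - s[t], Na[t] + Ni[t], qa(t));
  };
  // terms that change when N_ad[t] and N_imm[t] trade at fixed sum
  auto ll_swap = [&](int t) {
    double ll = lbin_full(Na[t] - s[t - 1], Na[t - 1] + Ni[t - 1], qa(t - 1)) +
                lpois_full(Ni[t], om(t - 1) * tot(t - 1));
    if (t < nt) ll += lpois_full(Nj[t + 1], be(t) * Na[t]);
    return ll;
  };

  // data terms (CMR + state-space) touched by year effect (r, t) ------------
  auto ll_rate_data = [&](int r, int t, double lv) {
    double val = (r == 9 && !immigration) ? 0.0 : inv_link(r, lv);
    double ll = 0.0;
    switch (r) {
    case 0:  // phi_juv_W
      ll += lbin(cnt.sJ[t], cnt.nJ[t], val);
      ll += lbin_full(s[t], Nj[t], val * (1.0 - v[t * N_RATE + 3]));
      break;
    case 1:  // phi_ad_W
      ll += lbin(cnt.sAW[t], cnt.nAW[t], val);
      ll += lbin_full(Na[t + 1] - s[t], Na[t] + Ni[t],
                      val * (1.0 - v[t * N_RATE + 4]));
      break;
    case 2: ll += lbin(cnt.sAE[t], cnt.nAE[t], val); break;
    case 3:  // psi_juv_WE
      ll += lbin(cnt.mJ[t], cnt.sJ[t], val);
      ll += lbin_full(s[t], Nj[t], v[t * N_RATE + 0] * (1.0 - val));
      break;
    case 4:  // psi_ad_WE
      ll += lbin(cnt.mAW[t], cnt.sAW[t], val);
      ll += lbin_full(Na[t + 1] - s[t], Na[t] + Ni[t],
                      v[t * N_RATE + 1] * (1.0 - val));
      break;
    case 5: ll += lbin(cnt.rAE[t], cnt.sAE[t], val); break;
    case 6: ll += lbin(cnt.dW[t], cnt.nW[t], val); break;
    case 7: ll += lbin(cnt.dE[t], cnt.nE[t], val); break;
    case 8: ll += lpois(Nj[t + 1], val * Na[t]); break;
    case 9: ll += lpois(Ni[t + 1], val * tot(t)); break;
    }
    return ll;
  };
  auto ll_rate = [&](int r, int t, double lv) {
    return ll_rate_data(r, t, lv) + R::dnorm(lv, mu[r], sigma[r], 1);
  };

  int keep = 0;
  for (int sweep = 0; sweep < n_iter; ++sweep) {
    const bool adapting = sweep < n_burn;
    const double arate = 1.0 / std::sqrt((double)(sweep + 1));

    // ---- 1. FFBS of latent capture states, then tally counts -------------
    cnt.reset();
    for (int i = 0; i < n_ind; ++i) {
      const int f = release[i] - 1;
      double* a0 = &alpha[4 * f];
      a0[0] = 1.0; a0[1] = a0[2] = a0[3] = 0.0;
      for (int t = f; t < T - 1; ++t) {
        const double* vt = &v[t * N_RATE];
        double row[4];
        double* at = &alpha[4 * t];
        double* an = &alpha[4 * (t + 1)];
        an[0] = an[1] = an[2] = an[3] = 0.0;
        for (int j = 0; j < 4; ++j) {
          if (at[j] == 0.0) continue;
          trans_row(vt, j, row);
          for (int k = 1; k < 4; ++k) an[k] += at[j] * row[k];
        }
        const int code = ch(i, t + 1);
        double sc = 0.0;
        for (int k = 1; k < 4; ++k) { an[k] *= emit(vt, k, code); sc += an[k]; }
        if (sc <= 0.0) stop("zero-probability capture history at forward pass");
        for (int k = 1; k < 4; ++k) an[k] /= sc;
      }
      // backward sampling
      {
        double* aT = &alpha[4 * (T - 1)];
        double u = unif_rand(), acc = 0.0;
        int zt = 3;
        for (int k = 0; k < 4; ++k) { acc += aT[k]; if (u <= acc) { zt = k; break; } }
        z(i, T - 1) = zt;
        for (int t = T - 2; t >= f; --t) {
          const double* vt = &v[t * N_RATE];
          double* at = &alpha[4 * t];
          double w[4], sw = 0.0, row[4];
          for (int j = 0; j < 4; ++j) {
            trans_row(vt, j, row);
            w[j] = at[j] * row[z(i, t + 1)];
            sw += w[j];
          }
          u = unif_rand() * sw; acc = 0.0; zt = 3;
          for (int j = 0; j < 4; ++j) { acc += w[j]; if (u <= acc) { zt = j; break; } }
          z(i, t) = zt;
        }
      }
      // tally
      for (int t = f; t < T - 1; ++t) {
        const int zj = z(i, t), zk = z(i, t + 1);
        if (zj == 0) {
          cnt.nJ[t]++;
          if (zk != 3) { cnt.sJ[t]++; if (zk == 2) cnt.mJ[t]++; }
        } else if (zj == 1) {
          cnt.nAW[t]++;
          if (zk != 3) { cnt.sAW[t]++; if (zk == 2) cnt.mAW[t]++; }
        } else if (zj == 2) {
          cnt.nAE[t]++;
          if (zk != 3) { cnt.sAE[t]++; if (zk == 1) cnt.rAE[t]++; }
        }
        if (zk == 1) { cnt.nW[t]++; if (ch(i, t + 1) == 1) cnt.dW[t]++; }
        else if (zk == 2) { cnt.nE[t]++; if (ch(i, t + 1) == 2) cnt.dE[t]++; }
      }
    }

    // ---- 2. year-effect updates (random-walk MH) --------------------------
    // parameter blocks are swept twice per latent-path refresh: they are
    // cheap next to the FFBS pass and dominate the slow directions
    for (int prep = 0; prep < 2; ++prep) {
    for (int r = 0; r < N_RATE; ++r) {
      if (r == 9 && !immigration) continue;
      for (int t = 0; t < nt; ++t) {
        const double cur = l[r][t];
        const double step = std::exp(lstep[r][t]);
        const double prop = cur + step * norm_rand();
        const double d = ll_rate(r, t, prop) - ll_rate(r, t, cur);
        const bool acc = std::log(unif_rand()) < d;
        if (acc) { l[r][t] = prop; v[t * N_RATE + r] = inv_link(r, prop); }
        if (adapting)
          lstep[r][t] += arate * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // ---- 3. hyperparameters (Gibbs) ---------------------------------------
    for (int r = 0; r < N_RATE; ++r) {
      if (r == 9 && !immigration) continue;
      double sum = 0.0;
      for (int t = 0; t < nt; ++t) sum += l[r][t];
      const double prec = nt / (sigma[r] * sigma[r]) + 1.0 / (mu0_sd * mu0_sd);
      const double mean = (sum / (sigma[r] * sigma[r])) / prec;
      mu[r] = mean + norm_rand() / std::sqrt(prec);
      double ss = 0.0;
      for (int t = 0; t < nt; ++t) {
        const double dlt = l[r][t] - mu[r];
        ss += dlt * dlt;
      }
      if (ss > 0.0) {
        const double up2 = sigma_upper * sigma_upper;
        for (int tries = 0; tries < 100; ++tries) {
          const double g = R::rgamma((nt - 1) / 2.0, 2.0 / ss);  // scale param
          if (g > 1.0 / up2) { sigma[r] = 1.0 / std::sqrt(g); break; }
        }
      }
    }

    // ---- 3b. interweaving: non-centered updates of mu and sigma ----------
    // holding the standardized year effects fixed, so the whole annual
    // series moves with the hyperparameter (breaks the slow centered-
    // parameterization coupling when sigma is small)
    for (int r = 0; r < N_RATE; ++r) {
      if (r == 9 && !immigration) continue;
      {  // hyper-mean shift
        const double prop = mu[r] + std::exp(lstepMu[r]) * norm_rand();
        const double shift = prop - mu[r];
        double d = R::dnorm(prop, 0.0, mu0_sd, 1) -
                   R::dnorm(mu[r], 0.0, mu0_sd, 1);
        for (int t = 0; t < nt; ++t)
          d += ll_rate_data(r, t, l[r][t] + shift) -
               ll_rate_data(r, t, l[r][t]);
        const bool acc = std::log(unif_rand()) < d;
        if (acc) {
          mu[r] = prop;
          for (int t = 0; t < nt; ++t) {
            l[r][t] += shift;
            v[t * N_RATE + r] = inv_link(r, l[r][t]);
          }
        }
        if (adapting) lstepMu[r] += arate * ((acc ? 1.0 : 0.0) - 0.35);
      }
      {  // year-effect SD rescale (flat prior on (0, sigma_upper))
        const double prop = sigma[r] + std::exp(lstepSig[r]) * norm_rand();
        if (prop > 0.0 && prop < sigma_upper) {
          const double f = prop / sigma[r];
          double d = 0.0;
          for (int t = 0; t < nt; ++t)
            d += ll_rate_data(r, t, mu[r] + f * (l[r][t] - mu[r])) -
                 ll_rate_data(r, t, l[r][t]);
          const bool acc = std::log(unif_rand()) < d;
          if (acc) {
            sigma[r] = prop;
            for (int t = 0; t < nt; ++t) {
              l[r][t] = mu[r] + f * (l[r][t] - mu[r]);
              v[t * N_RATE + r] = inv_link(r, l[r][t]);
            }
          }
          if (adapting) lstepSig[r] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
    }
    }  // end parameter-block repetitions

    // ---- 4. latent abundances and survivor splits (integer RW-MH) --------
    auto istep = [&](double ls) {
      const int d = std::max(1, (int)std::lround(std::exp(ls)));
      int delta = 0;
      while (delta == 0)
        delta = (int)std::floor(unif_rand() * (2 * d + 1)) - d;
      return delta;
    };
    for (int rep = 0; rep < 3; ++rep)
    for (int t = 0; t < T; ++t) {
      {  // N_juv
        const int prop = Nj[t] + istep(stepNj[t]);
        if (prop >= 0) {
          const double ll0 = ll_Nj(t);
          const int cur = Nj[t];
          Nj[t] = prop;
          const double d = ll_Nj(t) - ll0;
          const bool acc = std::log(unif_rand()) < d;
          if (!acc) Nj[t] = cur;
          if (adapting) stepNj[t] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
      {  // N_ad
        const int prop = Na[t] + istep(stepNa[t]);
        if (prop >= 0) {
          const double ll0 = ll_Na(t);
          const int cur = Na[t];
          Na[t] = prop;
          const double d = ll_Na(t) - ll0;
          const bool acc = std::log(unif_rand()) < d;
          if (!acc) Na[t] = cur;
          if (adapting) stepNa[t] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
      if (immigration && t > 0) {  // N_imm (year 1 fixed at 0)
        const int prop = Ni[t] + istep(stepNi[t]);
        if (prop >= 0) {
          const double ll0 = ll_Ni(t);
          const int cur = Ni[t];
          Ni[t] = prop;
          const double d = ll_Ni(t) - ll0;
          const bool acc = std::log(unif_rand()) < d;
          if (!acc) Ni[t] = cur;
          if (adapting) stepNi[t] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
      if (immigration && t > 0) {  // adult/immigrant swap at fixed sum
        const int delta = istep(stepSwap[t]);
        if (Na[t] + delta >= 0 && Ni[t] - delta >= 0) {
          const double ll0 = ll_swap(t);
          Na[t] += delta; Ni[t] -= delta;
          const double d = ll_swap(t) - ll0;
          const bool acc = std::log(unif_rand()) < d;
          if (!acc) { Na[t] -= delta; Ni[t] += delta; }
          if (adapting) stepSwap[t] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
      if (immigration && t > 0) {
        // joint move: shift N_imm[t] and the year t-1 immigration-rate
        // effect by the compensating amount, so the Poisson process term
        // stays near its mode (symmetric deterministic map, unit Jacobian)
        const int delta = istep(stepJoint[t]);
        if (Ni[t] + delta >= 0) {
          const int li = (t - 1) * N_RATE + 9;
          const double lc = std::log((Ni[t] + delta + 0.5) / (Ni[t] + 0.5));
          const double ll0 = ll_Ni(t) + R::dnorm(l[9][t - 1], mu[9], sigma[9], 1);
          const int cur = Ni[t];
          const double lcur = l[9][t - 1];
          Ni[t] += delta;
          l[9][t - 1] += lc;
          v[li] = inv_link(9, l[9][t - 1]);
          const double d = ll_Ni(t) +
            R::dnorm(l[9][t - 1], mu[9], sigma[9], 1) - ll0;
          const bool acc = std::log(unif_rand()) < d;
          if (!acc) { Ni[t] = cur; l[9][t - 1] = lcur; v[li] = inv_link(9, lcur); }
          if (adapting) stepJoint[t] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
      if (t < nt) {  // survivor split
        const int prop = s[t] + istep(stepS[t]);
        if (prop >= 0) {
          const double ll0 = ll_s(t);
          const int cur = s[t];
          s[t] = prop;
          const double d = ll_s(t) - ll0;
          const bool acc = std::log(unif_rand()) < d;
          if (!acc) s[t] = cur;
          if (adapting) stepS[t] += arate * ((acc ? 1.0 : 0.0) - 0.35);
        }
      }
    }

    // ---- 4b. census observation SDs (Gaussian law; conjugate Gibbs with
    // flat prior on the SD, as for the year-effect SDs) ---------------------
    if (obs_normal) {
      double ssJ = 0.0, ssA = 0.0;
      for (int t = 0; t < T; ++t) {
        const double dj = J[t] - (double)Nj[t];
        const double da = A[t] - (double)(Na[t] + Ni[t]);
        ssJ += dj * dj; ssA += da * da;
      }
      if (ssJ > 0.0) {
        const double g = R::rgamma((T - 1) / 2.0, 2.0 / ssJ);
        if (g > 0.0) sdJ = 1.0 / std::sqrt(g);
      }
      if (ssA > 0.0) {
        const double g = R::rgamma((T - 1) / 2.0, 2.0 / ssA);
        if (g > 0.0) sdA = 1.0 / std::sqrt(g);
      }
    }

    // ---- 5. record --------------------------------------------------------
    if (sweep >= n_burn && (sweep - n_burn) % thin == 0 && keep < n_keep) {
      for (int t = 0; t < nt; ++t)
        for (int r = 0; r < N_RATE; ++r)
          out_rates(keep, r * nt + t) = v[t * N_RATE + r];
      for (int t = 0; t < T; ++t) {
        out_latent(keep, t) = Nj[t];
        out_latent(keep, T + t) = Na[t];
        out_latent(keep, 2 * T + t) = Ni[t];
      }
      for (int r = 0; r < N_RATE; ++r) {
        out_hyper(keep, r) = mu[r];
        out_hyper(keep, N_RATE + r) = sigma[r];
      }
      out_obs_sd(keep, 0) = obs_normal ? sdJ : 0.0;
      out_obs_sd(keep, 1) = obs_normal ? sdA : 0.0;
      ++keep;
    }
    if ((sweep & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["rates"] = out_rates, _["latent"] = out_latent,
                      _["hyper"] = out_hyper, _["obs_sd"] = out_obs_sd);
}
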