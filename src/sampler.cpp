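// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// state-space deer model. The joint density evaluated here is the same
// quantity as the pure-R joint_log_density(); the R test suite asserts
// exact agreement between the two on random states.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_FLOOR = 1e-6; // positivity floor before log()

struct ModelData {
  int I, T;
  std::vector<double> area;
  std::vector<double> yd, se;       // I*T, column-major [i + I*t], NA allowed in yd
  std::vector<int> obsD;            // density observed flag
  std::vector<double> counts;       // I*T*3 [i + I*(t + T*j)]
  std::vector<double> yN;           // I*T
  std::vector<double> lmc;          // multinomial lgamma constant per cell
  std::vector<double> alpha1;       // I*3 Dirichlet parameters (counts year1 + 1)
  std::vector<double> ldirc;        // Dirichlet normalising constant per park
};

struct Priors {
  double a_shape[3], a_rate[3], b_shape[3], b_rate[3];
  double m_a, m_b, rf_mean, rf_sd, Kf_lo, Kf_hi, sp_lo, sp_hi;
  int fec_form; // 0 = ricker_exp, 1 = scaled
};

struct State {
  int I, T;
  std::vector<double> s;      // 3*I [j + 3*i]
  double a[3], b[3], m, rf, Kf, sp; // sp = sigma_p (SD on log scale)
  std::vector<double> gam;    // I*3 [i + I*j] simplex rows
  std::vector<double> d1;     // I
  std::vector<double> logn;   // I*T*3 [i + I*(t + T*j)]
};

static inline int idx2(const ModelData& D, int i, int t) { return i + D.I * t; }
static inline int idx3(const ModelData& D, int i, int t, int j) {
  return i + D.I * (t + D.T * j);
}

static inline double fec(double rf, double Kf, double dens, int form) {
  double e = std::exp(rf - (rf / Kf) * dens);
  return form == 0 ? e : rf * std::exp(-(rf / Kf) * dens);
}

// log of deterministic stage means after projecting state at time t
static void log_mu_next2(const ModelData& D, const State& S, const Priors& P,
                         int i, int t, double out[3]) {
  double n1 = std::exp(S.logn[idx3(D, i, t, 0)]);
  double n2 = std::exp(S.logn[idx3(D, i, t, 1)]);
  double n3 = std::exp(S.logn[idx3(D, i, t, 2)]);
  double s1 = S.s[0 + 3 * i], s2 = S.s[1 + 3 * i], s3 = S.s[2 + 3 * i];
  double f = fec(S.rf, S.Kf, (n1 + n2 + n3) / D.area[i], P.fec_form);
  double p1 = s2 * f * n2;
  double p2 = s1 * S.m * n1 + s2 * n2;
  double p3 = s1 * (1.0 - S.m) * n1 + s3 * n3;
  out[0] = std::log(std::max(p1, LOG_FLOOR));
  out[1] = std::log(std::max(p2, LOG_FLOOR));
  out[2] = std::log(std::max(p3, LOG_FLOOR));
}

// lognormal transition t -> t+1 for park i
static double lp_trans(const ModelData& D, const State& S, const Priors& P,
                       int i, int t) {
  double mu[3];
  log_mu_next2(D, S, P, i, t, mu);
  double lp = 0.0;
  for (int j = 0; j < 3; ++j)
    lp += R::dnorm4(S.logn[idx3(D, i, t + 1, j)], mu[j], S.sp, 1);
  return lp;
}

static double lp_park_process(const ModelData& D, const State& S,
                              const Priors& P, int i) {
  double lp = 0.0;
  for (int t = 0; t < D.T - 1; ++t) lp += lp_trans(D, S, P, i, t);
  return lp;
}

static double lp_all_process(const ModelData& D, const State& S,
                             const Priors& P) {
  double lp = 0.0;
  for (int i = 0; i < D.I; ++i) lp += lp_park_process(D, S, P, i);
  return lp;
}

// data likelihood for cell (i, t): multinomial classification + normal density
static double lp_data(const ModelData& D, const State& S, int i, int t) {
  double n1 = std::exp(S.logn[idx3(D, i, t, 0)]);
  double n2 = std::exp(S.logn[idx3(D, i, t, 1)]);
  double n3 = std::exp(S.logn[idx3(D, i, t, 2)]);
  double tot = n1 + n2 + n3;
  double lp = 0.0;
  if (D.yN[idx2(D, i, t)] > 0) {
    lp += D.lmc[idx2(D, i, t)] +
      D.counts[idx3(D, i, t, 0)] * std::log(n1 / tot) +
      D.counts[idx3(D, i, t, 1)] * std::log(n2 / tot) +
      D.counts[idx3(D, i, t, 2)] * std::log(n3 / tot);
  }
  if (D.obsD[idx2(D, i, t)])
    lp += R::dnorm4(D.yd[idx2(D, i, t)], tot / D.area[i],
                    D.se[idx2(D, i, t)], 1);
  return lp;
}

// initial-condition prior terms for park i (Dirichlet + truncated normal)
static double lp_init(const ModelData& D, const State& S, int i) {
  if (S.d1[i] <= 0) return R_NegInf;
  double lp = D.ldirc[i];
  for (int j = 0; j < 3; ++j) {
    double g = S.gam[i + D.I * j];
    if (g <= 0) return R_NegInf;
    lp += (D.alpha1[i + D.I * j] - 1.0) * std::log(g);
  }
  if (D.obsD[idx2(D, i, 0)])
    lp += R::dnorm4(S.d1[i], D.yd[idx2(D, i, 0)], D.se[idx2(D, i, 0)], 1);
  return lp;
}

static double lp_scalar_priors(const State& S, const Priors& P) {
  double lp = 0.0;
  for (int j = 0; j < 3; ++j) {
    if (S.a[j] <= 0 || S.b[j] <= 0) return R_NegInf;
    lp += R::dgamma(S.a[j], P.a_shape[j], 1.0 / P.a_rate[j], 1);
    lp += R::dgamma(S.b[j], P.b_shape[j], 1.0 / P.b_rate[j], 1);
    for (int i = 0; i < S.I; ++i) {
      double sv = S.s[j + 3 * i];
      if (sv <= 0 || sv >= 1) return R_NegInf;
      lp += R::dbeta(sv, S.a[j], S.b[j], 1);
    }
  }
  if (S.m <= 0 || S.m >= 1) return R_NegInf;
  lp += R::dbeta(S.m, P.m_a, P.m_b, 1);
  lp += R::dnorm4(S.rf, P.rf_mean, P.rf_sd, 1);
  if (S.Kf < P.Kf_lo || S.Kf > P.Kf_hi) return R_NegInf;
  lp += -std::log(P.Kf_hi - P.Kf_lo);
  if (S.sp < P.sp_lo || S.sp > P.sp_hi) return R_NegInf;
  lp += -std::log(P.sp_hi - P.sp_lo);
  return lp;
}

static double joint_lp(const ModelData& D, const State& S, const Priors& P) {
  double lp = lp_scalar_priors(S, P);
  if (!R_FINITE(lp)) return lp;
  for (int i = 0; i < D.I; ++i) {
    double li = lp_init(D, S, i);
    if (!R_FINITE(li)) return R_NegInf;
    lp += li;
    for (int t = 0; t < D.T; ++t) lp += lp_data(D, S, i, t);
  }
  lp += lp_all_process(D, S, P);
  return lp;
}

static ModelData build_data(const List& data) {
  ModelData D;
  D.I = as<int>(data["I"]);
  D.T = as<int>(data["T"]);
  D.area = as<std::vector<double> >(data["area"]);
  NumericVector yd = data["yd"], se = data["se"], counts = data["counts"],
    yN = data["yN"];
  D.yd.assign(yd.begin(), yd.end());
  D.se.assign(se.begin(), se.end());
  D.counts.assign(counts.begin(), counts.end());
  D.yN.assign(yN.begin(), yN.end());
  D.obsD.resize(D.I * D.T);
  for (int k = 0; k < D.I * D.T; ++k)
    D.obsD[k] = !NumericVector::is_na(D.yd[k]);
  D.lmc.resize(D.I * D.T);
  for (int i = 0; i < D.I; ++i)
    for (int t = 0; t < D.T; ++t) {
      double c = R::lgammafn(D.yN[idx2(D, i, t)] + 1.0);
      for (int j = 0; j < 3; ++j)
        c -= R::lgammafn(D.counts[idx3(D, i, t, j)] + 1.0);
      D.lmc[idx2(D, i, t)] = c;
    }
  D.alpha1.resize(D.I * 3);
  D.ldirc.resize(D.I);
  for (int i = 0; i < D.I; ++i) {
    double asum = 0.0, c = 0.0;
    for (int j = 0; j < 3; ++j) {
      double aj = D.counts[idx3(D, i, 0, j)] + 1.0;
      D.alpha1[i + D.I * j] = aj;
      asum += aj;
      c -= R::lgammafn(aj);
    }
    D.ldirc[i] = c + R::lgammafn(asum);
  }
  return D;
}

static Priors build_priors(const List& priors) {
  Priors P;
  NumericVector as_ = priors["a_shape"], ar = priors["a_rate"],
    bs = priors["b_shape"], br = priors["b_rate"];
  for (int j = 0; j < 3; ++j) {
    P.a_shape[j] = as_[j]; P.a_rate[j] = ar[j];
    P.b_shape[j] = bs[j]; P.b_rate[j] = br[j];
  }
  P.m_a = as<double>(priors["m_a"]);
  P.m_b = as<double>(priors["m_b"]);
  P.rf_mean = as<double>(priors["rf_mean"]);
  P.rf_sd = as<double>(priors["rf_sd"]);
  P.Kf_lo = as<double>(priors["Kf_lo"]);
  P.Kf_hi = as<double>(priors["Kf_hi"]);
  P.sp_lo = as<double>(priors["sp_lo"]);
  P.sp_hi = as<double>(priors["sp_hi"]);
  P.fec_form = as<int>(priors["fec_form"]);
  return P;
}

static State build_state(const List& init, int I, int T) {
  State S;
  S.I = I; S.T = T;
  NumericMatrix s = init["s"];        // 3 x I
  S.s.resize(3 * I);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < 3; ++j) S.s[j + 3 * i] = s(j, i);
  NumericVector a = init["a"], b = init["b"];
  for (int j = 0; j < 3; ++j) { S.a[j] = a[j]; S.b[j] = b[j]; }
  S.m = as<double>(init["m"]);
  S.rf = as<double>(init["r_f"]);
  S.Kf = as<double>(init["K_f"]);
  S.sp = std::sqrt(as<double>(init["sigma_p2"]));
  NumericMatrix g = init["gamma"];    // I x 3
  S.gam.resize(I * 3);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < 3; ++j) S.gam[i + I * j] = g(i, j);
  S.d1 = as<std::vector<double> >(init["d1"]);
  NumericVector logn = init["logn"];  // I x T x 3 array
  S.logn.assign(logn.begin(), logn.end());
  return S;
}

// [[Rcpp::export]]
double joint_lp_cpp(List data, List priors, List state) {
  ModelData D = build_data(data);
  Priors P = build_priors(priors);
  State S = build_state(state, D.I, D.T);
  return joint_lp(D, S, P);
}

// ---- adaptive Metropolis-within-Gibbs ----

struct Tuner {
  std::vector<double> ls;   // log proposal SD
  std::vector<int> acc, att;
  void init(int n, double sd0) {
    ls.assign(n, std::log(sd0));
    acc.assign(n, 0); att.assign(n, 0);
  }
  void adapt(int batch) {
    double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
    for (size_t k = 0; k < ls.size(); ++k) {
      if (att[k] > 0) {
        double rate = (double)acc[k] / att[k];
        ls[k] += (rate > 0.44 ? delta : -delta);
      }
      acc[k] = att[k] = 0;
    }
  }
};

static inline bool mh_accept(double log_ratio) {
  return std::log(unif_rand()) < log_ratio;
}

// [[Rcpp::export]]
List run_chain_cpp(List data, List priors, List init,
                   int n_burnin, int n_samples, int thin) {
  ModelData D = build_data(data);
  Priors P = build_priors(priors);
  State S = build_state(init, D.I, D.T);
  const int I = D.I, T = D.T;

  Tuner tn_s, tn_ab, tn_glob, tn_d1, tn_gam, tn_n;
  tn_s.init(3 * I, 0.3);
  tn_ab.init(6, 0.3);          // a1..a3, b1..b3
  tn_glob.init(4, 0.1);        // m(logit), rf, Kf(logit), sp(logit)
  tn_d1.init(I, 1.0);
  tn_gam.init(I, 0.2);
  tn_n.init(I * T * 3, 0.3);

  int n_keep = n_samples / thin;
  int n_scal = 3 * I + 6 + 3 + 4 + I + 3 * I; // s, a+b, mu, globals, d1, gamma
  NumericMatrix out_scal(n_keep, n_scal);
  NumericVector out_logn((R_xlen_t)n_keep * I * T * 3);
  int kept = 0;

  double mu_in[3];
  for (int iter = 0; iter < n_burnin + n_samples; ++iter) {
    bool adapting = iter < n_burnin;

    // -- latent log-states, t = 1..T-1 --
    for (int i = 0; i < I; ++i) {
      for (int t = 1; t < T; ++t) {
        log_mu_next2(D, S, P, i, t - 1, mu_in);
        for (int j = 0; j < 3; ++j) {
          int k = idx3(D, i, t, j);
          double cur = S.logn[k];
          double lp0 = R::dnorm4(cur, mu_in[j], S.sp, 1) + lp_data(D, S, i, t);
          if (t < T - 1) lp0 += lp_trans(D, S, P, i, t);
          double prop = cur + std::exp(tn_n.ls[k]) * norm_rand();
          S.logn[k] = prop;
          double lp1 = R::dnorm4(prop, mu_in[j], S.sp, 1) + lp_data(D, S, i, t);
          if (t < T - 1) lp1 += lp_trans(D, S, P, i, t);
          tn_n.att[k]++;
          if (mh_accept(lp1 - lp0)) tn_n.acc[k]++;
          else S.logn[k] = cur;
        }
      }
    }

    // -- initial conditions: d1 and gamma per park --
    for (int i = 0; i < I; ++i) {
      // d1: plain RW, support (0, Inf)
      double cur = S.d1[i];
      double lp0 = lp_init(D, S, i) + lp_data(D, S, i, 0);
      if (T > 1) lp0 += lp_trans(D, S, P, i, 0);
      double prop = cur + std::exp(tn_d1.ls[i]) * norm_rand();
      tn_d1.att[i]++;
      if (prop > 0) {
        std::vector<double> save(3);
        for (int j = 0; j < 3; ++j) save[j] = S.logn[idx3(D, i, 0, j)];
        S.d1[i] = prop;
        for (int j = 0; j < 3; ++j)
          S.logn[idx3(D, i, 0, j)] =
            std::log(prop * S.gam[i + I * j] * D.area[i]);
        double lp1 = lp_init(D, S, i) + lp_data(D, S, i, 0);
        if (T > 1) lp1 += lp_trans(D, S, P, i, 0);
        if (mh_accept(lp1 - lp0)) tn_d1.acc[i]++;
        else {
          S.d1[i] = cur;
          for (int j = 0; j < 3; ++j) S.logn[idx3(D, i, 0, j)] = save[j];
        }
      }
      // gamma: RW on additive log-ratio coordinates; Jacobian g1*g2*g3
      double g1 = S.gam[i], g2 = S.gam[i + I], g3 = S.gam[i + 2 * I];
      double z1 = std::log(g1 / g3), z2 = std::log(g2 / g3);
      lp0 = lp_init(D, S, i) + lp_data(D, S, i, 0) + std::log(g1 * g2 * g3);
      if (T > 1) lp0 += lp_trans(D, S, P, i, 0);
      double sd = std::exp(tn_gam.ls[i]);
      double z1p = z1 + sd * norm_rand(), z2p = z2 + sd * norm_rand();
      double e1 = std::exp(z1p), e2 = std::exp(z2p), den = 1.0 + e1 + e2;
      double g1p = e1 / den, g2p = e2 / den, g3p = 1.0 / den;
      std::vector<double> save(3);
      for (int j = 0; j < 3; ++j) save[j] = S.logn[idx3(D, i, 0, j)];
      S.gam[i] = g1p; S.gam[i + I] = g2p; S.gam[i + 2 * I] = g3p;
      for (int j = 0; j < 3; ++j)
        S.logn[idx3(D, i, 0, j)] =
          std::log(S.d1[i] * S.gam[i + I * j] * D.area[i]);
      double lp1 = lp_init(D, S, i) + lp_data(D, S, i, 0) +
        std::log(g1p * g2p * g3p);
      if (T > 1) lp1 += lp_trans(D, S, P, i, 0);
      tn_gam.att[i]++;
      if (mh_accept(lp1 - lp0)) tn_gam.acc[i]++;
      else {
        S.gam[i] = g1; S.gam[i + I] = g2; S.gam[i + 2 * I] = g3;
        for (int j = 0; j < 3; ++j) S.logn[idx3(D, i, 0, j)] = save[j];
      }
    }

    // -- park survival probabilities (logit RW) --
    for (int i = 0; i < I; ++i) {
      for (int j = 0; j < 3; ++j) {
        int k = j + 3 * i;
        double cur = S.s[k];
        double lp0 = R::dbeta(cur, S.a[j], S.b[j], 1) +
          std::log(cur * (1.0 - cur)) + lp_park_process(D, S, P, i);
        double z = std::log(cur / (1.0 - cur)) +
          std::exp(tn_s.ls[k]) * norm_rand();
        double prop = 1.0 / (1.0 + std::exp(-z));
        S.s[k] = prop;
        double lp1 = R::dbeta(prop, S.a[j], S.b[j], 1) +
          std::log(prop * (1.0 - prop)) + lp_park_process(D, S, P, i);
        tn_s.att[k]++;
        if (mh_accept(lp1 - lp0)) tn_s.acc[k]++;
        else S.s[k] = cur;
      }
    }

    // -- hyperparameters a_j, b_j (log RW) --
    for (int j = 0; j < 3; ++j) {
      for (int which = 0; which < 2; ++which) {
        int k = j + 3 * which;
        double cur = which == 0 ? S.a[j] : S.b[j];
        double lp0 = (which == 0
                      ? R::dgamma(cur, P.a_shape[j], 1.0 / P.a_rate[j], 1)
                      : R::dgamma(cur, P.b_shape[j], 1.0 / P.b_rate[j], 1)) +
          std::log(cur);
        for (int i = 0; i < I; ++i)
          lp0 += R::dbeta(S.s[j + 3 * i], S.a[j], S.b[j], 1);
        double prop = cur * std::exp(std::exp(tn_ab.ls[k]) * norm_rand());
        if (which == 0) S.a[j] = prop; else S.b[j] = prop;
        double lp1 = (which == 0
                      ? R::dgamma(prop, P.a_shape[j], 1.0 / P.a_rate[j], 1)
                      : R::dgamma(prop, P.b_shape[j], 1.0 / P.b_rate[j], 1)) +
          std::log(prop);
        for (int i = 0; i < I; ++i)
          lp1 += R::dbeta(S.s[j + 3 * i], S.a[j], S.b[j], 1);
        tn_ab.att[k]++;
        if (mh_accept(lp1 - lp0)) tn_ab.acc[k]++;
        else { if (which == 0) S.a[j] = cur; else S.b[j] = cur; }
      }
    }

    // -- global scalars: m, r_f, K_f, sigma_p --
    {
      // m: logit RW, prior beta + all-park process
      double cur = S.m;
      double lp0 = R::dbeta(cur, P.m_a, P.m_b, 1) +
        std::log(cur * (1.0 - cur)) + lp_all_process(D, S, P);
      double z = std::log(cur / (1.0 - cur)) +
        std::exp(tn_glob.ls[0]) * norm_rand();
      double prop = 1.0 / (1.0 + std::exp(-z));
      S.m = prop;
      double lp1 = R::dbeta(prop, P.m_a, P.m_b, 1) +
        std::log(prop * (1.0 - prop)) + lp_all_process(D, S, P);
      tn_glob.att[0]++;
      if (mh_accept(lp1 - lp0)) tn_glob.acc[0]++; else S.m = cur;

      // r_f: plain RW with support (0, Inf)
      cur = S.rf;
      tn_glob.att[1]++;
      prop = cur + std::exp(tn_glob.ls[1]) * norm_rand();
      if (prop > 0) {
        lp0 = R::dnorm4(cur, P.rf_mean, P.rf_sd, 1) + lp_all_process(D, S, P);
        S.rf = prop;
        lp1 = R::dnorm4(prop, P.rf_mean, P.rf_sd, 1) + lp_all_process(D, S, P);
        if (mh_accept(lp1 - lp0)) tn_glob.acc[1]++; else S.rf = cur;
      }

      // K_f: logit RW on (lo, hi)
      cur = S.Kf;
      double w0 = (cur - P.Kf_lo) * (P.Kf_hi - cur);
      lp0 = std::log(w0) + lp_all_process(D, S, P);
      z = std::log((cur - P.Kf_lo) / (P.Kf_hi - cur)) +
        std::exp(tn_glob.ls[2]) * norm_rand();
      prop = P.Kf_lo + (P.Kf_hi - P.Kf_lo) / (1.0 + std::exp(-z));
      S.Kf = prop;
      double w1 = (prop - P.Kf_lo) * (P.Kf_hi - prop);
      lp1 = std::log(w1) + lp_all_process(D, S, P);
      tn_glob.att[2]++;
      if (mh_accept(lp1 - lp0)) tn_glob.acc[2]++; else S.Kf = cur;

      // sigma_p: logit RW on (lo, hi); uniform prior cancels
      cur = S.sp;
      double lo = std::max(P.sp_lo, 1e-8);
      w0 = (cur - lo) * (P.sp_hi - cur);
      lp0 = std::log(w0) + lp_all_process(D, S, P);
      z = std::log((cur - lo) / (P.sp_hi - cur)) +
        std::exp(tn_glob.ls[3]) * norm_rand();
      prop = lo + (P.sp_hi - lo) / (1.0 + std::exp(-z));
      S.sp = prop;
      w1 = (prop - lo) * (P.sp_hi - prop);
      lp1 = std::log(w1) + lp_all_process(D, S, P);
      tn_glob.att[3]++;
      if (mh_accept(lp1 - lp0)) tn_glob.acc[3]++; else S.sp = cur;
    }

    if (adapting && (iter + 1) % 50 == 0) {
      int batch = (iter + 1) / 50;
      tn_s.adapt(batch); tn_ab.adapt(batch); tn_glob.adapt(batch);
      tn_d1.adapt(batch); tn_gam.adapt(batch); tn_n.adapt(batch);
    }

    if (!adapting && (iter - n_burnin + 1) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int i = 0; i < I; ++i)
        for (int j = 0; j < 3; ++j) out_scal(kept, c++) = S.s[j + 3 * i];
      for (int j = 0; j < 3; ++j) out_scal(kept, c++) = S.a[j];
      for (int j = 0; j < 3; ++j) out_scal(kept, c++) = S.b[j];
      for (int j = 0; j < 3; ++j)
        out_scal(kept, c++) = S.a[j] / (S.a[j] + S.b[j]);
      out_scal(kept, c++) = S.m;
      out_scal(kept, c++) = S.rf;
      out_scal(kept, c++) = S.Kf;
      out_scal(kept, c++) = S.sp * S.sp;
      for (int i = 0; i < I; ++i) out_scal(kept, c++) = S.d1[i];
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < I; ++i) out_scal(kept, c++) = S.gam[i + I * j];
      R_xlen_t off = (R_xlen_t)kept * I * T * 3;
      for (int k = 0; k < I * T * 3; ++k) out_logn[off + k] = S.logn[k];
      kept++;
    }
  }

  return List::create(
    _["scalars"] = out_scal,
    _["logn"] = out_logn,
    _["final_lp"] = joint_lp(D, S, P),
    _["kept"] = kept);
}
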