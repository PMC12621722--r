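#include <Rcpp.h>
using namespace Rcpp;

// Bootstrap particle filter for the policy-gradient learning-rule
// state-space model. The latent state is the policy weight vector w_t
// (plus a latent scalar learning-rate gate for variant 1, or a latent
// per-regressor baseline for variant 2). Particles are propagated through
// the learning rule conditioned on the animal's realized choice/reward and
// weighted by the Bernoulli likelihood of the realized choice; held-out
// trials are propagated but not reweighted (their predictive likelihood is
// still recorded). Systematic resampling triggers when ESS < n/2.
// All randomness comes from R's RNG so set.seed() governs the filter.

static const double PEPS = 1e-12;

static inline double clampp(double p) {
  if (p < PEPS) return PEPS;
  if (p > 1.0 - PEPS) return 1.0 - PEPS;
  return p;
}

// systematic resampling: fills idx with ancestor indices (0-based)
static void systematic_resample(const std::vector<double>& wnorm,
                                std::vector<int>& idx) {
  int n = wnorm.size();
  double u = unif_rand() / n;
  double cum = wnorm[0];
  int j = 0;
  for (int i = 0; i < n; ++i) {
    double target = u + (double)i / n;
    while (cum < target && j < n - 1) {
      ++j;
      cum += wnorm[j];
    }
    idx[i] = j;
  }
}

// [[Rcpp::export]]
List pf_pg_cpp(NumericMatrix X, NumericVector y, NumericVector r,
               LogicalVector boundary_next, LogicalVector observed,
               NumericVector alpha, NumericVector beta, NumericVector Qdiag,
               NumericVector sigma, NumericVector sigma_day,
               NumericVector w1_mean, NumericVector w1_sd,
               int variant, double alpha0, double sigma_alpha,
               double beta_sigma, int n_particles, bool store_paths) {
  int T = X.nrow();
  int M = X.ncol();
  int n = n_particles;
  int D = M + (variant == 1 ? 1 : 0) + (variant == 2 ? M : 0);

  std::vector<double> W(n * M);   // weights, particle-major
  std::vector<double> A(variant == 1 ? n : 0);
  std::vector<double> B(variant == 2 ? n * M : 0);
  std::vector<double> wnorm(n, 1.0 / n), p(n);
  std::vector<int> idx(n), cur_anc(n);

  NumericMatrix filt_mean(T, D), filt_sd(T, D);
  NumericVector loglik(T), ess_trace(T);
  IntegerMatrix anc;
  NumericVector states;
  if (store_paths) {
    anc = IntegerMatrix(T, n);
    states = NumericVector(Dimension(n, D, T));
  }

  // init particles from the prior
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < M; ++j)
      W[i * M + j] = w1_mean[j] + w1_sd[j] * norm_rand();
    if (variant == 1) A[i] = alpha0 + sigma_alpha * norm_rand();
    if (variant == 2)
      for (int j = 0; j < M; ++j) B[i * M + j] = beta[j];
    cur_anc[i] = i;
  }

  for (int t = 0; t < T; ++t) {
    // Bernoulli likelihood of the realized choice under each particle
    double yt = y[t];
    for (int i = 0; i < n; ++i) {
      double z = 0.0;
      for (int j = 0; j < M; ++j) z += W[i * M + j] * X(t, j);
      p[i] = clampp(1.0 / (1.0 + std::exp(-yt * z)));
    }
    double incr = 0.0;
    for (int i = 0; i < n; ++i) incr += wnorm[i] * p[i];
    loglik[t] = std::log(incr);
    if (observed[t]) {
      for (int i = 0; i < n; ++i) wnorm[i] *= p[i] / incr;
    }

    if (store_paths) {
      for (int i = 0; i < n; ++i) {
        anc(t, i) = cur_anc[i] + 1; // 1-based for R
        for (int j = 0; j < M; ++j) states[i + n * j + n * D * t] = W[i * M + j];
        if (variant == 1) states[i + n * M + n * D * t] = A[i];
        if (variant == 2)
          for (int j = 0; j < M; ++j)
            states[i + n * (M + j) + n * D * t] = B[i * M + j];
      }
    }

    // filtered moments
    for (int d = 0; d < D; ++d) {
      double m = 0.0, m2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = (d < M) ? W[i * M + d]
                 : (variant == 1 ? A[i] : B[i * M + (d - M)]);
        m += wnorm[i] * v;
        m2 += wnorm[i] * v * v;
      }
      filt_mean(t, d) = m;
      double var = m2 - m * m;
      filt_sd(t, d) = var > 0 ? std::sqrt(var) : 0.0;
    }

    double sw2 = 0.0;
    for (int i = 0; i < n; ++i) sw2 += wnorm[i] * wnorm[i];
    double ess = 1.0 / sw2;
    ess_trace[t] = ess;

    if (t < T - 1) {
      // resample if degenerate
      if (ess < n / 2.0) {
        systematic_resample(wnorm, idx);
        std::vector<double> W2(n * M);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < M; ++j) W2[i * M + j] = W[idx[i] * M + j];
        W.swap(W2);
        if (variant == 1) {
          std::vector<double> A2(n);
          for (int i = 0; i < n; ++i) A2[i] = A[idx[i]];
          A.swap(A2);
        }
        if (variant == 2) {
          std::vector<double> B2(n * M);
          for (int i = 0; i < n; ++i)
            for (int j = 0; j < M; ++j) B2[i * M + j] = B[idx[i] * M + j];
          B.swap(B2);
        }
        std::vector<double> pr(n);
        for (int i = 0; i < n; ++i) pr[i] = p[idx[i]];
        p.swap(pr);
        for (int i = 0; i < n; ++i) {
          wnorm[i] = 1.0 / n;
          cur_anc[i] = idx[i];
        }
      } else {
        for (int i = 0; i < n; ++i) cur_anc[i] = i;
      }

      // propagate through the learning rule + dynamics noise
      bool bnd = boundary_next[t];
      double rt = r[t];
      for (int i = 0; i < n; ++i) {
        double gate = (variant == 1) ? A[i] : 1.0;
        double onem = 1.0 - p[i];
        for (int j = 0; j < M; ++j) {
          double bj = (variant == 2) ? B[i * M + j] : beta[j];
          double drift = gate * alpha[j] * (rt - bj) * onem * yt * X(t, j)
                         - Qdiag[j] * W[i * M + j];
          double sd = bnd ? sigma_day[j] : sigma[j];
          W[i * M + j] += drift + (sd > 0 ? sd * norm_rand() : 0.0);
        }
        if (variant == 1 && sigma_alpha > 0) A[i] += sigma_alpha * norm_rand();
        if (variant == 2 && beta_sigma > 0)
          for (int j = 0; j < M; ++j) B[i * M + j] += beta_sigma * norm_rand();
      }
    }
  }

  NumericVector final_w(n);
  for (int i = 0; i < n; ++i) final_w[i] = wnorm[i];

  List out = List::create(
    Named("filt_mean") = filt_mean, Named("filt_sd") = filt_sd,
    Named("loglik_per_trial") = loglik, Named("ess_trace") = ess_trace,
    Named("final_weights") = final_w);
  if (store_paths) {
    out["states"] = states;
    out["ancestors"] = anc;
  }
  return out;
}

// Bootstrap particle filter for the TDRL action-value model. Latent state
// is the value pair (V_L, V_R); observation model is the percept-
// marginalized probit choice rule, propagation the belief-weighted TD
// update with its percept-noise fluctuation.

// [[Rcpp::export]]
List pf_tdrl_cpp(NumericVector s, NumericVector y, NumericVector r,
                 LogicalVector observed, double sigma_m, double td_rate,
                 double VL0, double VR0, double lapse, int n_particles) {
  int T = s.size();
  int n = n_particles;
  std::vector<double> VL(n, VL0), VR(n, VR0), wnorm(n, 1.0 / n), p(n);
  std::vector<int> idx(n);
  NumericMatrix filt_mean(T, 2), filt_sd(T, 2);
  NumericVector loglik(T), ess_trace(T);
  double inv_sm = 1.0 / sigma_m;
  double phi_norm = 1.0 / (sigma_m * std::sqrt(2.0 * M_PI));

  for (int t = 0; t < T; ++t) {
    double yt = y[t];
    for (int i = 0; i < n; ++i) {
      double frac = clampp(VL[i] / (VL[i] + VR[i]));
      double pR = clampp(R::pnorm(s[t] * inv_sm - R::qnorm(frac, 0, 1, 1, 0), 0, 1, 1, 0));
      pR = lapse * 0.5 + (1.0 - lapse) * pR;
      p[i] = clampp(yt > 0 ? pR : 1.0 - pR);
    }
    double incr = 0.0;
    for (int i = 0; i < n; ++i) incr += wnorm[i] * p[i];
    loglik[t] = std::log(incr);
    if (observed[t])
      for (int i = 0; i < n; ++i) wnorm[i] *= p[i] / incr;

    for (int d = 0; d < 2; ++d) {
      double m = 0.0, m2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = d == 0 ? VL[i] : VR[i];
        m += wnorm[i] * v;
        m2 += wnorm[i] * v * v;
      }
      filt_mean(t, d) = m;
      double var = m2 - m * m;
      filt_sd(t, d) = var > 0 ? std::sqrt(var) : 0.0;
    }
    double sw2 = 0.0;
    for (int i = 0; i < n; ++i) sw2 += wnorm[i] * wnorm[i];
    ess_trace[t] = 1.0 / sw2;

    if (t < T - 1) {
      if (ess_trace[t] < n / 2.0) {
        systematic_resample(wnorm, idx);
        std::vector<double> VL2(n), VR2(n);
        for (int i = 0; i < n; ++i) {
          VL2[i] = VL[idx[i]];
          VR2[i] = VR[idx[i]];
        }
        VL.swap(VL2);
        VR.swap(VR2);
        for (int i = 0; i < n; ++i) wnorm[i] = 1.0 / n;
      }
      double pc = R::pnorm(yt * s[t] / (2.0 * sigma_m), 0, 1, 1, 0);
      double phi = phi_norm * std::exp(-0.5 * s[t] * s[t] * inv_sm * inv_sm);
      for (int i = 0; i < n; ++i) {
        double* V = yt > 0 ? &VR[i] : &VL[i];
        *V += td_rate * (r[t] - (*V) * pc) + (*V) * phi * norm_rand();
        if (*V < 1e-8) *V = 1e-8;
      }
    }
  }
  return List::create(
    Named("filt_mean") = filt_mean, Named("filt_sd") = filt_sd,
    Named("loglik_per_trial") = loglik, Named("ess_trace") = ess_trace);
}
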