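// Compiled log-posterior and adaptive Metropolis-within-Gibbs sampler.
//
// The unconstrained parameter layout (0-based) mirrors R/model_state.R:
//   0..31   logit m*_{i,k} (group-major, area fast)
//   32..34  logit r_ad (Western, Central(=Eastern), Southern)
//   35..37  logit r_juv
//   38      mu_S_d13C
//   39      u_theta, theta = -exp(u)
//   40      mu_WCE_d15N; 41 mu_S_d15N
//   42..45  log sigma (C_WCE, N_WCE, C_S, N_S)
//   46      logit rho0_WCE; 47 logit rho0_S
//   48..67  logit f_nb (area fast, 4x5)
//   68      log a
//
// Blocks 0..7 are the eight m* rows, 8/9 the two reporting-probability
// triples, 10 the isotope parameters, 11 the parasite parameters.  Each
// block update recomputes only the posterior terms that depend on it.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NPAR = 69;
static const int NBLOCK = 12;

static inline double sigmoid(double z) {
  if (z >= 0) { double e = std::exp(-z); return 1.0 / (1.0 + e); }
  double e = std::exp(z); return e / (1.0 + e);
}
static inline double log_sigmoid(double z) {
  return z < 0 ? z - std::log1p(std::exp(z)) : -std::log1p(std::exp(-z));
}
static inline double logit_jac(double z) { // log |d sigmoid / dz|
  return log_sigmoid(z) + log_sigmoid(-z);
}

struct Model {
  // ring data (known matrices are 8x5 with the never column)
  NumericMatrix Rak, Rjk, Rau, Rju;
  std::vector<double> const_ak, const_jk, const_au, const_ju; // lgamma constants
  std::vector<double> Nad, Njuv, tot_au, tot_ju;
  // isotopes
  NumericMatrix Y; // n x 2 standardized
  std::vector<std::vector<int>> pop_idx; // per population, row indices in Y
  std::vector<int> pop_row;              // m row per population (0-based)
  // parasites
  NumericMatrix Gnb, Hnb, Gb, Hb;
  bool use_rings, use_iso, use_par;
  // prior hyperparameters
  double mu_SC_mean, mu_SC_sd, theta_sd, mu_N_sd;
  double rho0_S_a, rho0_S_b, rho0_WCE_a, rho0_WCE_b, sigma_sd, a_sd;

  void init(List data, List priors, LogicalVector active) {
    use_rings = active[0]; use_iso = active[1]; use_par = active[2];
    Rak = as<NumericMatrix>(data["R_ad_known"]);
    Rjk = as<NumericMatrix>(data["R_juv_known"]);
    Rau = as<NumericMatrix>(data["R_ad_unknown"]);
    Rju = as<NumericMatrix>(data["R_juv_unknown"]);
    Nad.assign(8, 0.0); Njuv.assign(8, 0.0);
    tot_au.assign(8, 0.0); tot_ju.assign(8, 0.0);
    const_ak.assign(8, 0.0); const_jk.assign(8, 0.0);
    const_au.assign(8, 0.0); const_ju.assign(8, 0.0);
    for (int i = 0; i < 8; i++) {
      for (int k = 0; k < 5; k++) { Nad[i] += Rak(i, k); Njuv[i] += Rjk(i, k); }
      for (int k = 0; k < 4; k++) { tot_au[i] += Rau(i, k); tot_ju[i] += Rju(i, k); }
      const_ak[i] = R::lgammafn(Nad[i] + 1.0);
      const_jk[i] = R::lgammafn(Njuv[i] + 1.0);
      for (int k = 0; k < 5; k++) {
        const_ak[i] -= R::lgammafn(Rak(i, k) + 1.0);
        const_jk[i] -= R::lgammafn(Rjk(i, k) + 1.0);
      }
      const_au[i] = R::lgammafn(tot_au[i] + 1.0);
      const_ju[i] = R::lgammafn(tot_ju[i] + 1.0);
      for (int k = 0; k < 4; k++) {
        const_au[i] -= R::lgammafn(Rau(i, k) + 1.0);
        const_ju[i] -= R::lgammafn(Rju(i, k) + 1.0);
      }
    }
    Y = as<NumericMatrix>(data["Y"]);
    IntegerVector pop = as<IntegerVector>(data["pop"]);       // 1..3
    IntegerVector prow = as<IntegerVector>(data["pop_rows"]); // 1..8
    pop_idx.assign(3, std::vector<int>());
    for (int j = 0; j < pop.size(); j++) pop_idx[pop[j] - 1].push_back(j);
    pop_row.assign(3, 0);
    for (int p = 0; p < 3; p++) pop_row[p] = prow[p] - 1;
    Gnb = as<NumericMatrix>(data["G_nb"]); Hnb = as<NumericMatrix>(data["H_nb"]);
    Gb = as<NumericMatrix>(data["G_b"]);   Hb = as<NumericMatrix>(data["H_b"]);
    mu_SC_mean = priors["mu_SC_mean"]; mu_SC_sd = priors["mu_SC_sd"];
    theta_sd = priors["theta_sd"]; mu_N_sd = priors["mu_N_sd"];
    rho0_S_a = priors["rho0_S_shape1"]; rho0_S_b = priors["rho0_S_shape2"];
    rho0_WCE_a = priors["rho0_WCE_shape1"]; rho0_WCE_b = priors["rho0_WCE_shape2"];
    sigma_sd = priors["sigma_sd"]; a_sd = priors["a_sd"];
  }

  // ---- natural parameters from theta ----
  void m_row(const double* th, int i, double* m) const {
    double s = 0.0, p[4];
    for (int k = 0; k < 4; k++) { p[k] = sigmoid(th[4 * i + k]); s += p[k]; }
    for (int k = 0; k < 4; k++) m[k] = p[k] / s;
  }
  void r_vec(const double* th, int off, double* r) const { // expand to 4 areas
    double w = sigmoid(th[off]), c = sigmoid(th[off + 1]), s = sigmoid(th[off + 2]);
    r[0] = w; r[1] = c; r[2] = c; r[3] = s;
  }

  // ---- prior terms (including Jacobians of the reparameterization) ----
  double prior_m_row(const double* th, int i) const {
    double lp = 0.0;
    for (int k = 0; k < 4; k++) lp += logit_jac(th[4 * i + k]);
    return lp; // Beta(1,1) densities are 0 on the log scale
  }
  double prior_r(const double* th, int off) const {
    return logit_jac(th[off]) + logit_jac(th[off + 1]) + logit_jac(th[off + 2]);
  }
  double prior_iso(const double* th) const {
    double lp = R::dnorm(th[38], mu_SC_mean, mu_SC_sd, 1);
    double theta = -std::exp(th[39]);
    lp += R::dnorm(theta, 0.0, theta_sd, 1) + M_LN2 + th[39];
    lp += R::dnorm(th[40], 0.0, mu_N_sd, 1) + R::dnorm(th[41], 0.0, mu_N_sd, 1);
    for (int s = 42; s <= 45; s++) {
      lp += R::dnorm(std::exp(th[s]), 0.0, sigma_sd, 1) + M_LN2 + th[s];
    }
    lp += R::dbeta(sigmoid(th[46]), rho0_WCE_a, rho0_WCE_b, 1) + logit_jac(th[46]);
    lp += R::dbeta(sigmoid(th[47]), rho0_S_a, rho0_S_b, 1) + logit_jac(th[47]);
    return lp;
  }
  double prior_par(const double* th) const {
    double lp = 0.0;
    for (int c = 48; c <= 67; c++) lp += logit_jac(th[c]);
    lp += R::dnorm(std::exp(th[68]), 0.0, a_sd, 1) + M_LN2 + th[68];
    return lp;
  }

  // ---- ring likelihood terms ----
  double ring_known_row(const NumericMatrix& R, const std::vector<double>& cst,
                        const std::vector<double>& N, int i,
                        const double* m, const double* r) const {
    if (N[i] == 0.0) return 0.0;
    double P[5], s = 0.0;
    for (int k = 0; k < 4; k++) { P[k] = m[k] * r[k]; s += P[k]; }
    P[4] = 1.0 - s;
    double ll = cst[i];
    for (int k = 0; k < 5; k++) {
      double x = R(i, k);
      if (x > 0) {
        if (P[k] <= 0) return R_NegInf;
        ll += x * std::log(P[k]);
      }
    }
    return ll;
  }
  double ring_unknown_row(const NumericMatrix& R, const std::vector<double>& cst,
                          const std::vector<double>& tot, int i,
                          const double* m, const double* r) const {
    if (tot[i] == 0.0) return 0.0;
    double P[4], s = 0.0;
    for (int k = 0; k < 4; k++) { P[k] = m[k] * r[k]; s += P[k]; }
    if (s <= 0) return R_NegInf;
    double ll = cst[i];
    for (int k = 0; k < 4; k++) {
      double x = R(i, k);
      if (x > 0) {
        double q = P[k] / s;
        if (q <= 0) return R_NegInf;
        ll += x * std::log(q);
      }
    }
    return ll;
  }
  double ring_rows_all(const double* th, int i, double* out4) const {
    // out4: ad_known, juv_known, ad_unknown, juv_unknown for row i
    double m[4], rad[4], rjv[4];
    m_row(th, i, m); r_vec(th, 32, rad); r_vec(th, 35, rjv);
    out4[0] = ring_known_row(Rak, const_ak, Nad, i, m, rad);
    out4[1] = ring_known_row(Rjk, const_jk, Njuv, i, m, rjv);
    out4[2] = ring_unknown_row(Rau, const_au, tot_au, i, m, rad);
    out4[3] = ring_unknown_row(Rju, const_ju, tot_ju, i, m, rjv);
    return out4[0] + out4[1] + out4[2] + out4[3];
  }

  // ---- isotope terms ----
  void iso_densities(const double* th, std::vector<double>& ld1,
                     std::vector<double>& ld2) const {
    int n = Y.nrow();
    ld1.resize(n); ld2.resize(n);
    double mu_SC = th[38], theta = -std::exp(th[39]);
    double mu1C = mu_SC + theta, mu1N = th[40];
    double mu2C = mu_SC, mu2N = th[41];
    double sC1 = std::exp(th[42]), sN1 = std::exp(th[43]);
    double sC2 = std::exp(th[44]), sN2 = std::exp(th[45]);
    double rho1 = 2.0 * (sigmoid(th[46]) - 0.5);
    double rho2 = 2.0 * (sigmoid(th[47]) - 0.5);
    double c1 = -std::log(2.0 * M_PI) - std::log(sC1) - std::log(sN1)
                - 0.5 * std::log1p(-rho1 * rho1);
    double c2 = -std::log(2.0 * M_PI) - std::log(sC2) - std::log(sN2)
                - 0.5 * std::log1p(-rho2 * rho2);
    double q1 = 1.0 / (1.0 - rho1 * rho1), q2 = 1.0 / (1.0 - rho2 * rho2);
    for (int j = 0; j < n; j++) {
      double zx = (Y(j, 0) - mu1C) / sC1, zy = (Y(j, 1) - mu1N) / sN1;
      ld1[j] = c1 - 0.5 * q1 * (zx * zx - 2.0 * rho1 * zx * zy + zy * zy);
      zx = (Y(j, 0) - mu2C) / sC2; zy = (Y(j, 1) - mu2N) / sN2;
      ld2[j] = c2 - 0.5 * q2 * (zx * zx - 2.0 * rho2 * zx * zy + zy * zy);
    }
  }
  double iso_pop_ll(const double* th, int p, const std::vector<double>& ld1,
                    const std::vector<double>& ld2) const {
    double m[4];
    m_row(th, pop_row[p], m);
    double v1 = m[0] + m[1] + m[2], v2 = m[3];
    double ll = 0.0;
    for (int j : pop_idx[p]) {
      double a = ld1[j], b = ld2[j];
      double hi = a > b ? a : b;
      ll += hi + std::log(v1 * std::exp(a - hi) + v2 * std::exp(b - hi));
    }
    return ll;
  }

  // ---- parasite terms ----
  double par_nb_ll(const double* th) const {
    double ll = 0.0;
    for (int l = 0; l < 5; l++) {
      for (int k = 0; k < 4; k++) {
        double f = sigmoid(th[48 + 4 * l + k]);
        ll += R::dbinom(Gnb(k, l), Hnb(k, l), f, 1);
      }
    }
    return ll;
  }
  double par_b_row(const double* th, int p) const {
    double m[4];
    m_row(th, pop_row[p], m);
    double a = std::exp(th[68]);
    double ll = 0.0;
    for (int l = 0; l < 5; l++) {
      double fb = 0.0;
      for (int k = 0; k < 4; k++) fb += sigmoid(th[48 + 4 * l + k]) * m[k];
      fb *= a;
      if (Hb(p, l) > 0) {
        if (fb <= 0.0 || fb >= 1.0) return R_NegInf;
        ll += R::dbinom(Gb(p, l), Hb(p, l), fb, 1);
      }
    }
    return ll;
  }
};

struct Cache {
  double prior_m[8], prior_rad, prior_rjuv, prior_iso, prior_par;
  double ring_row[8][4];
  double iso_pop[3];
  double par_nb, par_b[3];
  std::vector<double> ld1, ld2;

  double total() const {
    double s = prior_rad + prior_rjuv + prior_iso + prior_par + par_nb;
    for (int i = 0; i < 8; i++) {
      s += prior_m[i];
      for (int t = 0; t < 4; t++) s += ring_row[i][t];
    }
    for (int p = 0; p < 3; p++) s += iso_pop[p] + par_b[p];
    return s;
  }
};

static void full_eval(const Model& M, const double* th, Cache& C) {
  for (int i = 0; i < 8; i++) {
    C.prior_m[i] = M.prior_m_row(th, i);
    if (M.use_rings) M.ring_rows_all(th, i, C.ring_row[i]);
    else for (int t = 0; t < 4; t++) C.ring_row[i][t] = 0.0;
  }
  C.prior_rad = M.prior_r(th, 32);
  C.prior_rjuv = M.prior_r(th, 35);
  C.prior_iso = M.prior_iso(th);
  C.prior_par = M.prior_par(th);
  if (M.use_iso && M.Y.nrow() > 0) {
    M.iso_densities(th, C.ld1, C.ld2);
    for (int p = 0; p < 3; p++) C.iso_pop[p] = M.iso_pop_ll(th, p, C.ld1, C.ld2);
  } else {
    for (int p = 0; p < 3; p++) C.iso_pop[p] = 0.0;
  }
  if (M.use_par) {
    C.par_nb = M.par_nb_ll(th);
    for (int p = 0; p < 3; p++) C.par_b[p] = M.par_b_row(th, p);
  } else {
    C.par_nb = 0.0;
    for (int p = 0; p < 3; p++) C.par_b[p] = 0.0;
  }
}

// [[Rcpp::export]]
double lp_unconstrained_cpp(NumericVector theta, List data, List priors,
                            LogicalVector active) {
  if (theta.size() != NPAR) stop("theta must have length 69");
  Model M; M.init(data, priors, active);
  Cache C;
  full_eval(M, theta.begin(), C);
  return C.total();
}

// which population (0..2) a group row belongs to, or -1
static int row_pop(const Model& M, int i) {
  for (int p = 0; p < 3; p++) if (M.pop_row[p] == i) return p;
  return -1;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericVector theta0, int n_iter, int burn_in, int thin,
                   List data, List priors, LogicalVector active,
                   double init_scale, int adapt_batch, double target_accept) {
  if (theta0.size() != NPAR) stop("theta0 must have length 69");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");
  Model M; M.init(data, priors, active);

  std::vector<double> th(theta0.begin(), theta0.end());
  Cache C;
  full_eval(M, th.data(), C);
  if (!R_FINITE(C.total())) stop("log posterior not finite at the initial state");

  // block -> coordinate ranges
  int blk_lo[NBLOCK], blk_hi[NBLOCK];
  for (int b = 0; b < 8; b++) { blk_lo[b] = 4 * b; blk_hi[b] = 4 * b + 3; }
  blk_lo[8] = 32; blk_hi[8] = 34; blk_lo[9] = 35; blk_hi[9] = 37;
  blk_lo[10] = 38; blk_hi[10] = 47; blk_lo[11] = 48; blk_hi[11] = 68;

  std::vector<double> log_scale(NBLOCK, std::log(init_scale));
  std::vector<long> acc_tot(NBLOCK, 0), prop_tot(NBLOCK, 0);
  std::vector<int> acc_batch(NBLOCK, 0), batch_n(NBLOCK, 0);
  std::vector<int> batch_count(NBLOCK, 0);

  // per-coordinate posterior scale estimates (Welford running variance over
  // the burn-in trajectory); proposals are scale[block] * sd[coord] * N(0,1)
  std::vector<double> run_mean(NPAR, 0.0), run_m2(NPAR, 0.0), prop_sd(NPAR, 1.0);
  long run_n = 0;

  // full-vector adaptive-Metropolis kernel: empirical covariance accumulated
  // over the second three quarters of burn-in, proposal
  // gamma * (2.38/sqrt(d)) * L z.  This kernel travels the posterior ridges
  // that couple the reporting probabilities to every connectivity row, which
  // the block updates cannot follow.
  std::vector<double> am_sum(NPAR, 0.0), am_sprod((size_t)NPAR * NPAR, 0.0);
  long am_n = 0;
  std::vector<double> am_chol; // lower-triangular, row-major, when ready
  double am_log_gamma = 0.0;
  int am_acc_batch = 0, am_batch_n = 0, am_batch_count = 0;
  long am_acc_tot = 0, am_prop_tot = 0;
  Cache C2;
  std::vector<double> am_prop(NPAR);

  auto am_refresh = [&]() {
    if (am_n < 100) return;
    std::vector<double> cov((size_t)NPAR * NPAR);
    double tr = 0.0;
    for (int i = 0; i < NPAR; i++) {
      for (int j = 0; j < NPAR; j++) {
        cov[(size_t)i * NPAR + j] = am_sprod[(size_t)i * NPAR + j] / am_n
          - (am_sum[i] / am_n) * (am_sum[j] / am_n);
      }
      tr += cov[(size_t)i * NPAR + i];
    }
    double jitter = 1e-8 * (tr / NPAR) + 1e-12;
    for (int attempt = 0; attempt < 6; attempt++) {
      std::vector<double> L((size_t)NPAR * NPAR, 0.0);
      bool ok = true;
      for (int i = 0; i < NPAR && ok; i++) {
        for (int j = 0; j <= i; j++) {
          double s = cov[(size_t)i * NPAR + j] + (i == j ? jitter : 0.0);
          for (int k = 0; k < j; k++) {
            s -= L[(size_t)i * NPAR + k] * L[(size_t)j * NPAR + k];
          }
          if (i == j) {
            if (s <= 0) { ok = false; break; }
            L[(size_t)i * NPAR + i] = std::sqrt(s);
          } else {
            L[(size_t)i * NPAR + j] = s / L[(size_t)j * NPAR + j];
          }
        }
      }
      if (ok) { am_chol.swap(L); return; }
      jitter *= 100.0;
    }
  };

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, NPAR);
  NumericVector lp_keep(n_keep);
  int kept = 0;

  std::vector<double> prop(th);
  std::vector<double> ld1_new, ld2_new;

  // Sweeps with iter <= 0 are a greedy stochastic-ascent warm start: the
  // same block proposals, but only improvements are accepted.  Prior-drawn
  // initial states can sit far from a concentrated posterior; the ascent
  // moves each chain to the vicinity of the typical set in a few hundred
  // sweeps so the burn-in proper is spent adapting, not travelling.
  const int greedy_sweeps = 300;
  bool greedy = true;
  auto mh_accept = [&](double delta) {
    return greedy ? (delta > 0) : (std::log(unif_rand()) < delta);
  };

  for (int iter = 1 - greedy_sweeps; iter <= n_iter; iter++) {
    greedy = iter <= 0;
    for (int b = 0; b < NBLOCK; b++) {
      double sc = std::exp(log_scale[b]);
      for (int c = blk_lo[b]; c <= blk_hi[b]; c++) {
        prop[c] = th[c] + sc * prop_sd[c] * norm_rand();
      }
      double d_new = 0.0, d_old = 0.0;
      bool bad = false;
      // candidate term values (only those the block touches)
      double n_prior_m = 0.0, n_ring[4] = {0, 0, 0, 0};
      double n_iso_pop = 0.0, n_par_b = 0.0;
      double n_prior_scalar = 0.0, n_par_nb = 0.0;
      double n_iso_all[3] = {0, 0, 0}, n_par_b_all[3] = {0, 0, 0};
      bool iso_swap = false;

      if (b < 8) {
        int i = b, p = row_pop(M, i);
        n_prior_m = M.prior_m_row(prop.data(), i);
        d_new += n_prior_m; d_old += C.prior_m[i];
        if (M.use_rings) {
          double s = M.ring_rows_all(prop.data(), i, n_ring);
          if (!R_FINITE(s)) bad = true;
          d_new += s;
          for (int t = 0; t < 4; t++) d_old += C.ring_row[i][t];
        }
        if (!bad && p >= 0) {
          if (M.use_iso && M.Y.nrow() > 0) {
            n_iso_pop = M.iso_pop_ll(prop.data(), p, C.ld1, C.ld2);
            d_new += n_iso_pop; d_old += C.iso_pop[p];
          }
          if (M.use_par) {
            n_par_b = M.par_b_row(prop.data(), p);
            if (!R_FINITE(n_par_b)) bad = true;
            d_new += n_par_b; d_old += C.par_b[p];
          }
        }
        if (!bad && mh_accept(d_new - d_old)) {
          C.prior_m[i] = n_prior_m;
          if (M.use_rings) for (int t = 0; t < 4; t++) C.ring_row[i][t] = n_ring[t];
          if (p >= 0) {
            if (M.use_iso && M.Y.nrow() > 0) C.iso_pop[p] = n_iso_pop;
            if (M.use_par) C.par_b[p] = n_par_b;
          }
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) th[c] = prop[c];
          acc_batch[b]++; acc_tot[b]++;
        } else {
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) prop[c] = th[c];
        }
      } else if (b == 8 || b == 9) {
        int off = (b == 8) ? 32 : 35;
        int t0 = (b == 8) ? 0 : 1; // ad terms are columns 0,2; juv 1,3
        n_prior_scalar = M.prior_r(prop.data(), off);
        d_new += n_prior_scalar;
        d_old += (b == 8) ? C.prior_rad : C.prior_rjuv;
        double n_rows[8][2];
        if (M.use_rings) {
          double m[4], r[4];
          M.r_vec(prop.data(), off, r);
          for (int i = 0; i < 8 && !bad; i++) {
            M.m_row(prop.data(), i, m);
            if (b == 8) {
              n_rows[i][0] = M.ring_known_row(M.Rak, M.const_ak, M.Nad, i, m, r);
              n_rows[i][1] = M.ring_unknown_row(M.Rau, M.const_au, M.tot_au, i, m, r);
            } else {
              n_rows[i][0] = M.ring_known_row(M.Rjk, M.const_jk, M.Njuv, i, m, r);
              n_rows[i][1] = M.ring_unknown_row(M.Rju, M.const_ju, M.tot_ju, i, m, r);
            }
            if (!R_FINITE(n_rows[i][0]) || !R_FINITE(n_rows[i][1])) bad = true;
            d_new += n_rows[i][0] + n_rows[i][1];
            d_old += C.ring_row[i][t0] + C.ring_row[i][t0 + 2];
          }
        }
        if (!bad && mh_accept(d_new - d_old)) {
          if (b == 8) C.prior_rad = n_prior_scalar; else C.prior_rjuv = n_prior_scalar;
          if (M.use_rings) {
            for (int i = 0; i < 8; i++) {
              C.ring_row[i][t0] = n_rows[i][0];
              C.ring_row[i][t0 + 2] = n_rows[i][1];
            }
          }
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) th[c] = prop[c];
          acc_batch[b]++; acc_tot[b]++;
        } else {
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) prop[c] = th[c];
        }
      } else if (b == 10) {
        n_prior_scalar = M.prior_iso(prop.data());
        d_new += n_prior_scalar; d_old += C.prior_iso;
        if (M.use_iso && M.Y.nrow() > 0) {
          M.iso_densities(prop.data(), ld1_new, ld2_new);
          iso_swap = true;
          for (int p = 0; p < 3; p++) {
            n_iso_all[p] = M.iso_pop_ll(prop.data(), p, ld1_new, ld2_new);
            d_new += n_iso_all[p]; d_old += C.iso_pop[p];
          }
        }
        if (!bad && mh_accept(d_new - d_old)) {
          C.prior_iso = n_prior_scalar;
          if (iso_swap) {
            C.ld1.swap(ld1_new); C.ld2.swap(ld2_new);
            for (int p = 0; p < 3; p++) C.iso_pop[p] = n_iso_all[p];
          }
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) th[c] = prop[c];
          acc_batch[b]++; acc_tot[b]++;
        } else {
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) prop[c] = th[c];
        }
      } else { // b == 11, parasite block
        n_prior_scalar = M.prior_par(prop.data());
        d_new += n_prior_scalar; d_old += C.prior_par;
        if (M.use_par) {
          n_par_nb = M.par_nb_ll(prop.data());
          d_new += n_par_nb; d_old += C.par_nb;
          for (int p = 0; p < 3 && !bad; p++) {
            n_par_b_all[p] = M.par_b_row(prop.data(), p);
            if (!R_FINITE(n_par_b_all[p])) bad = true;
            d_new += n_par_b_all[p]; d_old += C.par_b[p];
          }
        }
        if (!bad && mh_accept(d_new - d_old)) {
          C.prior_par = n_prior_scalar;
          if (M.use_par) {
            C.par_nb = n_par_nb;
            for (int p = 0; p < 3; p++) C.par_b[p] = n_par_b_all[p];
          }
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) th[c] = prop[c];
          acc_batch[b]++; acc_tot[b]++;
        } else {
          for (int c = blk_lo[b]; c <= blk_hi[b]; c++) prop[c] = th[c];
        }
      }
      prop_tot[b]++; batch_n[b]++;

      // adaptation during burn-in only (Roberts & Rosenthal batch scheme)
      if (iter <= burn_in && batch_n[b] >= adapt_batch) {
        double rate = (double)acc_batch[b] / batch_n[b];
        batch_count[b]++;
        double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_count[b]));
        log_scale[b] += (rate > target_accept) ? delta : -delta;
        acc_batch[b] = 0; batch_n[b] = 0;
      }
    }
    // full-vector adaptive-Metropolis updates (once the covariance is
    // ready); several per iteration during late burn-in to speed the
    // approach to the typical set, one per iteration afterwards
    if (!am_chol.empty()) {
      int am_reps = (iter <= burn_in) ? 4 : 1;
      for (int rep = 0; rep < am_reps; rep++) {
        double step = std::exp(am_log_gamma) * 2.38 / std::sqrt((double)NPAR);
        for (int i = 0; i < NPAR; i++) am_prop[i] = norm_rand();
        for (int i = NPAR - 1; i >= 0; i--) {
          double s = 0.0;
          for (int k = 0; k <= i; k++) s += am_chol[(size_t)i * NPAR + k] * am_prop[k];
          am_prop[i] = th[i] + step * s;
        }
        full_eval(M, am_prop.data(), C2);
        double lp_new = C2.total(), lp_old = C.total();
        am_prop_tot++; am_batch_n++;
        if (R_FINITE(lp_new) && std::log(unif_rand()) < lp_new - lp_old) {
          for (int i = 0; i < NPAR; i++) { th[i] = am_prop[i]; prop[i] = am_prop[i]; }
          std::swap(C, C2);
          am_acc_tot++; am_acc_batch++;
        }
        if (iter <= burn_in && am_batch_n >= adapt_batch) {
          double rate = (double)am_acc_batch / am_batch_n;
          am_batch_count++;
          double delta = std::min(0.05, 1.0 / std::sqrt((double)am_batch_count));
          am_log_gamma += (rate > 0.234) ? delta : -delta;
          am_acc_batch = 0; am_batch_n = 0;
        }
      }
    }

    // covariance accumulation and refresh schedule; the accumulator is
    // restarted at mid-burn-in so the covariance frozen at the end of
    // burn-in reflects the equilibrated chain, not the initial transient
    if (iter <= burn_in) {
      if (iter > burn_in / 4) {
        am_n++;
        for (int i = 0; i < NPAR; i++) {
          am_sum[i] += th[i];
          for (int j = 0; j <= i; j++) {
            am_sprod[(size_t)i * NPAR + j] += th[i] * th[j];
          }
        }
      }
      if ((iter == burn_in / 2 || (iter > burn_in / 2 && iter % 500 == 0) ||
           iter == burn_in) && am_n >= 100) {
        // mirror the lower triangle before use
        for (int i = 0; i < NPAR; i++) {
          for (int j = i + 1; j < NPAR; j++) {
            am_sprod[(size_t)i * NPAR + j] = am_sprod[(size_t)j * NPAR + i];
          }
        }
        am_refresh();
        if (iter == burn_in / 2) {
          std::fill(am_sum.begin(), am_sum.end(), 0.0);
          std::fill(am_sprod.begin(), am_sprod.end(), 0.0);
          am_n = 0;
        }
      }
    }

    // Two-phase adaptation: the first half of burn-in uses unit coordinate
    // scales while the block factors tune; coordinate sds are estimated from
    // the second quarter of that phase and switched on at mid-burn-in (with
    // the batch clocks reset so the block factors re-tune), avoiding the
    // freeze feedback of estimating scales from a chain that has not moved.
    if (iter <= burn_in) {
      if (iter > burn_in / 4 && iter <= burn_in / 2) {
        run_n++;
        for (int c = 0; c < NPAR; c++) {
          double d = th[c] - run_mean[c];
          run_mean[c] += d / run_n;
          run_m2[c] += d * (th[c] - run_mean[c]);
        }
      }
      if (iter == burn_in / 2 && run_n > 10) {
        for (int c = 0; c < NPAR; c++) {
          double sdc = std::sqrt(run_m2[c] / (run_n - 1));
          if (sdc > 1e-8) prop_sd[c] = sdc;
        }
        for (int b = 0; b < NBLOCK; b++) {
          log_scale[b] = std::log(1.0); // restart near unit factor
          acc_batch[b] = 0; batch_n[b] = 0; batch_count[b] = 0;
        }
      }
    }
    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      for (int c = 0; c < NPAR; c++) draws(kept, c) = th[c];
      lp_keep[kept] = C.total();
      kept++;
    }
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc(NBLOCK + 1), scl(NBLOCK);
  for (int b = 0; b < NBLOCK; b++) {
    acc[b] = prop_tot[b] > 0 ? (double)acc_tot[b] / prop_tot[b] : NA_REAL;
    scl[b] = std::exp(log_scale[b]);
  }
  acc[NBLOCK] = am_prop_tot > 0 ? (double)am_acc_tot / am_prop_tot : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = acc,
                      _["scales"] = scl, _["lp"] = lp_keep);
}
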