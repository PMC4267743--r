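#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Copying emission: the next haplotype copies its donor with a per-site
// mutation parameter theta; matching alleles get k/(k+theta) + theta/(2(k+theta)),
// mismatches theta/(2(k+theta)).
static inline void emission_pair(int k, double theta, double &em_match, double &em_mis) {
  double denom = (double)k + theta;
  em_mis = 0.5 * theta / denom;
  em_match = (double)k / denom + em_mis;
}

// Forward pass for the crossover-only copying HMM (k donor states).
// target, panel alleles in {0,1}; pos in kb; returns log pi-hat.
static double fwd_cross(const int *target, const int *panel, int k, int S,
                        const double *pos, double rho, double theta) {
  double em_match, em_mis;
  emission_pair(k, theta, em_match, em_mis);
  std::vector<double> alpha(k), alpha_new(k);
  double loglik = 0.0;
  double norm = 0.0;
  for (int x = 0; x < k; ++x) {
    double em = (target[0] == panel[x]) ? em_match : em_mis;
    alpha[x] = em / (double)k;
    norm += alpha[x];
  }
  if (norm <= 0.0) return R_NegInf;
  loglik += std::log(norm);
  for (int x = 0; x < k; ++x) alpha[x] /= norm;
  for (int j = 1; j < S; ++j) {
    double d = pos[j] - pos[j - 1];
    double p = std::exp(-rho * d / (double)k);
    double tot = 0.0;
    for (int x = 0; x < k; ++x) tot += alpha[x];
    double mix = (1.0 - p) * tot / (double)k;
    const int *col = panel + (size_t)j * k;
    norm = 0.0;
    for (int x = 0; x < k; ++x) {
      double em = (target[j] == col[x]) ? em_match : em_mis;
      alpha_new[x] = em * (p * alpha[x] + mix);
      norm += alpha_new[x];
    }
    if (norm <= 0.0) return R_NegInf;
    loglik += std::log(norm);
    for (int x = 0; x < k; ++x) alpha[x] = alpha_new[x] / norm;
    }
  return loglik;
}

// Forward pass for the interleaved crossover/conversion copying HMM.
// Joint states (x, g): x in 0..k-1 the crossover-chain donor, g = -1 (outside
// any conversion tract) or a donor 0..k-1. alpha stored as k x (k+1):
// column 0 holds g = empty, column 1+b holds g = b.
static double fwd_joint(const int *target, const int *panel, int k, int S,
                        const double *pos, double rho, double gamma, double lam,
                        double theta) {
  if (gamma <= 0.0) return fwd_cross(target, panel, k, S, pos, rho, theta);
  double em_match, em_mis;
  emission_pair(k, theta, em_match, em_mis);
  const int K = k + 1;
  std::vector<double> alpha((size_t)k * K), anew((size_t)k * K);
  std::vector<double> Atr(k), W(k), A(k);
  double loglik = 0.0;

  // initial distribution: X uniform; G empty with prob 1/(1 + gamma*lam/k),
  // otherwise uniform over donors (stationary balance of initiation gamma/k
  // and termination 1/lam)
  double odds = gamma * lam / (double)k;
  double pg_empty = 1.0 / (1.0 + odds);
  double pg_each = (1.0 - pg_empty) / (double)k;
  double norm = 0.0;
  for (int x = 0; x < k; ++x) {
    double em0 = (target[0] == panel[x]) ? em_match : em_mis;
    alpha[x] = em0 * pg_empty / (double)k;
    norm += alpha[x];
  }
  for (int b = 0; b < k; ++b) {
    double emb = (target[0] == panel[b]) ? em_match : em_mis;
    for (int x = 0; x < k; ++x) {
      double v = emb * pg_each / (double)k;
      alpha[(size_t)(b + 1) * k + x] = v;
      norm += v;
    }
  }
  if (norm <= 0.0) return R_NegInf;
  loglik += std::log(norm);
  for (size_t i = 0; i < alpha.size(); ++i) alpha[i] /= norm;

  std::vector<double> em(k);
  double inv_norm = 1.0;
  for (int j = 1; j < S; ++j) {
    double d = pos[j] - pos[j - 1];
    double p = std::exp(-rho * d / (double)k);
    double c = 1.0 - std::exp(-gamma * d / (double)k);
    double e = (lam > 0.0) ? (1.0 - std::exp(-d / lam)) : 1.0;
    // column-major accumulation of the tract mass per crossover state;
    // the pending 1/norm from the previous site is folded in here
    for (int x = 0; x < k; ++x) Atr[x] = 0.0;
    for (int b = 0; b < k; ++b) {
      const double *col = &alpha[(size_t)(b + 1) * k];
      for (int x = 0; x < k; ++x) Atr[x] += col[x];
    }
    // competing-risks tract chain: c = new tract covers the next site,
    // e = an ongoing tract has ended before it
    double enter = c / (double)k;              // any state -> given donor
    double to_off_from_off = 1.0 - c;          // empty -> empty
    double to_off_from_on = (1.0 - c) * e;     // tract -> empty
    double keep = (1.0 - c) * (1.0 - e);       // same tract continues
    double SW = 0.0;
    for (int x = 0; x < k; ++x) {
      // A[x]: donor-independent inflow into tract states
      A[x] = enter * (alpha[x] + Atr[x]) * inv_norm;
      W[x] = (to_off_from_off * alpha[x] + to_off_from_on * Atr[x]) * inv_norm;
      SW += W[x];
    }
    const int *colp = panel + (size_t)j * k;
    int tj = target[j];
    for (int x = 0; x < k; ++x) em[x] = (tj == colp[x]) ? em_match : em_mis;
    double mix = (1.0 - p) * SW / (double)k;
    norm = 0.0;
    for (int x = 0; x < k; ++x) {
      double v = em[x] * (p * W[x] + mix);
      anew[x] = v;
      norm += v;
    }
    double keep_n = keep * inv_norm;
    for (int b = 0; b < k; ++b) {
      double emb = em[b];
      double *dst = &anew[(size_t)(b + 1) * k];
      const double *src = &alpha[(size_t)(b + 1) * k];
      double colsum = 0.0;
      for (int x = 0; x < k; ++x) {
        double v = emb * (A[x] + keep_n * src[x]);
        dst[x] = v;
        colsum += v;
      }
      norm += colsum;
    }
    if (norm <= 0.0) return R_NegInf;
    loglik += std::log(norm);
    inv_norm = 1.0 / norm;
    alpha.swap(anew);
  }
  return loglik;
}

// Column-major copy of panel rows into site-major scratch (k consecutive
// entries per site) so the inner loops stream contiguously.
static void pack_panel(const IntegerMatrix &H, const std::vector<int> &rows,
                       std::vector<int> &out) {
  int k = (int)rows.size(), S = H.ncol();
  out.resize((size_t)k * S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < k; ++i)
      out[(size_t)j * k + i] = H(rows[i], j);
}

// [[Rcpp::export(name = ".fwd_joint_cpp")]]
double fwd_joint_cpp(IntegerVector target, IntegerMatrix panel, NumericVector pos,
                     double rho, double gamma, double lam, double theta) {
  int k = panel.nrow(), S = panel.ncol();
  std::vector<int> tg(target.begin(), target.end());
  std::vector<int> pk((size_t)k * S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < k; ++i) pk[(size_t)j * k + i] = panel(i, j);
  return fwd_joint(tg.data(), pk.data(), k, S, REAL(pos), rho, gamma, lam, theta);
}

// [[Rcpp::export(name = ".fwd_cross_cpp")]]
double fwd_cross_cpp(IntegerVector target, IntegerMatrix panel, NumericVector pos,
                     double rho, double theta) {
  int k = panel.nrow(), S = panel.ncol();
  std::vector<int> tg(target.begin(), target.end());
  std::vector<int> pk((size_t)k * S);
  for (int j = 0; j < S; ++j)
    for (int i = 0; i < k; ++i) pk[(size_t)j * k + i] = panel(i, j);
  return fwd_cross(tg.data(), pk.data(), k, S, REAL(pos), rho, theta);
}

// PAC product over one conditioning order: rows of H are haplotypes already
// permuted into the order h_1, ..., h_n. Adds S*log(1/2) for the first
// haplotype (uniform allele model; cancels in likelihood ratios).
// [[Rcpp::export(name = ".pac_loglik_cpp")]]
double pac_loglik_cpp(IntegerMatrix H, NumericVector pos, double rho, double gamma,
                      double lam, double theta, bool crossover_only,
                      bool first_term) {
  int n = H.nrow(), S = H.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  double ll = first_term ? S * std::log(0.5) : 0.0;
  std::vector<int> tg(S), pk;
  std::vector<int> rows;
  for (int k = 1; k < n; ++k) {
    rows.push_back(k - 1);
    pack_panel(H, rows, pk);
    for (int j = 0; j < S; ++j) tg[j] = H(k, j);
    double lp;
    if (crossover_only || gamma <= 0.0)
      lp = fwd_cross(tg.data(), pk.data(), k, S, REAL(pos), rho, theta);
    else
      lp = fwd_joint(tg.data(), pk.data(), k, S, REAL(pos), rho, gamma, lam, theta);
    if (!R_FINITE(lp)) return R_NegInf;
    ll += lp;
  }
  return ll;
}
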