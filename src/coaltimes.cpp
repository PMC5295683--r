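#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expected allele-frequency spectrum f_nb / mu = sum_{j=2}^{n} W_bjn * e_j,
// with the W three-term recursion advanced in j for each b. O(n^2) time,
// O(n) memory: W is never stored, only accumulated against e_j.
// e[0] = e_2, ..., e[n-2] = e_n.
// [[Rcpp::export]]
NumericVector cpp_spectrum_from_ej(NumericVector e) {
  const int n = e.size() + 1;
  if (n < 2) stop("need e_j for j = 2..n with n >= 2");
  NumericVector f(n - 1);

  // j-dependent recursion coefficients, shared across b
  std::vector<double> a1(n + 1, 0.0), a2(n + 1, 0.0);
  for (int j = 2; j <= n - 2; ++j) {
    a1[j] = -((1.0 + j) * (3.0 + 2.0 * j) * (n - j)) /
            (j * (2.0 * j - 1.0) * (n + j + 1.0));
    a2[j] = (3.0 + 2.0 * j) / (j * (n + j + 1.0));
  }

  const double w2 = 6.0 / (n + 1.0);
  for (int b = 1; b <= n - 1; ++b) {
    const double nb = n - 2.0 * b;
    double wj = w2;                                    // W_{b,2,n}
    double acc = wj * e[0];
    if (n >= 3) {
      double wj1 = 30.0 * nb / ((n + 1.0) * (n + 2.0)); // W_{b,3,n}
      acc += wj1 * e[1];
      for (int j = 2; j <= n - 2; ++j) {
        const double wj2 = a1[j] * wj + a2[j] * nb * wj1;
        acc += wj2 * e[j];                              // e_{j+2}
        wj = wj1;
        wj1 = wj2;
        // once two consecutive W are this small the solution has decayed
        // for good (a single small value can regrow: W_b3n = 0 exactly at
        // b = n/2); stopping avoids a long subnormal-arithmetic tail
        if (std::fabs(wj) < 1e-270 && std::fabs(wj1) < 1e-270) break;
      }
    }
    // an overflow anywhere in the recursion propagates into acc
    if (!std::isfinite(acc))
      stop("numerical-stability failure: f_nb not finite at b=%d", b);
    f[b - 1] = acc;
  }
  return f;
}

// Expected spectrum from interval expectations E(S_k) via the direct
// combinatorial formula
//   f_nb / mu = (n-b-1)! (b-1)! / (n-1)! * sum_k C(n-k, b-1) k(k-1) E(S_k),
// with the binomial factor tracked in log space (it overflows in doubles
// for n in the thousands). es[0] = E(S_2), ..., es[n-2] = E(S_n).
// [[Rcpp::export]]
NumericVector cpp_spectrum_from_esk(NumericVector es) {
  const int n = es.size() + 1;
  if (n < 2) stop("need E(S_k) for k = 2..n with n >= 2");
  NumericVector f(n - 1);
  for (int b = 1; b <= n - 1; ++b) {
    // log prefactor (n-b-1)! (b-1)! / (n-1)!
    const double lpref = std::lgamma((double)(n - b)) +
                         std::lgamma((double)b) -
                         std::lgamma((double)n);
    // k runs 2..n-b+1 (C(n-k, b-1) = 0 beyond); log C updated multiplicatively
    double lc = std::lgamma((double)(n - 1)) -
                std::lgamma((double)b) -
                std::lgamma((double)(n - b));          // log C(n-2, b-1)
    double acc = 0.0;
    for (int k = 2; k <= n - b + 1; ++k) {
      // lc falls monotonically in k; once the term underflows it stays 0
      if (lpref + lc < -745.0) break;
      acc += std::exp(lpref + lc) * (double)k * (k - 1.0) * es[k - 2];
      const int m = n - k;                             // current upper index
      // C(m-1, b-1) = C(m, b-1) * (m-b+1)/m
      if (m - b + 1 > 0) lc += std::log((m - b + 1.0) / m);
    }
    f[b - 1] = acc;
  }
  return f;
}

// --- counter-based substream RNG (splitmix64), so each genealogy can be
// regenerated exactly from a compact per-genealogy seed without storing
// its O(n) epoch durations. Seeds come from R's RNG, keeping the whole
// simulation reproducible under set.seed().
static inline uint64_t splitmix64(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4B5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double sm_unif(uint64_t &s) {
  // in (0, 1): 53-bit mantissa, never exactly 0
  return ((splitmix64(s) >> 11) + 1.0) * (1.0 / 9007199254740993.0);
}
static inline double sm_exp(uint64_t &s) { return -std::log(sm_unif(s)); }

// real-time epoch lengths tlen[j] (j lineages present) for one genealogy
// generated from substream state `st`; returns total branch length
static double gen_epochs(uint64_t st, int n, int model_kind, double N0,
                         double r, std::vector<double> &tlen) {
  double tau = 0.0, tprev = 0.0, total = 0.0;
  for (int j = n; j >= 2; --j) {
    const double lam = j * (j - 1.0) / 2.0;
    tau += sm_exp(st) / lam;
    const double t = (model_kind == 1 && r > 0.0)
                       ? std::log1p(N0 * r * tau) / r
                       : N0 * tau;
    tlen[j] = t - tprev;
    tprev = t;
    total += j * tlen[j];
  }
  return total;
}

// Infinite-sites site-frequency simulation: n_sites segregating sites are
// scattered over n_sites independent genealogies with probability
// proportional to each genealogy's total branch length (the exact
// conditional of Poisson mutation given the total number of sites); each
// site then lands uniformly on its genealogy's branches and its allele
// class is the number of subtended leaves. Two passes over compact
// per-genealogy seeds keep memory at O(n_sites). model_kind: 0 constant,
// 1 exponential. Returns counts per class b = 1..n-1 (unfolded).
// [[Rcpp::export]]
IntegerVector cpp_sim_sfs(int n, int n_sites, int model_kind,
                          double N0, double r) {
  if (n < 2) stop("n must be >= 2");
  if (n_sites < 1) stop("n_sites must be >= 1");
  const int G = n_sites;
  std::vector<uint64_t> seed(G);
  std::vector<double> L(G);
  std::vector<double> tlen(n + 1);
  std::vector<int> sizes(n);

  // pass 1: lengths
  for (int g = 0; g < G; ++g) {
    seed[g] = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
              (uint64_t)(unif_rand() * 4294967296.0);
    L[g] = gen_epochs(seed[g], n, model_kind, N0, r, tlen);
  }
  // multinomial split of sites over genealogies by sequential binomials
  double Lrem = 0.0;
  for (int g = 0; g < G; ++g) Lrem += L[g];
  IntegerVector counts(n - 1);
  int srem = n_sites;
  for (int g = 0; g < G && srem > 0; ++g) {
    const double p = (Lrem > 0.0) ? std::min(1.0, L[g] / Lrem) : 1.0;
    const int m = (g == G - 1) ? srem : (int)R::rbinom(srem, p);
    Lrem -= L[g];
    if (m == 0) continue;
    srem -= m;
    // pass 2 for this genealogy: regenerate epochs, then place its sites
    const double total = gen_epochs(seed[g], n, model_kind, N0, r, tlen);
    const uint64_t topo_seed = seed[g] ^ 0xA3EC4E7B12D96C0DULL;
    for (int s = 0; s < m; ++s) {
      double u = unif_rand() * total;
      int jstar = 2;
      for (int j = n; j >= 2; --j) {
        u -= j * tlen[j];
        if (u <= 0.0) { jstar = j; break; }
      }
      // replay this genealogy's (fixed) merge sequence down to jstar
      // lineages to know the subtree leaf counts
      uint64_t ts = topo_seed;
      for (int i = 0; i < n; ++i) sizes[i] = 1;
      for (int mm = n; mm > jstar; --mm) {
        const int i1 = (int)(sm_unif(ts) * mm);
        int i2 = (int)(sm_unif(ts) * (mm - 1));
        if (i2 >= i1) ++i2;
        sizes[std::min(i1, i2)] += sizes[std::max(i1, i2)];
        sizes[std::max(i1, i2)] = sizes[mm - 1];
      }
      const int pick = (int)(unif_rand() * jstar);
      const int b = sizes[pick];
      // b = n cannot happen: the root epoch has 2 lineages, each < n leaves
      if (b >= 1 && b <= n - 1) counts[b - 1] += 1;
    }
  }
  return counts;
}
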