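#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based per-cell RNG: each cell gets an independent stream derived
// from (master seed, cell index) via splitmix64, so results do not depend on
// how cells are batched.
static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct CellRng {
  uint64_t s0, s1;
  CellRng(uint64_t seed, uint64_t cell) {
    uint64_t x = seed ^ (cell * 0xD1342543DE82EF95ULL + 0x2545F4914F6CDD1DULL);
    s0 = splitmix64_next(x);
    s1 = splitmix64_next(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  // xorshift128+
  uint64_t next_u64() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform on (0,1), never exactly 0 or 1
  double runif01() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Exact (Gillespie) simulation of the telegraph chain for one cell.
// Allele states: 2-state model {0 = off, 1 = on}; 3-state model
// {0 = off, 1 = intermediate, 2 = on}. mRNA degradation is first order in
// the pooled transcript count. `sw` is the S x S matrix of allele switching
// rates (row = from, col = to, off-diagonal), `ktr[s]` the transcription
// rate while an allele sits in state s.
static int ssa_one_cell(const NumericMatrix &sw, const NumericVector &ktr,
                        double kd, double t_end, int n_alleles, CellRng &rng) {
  const int S = sw.nrow();
  std::vector<int> allele(n_alleles, 0); // all start 'off'
  int m = 0;                             // no mRNA initially
  double t = 0.0;

  std::vector<double> prop; // propensities, rebuilt each event (few channels)
  for (;;) {
    prop.clear();
    // switching channels: (allele a, target state s2)
    for (int a = 0; a < n_alleles; ++a)
      for (int s2 = 0; s2 < S; ++s2)
        if (s2 != allele[a]) prop.push_back(sw(allele[a], s2));
    // transcription per allele
    for (int a = 0; a < n_alleles; ++a) prop.push_back(ktr[allele[a]]);
    // degradation
    prop.push_back(kd * m);

    double a0 = 0.0;
    for (double p : prop) a0 += p;
    if (a0 <= 0.0) break;

    double dt = -std::log(rng.runif01()) / a0;
    t += dt;
    if (t > t_end) break;

    double r = rng.runif01() * a0, acc = 0.0;
    size_t j = 0;
    for (; j < prop.size(); ++j) {
      acc += prop[j];
      if (r <= acc) break;
    }
    if (j >= prop.size()) j = prop.size() - 1;

    const size_t n_switch = (size_t)n_alleles * (S - 1);
    if (j < n_switch) {
      int a = (int)(j / (S - 1));
      int k = (int)(j % (S - 1));
      // k-th state != current state of allele a
      int s2 = 0, cnt = -1;
      for (s2 = 0; s2 < S; ++s2) {
        if (s2 != allele[a]) ++cnt;
        if (cnt == k) break;
      }
      allele[a] = s2;
    } else if (j < n_switch + (size_t)n_alleles) {
      ++m;
    } else {
      if (m > 0) --m;
    }
  }
  return m;
}

// [[Rcpp::export(name = ".ssa_telegraph_cpp")]]
IntegerVector ssa_telegraph_cpp(NumericMatrix sw, NumericVector ktr,
                                double kd, double t_end, int n_cells,
                                int n_alleles, double seed) {
  IntegerVector out(n_cells);
  uint64_t s = (uint64_t)seed;
  for (int c = 0; c < n_cells; ++c) {
    CellRng rng(s, (uint64_t)(c + 1));
    out[c] = ssa_one_cell(sw, ktr, kd, t_end, n_alleles, rng);
  }
  return out;
}
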