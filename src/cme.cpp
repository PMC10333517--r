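#include <Rcpp.h>
using namespace Rcpp;

// Uniformization solver for the single-gene chemical master equation on the
// truncated state space {allele state s = 0..S-1} x {mRNA count m = 0..N}.
// The generator couples allele switching (rates sw[s,s2]), transcription in
// state s at rate ktr[s] (suppressed at the truncation boundary m = N, so
// probability is conserved and any deficit shows up as mass piling at N,
// which the caller checks), and first-order degradation at rate m * kd.
//
// e^{Qt} p0 is computed as a Poisson-weighted sum of powers of the
// uniformized transition matrix P = I + Q/lambda, stepping in time chunks so
// that lambda * dt stays moderate and the Poisson weights never underflow.
// All rates are pre-divided by lambda and the diagonal terms cached so the
// per-power matrix-vector product is a tight loop.

// [[Rcpp::export(name = ".cme_propagate_cpp")]]
NumericVector cme_propagate_cpp(NumericMatrix sw, NumericVector ktr,
                                double kd, double t, int N,
                                NumericVector p0) {
  const int S = sw.nrow();
  const int n = S * (N + 1);
  if (p0.size() != n) stop("initial vector has wrong length");

  std::vector<double> p(p0.begin(), p0.end());
  if (t <= 0.0) return NumericVector(p.begin(), p.end());

  // uniformization rate: upper bound on total outflow over all states
  double max_sw = 0.0, max_ktr = 0.0;
  for (int s = 0; s < S; ++s) {
    double row = 0.0;
    for (int s2 = 0; s2 < S; ++s2)
      if (s2 != s) row += sw(s, s2);
    if (row > max_sw) max_sw = row;
    if (ktr[s] > max_ktr) max_ktr = ktr[s];
  }
  double lam = max_sw + max_ktr + N * kd;
  if (lam <= 0.0) return NumericVector(p.begin(), p.end());

  // normalized rates (divided by lambda), cached per state
  std::vector<double> swn(S * S, 0.0), ktrn(S), rowsum(S, 0.0);
  for (int s = 0; s < S; ++s) {
    ktrn[s] = ktr[s] / lam;
    for (int s2 = 0; s2 < S; ++s2) {
      if (s2 == s) continue;
      swn[s2 * S + s] = sw(s2, s) / lam; // inflow coefficient into s from s2
      rowsum[s] += sw(s, s2);
    }
  }
  const double kdn = kd / lam;
  // diagonal of P = 1 - outflow/lambda, per joint state
  std::vector<double> diagv(n);
  for (int m = 0; m <= N; ++m)
    for (int s = 0; s < S; ++s) {
      double outflow = rowsum[s] + m * kd;
      if (m < N) outflow += ktr[s];
      diagv[s + S * m] = 1.0 - outflow / lam;
    }

  const double chunk_cap = 500.0;
  int nchunk = (int)std::ceil(lam * t / chunk_cap);
  if (nchunk < 1) nchunk = 1;
  const double dt = t / nchunk;
  const double a = lam * dt;
  const int kmax = (int)std::ceil(a + 12.0 * std::sqrt(a) + 40.0);

  std::vector<double> v(n), vn(n), res(n);
  for (int c = 0; c < nchunk; ++c) {
    double w = std::exp(-a), wsum = w;
    for (int i = 0; i < n; ++i) {
      v[i] = p[i];
      res[i] = w * p[i];
    }
    for (int k = 1; k <= kmax; ++k) {
      // vn = P v
      const double *vp = v.data();
      double *op = vn.data();
      for (int m = 0; m <= N; ++m) {
        const int base = S * m;
        for (int s = 0; s < S; ++s) {
          const int idx = base + s;
          double acc = vp[idx] * diagv[idx];
          const double *swcol = swn.data() + s; // swn[s2*S+s], stride S
          for (int s2 = 0; s2 < S; ++s2)
            acc += vp[base + s2] * swcol[s2 * S];
          if (m > 0) acc += vp[idx - S] * ktrn[s];
          if (m < N) acc += vp[idx + S] * (m + 1) * kdn;
          op[idx] = acc;
        }
      }
      std::swap(v, vn);
      w *= a / k;
      wsum += w;
      for (int i = 0; i < n; ++i) res[i] += w * v[i];
      if (k > a && 1.0 - wsum < 1e-14) break;
    }
    // renormalize the Poisson truncation (wsum <= 1)
    for (int i = 0; i < n; ++i) p[i] = res[i] / wsum;
  }
  return NumericVector(p.begin(), p.end());
}
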