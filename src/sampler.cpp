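#include <Rcpp.h>
using namespace Rcpp;

// Metropolis sampling of protonation microstates.
// Reduced energy: u(x; pH) = ln10 * sum_i x_i (pH - pKa_i)
//                          + sum_{i<j} w_ij x_i x_j   (w in RT units).
// One sweep = q random-scan single-site flip attempts, then one joint flip
// attempt per strongly coupled pair (random scan keeps independent sites
// desynchronised even when flips are always accepted at pH = pKa).
// Uses R's RNG, so traces are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix cpp_sample_microstates(NumericVector pka, NumericMatrix w,
                                     double ph, int n_sweeps,
                                     int record_every, IntegerMatrix pairs) {
  const double LN10 = std::log(10.0);
  const int q = pka.size();
  std::vector<int> x(q, 0);

  // energy change of flipping site i in the current state
  auto dU = [&](int i) {
    double f = LN10 * (ph - pka[i]);
    for (int j = 0; j < q; ++j)
      if (j != i) f += w(i, j) * x[j];
    return (1 - 2 * x[i]) * f;
  };

  const int n_rec = n_sweeps / record_every;
  IntegerMatrix out(n_rec, q);
  int rec = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int a = 0; a < q; ++a) {
      int i = (int)(unif_rand() * q);
      if (i == q) i = q - 1;
      double d = dU(i);
      if (d <= 0.0 || unif_rand() < std::exp(-d)) x[i] = 1 - x[i];
    }
    for (int p = 0; p < pairs.nrow(); ++p) {
      int i = pairs(p, 0), j = pairs(p, 1);
      double d = dU(i);
      x[i] = 1 - x[i];
      d += dU(j);
      x[i] = 1 - x[i];
      if (d <= 0.0 || unif_rand() < std::exp(-d)) {
        x[i] = 1 - x[i];
        x[j] = 1 - x[j];
      }
    }
    if (rec < n_rec && sweep % record_every == 0) {
      for (int i = 0; i < q; ++i) out(rec, i) = x[i];
      ++rec;
    }
  }
  return out;
}
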