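#include <Rcpp.h>
using namespace Rcpp;

// Online passive-aggressive (PA-I) max-margin training for keyword vs
// non-keyword pairs. X holds the PC feature series (frames x k). For each
// pair the competitor is the frame within +/- halfwidth of the
// non-keyword alignment frame whose score w.x is maximal under the
// current boundary; the update is the PA-I step
//   w <- w + tau * (x+ - x-),  tau = min(C, loss / ||x+ - x-||^2).
// Pairs are visited in the caller-supplied shuffled order, `epochs` times
// (early stop when an epoch incurs zero hinge loss).
// [[Rcpp::export]]
List pa_train_cpp(NumericMatrix X, IntegerVector pos_frame,
                  IntegerVector neg_center, IntegerVector order,
                  int halfwidth, double C, int epochs) {
  const int k = X.ncol();
  const int n = X.nrow();
  const int np = pos_frame.size();
  std::vector<double> w(k, 0.0);
  NumericVector epoch_loss(epochs);
  int skipped = 0;

  for (int e = 0; e < epochs; ++e) {
    double total = 0.0;
    for (int oi = 0; oi < np; ++oi) {
      const int i = order[oi] - 1;
      const int pf = pos_frame[i] - 1;
      if (pf < 0 || pf >= n) continue;
      int c0 = neg_center[i] - 1 - halfwidth;
      int c1 = neg_center[i] - 1 + halfwidth;
      if (c0 < 0) c0 = 0;
      if (c1 > n - 1) c1 = n - 1;
      if (c0 > c1) continue;
      // competitor: maximally keyword-like frame in the context window
      int best = c0;
      double bestv = -std::numeric_limits<double>::infinity();
      for (int f = c0; f <= c1; ++f) {
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += w[j] * X(f, j);
        if (s > bestv) { bestv = s; best = f; }
      }
      double sp = 0.0;
      for (int j = 0; j < k; ++j) sp += w[j] * X(pf, j);
      double loss = 1.0 - sp + bestv;
      if (loss > 0.0) {
        double nrm = 0.0;
        for (int j = 0; j < k; ++j) {
          const double d = X(pf, j) - X(best, j);
          nrm += d * d;
        }
        if (nrm <= 0.0) {
          ++skipped;
        } else {
          const double tau = std::min(C, loss / nrm);
          for (int j = 0; j < k; ++j) w[j] += tau * (X(pf, j) - X(best, j));
          total += loss;
        }
      }
    }
    epoch_loss[e] = total;
    if (total == 0.0) {
      for (int r = e + 1; r < epochs; ++r) epoch_loss[r] = 0.0;
      break;
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["epoch_loss"] = epoch_loss,
                      _["skipped"] = skipped);
}
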