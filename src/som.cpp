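#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training on a rectangular grid.
//
// data:   n x d training matrix (rows = cells)
// codes:  nodes x d initial codebook (modified copy returned)
// gx, gy: grid coordinates of each node (1-based columns/rows)
// order:  0-based row indices of data, one per update step, pre-shuffled
//         in R so determinism follows R's RNG
// Learning rate and neighbourhood radius decay linearly over the steps;
// the neighbourhood is a bubble: every node whose grid (Euclidean)
// distance to the BMU is strictly below the current radius is moved by
// alpha, so the terminal radius of 1 updates the BMU alone.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix data, NumericMatrix codes,
                            IntegerVector gx, IntegerVector gy,
                            IntegerVector order,
                            double alpha_start, double alpha_end,
                            double radius_start, double radius_end) {
  const int d = data.ncol();
  const int ncodes = codes.nrow();
  const int nsteps = order.size();
  NumericMatrix cb = clone(codes);

  for (int step = 0; step < nsteps; ++step) {
    const double frac = nsteps > 1 ? (double)step / (double)(nsteps - 1) : 0.0;
    const double alpha = alpha_start + frac * (alpha_end - alpha_start);
    const double radius = radius_start + frac * (radius_end - radius_start);
    const double r2 = radius * radius;
    const int row = order[step];

    // best-matching unit (ties -> lowest node index)
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < ncodes; ++j) {
      double dist = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = data(row, c) - cb(j, c);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = j; }
    }

    for (int j = 0; j < ncodes; ++j) {
      const double dx = gx[j] - gx[bmu];
      const double dy = gy[j] - gy[bmu];
      if (dx * dx + dy * dy < r2) {
        for (int c = 0; c < d; ++c)
          cb(j, c) += alpha * (data(row, c) - cb(j, c));
      }
    }
  }
  return cb;
}

// Best-matching unit per row of `data`, 1-based; ties -> lowest index.
// [[Rcpp::export]]
IntegerVector bmu_cpp(NumericMatrix data, NumericMatrix codes) {
  const int n = data.nrow();
  const int d = data.ncol();
  const int ncodes = codes.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int j = 0; j < ncodes; ++j) {
      double dist = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = data(i, c) - codes(j, c);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = j; }
    }
    out[i] = bmu + 1;
  }
  return out;
}
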