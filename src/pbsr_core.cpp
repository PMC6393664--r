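#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (edge-inclusive) mirror reflection of index i into [0, n).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Sum of squared differences between the (2p+1)^2 guide patches centred at
// (ri,ci) and (rj,cj); borders mirror-padded.
static double patch_ssd(const NumericMatrix& hist, int ri, int ci,
                        int rj, int cj, int p) {
  const int nr = hist.nrow(), nc = hist.ncol();
  double ssd = 0.0;
  for (int dr = -p; dr <= p; ++dr) {
    const int ra = reflect(ri + dr, nr), rb = reflect(rj + dr, nr);
    for (int dc = -p; dc <= p; ++dc) {
      const double d = hist(ra, reflect(ci + dc, nc)) -
                       hist(rb, reflect(cj + dc, nc));
      ssd += d * d;
    }
  }
  return ssd;
}

// Sample standard deviation of guide intensities in the search window
// centred at (r,c), clipped to the image; used for the "auto" bandwidth.
static double window_sd(const NumericMatrix& hist, int r, int c, int s) {
  const int nr = hist.nrow(), nc = hist.ncol();
  const int r0 = std::max(0, r - s), r1 = std::min(nr - 1, r + s);
  const int c0 = std::max(0, c - s), c1 = std::min(nc - 1, c + s);
  double sum = 0.0, sum2 = 0.0;
  int n = 0;
  for (int rr = r0; rr <= r1; ++rr)
    for (int cc = c0; cc <= c1; ++cc) {
      const double v = hist(rr, cc);
      sum += v; sum2 += v * v; ++n;
    }
  if (n < 2) return 0.0;
  double var = (sum2 - sum * sum / n) / (n - 1);
  if (var < 0.0) var = 0.0;
  return std::sqrt(var);
}

// One non-local reconstruction sweep: each pixel becomes the normalised
// weighted mean of the previous estimate over its search window. Weights are
// exp(-SSD/h^2) on guide patches; under the hard class constraint neighbours
// of a different label get weight 0 (soft: multiplied by exp(-beta)). The
// centre pixel always participates with weight 1, so the weight sum is
// positive under either constraint; the zero-sum fallback (keep the previous
// value) is retained for safety.
// [[Rcpp::export]]
NumericMatrix pbsr_reconstruct_cpp(const NumericMatrix& est,
                                   const NumericMatrix& hist,
                                   const IntegerMatrix& mask,
                                   int patch_radius, int search_radius,
                                   double h, bool h_auto,
                                   bool hard, double beta) {
  const int nr = est.nrow(), nc = est.ncol();
  NumericMatrix out(nr, nc);
  const double soft_factor = std::exp(-beta);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double hi = h;
      if (h_auto) {
        // noise-proportional bandwidth h = sigma * sqrt(2 * beta * N),
        // beta = 2, N = patch pixel count; sigma from the local window
        const double npatch = (2.0 * patch_radius + 1.0) *
                              (2.0 * patch_radius + 1.0);
        hi = window_sd(hist, r, c, search_radius) * std::sqrt(4.0 * npatch);
        if (hi < 1e-6) hi = 1e-6;
      }
      const double h2 = hi * hi;
      const int li = mask(r, c);
      const int r0 = std::max(0, r - search_radius);
      const int r1 = std::min(nr - 1, r + search_radius);
      const int c0 = std::max(0, c - search_radius);
      const int c1 = std::min(nc - 1, c + search_radius);
      double wsum = 0.0, acc = 0.0;
      for (int cc = c0; cc <= c1; ++cc) {
        for (int rr = r0; rr <= r1; ++rr) {
          const bool same = (mask(rr, cc) == li);
          if (hard && !same) continue;
          double w = std::exp(-patch_ssd(hist, r, c, rr, cc, patch_radius) / h2);
          if (!hard && !same) w *= soft_factor;
          wsum += w;
          acc += w * est(rr, cc);
        }
      }
      out(r, c) = (wsum > 0.0) ? acc / wsum : est(r, c);
    }
  }
  return out;
}

// Unnormalised weight field over the (2s+1)^2 search window around one
// centre (0-based r, c). Positions falling outside the image are NA.
// [[Rcpp::export]]
NumericMatrix pbsr_weights_cpp(const NumericMatrix& hist,
                               const IntegerMatrix& mask,
                               int r, int c,
                               int patch_radius, int search_radius,
                               double h, bool h_auto,
                               bool hard, double beta) {
  const int nr = hist.nrow(), nc = hist.ncol();
  const int s = search_radius;
  NumericMatrix w(2 * s + 1, 2 * s + 1);
  std::fill(w.begin(), w.end(), NA_REAL);
  double hi = h;
  if (h_auto) {
    const double npatch = (2.0 * patch_radius + 1.0) *
                          (2.0 * patch_radius + 1.0);
    hi = window_sd(hist, r, c, s) * std::sqrt(4.0 * npatch);
    if (hi < 1e-6) hi = 1e-6;
  }
  const double h2 = hi * hi;
  const int li = mask(r, c);
  const double soft_factor = std::exp(-beta);
  for (int dc = -s; dc <= s; ++dc) {
    for (int dr = -s; dr <= s; ++dr) {
      const int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const bool same = (mask(rr, cc) == li);
      if (hard && !same) { w(dr + s, dc + s) = 0.0; continue; }
      double wij = std::exp(-patch_ssd(hist, r, c, rr, cc, patch_radius) / h2);
      if (!hard && !same) wij *= soft_factor;
      w(dr + s, dc + s) = wij;
    }
  }
  return w;
}
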