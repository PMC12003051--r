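#include <Rcpp.h>
using namespace Rcpp;

// Local window sums of I and I^2 for every center whose window fits inside
// P. The window is described by per-row chord half-widths (square kernels:
// constant m; discs: floor(sqrt(r2 - dy^2))), so each window row is a
// contiguous run and can be taken from row prefix sums in O(1).
// [[Rcpp::export(name = ".chord_local_sums")]]
List chord_local_sums(NumericMatrix P, IntegerVector half, int m) {
  const int nP = P.nrow(), pP = P.ncol();
  const int nr = nP - 2 * m, nc = pP - 2 * m;
  if (nr < 1 || nc < 1) stop("image smaller than the kernel");
  const int K = 2 * m + 1;
  const std::vector<int> hw(half.begin(), half.end());

  // column-prefix layout: C1[j*(nP+1) + i+1] = sum_{r<=i} P(r, j), so the
  // hot loop walks contiguous memory down each image column
  const int H = nP + 1;
  std::vector<double> C1((size_t)pP * H), C2((size_t)pP * H);
  const double* p = REAL(P);
  for (int j = 0; j < pP; ++j) {
    const double* col = p + (size_t)j * nP;
    double* c1 = &C1[(size_t)j * H];
    double* c2 = &C2[(size_t)j * H];
    double a1 = 0.0, a2 = 0.0;
    c1[0] = 0.0; c2[0] = 0.0;
    for (int i = 0; i < nP; ++i) {
      const double v = col[i];
      a1 += v; a2 += v * v;
      c1[i + 1] = a1; c2[i + 1] = a2;
    }
  }

  // vertical chords: for output column j, window rows are image columns
  // j..j+2m; chord k contributes a column-run of height 2*hw+1 centered at
  // the output row offset. Accumulate per chord, sweeping rows contiguously.
  NumericMatrix s1(nr, nc), s2(nr, nc);
  double* o1 = REAL(s1);
  double* o2 = REAL(s2);
  for (int j = 0; j < nc; ++j) {
    double* out1 = o1 + (size_t)j * nr;
    double* out2 = o2 + (size_t)j * nr;
    std::fill(out1, out1 + nr, 0.0);
    std::fill(out2, out2 + nr, 0.0);
    for (int k = 0; k < K; ++k) {
      // chord at horizontal offset (k - m) spans vertical half-width hw
      const int w = hw[k];
      const double* c1 = &C1[(size_t)(j + k) * H];
      const double* c2 = &C2[(size_t)(j + k) * H];
      const int lo = m - w, hi = m + w + 1;
      for (int i = 0; i < nr; ++i) {
        out1[i] += c1[i + hi] - c1[i + lo];
        out2[i] += c2[i + hi] - c2[i + lo];
      }
    }
  }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}
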