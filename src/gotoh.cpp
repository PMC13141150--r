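// Three-state affine-gap Needleman-Wunsch-Gotoh over a fixed score matrix.
// Gap-cost convention: a length-L gap costs gap_open + (L-1)*gap_extend,
// terminal gaps charged like internal ones (true global alignment).
// States: 0 = M (match), 1 = Ix (gap in right trace; consumes left axis i),
// 2 = Iy (gap in left trace; consumes right axis j).  Ties broken with the
// fixed preference M > Ix > Iy, both in the fill and in the traceback, so
// traces (not just scores) are reproducible.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static inline int argmax3(double m, double ix, double iy) {
  // preference order M > Ix > Iy at equal scores
  if (m >= ix && m >= iy) return 0;
  if (ix >= iy) return 1;
  return 2;
}

// [[Rcpp::export(name = ".gotoh_core")]]
List gotoh_core(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();

  // Degenerate axes: a single gap spanning the non-empty axis.
  if (n == 0 || m == 0) {
    int L = n > 0 ? n : m;
    double sc = (L == 0) ? 0.0 : gap_open + (L - 1) * gap_extend;
    IntegerVector lt(L), rt(L);
    for (int k = 0; k < L; ++k) {
      lt[k] = (n > 0) ? k + 1 : NA_INTEGER;
      rt[k] = (m > 0) ? k + 1 : NA_INTEGER;
    }
    return List::create(_["score"] = sc, _["left"] = lt, _["right"] = rt,
                        _["cells"] = (double)(n + 1) * (m + 1));
  }

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  // predecessor state for each cell of each state matrix
  std::vector<signed char> pM((n + 1) * W, -1), pIx((n + 1) * W, -1),
      pIy((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = (i == 1) ? gap_open : Ix[(i - 1) * W] + gap_extend;
    pIx[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = (j == 1) ? gap_open : Iy[j - 1] + gap_extend;
    pIy[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: diagonal move from any state
      {
        int s = argmax3(M[d], Ix[d], Iy[d]);
        double best = (s == 0) ? M[d] : (s == 1) ? Ix[d] : Iy[d];
        M[c] = S(i - 1, j - 1) + best;
        pM[c] = (signed char)s;
      }
      // Ix: consume left axis; entering a new gap run costs gap_open,
      // extending an Ix run costs gap_extend
      {
        double fm = M[u] + gap_open, fx = Ix[u] + gap_extend,
               fy = Iy[u] + gap_open;
        int s = argmax3(fm, fx, fy);
        Ix[c] = (s == 0) ? fm : (s == 1) ? fx : fy;
        pIx[c] = (signed char)s;
      }
      // Iy: consume right axis
      {
        double fm = M[l] + gap_open, fx = Ix[l] + gap_open,
               fy = Iy[l] + gap_extend;
        int s = argmax3(fm, fx, fy);
        Iy[c] = (s == 0) ? fm : (s == 1) ? fx : fy;
        pIy[c] = (signed char)s;
      }
    }
  }

  const int e = n * W + m;
  int state = argmax3(M[e], Ix[e], Iy[e]);
  double score = (state == 0) ? M[e] : (state == 1) ? Ix[e] : Iy[e];

  std::vector<int> lt, rt;
  lt.reserve(n + m);
  rt.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      lt.push_back(i);
      rt.push_back(j);
      state = pM[c];
      --i; --j;
    } else if (state == 1) {
      lt.push_back(i);
      rt.push_back(NA_INTEGER);
      state = pIx[c];
      --i;
    } else {
      lt.push_back(NA_INTEGER);
      rt.push_back(j);
      state = pIy[c];
      --j;
    }
  }
  std::reverse(lt.begin(), lt.end());
  std::reverse(rt.begin(), rt.end());
  return List::create(_["score"] = score, _["left"] = wrap(lt),
                      _["right"] = wrap(rt),
                      _["cells"] = (double)(n + 1) * (m + 1));
}
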