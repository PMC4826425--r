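#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Compiled hot path of the stochastic block-coordinate Frank-Wolfe solver
// for the eigenvector program f(x) = 0.5 * ||Bhat x - x||^2 on the unit
// simplex. The adjacencies arrive as CSC index arrays (symmetric, so each
// column is a neighbor list); pair index is query-major, 0-based here:
// t = u * Nb + v.
//
// Per-iteration work is proportional to the sampled block and its product
// neighborhood, not to N: the residual p = E x is updated only on the
// sparse support of E(s - x), and the scalars p'p, x'x and sbar'p needed by
// the step size and stopping rule are tracked incrementally (with periodic
// full recomputation to cancel floating-point drift). Nothing of quadratic
// size is ever allocated.

namespace {

struct Adj {
  const int *ptr;   // length n + 1
  const int *idx;   // neighbor indices
  int n;
};

// z = Bhat * y (full apply, used once for the initial residual).
void applyBhatFull(const Adj &Aa, const Adj &Ab, const double *d,
                   const double *sbar, double alpha, int Nb,
                   const double *y, double *z, int N) {
  std::vector<double> yd(N);
  double ysum = 0.0;
  for (int t = 0; t < N; ++t) {
    yd[t] = d[t] > 0 ? y[t] / d[t] : 0.0;
    ysum += y[t];
  }
  std::fill(z, z + N, 0.0);
  for (int u = 0; u < Aa.n; ++u) {
    for (int v = 0; v < Ab.n; ++v) {
      double w = yd[u * Nb + v];
      if (w == 0.0) continue;
      for (int a = Aa.ptr[u]; a < Aa.ptr[u + 1]; ++a) {
        double *zrow = z + (size_t)Aa.idx[a] * Nb;
        for (int b = Ab.ptr[v]; b < Ab.ptr[v + 1]; ++b)
          zrow[Ab.idx[b]] += w;
      }
    }
  }
  if (alpha < 1.0) {
    for (int t = 0; t < N; ++t)
      z[t] = alpha * z[t] + (1.0 - alpha) * ysum * sbar[t];
  }
}

inline double dot(const double *a, const double *b, int N) {
  double s = 0.0;
  for (int t = 0; t < N; ++t) s += a[t] * b[t];
  return s;
}

} // namespace

// [[Rcpp::export(name = ".sbcfwKernel")]]
List sbcfwKernel(IntegerVector aaPtr, IntegerVector aaIdx,
                 IntegerVector abPtr, IntegerVector abIdx,
                 int Na, int Nb, NumericVector dVec, NumericVector sbarVec,
                 double alpha, NumericVector x0, int nBlocks,
                 std::string mode, double xi, int maxIter,
                 bool wantIterLog, IntegerVector perm0) {
  const int N = Na * Nb;
  Adj Aa{aaPtr.begin(), aaIdx.begin(), Na};
  Adj Ab{abPtr.begin(), abIdx.begin(), Nb};
  const double *d = dVec.begin();
  const double *sbar = (alpha < 1.0) ? sbarVec.begin() : nullptr;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> p(N);
  applyBhatFull(Aa, Ab, d, sbar, alpha, Nb, x.data(), p.data(), N);
  for (int t = 0; t < N; ++t) p[t] -= x[t];

  // tracked scalars (refreshed periodically against drift)
  double pp = dot(p.data(), p.data(), N);
  double xx = dot(x.data(), x.data(), N);
  double sp = (alpha < 1.0) ? dot(sbar, p.data(), N) : 0.0;
  const int refreshEvery = 16384;

  const bool fixed = (mode == "fixed_partition");
  const int base = N / nBlocks, extra = N % nBlocks;
  // the permutation buffer continues the scheme's state: the R side may
  // already have consumed draws (block-sparse initialization)
  std::vector<int> perm;
  if (!fixed && nBlocks > 1) {
    perm.resize(N);
    if (perm0.size() == N) {
      for (int t = 0; t < N; ++t) perm[t] = perm0[t] - 1;
    } else {
      for (int t = 0; t < N; ++t) perm[t] = t;
    }
  }
  std::vector<int> block;
  block.reserve(nBlocks == 1 ? N : base + 1);

  // sparse accumulator for c = Bhat(delta) - delta (delta sums to zero,
  // so the rank-1 similarity term drops out of c)
  std::vector<double> acc(N, 0.0);
  std::vector<char> inAcc(N, 0);
  std::vector<int> touched;
  touched.reserve(256);

  std::vector<double> trace;
  trace.reserve(std::min(maxIter + 1, 1 << 22));
  double f = 0.5 * pp;
  trace.push_back(f);
  std::vector<double> gammaLog;
  std::vector<int> stallLog, sizeLog;

  int k = 0, stalls = 0;
  bool conv = false;
  double lastGamma = 0.0;

  while (k < maxIter) {
    if (std::sqrt(std::max(pp, 0.0)) <= xi * std::sqrt(xx)) {
      conv = true; break;
    }

    // ---- sample block
    block.clear();
    if (nBlocks == 1) {
      for (int t = 0; t < N; ++t) block.push_back(t);
    } else if (fixed) {
      int bi = (int)(unif_rand() * nBlocks);
      if (bi >= nBlocks) bi = nBlocks - 1;
      int start = bi * base + std::min(bi, extra);
      int len = base + (bi < extra ? 1 : 0);
      for (int t = 0; t < len; ++t) block.push_back(start + t);
    } else {
      int b = (N + nBlocks - 1) / nBlocks;  // ceiling(N / n)
      for (int i = 0; i < b; ++i) {
        int r = i + (int)(unif_rand() * (N - i));
        if (r >= N) r = N - 1;
        std::swap(perm[i], perm[r]);
      }
      block.assign(perm.begin(), perm.begin() + b);
      std::sort(block.begin(), block.end());
    }
    const int bsz = (int)block.size();

    // ---- block partial gradient [Bhat' p - p], argmin and block mass
    double gmin = 0.0;
    int jmin = -1;
    double L = 0.0;
    for (int bi = 0; bi < bsz; ++bi) {
      int t = block[bi];
      int u = t / Nb, v = t % Nb;
      double accg = 0.0;
      if (d[t] > 0) {
        for (int a = Aa.ptr[u]; a < Aa.ptr[u + 1]; ++a) {
          const double *prow = p.data() + (size_t)Aa.idx[a] * Nb;
          for (int bb = Ab.ptr[v]; bb < Ab.ptr[v + 1]; ++bb)
            accg += prow[Ab.idx[bb]];
        }
        accg /= d[t];
      }
      double g = (alpha < 1.0 ? alpha * accg + (1.0 - alpha) * sp : accg)
                 - p[t];
      if (jmin < 0 || g < gmin) { gmin = g; jmin = t; }
      L += x[t];
    }

    // ---- c = E (s - x) on its sparse support
    touched.clear();
    bool moved = false;
    for (int bi = 0; bi < bsz; ++bi) {
      int t = block[bi];
      double del = (t == jmin ? L - x[t] : -x[t]);
      if (del == 0.0) continue;
      moved = true;
      if (!inAcc[t]) { inAcc[t] = 1; touched.push_back(t); }
      acc[t] -= del;
      if (d[t] > 0) {
        int u = t / Nb, v = t % Nb;
        double w = alpha * del / d[t];
        for (int a = Aa.ptr[u]; a < Aa.ptr[u + 1]; ++a) {
          size_t row = (size_t)Aa.idx[a] * Nb;
          for (int bb = Ab.ptr[v]; bb < Ab.ptr[v + 1]; ++bb) {
            int tt = (int)(row + Ab.idx[bb]);
            if (!inAcc[tt]) { inAcc[tt] = 1; touched.push_back(tt); }
            acc[tt] += w;
          }
        }
      }
    }

    // ---- exact line search: residual along the segment is p + gamma c,
    //      so gamma* = -p'c / c'c clipped to [0, 1]
    double pc = 0.0, cc = 0.0, sc = 0.0;
    for (size_t i = 0; i < touched.size(); ++i) {
      int t = touched[i];
      pc += p[t] * acc[t];
      cc += acc[t] * acc[t];
      if (alpha < 1.0) sc += sbar[t] * acc[t];
    }
    double gamma = 0.0;
    if (moved && cc >= 1e-15) {
      double ghat = -pc / cc;
      gamma = ghat <= 0 ? 0.0 : std::min(1.0, ghat);
    }
    bool stall = (!moved) || gamma == 0.0;
    if (stall) ++stalls;

    // ---- sparse updates of x, p and the tracked scalars
    if (gamma > 0.0) {
      for (int bi = 0; bi < bsz; ++bi) {
        int t = block[bi];
        double del = (t == jmin ? L - x[t] : -x[t]);
        if (del == 0.0) continue;
        xx += 2.0 * gamma * del * x[t] + gamma * gamma * del * del;
        x[t] += gamma * del;
      }
      for (size_t i = 0; i < touched.size(); ++i) {
        int t = touched[i];
        p[t] += gamma * acc[t];
      }
      pp += 2.0 * gamma * pc + gamma * gamma * cc;
      if (alpha < 1.0) sp += gamma * sc;
    }
    for (size_t i = 0; i < touched.size(); ++i) {
      acc[touched[i]] = 0.0;
      inAcc[touched[i]] = 0;
    }

    ++k;
    if (k % refreshEvery == 0) {
      pp = dot(p.data(), p.data(), N);
      xx = dot(x.data(), x.data(), N);
      if (alpha < 1.0) sp = dot(sbar, p.data(), N);
    }
    double fNew = 0.5 * std::max(pp, 0.0);
    if (fNew > f + 1e-9)
      stop("objective increased from %g to %g at iteration %d",
           f, fNew, k);
    f = fNew;
    trace.push_back(f);
    lastGamma = gamma;
    if (wantIterLog) {
      gammaLog.push_back(gamma);
      stallLog.push_back(stall ? 1 : 0);
      sizeLog.push_back(bsz);
    }
    if (k % 8192 == 0) checkUserInterrupt();
  }
  if (!conv && k >= maxIter) {
    pp = dot(p.data(), p.data(), N);
    xx = dot(x.data(), x.data(), N);
    if (std::sqrt(std::max(pp, 0.0)) <= xi * std::sqrt(xx)) conv = true;
  }

  List out = List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["k"] = k,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["converged"] = conv,
      _["stalls"] = stalls,
      _["lastGamma"] = lastGamma);
  if (wantIterLog) {
    out["gammaLog"] = NumericVector(gammaLog.begin(), gammaLog.end());
    out["stallLog"] = IntegerVector(stallLog.begin(), stallLog.end());
    out["sizeLog"] = IntegerVector(sizeLog.begin(), sizeLog.end());
  }
  return out;
}
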