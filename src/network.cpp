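#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pairwise extractor forward/backward for one dataset. Mirrors the layout
// used by the R-level weight containers:
//  - conv weights W_b: (F x C*kernel), column index o*C + c (offset-major);
//  - pair dense input: flattened last conv block (filter fastest) + scaled
//    pair distance;
//  - head weights: pair-major blocks of pair_dense entries, canonical
//    lexicographic pair order.
// Gradients flow into conv/dense parameters only through "selected" pairs
// (the k_extract gate); the head always accumulates over all pairs.

struct BlockCache {
  std::vector<double> X;     // patches (C*k x Lc)
  std::vector<char> mask;    // relu mask (F x Lc)
  int Cin, Lc;
};

// [[Rcpp::export(name = ".net_pass_cpp")]]
List net_pass_cpp(NumericMatrix counts, IntegerMatrix pairs,
                  NumericVector dists, List conv_W, List conv_b,
                  NumericMatrix dense_W, NumericVector dense_b,
                  NumericVector head_w, double head_b,
                  IntegerMatrix layout, int kernel, bool phased,
                  double dist_scale, bool want_grad, double y_norm,
                  double loss_scale, LogicalVector selected) {
  const int P = pairs.nrow();
  const int n_blocks = layout.nrow();
  const int m = counts.ncol();
  const int C0 = phased ? 4 : 2;
  const int pair_dense = dense_W.nrow();
  const int d_in = dense_W.ncol();

  std::vector<NumericMatrix> Ws(n_blocks);
  std::vector<NumericVector> bs(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    Ws[b] = as<NumericMatrix>(conv_W[b]);
    bs[b] = as<NumericVector>(conv_b[b]);
  }

  // caches per pair per block
  std::vector<std::vector<BlockCache>> caches(P);
  std::vector<std::vector<double>> Din_all(P), Hpre_all(P);
  NumericVector hvec(P * pair_dense);

  std::vector<double> A, Z, pooled;
  for (int p = 0; p < P; ++p) {
    caches[p].resize(n_blocks);
    // initial slab
    int C = C0, L = m;
    A.assign(static_cast<size_t>(C) * L, 0.0);
    if (phased) {
      int r1 = 2 * (pairs(p, 0) - 1), r3 = 2 * (pairs(p, 1) - 1);
      for (int t = 0; t < L; ++t) {
        A[t * 4 + 0] = counts(r1, t);
        A[t * 4 + 1] = counts(r1 + 1, t);
        A[t * 4 + 2] = counts(r3, t);
        A[t * 4 + 3] = counts(r3 + 1, t);
      }
    } else {
      int r1 = pairs(p, 0) - 1, r2 = pairs(p, 1) - 1;
      for (int t = 0; t < L; ++t) {
        A[t * 2 + 0] = counts(r1, t);
        A[t * 2 + 1] = counts(r2, t);
      }
    }
    for (int b = 0; b < n_blocks; ++b) {
      const int Lc = layout(b, 1), pw = layout(b, 2), Lo = layout(b, 3);
      const int F = Ws[b].nrow();
      BlockCache &bc = caches[p][b];
      bc.Cin = C;
      bc.Lc = Lc;
      // patches: column t holds A[, t..t+kernel-1] stacked offset-major
      bc.X.assign(static_cast<size_t>(C) * kernel * Lc, 0.0);
      for (int t = 0; t < Lc; ++t) {
        for (int o = 0; o < kernel; ++o) {
          for (int c = 0; c < C; ++c) {
            bc.X[static_cast<size_t>(t) * C * kernel + o * C + c] =
                A[static_cast<size_t>(t + o) * C + c];
          }
        }
      }
      // conv + relu
      Z.assign(static_cast<size_t>(F) * Lc, 0.0);
      bc.mask.assign(static_cast<size_t>(F) * Lc, 0);
      const double *Wb = &Ws[b](0, 0); // (F x C*kernel), column-major
      const int CK = C * kernel;
      for (int t = 0; t < Lc; ++t) {
        const double *xt = &bc.X[static_cast<size_t>(t) * CK];
        for (int f = 0; f < F; ++f) {
          double acc = bs[b][f];
          for (int q = 0; q < CK; ++q) acc += Wb[f + q * F] * xt[q];
          if (acc > 0) {
            Z[static_cast<size_t>(t) * F + f] = acc;
            bc.mask[static_cast<size_t>(t) * F + f] = 1;
          }
        }
      }
      // average pooling (truncates the tail beyond pw*Lo)
      pooled.assign(static_cast<size_t>(F) * Lo, 0.0);
      for (int t = 0; t < Lo; ++t) {
        for (int u = 0; u < pw; ++u) {
          const double *zt = &Z[static_cast<size_t>(t * pw + u) * F];
          double *pt = &pooled[static_cast<size_t>(t) * F];
          for (int f = 0; f < F; ++f) pt[f] += zt[f];
        }
        double *pt = &pooled[static_cast<size_t>(t) * F];
        for (int f = 0; f < F; ++f) pt[f] /= pw;
      }
      A = pooled;
      C = F;
      L = Lo;
    }
    // dense layer: input = flatten(A) + scaled distance
    std::vector<double> &din = Din_all[p];
    din.assign(d_in, 0.0);
    for (size_t q = 0; q < A.size(); ++q) din[q] = A[q];
    din[d_in - 1] = dists[p] / dist_scale;
    std::vector<double> &hpre = Hpre_all[p];
    hpre.assign(pair_dense, 0.0);
    for (int u = 0; u < pair_dense; ++u) {
      double acc = dense_b[u];
      for (int q = 0; q < d_in; ++q) acc += dense_W(u, q) * din[q];
      hpre[u] = acc;
      hvec[p * pair_dense + u] = acc > 0 ? acc : 0.0;
    }
  }

  double yhat = head_b;
  for (int q = 0; q < P * pair_dense; ++q) yhat += head_w[q] * hvec[q];

  if (!want_grad) {
    return List::create(_["yhat_norm"] = yhat, _["H"] = hvec);
  }

  const double err = yhat - y_norm;
  const double dy = 2.0 * err * loss_scale;

  NumericVector g_head_w(P * pair_dense);
  double g_head_b = dy;
  for (int q = 0; q < P * pair_dense; ++q) g_head_w[q] = dy * hvec[q];

  NumericMatrix g_dense_W(pair_dense, d_in);
  NumericVector g_dense_b(pair_dense);
  List g_conv_W(n_blocks), g_conv_b(n_blocks);
  std::vector<NumericMatrix> gW(n_blocks);
  std::vector<NumericVector> gb(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    gW[b] = NumericMatrix(Ws[b].nrow(), Ws[b].ncol());
    gb[b] = NumericVector(bs[b].size());
  }

  std::vector<double> dHpre(pair_dense), dDin, dA, dZ, dX;
  for (int p = 0; p < P; ++p) {
    if (!selected[p]) continue;
    // through the pair dense layer
    for (int u = 0; u < pair_dense; ++u) {
      double g = head_w[p * pair_dense + u] * dy;
      dHpre[u] = (Hpre_all[p][u] > 0) ? g : 0.0;
    }
    dDin.assign(d_in, 0.0);
    for (int u = 0; u < pair_dense; ++u) {
      const double g = dHpre[u];
      if (g == 0.0) continue;
      g_dense_b[u] += g;
      const std::vector<double> &din = Din_all[p];
      for (int q = 0; q < d_in; ++q) {
        g_dense_W(u, q) += g * din[q];
        dDin[q] += dense_W(u, q) * g;
      }
    }
    // back through conv blocks
    int L_last = layout(n_blocks - 1, 3);
    int F_last = Ws[n_blocks - 1].nrow();
    dA.assign(dDin.begin(), dDin.begin() + static_cast<size_t>(F_last) * L_last);
    for (int b = n_blocks - 1; b >= 0; --b) {
      const int Lc = layout(b, 1), pw = layout(b, 2), Lo = layout(b, 3);
      const int F = Ws[b].nrow();
      const BlockCache &bc = caches[p][b];
      const int CK = bc.Cin * kernel;
      // unpool + relu mask
      dZ.assign(static_cast<size_t>(F) * Lc, 0.0);
      for (int t = 0; t < Lo; ++t) {
        const double *da = &dA[static_cast<size_t>(t) * F];
        for (int u = 0; u < pw; ++u) {
          double *dz = &dZ[static_cast<size_t>(t * pw + u) * F];
          const char *mk = &bc.mask[static_cast<size_t>(t * pw + u) * F];
          for (int f = 0; f < F; ++f) {
            if (mk[f]) dz[f] = da[f] / pw;
          }
        }
      }
      // parameter grads and input grad
      const double *Wb = &Ws[b](0, 0);
      double *gWb = &gW[b](0, 0);
      if (b > 0) {
        dX.assign(static_cast<size_t>(CK) * Lc, 0.0);
      }
      for (int t = 0; t < Lc; ++t) {
        const double *dz = &dZ[static_cast<size_t>(t) * F];
        const double *xt = &bc.X[static_cast<size_t>(t) * CK];
        double *dxt = b > 0 ? &dX[static_cast<size_t>(t) * CK] : nullptr;
        for (int f = 0; f < F; ++f) {
          const double g = dz[f];
          if (g == 0.0) continue;
          gb[b][f] += g;
          for (int q = 0; q < CK; ++q) {
            gWb[f + q * F] += g * xt[q];
            if (dxt) dxt[q] += Wb[f + q * F] * g;
          }
        }
      }
      if (b > 0) {
        const int C = bc.Cin, L_in = layout(b, 0);
        dA.assign(static_cast<size_t>(C) * L_in, 0.0);
        for (int t = 0; t < Lc; ++t) {
          for (int o = 0; o < kernel; ++o) {
            for (int c = 0; c < C; ++c) {
              dA[static_cast<size_t>(t + o) * C + c] +=
                  dX[static_cast<size_t>(t) * CK + o * C + c];
            }
          }
        }
      }
    }
  }
  for (int b = 0; b < n_blocks; ++b) {
    g_conv_W[b] = gW[b];
    g_conv_b[b] = gb[b];
  }
  return List::create(
      _["yhat_norm"] = yhat, _["loss"] = err * err * loss_scale,
      _["g_head_w"] = g_head_w, _["g_head_b"] = g_head_b,
      _["g_dense_W"] = g_dense_W, _["g_dense_b"] = g_dense_b,
      _["g_conv_W"] = g_conv_W, _["g_conv_b"] = g_conv_b);
}
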