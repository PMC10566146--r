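#include <Rcpp.h>
using namespace Rcpp;

// One generation of the continuous-space model: density-regulated Poisson
// fecundity, Gaussian mate choice truncated at 3*sigma_f, Gaussian
// dispersal with redraw (or reflection) at the habitat boundary. Uses R's
// RNG so runs are reproducible under set.seed().
//
// Returns NULL when no offspring are produced (extinction; handled in R).
// [[Rcpp::export(name = ".spatial_generation")]]
SEXP spatial_generation(NumericVector x, NumericVector y, double sf,
                        double K, double W, bool redraw) {
  const int n = x.size();
  const double inv2s2 = 1.0 / (2.0 * sf * sf);
  const double r2max = 9.0 * sf * sf;
  const double dens_norm = 1.0 / (2.0 * M_PI * sf * sf);

  // pairwise squared distances (symmetric, computed once)
  std::vector<double> d2(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i) {
    d2[static_cast<size_t>(i) * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double v = dx * dx + dy * dy;
      d2[static_cast<size_t>(i) * n + j] = v;
      d2[static_cast<size_t>(j) * n + i] = v;
    }
  }

  // local density and fecundity; the kernel is renormalised by the
  // Gaussian mass actually inside the habitat (separable in x and y), so
  // edge individuals do not systematically under-count their neighbours
  IntegerVector n_off(n);
  int m_total = 0;
  std::vector<bool> has_mate(n, false);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    bool mate = false;
    const double *row = &d2[static_cast<size_t>(i) * n];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      s += std::exp(-row[j] * inv2s2);
      if (row[j] <= r2max) mate = true;
    }
    has_mate[i] = mate;
    double mass_x = R::pnorm(W - x[i], 0.0, sf, 1, 0) -
                    R::pnorm(-x[i], 0.0, sf, 1, 0);
    double mass_y = R::pnorm(W - y[i], 0.0, sf, 1, 0) -
                    R::pnorm(-y[i], 0.0, sf, 1, 0);
    double mass = std::max(mass_x * mass_y, 1e-12);
    double lambda = 2.0 / (1.0 + (s * dens_norm / mass) / K);
    int k = mate ? static_cast<int>(R::rpois(lambda)) : 0;
    n_off[i] = k;
    m_total += k;
  }
  if (m_total == 0) return R_NilValue;

  NumericVector nx(m_total), ny(m_total), ddx(m_total), ddy(m_total),
      edge(m_total);
  IntegerVector mothers(m_total), fathers(m_total);
  std::vector<double> cumw(n);

  int o = 0;
  for (int i = 0; i < n; ++i) {
    if (n_off[i] == 0) continue;
    // cumulative mate weights for this mother (truncated Gaussian kernel)
    const double *row = &d2[static_cast<size_t>(i) * n];
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j != i && row[j] <= r2max) tot += std::exp(-row[j] * inv2s2);
      cumw[j] = tot;
    }
    for (int k = 0; k < n_off[i]; ++k, ++o) {
      double u = unif_rand() * tot;
      int f = static_cast<int>(
          std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      // guard: land on a valid candidate (u == cumw boundary ties)
      while (f < n - 1 && (f == i || row[f] > r2max)) ++f;
      mothers[o] = i + 1;
      fathers[o] = f + 1;
      double px, py, dx, dy;
      int tries = 0;
      do {
        dx = norm_rand() * sf;
        dy = norm_rand() * sf;
        px = x[i] + dx;
        py = y[i] + dy;
        ++tries;
      } while (redraw && tries < 100 &&
               (px < 0.0 || px > W || py < 0.0 || py > W));
      // reflect whatever remains out of bounds
      px = std::fabs(px);
      px -= 2.0 * W * std::floor(px / (2.0 * W));
      if (px > W) px = 2.0 * W - px;
      py = std::fabs(py);
      py -= 2.0 * W * std::floor(py / (2.0 * W));
      if (py > W) py = 2.0 * W - py;
      nx[o] = px;
      ny[o] = py;
      ddx[o] = px - x[i];
      ddy[o] = py - y[i];
      double e = std::min(std::min(x[i], W - x[i]), std::min(y[i], W - y[i]));
      edge[o] = e;
    }
  }

  return List::create(_["x"] = nx, _["y"] = ny, _["mothers"] = mothers,
                      _["fathers"] = fathers, _["dx"] = ddx, _["dy"] = ddy,
                      _["edge_dist"] = edge);
}

// One backward gene-dropping step for few lineages: every column (locus)
// maps its distinct ancestor haplotypes through an independent Mendelian
// coin. `A` holds 1-based haplotype ids of generation g; `p_ind` gives,
// for each generation-g haplotype, the 1-based parent individual it was
// inherited from.
// [[Rcpp::export(name = ".step_back_sparse")]]
IntegerMatrix step_back_sparse(IntegerMatrix A, IntegerVector p_ind) {
  const int nr = A.nrow(), nc = A.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> u(nr), newval(nr);
  for (int l = 0; l < nc; ++l) {
    int nu = 0;
    for (int r = 0; r < nr; ++r) {
      int v = A(r, l);
      int k = -1;
      for (int q = 0; q < nu; ++q) {
        if (u[q] == v) { k = q; break; }
      }
      if (k < 0) {
        u[nu] = v;
        int coin = (unif_rand() < 0.5) ? 0 : 1;
        newval[nu] = 2 * p_ind[v - 1] - coin;
        k = nu++;
      }
      out(r, l) = newval[k];
    }
  }
  return out;
}
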