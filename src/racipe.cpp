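#include <Rcpp.h>
using namespace Rcpp;

// integer power; Hill coefficients are integers in 1..6
static inline double ipow(double x, int n) {
  double r = 1.0;
  while (n > 0) {
    if (n & 1) r *= x;
    x *= x;
    n >>= 1;
  }
  return r;
}

// shifted Hill regulation factor: lambda + (1 - lambda) / (1 + (x/x0)^n)
static inline double hs(double x, double x0, int n, double lambda) {
  return lambda + (1.0 - lambda) / (1.0 + ipow(x / x0, n));
}

// Fixed-step Euler integration of the ensemble.
//
// dY/dt = G_Y / (prod of lambda+ over excitatory in-edges) *
//         prod over in-edges Hs(X, X0, n, lambda)  -  k_Y * Y
//
// esrc/etgt: 0-based gene indices per edge; esign: +1 excitatory, -1 inhibitory.
// G, K: n_models x n_genes.  lam, x0: n_models x n_edges.  hn: Hill coefficients.
// init: n_models x n_genes initial conditions.
// Convergence: max_g |dY_g/dt| / max(Y_g, eps) < tol, checked every check_every
// steps (and at t_max); integration stops early once converged.
// [[Rcpp::export]]
List racipe_integrate(IntegerVector esrc, IntegerVector etgt, IntegerVector esign,
                      NumericMatrix G, NumericMatrix K,
                      NumericMatrix lam, NumericMatrix x0, IntegerMatrix hn,
                      NumericMatrix init,
                      double dt, double t_max, double tol, int check_every) {
  const int n_models = G.nrow(), n_genes = G.ncol(), n_edges = esrc.size();
  const int n_steps = (int)std::ceil(t_max / dt);
  const double eps = 1e-12;

  NumericMatrix steady(n_models, n_genes);
  LogicalVector converged(n_models);

  std::vector<double> y(n_genes), dy(n_genes), base(n_genes), k_loc(n_genes);
  std::vector<double> e_lam(n_edges), e_x0inv(n_edges);
  std::vector<int> e_n(n_edges), e_src(n_edges), e_tgt(n_edges);
  for (int e = 0; e < n_edges; ++e) { e_src[e] = esrc[e]; e_tgt[e] = etgt[e]; }

  for (int m = 0; m < n_models; ++m) {
    // contiguous per-model copies (the matrices are model-major strided)
    for (int g = 0; g < n_genes; ++g) {
      y[g] = init(m, g);
      base[g] = G(m, g);
      k_loc[g] = K(m, g);
    }
    for (int e = 0; e < n_edges; ++e) {
      e_lam[e] = lam(m, e);
      e_x0inv[e] = 1.0 / x0(m, e);
      e_n[e] = hn(m, e);
      // fold the per-gene scaling (product of lambda+ over excitatory
      // in-edges) into the base production rate
      if (esign[e] > 0) base[e_tgt[e]] /= e_lam[e];
    }

    bool conv = false;
    for (int s = 0; s < n_steps; ++s) {
      for (int g = 0; g < n_genes; ++g) dy[g] = base[g];
      for (int e = 0; e < n_edges; ++e) {
        const double lm = e_lam[e];
        dy[e_tgt[e]] *= lm + (1.0 - lm) /
          (1.0 + ipow(y[e_src[e]] * e_x0inv[e], e_n[e]));
      }
      for (int g = 0; g < n_genes; ++g) dy[g] -= k_loc[g] * y[g];

      if (s % check_every == 0 || s == n_steps - 1) {
        double worst = 0.0;
        for (int g = 0; g < n_genes; ++g) {
          double rel = std::fabs(dy[g]) / std::max(y[g], eps);
          if (rel > worst) worst = rel;
        }
        if (worst < tol) { conv = true; break; }
      }
      for (int g = 0; g < n_genes; ++g) y[g] += dt * dy[g];
    }
    for (int g = 0; g < n_genes; ++g) steady(m, g) = y[g];
    converged[m] = conv;
  }
  return List::create(_["steady"] = steady, _["converged"] = converged);
}

// Evaluate dY/dt at given states (post-hoc residual check, independent of the
// integrator loop above in the sense that it is a single direct evaluation).
// [[Rcpp::export]]
NumericMatrix racipe_dydt(IntegerVector esrc, IntegerVector etgt, IntegerVector esign,
                          NumericMatrix G, NumericMatrix K,
                          NumericMatrix lam, NumericMatrix x0, IntegerMatrix hn,
                          NumericMatrix states) {
  const int n_models = G.nrow(), n_genes = G.ncol(), n_edges = esrc.size();
  NumericMatrix out(n_models, n_genes);
  std::vector<double> scale(n_genes);
  for (int m = 0; m < n_models; ++m) {
    for (int g = 0; g < n_genes; ++g) scale[g] = 1.0;
    for (int e = 0; e < n_edges; ++e)
      if (esign[e] > 0) scale[etgt[e]] *= lam(m, e);
    for (int g = 0; g < n_genes; ++g) out(m, g) = G(m, g) / scale[g];
    for (int e = 0; e < n_edges; ++e)
      out(m, etgt[e]) *= hs(states(m, esrc[e]), x0(m, e), hn(m, e), lam(m, e));
    for (int g = 0; g < n_genes; ++g) out(m, g) -= K(m, g) * states(m, g);
  }
  return out;
}

// Distance-to-nearest-sample state assignment with a gene-shuffle null.
//
// models:  n_models x n_genes (standardized simulated profiles)
// samples: n_samples x n_genes (standardized activity profiles)
// state:   0/1 per sample (two experimental states)
// For each model: observed d_s = min squared Euclidean distance to any sample of
// state s; then n_null gene-label permutations of the model profile (one common
// permutation set across both states), each yielding its own min distance per
// state; p_s = fraction of null distances <= d_s.  Uses R's RNG (reproducible
// under set.seed()).
// [[Rcpp::export]]
List assign_null_pvals(NumericMatrix models, NumericMatrix samples,
                       IntegerVector state, int n_null) {
  const int n_models = models.nrow(), n_genes = models.ncol();
  const int n_samples = samples.nrow();
  NumericMatrix pvals(n_models, 2), dmin(n_models, 2);

  std::vector<double> prof(n_genes);
  std::vector<int> perm(n_genes);

  for (int m = 0; m < n_models; ++m) {
    // observed min squared distance per state
    double d0[2] = {R_PosInf, R_PosInf};
    for (int s = 0; s < n_samples; ++s) {
      double d = 0.0;
      for (int g = 0; g < n_genes; ++g) {
        double diff = models(m, g) - samples(s, g);
        d += diff * diff;
      }
      int st = state[s];
      if (d < d0[st]) d0[st] = d;
    }
    int cnt[2] = {0, 0};
    for (int r = 0; r < n_null; ++r) {
      // Fisher-Yates permutation of the model's gene labels
      for (int g = 0; g < n_genes; ++g) perm[g] = g;
      for (int g = n_genes - 1; g > 0; --g) {
        int j = (int)(unif_rand() * (g + 1));
        if (j > g) j = g;
        std::swap(perm[g], perm[j]);
      }
      for (int g = 0; g < n_genes; ++g) prof[g] = models(m, perm[g]);
      double dn[2] = {R_PosInf, R_PosInf};
      for (int s = 0; s < n_samples; ++s) {
        double d = 0.0;
        for (int g = 0; g < n_genes; ++g) {
          double diff = prof[g] - samples(s, g);
          d += diff * diff;
        }
        int st = state[s];
        if (d < dn[st]) dn[st] = d;
      }
      if (dn[0] <= d0[0]) ++cnt[0];
      if (dn[1] <= d0[1]) ++cnt[1];
    }
    for (int st = 0; st < 2; ++st) {
      pvals(m, st) = (double)cnt[st] / n_null;
      dmin(m, st) = std::sqrt(d0[st]);
    }
  }
  return List::create(_["pvals"] = pvals, _["dmin"] = dmin);
}
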