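// Likelihood, gradient and diagonal-Hessian kernels for symbolic-network
// covariate models of the discrete-time multistate likelihood.
//
// Parameter layout per mapping (must match R/snn.R flattenSnn):
//   W1 (5 x np, column-major), b1 (5), W2 (5 x 3, column-major), b2 (5),
//   W3 (3), b3 (1)  -> length 5*np + 29.
//
// The prepared data (R: prepare_likelihood_data + map offsets) arrive as a
// list of per-from-state "designs": a covariate matrix with one row per
// (observation, month) pair, CSR offsets per observation, the observation
// kind/timing, and the offset of each destination mapping's parameters in
// the global parameter vector.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double POWER_EPS = 1e-8;
static const double LAM_LO = 1e-300;
static const double LAM_HI = 1.0 - 1e-12;

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double sgn(double x) { return (x > 0) - (x < 0); }

struct Design {
  NumericMatrix Phi;       // n x np
  IntegerVector obs_ptr;   // nObs + 1, 0-based row offsets
  IntegerVector kind;      // 0 exact, 1 censored, 2 interval
  IntegerVector dest;      // 0-based destination column, -1 censored
  IntegerVector kstar, k1, k2;
  IntegerVector map_off;   // D offsets into theta
  int D, n, np, nObs;
};

static std::vector<Design> parse_designs(List designs) {
  std::vector<Design> out;
  for (int i = 0; i < designs.size(); ++i) {
    List d(designs[i]);
    Design s;
    s.Phi = as<NumericMatrix>(d["Phi"]);
    s.obs_ptr = as<IntegerVector>(d["obs_ptr"]);
    s.kind = as<IntegerVector>(d["kind"]);
    s.dest = as<IntegerVector>(d["dest_idx"]);
    s.kstar = as<IntegerVector>(d["kstar"]);
    s.k1 = as<IntegerVector>(d["k1"]);
    s.k2 = as<IntegerVector>(d["k2"]);
    s.map_off = as<IntegerVector>(d["map_off"]);
    s.D = s.map_off.size();
    s.n = s.Phi.nrow();
    s.np = s.Phi.ncol();
    s.nObs = s.kind.size();
    out.push_back(s);
  }
  return out;
}

// Forward pass of one mapping over all rows of a design. When `cache` is
// non-null it receives 16 doubles per row: z1(5), x2(3), z2(5), x3(3).
static void map_forward(const double* th, const Design& s,
                        double* lam, double* cache) {
  const int np = s.np;
  const double* W1 = th;             // 5 x np col-major
  const double* b1 = th + 5 * np;
  const double* W2 = th + 5 * np + 5;   // 5 x 3 col-major
  const double* b2 = th + 5 * np + 20;
  const double* W3 = th + 5 * np + 25;
  const double  b3 = th[5 * np + 28];
  for (int r = 0; r < s.n; ++r) {
    double z1[5], x2[3], z2[5], x3[3];
    for (int i = 0; i < 5; ++i) z1[i] = b1[i];
    for (int j = 0; j < np; ++j) {
      double v = s.Phi(r, j);
      const double* col = W1 + 5 * j;
      for (int i = 0; i < 5; ++i) z1[i] += col[i] * v;
    }
    x2[0] = z1[0];
    x2[1] = z1[1] * z1[2];
    x2[2] = std::pow(std::fabs(z1[3]) + POWER_EPS, z1[4]);
    for (int i = 0; i < 5; ++i)
      z2[i] = b2[i] + W2[i] * x2[0] + W2[i + 5] * x2[1] + W2[i + 10] * x2[2];
    x3[0] = z2[0];
    x3[1] = z2[1] * z2[2];
    x3[2] = z2[3] / (std::fabs(z2[4]) + 1.0);
    double z3 = b3 + W3[0] * x3[0] + W3[1] * x3[1] + W3[2] * x3[2];
    double p = sigmoid(z3);
    if (p < LAM_LO) p = LAM_LO;
    if (p > LAM_HI) p = LAM_HI;
    lam[r] = p;
    if (cache) {
      double* c = cache + 16 * r;
      for (int i = 0; i < 5; ++i) c[i] = z1[i];
      for (int i = 0; i < 3; ++i) c[5 + i] = x2[i];
      for (int i = 0; i < 5; ++i) c[8 + i] = z2[i];
      for (int i = 0; i < 3; ++i) c[13 + i] = x3[i];
    }
  }
}

// Stick-breaking row bound (ascending destination order, original values in
// the product factors), applied in place. lam is n x D column-major.
static void row_bound(double* lam, int n, int D) {
  for (int r = 0; r < n; ++r) {
    double s = 0;
    for (int d = 0; d < D; ++d) s += lam[r + (size_t)n * d];
    if (s < 1.0) continue;
    double acc = 1.0;
    for (int d = 0; d < D; ++d) {
      double raw = lam[r + (size_t)n * d];
      lam[r + (size_t)n * d] = raw * acc;
      acc *= (1.0 - raw);
    }
  }
}

// Log-likelihood of one design given the bounded hazards (n x D col-major).
static double design_loglik(const Design& s, const double* lam,
                            std::vector<double>& work) {
  const int n = s.n, D = s.D;
  work.resize(n + 1);
  // cumulative log-survival; work[r+1] = sum_{rows <= r} log(1 - rowsum)
  work[0] = 0.0;
  for (int r = 0; r < n; ++r) {
    double rs = 0;
    for (int d = 0; d < D; ++d) rs += lam[r + (size_t)n * d];
    work[r + 1] = work[r] + std::log1p(-rs);
  }
  double total = 0.0;
  for (int i = 0; i < s.nObs; ++i) {
    int r0 = s.obs_ptr[i];
    double base = work[r0];
    if (s.kind[i] == 0) {
      int k = s.kstar[i];
      total += std::log(lam[r0 + k + (size_t)n * s.dest[i]]) + (work[r0 + k] - base);
    } else if (s.kind[i] == 1) {
      total += work[r0 + s.kstar[i]] - base;
    } else {
      double mx = -INFINITY;
      for (int k = s.k1[i]; k <= s.k2[i]; ++k) {
        double lw = std::log(lam[r0 + k + (size_t)n * s.dest[i]]) + (work[r0 + k] - base);
        if (lw > mx) mx = lw;
      }
      double acc = 0.0;
      for (int k = s.k1[i]; k <= s.k2[i]; ++k) {
        double lw = std::log(lam[r0 + k + (size_t)n * s.dest[i]]) + (work[r0 + k] - base);
        acc += std::exp(lw - mx);
      }
      total += mx + std::log(acc);
    }
  }
  return total;
}

// [[Rcpp::export(name = ".cpp_negloglik")]]
double cpp_negloglik(NumericVector theta, List designs) {
  std::vector<Design> ds = parse_designs(designs);
  const double* th = theta.begin();
  double total = 0.0;
  std::vector<double> lam, work;
  for (size_t si = 0; si < ds.size(); ++si) {
    Design& s = ds[si];
    lam.assign((size_t)s.n * s.D, 0.0);
    for (int d = 0; d < s.D; ++d)
      map_forward(th + s.map_off[d], s, lam.data() + (size_t)s.n * d, nullptr);
    row_bound(lam.data(), s.n, s.D);
    total += design_loglik(s, lam.data(), work);
  }
  return -total;
}

// Backprop of d(loglik)/d(raw lambda) through one mapping, accumulating into
// the gradient slice for that mapping.
static void map_backward(const double* th, const Design& s,
                         const double* lam_raw, const double* cache,
                         const double* graw, double* grad) {
  const int np = s.np;
  const double* W2 = th + 5 * np + 5;
  const double* W3 = th + 5 * np + 25;
  double* gW1 = grad;
  double* gb1 = grad + 5 * np;
  double* gW2 = grad + 5 * np + 5;
  double* gb2 = grad + 5 * np + 20;
  double* gW3 = grad + 5 * np + 25;
  double* gb3 = grad + 5 * np + 28;
  for (int r = 0; r < s.n; ++r) {
    double u = graw[r];
    if (u == 0.0) continue;
    const double* c = cache + 16 * r;
    const double* z1 = c;
    const double* x2 = c + 5;
    const double* z2 = c + 8;
    const double* x3 = c + 13;
    double p = lam_raw[r];
    double dz3 = u * p * (1.0 - p);
    gb3[0] += dz3;
    double dx3[3];
    for (int i = 0; i < 3; ++i) { gW3[i] += dz3 * x3[i]; dx3[i] = dz3 * W3[i]; }
    double dz2[5];
    dz2[0] = dx3[0];
    dz2[1] = dx3[1] * z2[2];
    dz2[2] = dx3[1] * z2[1];
    double den = std::fabs(z2[4]) + 1.0;
    dz2[3] = dx3[2] / den;
    dz2[4] = -dx3[2] * z2[3] * sgn(z2[4]) / (den * den);
    double dx2[3] = {0, 0, 0};
    for (int i = 0; i < 5; ++i) {
      gb2[i] += dz2[i];
      for (int k = 0; k < 3; ++k) {
        gW2[i + 5 * k] += dz2[i] * x2[k];
        dx2[k] += dz2[i] * W2[i + 5 * k];
      }
    }
    double dz1[5];
    dz1[0] = dx2[0];
    dz1[1] = dx2[1] * z1[2];
    dz1[2] = dx2[1] * z1[1];
    double base = std::fabs(z1[3]) + POWER_EPS;
    dz1[3] = dx2[2] * z1[4] * std::pow(base, z1[4] - 1.0) * sgn(z1[3]);
    dz1[4] = dx2[2] * x2[2] * std::log(base);
    for (int i = 0; i < 5; ++i) gb1[i] += dz1[i];
    for (int j = 0; j < np; ++j) {
      double v = s.Phi(r, j);
      for (int i = 0; i < 5; ++i) gW1[i + 5 * j] += dz1[i] * v;
    }
  }
}

// [[Rcpp::export(name = ".cpp_negloglik_grad")]]
List cpp_negloglik_grad(NumericVector theta, List designs) {
  std::vector<Design> ds = parse_designs(designs);
  const double* th = theta.begin();
  NumericVector grad(theta.size());
  double total = 0.0;
  std::vector<double> lam_raw, lam, cache, work, glam, graw;
  for (size_t si = 0; si < ds.size(); ++si) {
    Design& s = ds[si];
    const size_t nd = (size_t)s.n * s.D;
    lam_raw.assign(nd, 0.0);
    cache.assign((size_t)16 * s.n * s.D, 0.0);
    for (int d = 0; d < s.D; ++d)
      map_forward(th + s.map_off[d], s, lam_raw.data() + (size_t)s.n * d,
                  cache.data() + (size_t)16 * s.n * d);
    lam = lam_raw;
    row_bound(lam.data(), s.n, s.D);

    // cumulative log-survival and row sums of the bounded hazards
    work.resize(s.n + 1);
    std::vector<double> rs(s.n);
    work[0] = 0.0;
    for (int r = 0; r < s.n; ++r) {
      double v = 0;
      for (int d = 0; d < s.D; ++d) v += lam[r + (size_t)s.n * d];
      rs[r] = v;
      work[r + 1] = work[r] + std::log1p(-v);
    }

    // d(loglik)/d(bounded lambda)
    glam.assign(nd, 0.0);
    for (int i = 0; i < s.nObs; ++i) {
      int r0 = s.obs_ptr[i];
      double base = work[r0];
      if (s.kind[i] == 0) {
        int k = s.kstar[i];
        int rk = r0 + k;
        total += std::log(lam[rk + (size_t)s.n * s.dest[i]]) + (work[rk] - base);
        glam[rk + (size_t)s.n * s.dest[i]] += 1.0 / lam[rk + (size_t)s.n * s.dest[i]];
        for (int r = r0; r < rk; ++r) {
          double g = -1.0 / (1.0 - rs[r]);
          for (int d = 0; d < s.D; ++d) glam[r + (size_t)s.n * d] += g;
        }
      } else if (s.kind[i] == 1) {
        int rk = r0 + s.kstar[i];
        total += work[rk] - base;
        for (int r = r0; r < rk; ++r) {
          double g = -1.0 / (1.0 - rs[r]);
          for (int d = 0; d < s.D; ++d) glam[r + (size_t)s.n * d] += g;
        }
      } else {
        int k1 = s.k1[i], k2 = s.k2[i], dd = s.dest[i];
        double mx = -INFINITY;
        for (int k = k1; k <= k2; ++k) {
          double lw = std::log(lam[r0 + k + (size_t)s.n * dd]) + (work[r0 + k] - base);
          if (lw > mx) mx = lw;
        }
        double acc = 0.0;
        std::vector<double> p(k2 - k1 + 1);
        for (int k = k1; k <= k2; ++k) {
          double lw = std::log(lam[r0 + k + (size_t)s.n * dd]) + (work[r0 + k] - base);
          p[k - k1] = std::exp(lw - mx);
          acc += p[k - k1];
        }
        total += mx + std::log(acc);
        for (int k = k1; k <= k2; ++k) p[k - k1] /= acc;
        // suffix sums of p over k >= j+1
        double suffix = 0.0;
        std::vector<double> cj(k2 + 1, 0.0);
        for (int k = k2; k >= k1; --k) {
          suffix += p[k - k1];
          cj[k] = suffix; // sum of p for events at month >= k
        }
        for (int j = 0; j < k2; ++j) {
          double cjj = (j + 1 <= k1) ? 1.0 : cj[j + 1];
          double gg = -cjj / (1.0 - rs[r0 + j]);
          for (int d = 0; d < s.D; ++d) glam[(size_t)(r0 + j) + (size_t)s.n * d] += gg;
        }
        // target-month terms
        for (int k = k1; k <= k2; ++k)
          glam[(size_t)(r0 + k) + (size_t)s.n * dd] +=
            p[k - k1] / lam[(size_t)(r0 + k) + (size_t)s.n * dd];
      }
    }

    // chain through the row bound: bounded -> raw
    graw.assign(nd, 0.0);
    for (int r = 0; r < s.n; ++r) {
      double sraw = 0;
      for (int d = 0; d < s.D; ++d) sraw += lam_raw[r + (size_t)s.n * d];
      if (sraw < 1.0) {
        for (int d = 0; d < s.D; ++d)
          graw[r + (size_t)s.n * d] = glam[r + (size_t)s.n * d];
      } else {
        double P[3];
        double acc = 1.0;
        for (int d = 0; d < s.D; ++d) { P[d] = acc; acc *= (1.0 - lam_raw[r + (size_t)s.n * d]); }
        for (int j = 0; j < s.D; ++j) {
          double g = glam[r + (size_t)s.n * j] * P[j];
          for (int i = j + 1; i < s.D; ++i) {
            double ai = lam_raw[r + (size_t)s.n * i];
            g += glam[r + (size_t)s.n * i] *
                 (-ai * P[i] / (1.0 - lam_raw[r + (size_t)s.n * j]));
          }
          graw[r + (size_t)s.n * j] = g;
        }
      }
    }

    for (int d = 0; d < s.D; ++d)
      map_backward(th + s.map_off[d], s,
                   lam_raw.data() + (size_t)s.n * d,
                   cache.data() + (size_t)16 * s.n * d,
                   graw.data() + (size_t)s.n * d,
                   grad.begin() + s.map_off[d]);
  }
  for (R_xlen_t i = 0; i < grad.size(); ++i) grad[i] = -grad[i];
  return List::create(Named("loss") = -total, Named("grad") = grad);
}

// Diagonal Hessian of the negative log-likelihood by central second
// differences, recomputing only the from-state whose mapping owns the
// perturbed parameter. Step per parameter: h * max(1, |theta_k|).
// [[Rcpp::export(name = ".cpp_hessian_diag")]]
NumericVector cpp_hessian_diag(NumericVector theta, List designs,
                               IntegerVector active, double h) {
  std::vector<Design> ds = parse_designs(designs);
  NumericVector th = clone(theta);
  std::vector<double> work;

  // cache raw hazards and base loss per design
  std::vector< std::vector<double> > lam_cache(ds.size());
  std::vector<double> base_loss(ds.size());
  for (size_t si = 0; si < ds.size(); ++si) {
    Design& s = ds[si];
    lam_cache[si].assign((size_t)s.n * s.D, 0.0);
    for (int d = 0; d < s.D; ++d)
      map_forward(th.begin() + s.map_off[d], s,
                  lam_cache[si].data() + (size_t)s.n * d, nullptr);
    std::vector<double> lam = lam_cache[si];
    row_bound(lam.data(), s.n, s.D);
    base_loss[si] = -design_loglik(s, lam.data(), work);
  }

  NumericVector out(active.size());
  std::vector<double> lam;
  for (int a = 0; a < active.size(); ++a) {
    int idx = active[a];
    // locate the mapping that owns parameter idx
    int dsi = -1, dcol = -1;
    for (size_t si = 0; si < ds.size() && dsi < 0; ++si) {
      int Lm = 5 * ds[si].np + 29;
      for (int d = 0; d < ds[si].D; ++d) {
        int off = ds[si].map_off[d];
        if (idx >= off && idx < off + Lm) { dsi = (int)si; dcol = d; break; }
      }
    }
    if (dsi < 0) { out[a] = NA_REAL; continue; }
    Design& s = ds[dsi];
    double hk = h * std::max(1.0, std::fabs(th[idx]));
    double orig = th[idx];
    double losses[2];
    for (int sideI = 0; sideI < 2; ++sideI) {
      th[idx] = orig + (sideI == 0 ? hk : -hk);
      lam = lam_cache[dsi];
      map_forward(th.begin() + s.map_off[dcol], s, lam.data() + (size_t)s.n * dcol,
                  nullptr);
      row_bound(lam.data(), s.n, s.D);
      losses[sideI] = -design_loglik(s, lam.data(), work);
    }
    th[idx] = orig;
    out[a] = (losses[0] - 2.0 * base_loss[dsi] + losses[1]) / (hk * hk);
  }
  return out;
}
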