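// Adaptive Gauss-Hermite machinery for p-variate logistic random-intercept
// models (random intercept per outcome, shared cluster). Parameters enter as
// theta = c(vec beta, outcome-major), log-Cholesky of the p x p random-
// intercept covariance (lower triangle, column-major, log on the diagonal).
// The per-cluster and per-node loops run on raw fixed-size buffers (p <= 3)
// because the evaluation is called thousands of times per fit and dynamic
// small-matrix overhead would dominate the arithmetic.
#define ARMA_WARN_LEVEL 0 // every solve/inversion below has an explicit fallback
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

#define PMAX 3

// Cholesky of an SPD p x p matrix in raw storage (column-major), with a
// diagonal ridge fallback; returns false only if hopeless.
static bool chol_raw(int p, const double* A, double* L) {
  for (double ridge = 0.0;; ridge = (ridge == 0.0 ? 1e-12 : ridge * 100)) {
    bool ok = true;
    for (int c = 0; c < p && ok; ++c) {
      double d = A[c + c * p] + ridge;
      for (int t = 0; t < c; ++t) d -= L[c + t * p] * L[c + t * p];
      if (d <= 0.0 || !std::isfinite(d)) { ok = false; break; }
      double s = std::sqrt(d);
      L[c + c * p] = s;
      for (int r = c + 1; r < p; ++r) {
        double v = A[r + c * p];
        for (int t = 0; t < c; ++t) v -= L[r + t * p] * L[c + t * p];
        L[r + c * p] = v / s;
      }
      for (int r = 0; r < c; ++r) L[r + c * p] = 0.0;
    }
    if (ok) return true;
    if (ridge > 1e6) return false;
  }
}

// inverse from a Cholesky factor: A^{-1} = L^{-T} L^{-1}
static void inv_from_chol(int p, const double* L, double* Ainv) {
  double Linv[PMAX * PMAX] = {0};
  for (int c = 0; c < p; ++c) {
    Linv[c + c * p] = 1.0 / L[c + c * p];
    for (int r = c + 1; r < p; ++r) {
      double v = 0.0;
      for (int t = c; t < r; ++t) v -= L[r + t * p] * Linv[t + c * p];
      Linv[r + c * p] = v / L[r + r * p];
    }
  }
  for (int i = 0; i < p; ++i)
    for (int j = 0; j <= i; ++j) {
      double v = 0.0;
      for (int t = i; t < p; ++t) v += Linv[t + i * p] * Linv[t + j * p];
      Ainv[i + j * p] = Ainv[j + i * p] = v;
    }
}

// [[Rcpp::export]]
Rcpp::List aghq_eval_cpp(const arma::vec& theta,
                         const arma::mat& Y,
                         const arma::mat& X,
                         const arma::ivec& cluster, // 1-based, contiguous 1..J
                         int J,
                         const arma::vec& gh_nodes,
                         const arma::vec& gh_logw,
                         bool want_score,
                         Rcpp::Nullable<Rcpp::NumericMatrix> b_init = R_NilValue) {
  const int N = Y.n_rows, p = Y.n_cols, k = X.n_cols;
  const int nq = gh_nodes.n_elem;
  const int nch = p * (p + 1) / 2;
  const int ntheta = p * k + nch;
  if (p > PMAX) Rcpp::stop("p > 3 not supported");
  if ((int)theta.n_elem != ntheta) Rcpp::stop("theta has wrong length");

  mat Beta(k, p); // column r = coefficients of outcome r
  for (int r = 0; r < p; ++r)
    Beta.col(r) = theta.subvec(r * k, r * k + k - 1);

  // L, D, Dinv in raw column-major storage
  double Lm[PMAX * PMAX] = {0}, Dm[PMAX * PMAX] = {0}, Dinv[PMAX * PMAX] = {0};
  {
    int pos = p * k;
    for (int c = 0; c < p; ++c)
      for (int r = c; r < p; ++r) {
        double v = theta(pos++);
        Lm[r + c * p] = (r == c) ? std::exp(v) : v;
      }
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) {
        double v = 0.0;
        for (int t = 0; t <= std::min(i, j); ++t)
          v += Lm[i + t * p] * Lm[j + t * p];
        Dm[i + j * p] = v;
      }
    double Lc[PMAX * PMAX] = {0};
    if (!chol_raw(p, Dm, Lc))
      Rcpp::stop("random-effect covariance not invertible");
    inv_from_chol(p, Lc, Dinv);
  }
  double logdetD = 0.0;
  for (int c = 0; c < p; ++c) logdetD += 2.0 * std::log(Lm[c + c * p]);
  const double LOG2PI = std::log(2.0 * M_PI);

  // tensor quadrature grid: G = nq^p nodes, column-major p x G
  int G = 1;
  for (int d = 0; d < p; ++d) G *= nq;
  std::vector<double> Znodes(p * G), logw(G, 0.0), zsq(G, 0.0);
  for (int g = 0; g < G; ++g) {
    int rem = g;
    for (int d = 0; d < p; ++d) {
      int idx = rem % nq;
      rem /= nq;
      double z = gh_nodes(idx);
      Znodes[d + g * p] = z;
      logw[g] += gh_logw(idx);
      zsq[g] += z * z;
    }
  }

  // rows grouped by cluster (counting sort, stable)
  ivec cnt(J, fill::zeros);
  for (int i = 0; i < N; ++i) {
    int c = cluster(i) - 1;
    if (c < 0 || c >= J) Rcpp::stop("cluster index out of range");
    cnt(c)++;
  }
  ivec off(J + 1, fill::zeros);
  for (int j = 0; j < J; ++j) off(j + 1) = off(j) + cnt(j);
  ivec pos_fill = off.head(J);
  ivec rows_of(N);
  for (int i = 0; i < N; ++i) {
    int c = cluster(i) - 1;
    rows_of(pos_fill(c)++) = i;
  }

  mat Eta0 = X * Beta; // N x p, fixed-effect part, one GEMM per evaluation
  const double* eta0 = Eta0.memptr();
  const double* yptr = Y.memptr();
  const double* xptr = X.memptr();

  vec cl_ll(J, fill::zeros);
  mat cl_sc;
  if (want_score) cl_sc.zeros(J, ntheta);

  mat Bmodes(J, p, fill::zeros);
  if (b_init.isNotNull()) {
    Rcpp::NumericMatrix bi(b_init);
    if ((int)bi.nrow() == J && (int)bi.ncol() == p)
      for (int j = 0; j < J; ++j)
        for (int r = 0; r < p; ++r) Bmodes(j, r) = bi(j, r);
  }

  const int max_nj = cnt.max();
  std::vector<double> lg(G), Gsc(want_score ? (size_t)ntheta * G : 0),
      Mubuf((size_t)max_nj * p);
  const double sqrt2 = std::sqrt(2.0);

  for (int j = 0; j < J; ++j) {
    const int nj = cnt(j);
    const int* rj = rows_of.memptr() + off(j);

    double b[PMAX], g1[PMAX], Wm[PMAX * PMAX], step[PMAX], bnew[PMAX];
    for (int r = 0; r < p; ++r) b[r] = Bmodes(j, r);

    // fused objective / gradient / curvature of the penalized loglik
    double f0 = 0.0;
    auto eval_fgW = [&](const double* bb, double& f, double* gg, double* WW) {
      f = 0.0;
      for (int r = 0; r < p; ++r) {
        double a = 0.0;
        for (int t = 0; t < p; ++t) a += Dinv[r + t * p] * bb[t];
        gg[r] = -a;
        f += -0.5 * bb[r] * a;
        for (int t = 0; t < p; ++t) WW[r + t * p] = Dinv[r + t * p];
      }
      for (int a = 0; a < nj; ++a) {
        int row = rj[a];
        for (int r = 0; r < p; ++r) {
          double e = eta0[row + (size_t)r * N] + bb[r];
          double sp = softplus(e);
          f += yptr[row + (size_t)r * N] * e - sp;
          double mu = std::exp(e - sp);
          gg[r] += yptr[row + (size_t)r * N] - mu;
          WW[r + r * p] += mu * (1.0 - mu);
        }
      }
    };
    auto pen_ll = [&](const double* bb) {
      double f = 0.0;
      for (int r = 0; r < p; ++r) {
        double a = 0.0;
        for (int t = 0; t < p; ++t) a += Dinv[r + t * p] * bb[t];
        f += -0.5 * bb[r] * a;
      }
      for (int a = 0; a < nj; ++a) {
        int row = rj[a];
        for (int r = 0; r < p; ++r) {
          double e = eta0[row + (size_t)r * N] + bb[r];
          f += yptr[row + (size_t)r * N] * e - softplus(e);
        }
      }
      return f;
    };

    eval_fgW(b, f0, g1, Wm); // Wm holds the positive curvature matrix
    double Lw[PMAX * PMAX] = {0};
    for (int it = 0; it < 100; ++it) {
      double gmax = 0.0;
      for (int r = 0; r < p; ++r) gmax = std::max(gmax, std::abs(g1[r]));
      if (gmax < 1e-9) break;
      if (!chol_raw(p, Wm, Lw)) break;
      // solve W step = g via the factor
      double tmp[PMAX];
      for (int r = 0; r < p; ++r) {
        double v = g1[r];
        for (int t = 0; t < r; ++t) v -= Lw[r + t * p] * tmp[t];
        tmp[r] = v / Lw[r + r * p];
      }
      for (int r = p - 1; r >= 0; --r) {
        double v = tmp[r];
        for (int t = r + 1; t < p; ++t) v -= Lw[t + r * p] * step[t];
        step[r] = v / Lw[r + r * p];
      }
      double halve = 1.0;
      for (int r = 0; r < p; ++r) bnew[r] = b[r] + step[r];
      for (int h = 0; h < 30; ++h) {
        if (pen_ll(bnew) >= f0 - 1e-12) break;
        halve *= 0.5;
        for (int r = 0; r < p; ++r) bnew[r] = b[r] + halve * step[r];
      }
      for (int r = 0; r < p; ++r) b[r] = bnew[r];
      double f1;
      eval_fgW(b, f1, g1, Wm);
      bool flat = std::abs(f1 - f0) < 1e-13 && it > 2;
      f0 = f1;
      if (flat) break;
    }
    for (int r = 0; r < p; ++r) Bmodes(j, r) = b[r];

    // adaptive scaling from the curvature at the mode
    double Sig[PMAX * PMAX] = {0}, Ls[PMAX * PMAX] = {0};
    if (chol_raw(p, Wm, Lw)) {
      inv_from_chol(p, Lw, Sig);
    } else {
      for (int r = 0; r < p; ++r)
        Sig[r + r * p] = 1.0 / std::max(Wm[r + r * p], 1e-8);
    }
    if (!chol_raw(p, Sig, Ls)) {
      for (int r = 0; r < p * p; ++r) Ls[r] = 0.0;
      for (int r = 0; r < p; ++r)
        Ls[r + r * p] = std::sqrt(std::max(Sig[r + r * p], 1e-12));
    }
    double ldLs = 0.0;
    for (int r = 0; r < p; ++r) ldLs += std::log(Ls[r + r * p]);

    double lmax = -std::numeric_limits<double>::infinity();
    for (int g = 0; g < G; ++g) {
      double bg[PMAX], alpha[PMAX];
      const double* z = &Znodes[(size_t)g * p];
      for (int r = 0; r < p; ++r) {
        double v = b[r];
        for (int t = 0; t <= r; ++t) v += sqrt2 * Ls[r + t * p] * z[t];
        bg[r] = v;
      }
      double ll = 0.0;
      if (want_score) {
        for (int a = 0; a < nj; ++a) {
          int row = rj[a];
          for (int r = 0; r < p; ++r) {
            double e = eta0[row + (size_t)r * N] + bg[r];
            double sp = softplus(e);
            double yv = yptr[row + (size_t)r * N];
            ll += yv * e - sp;
            Mubuf[a + (size_t)r * max_nj] = yv - std::exp(e - sp);
          }
        }
      } else {
        for (int a = 0; a < nj; ++a) {
          int row = rj[a];
          for (int r = 0; r < p; ++r) {
            double e = eta0[row + (size_t)r * N] + bg[r];
            ll += yptr[row + (size_t)r * N] * e - softplus(e);
          }
        }
      }
      double quad = 0.0;
      for (int r = 0; r < p; ++r) {
        double a = 0.0;
        for (int t = 0; t < p; ++t) a += Dinv[r + t * p] * bg[t];
        alpha[r] = a;
        quad += bg[r] * a;
      }
      ll += -0.5 * p * LOG2PI - 0.5 * logdetD - 0.5 * quad;
      double v = logw[g] + zsq[g] + ll;
      lg[g] = v;
      if (v > lmax) lmax = v;

      if (want_score) {
        double* sc = &Gsc[(size_t)g * ntheta];
        for (int r = 0; r < p; ++r) {
          const double* mcol = &Mubuf[(size_t)r * max_nj];
          for (int c = 0; c < k; ++c) {
            double acc = 0.0;
            const double* xcol = xptr + (size_t)c * N;
            for (int a = 0; a < nj; ++a) acc += xcol[rj[a]] * mcol[a];
            sc[r * k + c] = acc;
          }
        }
        // d log phi / dL = (alpha alpha' - Dinv) L, log-diagonal chain rule
        int ppos = p * k;
        for (int c = 0; c < p; ++c)
          for (int r = c; r < p; ++r) {
            double dv = 0.0;
            for (int t = c; t < p; ++t)
              dv += (alpha[r] * alpha[t] - Dinv[r + t * p]) * Lm[t + c * p];
            if (r == c) dv *= Lm[c + c * p];
            sc[ppos++] = dv;
          }
      }
    }
    double sum = 0.0;
    for (int g = 0; g < G; ++g) sum += std::exp(lg[g] - lmax);
    double lse = lmax + std::log(sum);
    cl_ll(j) = lse + 0.5 * p * std::log(2.0) + ldLs;
    if (want_score) {
      double* out_sc = cl_sc.memptr() + j; // row j, stride J
      for (int t = 0; t < ntheta; ++t) {
        double acc = 0.0;
        for (int g = 0; g < G; ++g)
          acc += std::exp(lg[g] - lse) * Gsc[(size_t)g * ntheta + t];
        out_sc[(size_t)t * J] = acc;
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = accu(cl_ll),
      Rcpp::Named("cluster_loglik") = cl_ll,
      Rcpp::Named("b_modes") = Bmodes);
  if (want_score) {
    out["score"] = sum(cl_sc, 0).t();
    out["cluster_scores"] = cl_sc;
  }
  return out;
}
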