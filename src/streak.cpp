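#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel-integrated Gaussian helpers. Coordinates are 0-based with the
// pixel-centre convention: position p.0 is the centre of pixel p, so pixel p
// covers [p - 0.5, p + 0.5).

static inline double ncdf(double z) { return 0.5 * (1.0 + std::erf(z * M_SQRT1_2)); }
static inline double npdf(double z) { return std::exp(-0.5 * z * z) / std::sqrt(2.0 * M_PI); }

// Fraction of a unit-total Gaussian centred at x with sd sigma that falls in
// pixel p (1D).
static inline double pixint(double p, double x, double sigma) {
  return ncdf((p + 0.5 - x) / sigma) - ncdf((p - 0.5 - x) / sigma);
}

// [[Rcpp::export]]
NumericMatrix add_psf_cpp(NumericMatrix img, NumericVector row_y,
                          NumericVector col_x, NumericVector photons,
                          double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hw = (int)std::ceil(4.0 * sigma) + 1;
  const int n = row_y.size();
  for (int i = 0; i < n; i++) {
    const double y = row_y[i], x = col_x[i], N = photons[i];
    const int r0 = std::max(0, (int)std::floor(y) - hw);
    const int r1 = std::min(nr - 1, (int)std::floor(y) + hw);
    const int c0 = std::max(0, (int)std::floor(x) - hw);
    const int c1 = std::min(nc - 1, (int)std::floor(x) + hw);
    if (r1 < r0 || c1 < c0) continue;
    for (int c = c0; c <= c1; c++) {
      const double ex = pixint((double)c, x, sigma);
      for (int r = r0; r <= r1; r++) {
        img(r, c) += N * ex * pixint((double)r, y, sigma);
      }
    }
  }
  return img;
}

// Solve a small symmetric linear system in place (Gaussian elimination with
// partial pivoting). Returns false if singular.
static bool solve_small(std::vector<double>& A, std::vector<double>& b, int n) {
  for (int k = 0; k < n; k++) {
    int piv = k;
    for (int i = k + 1; i < n; i++)
      if (std::fabs(A[i * n + k]) > std::fabs(A[piv * n + k])) piv = i;
    if (std::fabs(A[piv * n + k]) < 1e-14) return false;
    if (piv != k) {
      for (int j = 0; j < n; j++) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; i++) {
      const double f = A[i * n + k] / A[k * n + k];
      for (int j = k; j < n; j++) A[i * n + j] -= f * A[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; i--) {
    double s = b[i];
    for (int j = i + 1; j < n; j++) s -= A[i * n + j] * b[j];
    b[i] = s / A[i * n + i];
  }
  return true;
}

// Least-squares fit of an integrated 2D Gaussian (x, y, sigma, N, offset) to
// square ROIs around candidate pixels, by Levenberg-Marquardt. Candidates are
// 0-based pixel indices; the ROI is (2*hw+1)^2 and must lie fully on the chip
// (checked by the caller). Returns one row per candidate:
// x, y, sigma, N, offset, rss, converged(0/1), iters.
// [[Rcpp::export]]
NumericMatrix fit_gauss2d_cpp(NumericMatrix frame, IntegerVector cand_row,
                              IntegerVector cand_col, int hw, double sigma0,
                              int max_iter = 60, double tol = 1e-9) {
  const int n = cand_row.size();
  const int w = 2 * hw + 1, npx = w * w;
  NumericMatrix out(n, 8);
  std::vector<double> z(npx), ex(w), ey(w), dex(w), dey(w), sex(w), sey(w);
  std::vector<double> resid(npx), J(npx * 5);

  for (int i = 0; i < n; i++) {
    const int rc = cand_row[i], cc = cand_col[i];
    // extract ROI, initial estimates
    double zmin = R_PosInf, zsum = 0.0;
    for (int c = 0; c < w; c++)
      for (int r = 0; r < w; r++) {
        const double v = frame(rc - hw + r, cc - hw + c);
        z[c * w + r] = v;
        if (v < zmin) zmin = v;
        zsum += v;
      }
    double off = zmin;
    double N = zsum - off * npx;
    if (N <= 0) N = 1.0;
    double sx = 0.0, sy = 0.0, wsum = 0.0;
    for (int c = 0; c < w; c++)
      for (int r = 0; r < w; r++) {
        const double v = z[c * w + r] - off;
        if (v > 0) { sx += v * c; sy += v * r; wsum += v; }
      }
    double x = (wsum > 0 ? sx / wsum : hw) + (cc - hw);
    double y = (wsum > 0 ? sy / wsum : hw) + (rc - hw);
    double sig = sigma0;

    double par[5] = {x, y, sig, N, off};
    double lambda = 1e-3, rss = R_PosInf;
    bool conv = false;
    int it = 0;

    // current residuals/Jacobian at par
    auto eval = [&](const double* p, bool jac) -> double {
      const double px = p[0], py = p[1], ps = p[2], pN = p[3], po = p[4];
      for (int c = 0; c < w; c++) {
        const double pc = cc - hw + c;
        const double u1 = (pc + 0.5 - px) / ps, u0 = (pc - 0.5 - px) / ps;
        ex[c] = ncdf(u1) - ncdf(u0);
        dex[c] = -(npdf(u1) - npdf(u0)) / ps;
        sex[c] = -(u1 * npdf(u1) - u0 * npdf(u0)) / ps;
      }
      for (int r = 0; r < w; r++) {
        const double pr = rc - hw + r;
        const double u1 = (pr + 0.5 - py) / ps, u0 = (pr - 0.5 - py) / ps;
        ey[r] = ncdf(u1) - ncdf(u0);
        dey[r] = -(npdf(u1) - npdf(u0)) / ps;
        sey[r] = -(u1 * npdf(u1) - u0 * npdf(u0)) / ps;
      }
      double s = 0.0;
      for (int c = 0; c < w; c++)
        for (int r = 0; r < w; r++) {
          const int k = c * w + r;
          const double m = po + pN * ex[c] * ey[r];
          resid[k] = z[k] - m;
          s += resid[k] * resid[k];
          if (jac) {
            J[k] = pN * dex[c] * ey[r];            // d/dx
            J[npx + k] = pN * ex[c] * dey[r];      // d/dy
            J[2 * npx + k] = pN * (sex[c] * ey[r] + ex[c] * sey[r]); // d/dsigma
            J[3 * npx + k] = ex[c] * ey[r];        // d/dN
            J[4 * npx + k] = 1.0;                  // d/doffset
          }
        }
      return s;
    };

    rss = eval(par, true);
    for (it = 0; it < max_iter; it++) {
      // normal equations
      std::vector<double> A(25), g(5);
      for (int a = 0; a < 5; a++) {
        double ga = 0.0;
        for (int k = 0; k < npx; k++) ga += J[a * npx + k] * resid[k];
        g[a] = ga;
        for (int b = a; b < 5; b++) {
          double s = 0.0;
          for (int k = 0; k < npx; k++) s += J[a * npx + k] * J[b * npx + k];
          A[a * 5 + b] = s;
          A[b * 5 + a] = s;
        }
      }
      bool stepped = false;
      for (int tries = 0; tries < 12; tries++) {
        std::vector<double> Ad(A), gd(g);
        for (int a = 0; a < 5; a++) Ad[a * 5 + a] *= (1.0 + lambda);
        if (!solve_small(Ad, gd, 5)) { lambda *= 10; continue; }
        double trial[5];
        for (int a = 0; a < 5; a++) trial[a] = par[a] + gd[a];
        if (trial[2] < 0.05) trial[2] = 0.05; // keep sigma positive
        const double rss_t = eval(trial, false);
        if (rss_t < rss) {
          const double drop = (rss - rss_t) / (rss + 1e-300);
          for (int a = 0; a < 5; a++) par[a] = trial[a];
          rss = rss_t;
          lambda = std::max(lambda * 0.3, 1e-9);
          eval(par, true);
          stepped = true;
          if (drop < tol) conv = true;
          break;
        }
        lambda *= 10;
      }
      if (!stepped) { conv = true; break; } // in a local minimum
      if (conv) break;
    }

    out(i, 0) = par[0];
    out(i, 1) = par[1];
    out(i, 2) = par[2];
    out(i, 3) = par[3];
    out(i, 4) = par[4];
    out(i, 5) = rss;
    out(i, 6) = conv ? 1.0 : 0.0;
    out(i, 7) = it;
  }
  return out;
}
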