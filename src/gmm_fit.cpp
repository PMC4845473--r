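// Penalized Gaussian-mixture image objective and Powell direction-set
// minimizer.  This is the per-frame workhorse: a 12- or 18-parameter
// derivative-free local fit of the mixture model to one video frame.
//
// Parameter layout per component: (w, mu_x, mu_y, s11, s22, s12).
// Coordinates are 0-based pixel-centered; image element (y, x) is
// img(y, x) with y the row index.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct GmmObjective {
  const NumericMatrix img;
  const NumericMatrix D;
  double a_nuc, w_nuc;
  int K;
  double trunc_q;            // Mahalanobis^2 cutoff for rendering support
  int nr, nc;
  std::vector<double> M;     // scratch model image
  std::vector<double> SII;   // (nr+1) x (nc+1) integral image of I^2
  double total_I2;
  long n_eval;

  GmmObjective(const NumericMatrix& img_, const NumericMatrix& D_,
               double a_nuc_, double w_nuc_, int K_, double trunc_q_)
    : img(img_), D(D_), a_nuc(a_nuc_), w_nuc(w_nuc_), K(K_),
      trunc_q(trunc_q_), nr(img_.nrow()), nc(img_.ncol()),
      M(static_cast<size_t>(nr) * nc, 0.0),
      SII(static_cast<size_t>(nr + 1) * (nc + 1), 0.0), n_eval(0) {
    for (int x = 0; x < nc; ++x) {
      const double* icol = &img(0, x);
      double colsum = 0.0;
      for (int y = 0; y < nr; ++y) {
        colsum += icol[y] * icol[y];
        SII[(size_t)(x + 1) * (nr + 1) + (y + 1)] =
          SII[(size_t) x * (nr + 1) + (y + 1)] + colsum;
      }
    }
    total_I2 = SII[(size_t) nc * (nr + 1) + nr];
  }

  // sum of I^2 over the inclusive pixel rectangle [y0..y1] x [x0..x1]
  double rect_I2(int y0, int y1, int x0, int x1) const {
    const size_t W = nr + 1;
    return SII[(size_t)(x1 + 1) * W + (y1 + 1)] -
           SII[(size_t) x0 * W + (y1 + 1)] -
           SII[(size_t)(x1 + 1) * W + y0] +
           SII[(size_t) x0 * W + y0];
  }

  // Guarded objective: parameter vectors outside the feasible region
  // (non-positive-definite covariance, non-positive weight) get a large
  // finite value that grows with the violation, keeping the derivative-free
  // search inside the feasible region without exceptions.
  double operator()(const double* p) {
    ++n_eval;
    double f_loc = 0.0, f_vol = 0.0, f_int = 0.0;
    double viol = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* q = p + 6 * k;
      double w = q[0], s11 = q[3], s22 = q[4], s12 = q[5];
      double det = s11 * s22 - s12 * s12;
      if (det <= 1e-6 || s11 <= 0.0 || s22 <= 0.0 || w <= 0.0) {
        viol += std::fabs(det) + std::max(0.0, -w) + 1.0;
      }
    }
    if (viol > 0.0) return 1e12 * viol;

    int x0 = nc, x1 = -1, y0 = nr, y1 = -1;
    for (int k = 0; k < K; ++k) {
      const double* q = p + 6 * k;
      double w = q[0], mx = q[1], my = q[2];
      double s11 = q[3], s22 = q[4], s12 = q[5];
      double det = s11 * s22 - s12 * s12;

      // penalties
      int xi = (int) std::lround(mx), yi = (int) std::lround(my);
      int xc = std::min(std::max(xi, 0), nc - 1);
      int yc = std::min(std::max(yi, 0), nr - 1);
      double dd = D(yc, xc) +
        std::sqrt((double)((xi - xc) * (xi - xc) + (yi - yc) * (yi - yc)));
      f_loc += dd * dd;
      f_vol += (det - a_nuc) * (det - a_nuc);
      f_int += (w - w_nuc) * (w - w_nuc);

      // truncated support box: q(x,y) <= trunc_q
      double ex = std::sqrt(trunc_q * s11), ey = std::sqrt(trunc_q * s22);
      int bx0 = std::max(0, (int) std::floor(mx - ex));
      int bx1 = std::min(nc - 1, (int) std::ceil(mx + ex));
      int by0 = std::max(0, (int) std::floor(my - ey));
      int by1 = std::min(nr - 1, (int) std::ceil(my + ey));
      if (bx0 > bx1 || by0 > by1) continue;
      x0 = std::min(x0, bx0); x1 = std::max(x1, bx1);
      y0 = std::min(y0, by0); y1 = std::max(y1, by1);
    }

    // union rectangle: zero, render, residual; outside it M == 0
    double f_err = 0.0;
    if (x1 >= x0 && y1 >= y0) {
      for (int x = x0; x <= x1; ++x) {
        double* col = &M[(size_t) x * nr];
        for (int y = y0; y <= y1; ++y) col[y] = 0.0;
      }
      for (int k = 0; k < K; ++k) {
        const double* q = p + 6 * k;
        double w = q[0], mx = q[1], my = q[2];
        double s11 = q[3], s22 = q[4], s12 = q[5];
        double det = s11 * s22 - s12 * s12;
        double ia = s22 / det, ib = s11 / det, ic = -s12 / det;
        double ex = std::sqrt(trunc_q * s11), ey = std::sqrt(trunc_q * s22);
        int bx0 = std::max(0, (int) std::floor(mx - ex));
        int bx1 = std::min(nc - 1, (int) std::ceil(mx + ex));
        int by0 = std::max(0, (int) std::floor(my - ey));
        int by1 = std::min(nr - 1, (int) std::ceil(my + ey));
        for (int x = bx0; x <= bx1; ++x) {
          double dx = x - mx;
          double* col = &M[(size_t) x * nr];
          for (int y = by0; y <= by1; ++y) {
            double dy = y - my;
            double qv = ia * dx * dx + ib * dy * dy + 2.0 * ic * dx * dy;
            if (qv <= trunc_q) col[y] += w * std::exp(-0.5 * qv);
          }
        }
      }
      f_err = total_I2 - rect_I2(y0, y1, x0, x1);
      for (int x = x0; x <= x1; ++x) {
        const double* icol = &img(0, x);
        const double* mcol = &M[(size_t) x * nr];
        for (int y = y0; y <= y1; ++y) {
          double r = icol[y] - mcol[y];
          f_err += r * r;
        }
      }
    } else {
      f_err = total_I2;
    }
    return f_err * (1.0 + f_loc + f_vol + f_int);
  }
};

constexpr double GOLD = 1.618034, GLIMIT = 100.0, TINY = 1e-20;
constexpr double CGOLD = 0.3819660;

// one-dimensional function along a search direction
struct LineFun {
  GmmObjective& fn;
  const std::vector<double>& p;
  const std::vector<double>& dir;
  std::vector<double> buf;
  LineFun(GmmObjective& f, const std::vector<double>& p_,
          const std::vector<double>& d_) : fn(f), p(p_), dir(d_), buf(p_.size()) {}
  double operator()(double t) {
    for (size_t i = 0; i < p.size(); ++i) buf[i] = p[i] + t * dir[i];
    return fn(buf.data());
  }
};

void mnbrak(LineFun& f, double& ax, double& bx, double& cx,
            double& fa, double& fb, double& fc) {
  fa = f(ax); fb = f(bx);
  if (fb > fa) { std::swap(ax, bx); std::swap(fa, fb); }
  cx = bx + GOLD * (bx - ax);
  fc = f(cx);
  while (fb > fc) {
    double r = (bx - ax) * (fb - fc);
    double q = (bx - cx) * (fb - fa);
    double denom = 2.0 * std::max(std::fabs(q - r), TINY) * (q - r >= 0 ? 1.0 : -1.0);
    double u = bx - ((bx - cx) * q - (bx - ax) * r) / denom;
    double ulim = bx + GLIMIT * (cx - bx);
    double fu;
    if ((bx - u) * (u - cx) > 0.0) {
      fu = f(u);
      if (fu < fc) { ax = bx; bx = u; fa = fb; fb = fu; return; }
      else if (fu > fb) { cx = u; fc = fu; return; }
      u = cx + GOLD * (cx - bx); fu = f(u);
    } else if ((cx - u) * (u - ulim) > 0.0) {
      fu = f(u);
      if (fu < fc) {
        bx = cx; cx = u; u = cx + GOLD * (cx - bx);
        fb = fc; fc = fu; fu = f(u);
      }
    } else if ((u - ulim) * (ulim - cx) >= 0.0) {
      u = ulim; fu = f(u);
    } else {
      u = cx + GOLD * (cx - bx); fu = f(u);
    }
    ax = bx; bx = cx; cx = u;
    fa = fb; fb = fc; fc = fu;
  }
}

double brent(LineFun& f, double ax, double bx, double cx, double fbx,
             double tol, int itmax, double& xmin) {
  double a = std::min(ax, cx), b = std::max(ax, cx);
  double x = bx, w = bx, v = bx;
  double fx = fbx, fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < itmax; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= (tol2 - 0.5 * (b - a))) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e; e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) ||
            p <= q * (a - x) || p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm - x >= 0 ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm ? a - x : b - x);
      d = CGOLD * e;
    }
    double u = (std::fabs(d) >= tol1 ? x + d : x + (d >= 0 ? tol1 : -tol1));
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  xmin = x;
  return fx;
}

// minimize along `dir` from `p`; updates p and fret, rescales dir by the
// step actually taken (Powell direction-set update).
void linmin(GmmObjective& fn, std::vector<double>& p, std::vector<double>& dir,
            double& fret, double line_tol, int line_itmax) {
  LineFun f(fn, p, dir);
  double ax = 0.0, bx = 1.0, cx, fa, fb, fc;
  mnbrak(f, ax, bx, cx, fa, fb, fc);
  double tmin;
  fret = brent(f, ax, bx, cx, fb, line_tol, line_itmax, tmin);
  for (size_t i = 0; i < p.size(); ++i) {
    dir[i] *= tmin;
    p[i] += dir[i];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_fit_powell(NumericMatrix img, NumericVector par0, NumericMatrix D,
                    double a_nuc, double w_nuc, double ftol, int maxit,
                    NumericVector steps, double trunc_q = 18.0,
                    double line_tol = 0.05, int line_itmax = 40,
                    long max_eval = 100000) {
  int n = par0.size();
  if (n % 6 != 0) stop("parameter vector length must be a multiple of 6");
  int K = n / 6;
  if (steps.size() != n) stop("steps must match the parameter vector length");
  GmmObjective fn(img, D, a_nuc, w_nuc, K, trunc_q);

  std::vector<double> p(par0.begin(), par0.end());
  std::vector<std::vector<double>> xi(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i) xi[i][i] = steps[i];

  double fret = fn(p.data());
  std::vector<double> p0 = p, ptt(n), xit(n);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    double fp = fret, del = 0.0;
    int ibig = 0;
    for (int i = 0; i < n; ++i) {
      double fptt = fret;
      linmin(fn, p, xi[i], fret, line_tol, line_itmax);
      if (fptt - fret > del) { del = fptt - fret; ibig = i; }
      if (fn.n_eval > max_eval) break;
    }
    if (2.0 * (fp - fret) <= ftol * (std::fabs(fp) + std::fabs(fret)) + 1e-25) {
      converged = true;
      break;
    }
    if (fn.n_eval > max_eval) break;
    for (int i = 0; i < n; ++i) {
      ptt[i] = 2.0 * p[i] - p0[i];
      xit[i] = p[i] - p0[i];
      p0[i] = p[i];
    }
    double fptt = fn(ptt.data());
    if (fptt < fp) {
      double t = 2.0 * (fp - 2.0 * fret + fptt) *
                 (fp - fret - del) * (fp - fret - del) -
                 del * (fp - fptt) * (fp - fptt);
      if (t < 0.0) {
        linmin(fn, p, xit, fret, line_tol, line_itmax);
        xi[ibig] = xi[n - 1];
        xi[n - 1] = xit;
      }
    }
  }

  return List::create(_["par"] = NumericVector(p.begin(), p.end()),
                      _["f_global"] = fret,
                      _["n_eval"] = (double) fn.n_eval,
                      _["n_iter"] = iter,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
NumericVector cpp_global_error(NumericMatrix img, NumericVector par,
                               NumericMatrix D, double a_nuc, double w_nuc,
                               double trunc_q = 1e12) {
  int n = par.size();
  if (n % 6 != 0) stop("parameter vector length must be a multiple of 6");
  GmmObjective fn(img, D, a_nuc, w_nuc, n / 6, trunc_q);
  std::vector<double> p(par.begin(), par.end());
  double fg = fn(p.data());
  return NumericVector::create(_["f_global"] = fg);
}
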