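#include <Rcpp.h>
using namespace Rcpp;

// Standard bivariate normal CDF P(X <= h, Y <= k) with correlation rho,
// via Sheppard's single integral
//   Phi2(h,k,rho) = Phi(h)Phi(k)
//     + (1/2pi) * Int_0^{asin(rho)} exp(-(h^2 - 2 h k sin t + k^2)
//                                        / (2 cos^2 t)) dt
// evaluated with 64-point Gauss-Legendre. Accurate to ~1e-10 for
// |rho| <= 0.999, which covers the clamped polychoric search range.

static const int GL_N = 32;  // nodes per half (64 total via symmetry)

static void gl_nodes(double* xg, double* wg) {
  // Newton iteration on Legendre polynomials for the 64-point rule
  const int n = 2 * GL_N;
  for (int i = 0; i < GL_N; i++) {
    double x = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double x0, p0, p1, p2, dp;
    do {
      p0 = 1.0; p1 = x;
      for (int j = 2; j <= n; j++) {
        p2 = ((2.0 * j - 1.0) * x * p1 - (j - 1.0) * p0) / j;
        p0 = p1; p1 = p2;
      }
      dp = n * (x * p1 - p0) / (x * x - 1.0);
      x0 = x;
      x = x0 - p1 / dp;
    } while (std::fabs(x - x0) > 1e-14);
    xg[i] = x;
    wg[i] = 2.0 / ((1.0 - x * x) * dp * dp);
  }
}

// [[Rcpp::export]]
double pbinorm_cpp(double h, double k, double rho) {
  if (rho < -0.99999) rho = -0.99999;
  if (rho >  0.99999) rho =  0.99999;
  if (!R_FINITE(h) || !R_FINITE(k)) {
    if (h == R_NegInf || k == R_NegInf) return 0.0;
    if (h == R_PosInf) return R::pnorm(k, 0.0, 1.0, 1, 0);
    if (k == R_PosInf) return R::pnorm(h, 0.0, 1.0, 1, 0);
  }
  static double xg[GL_N], wg[GL_N];
  static bool init = false;
  if (!init) { gl_nodes(xg, wg); init = true; }

  double upper = std::asin(rho);
  double mid = upper / 2.0, half = upper / 2.0;
  double sum = 0.0;
  for (int i = 0; i < GL_N; i++) {
    for (int s = -1; s <= 1; s += 2) {
      double t = mid + s * half * xg[i];
      double ct2 = std::cos(t); ct2 *= ct2;
      double e = std::exp(-(h * h - 2.0 * h * k * std::sin(t) + k * k)
                          / (2.0 * ct2));
      sum += wg[i] * e;
    }
  }
  sum *= half / (2.0 * M_PI);
  double p = R::pnorm(h, 0, 1, 1, 0) * R::pnorm(k, 0, 1, 1, 0) + sum;
  if (p < 0) p = 0;
  if (p > 1) p = 1;
  return p;
}

// Rectangle probability P(a1 < X <= a2, b1 < Y <= b2) under the standard
// bivariate normal; bounds may be +/-Inf.
// [[Rcpp::export]]
double binorm_rect_cpp(double a1, double a2, double b1, double b2,
                       double rho) {
  double p = pbinorm_cpp(a2, b2, rho) - pbinorm_cpp(a1, b2, rho)
           - pbinorm_cpp(a2, b1, rho) + pbinorm_cpp(a1, b1, rho);
  return p < 0 ? 0 : p;
}

// Negative log-likelihood of an ordinal contingency table under the
// latent bivariate normal with fixed thresholds; used by the polychoric
// rho search.
// [[Rcpp::export]]
double polychoric_negll_cpp(NumericMatrix tab, NumericVector tx,
                            NumericVector ty, double rho) {
  int R_ = tab.nrow(), C_ = tab.ncol();
  std::vector<double> cx(R_ + 1), cy(C_ + 1);
  cx[0] = R_NegInf; cx[R_] = R_PosInf;
  cy[0] = R_NegInf; cy[C_] = R_PosInf;
  for (int i = 1; i < R_; i++) cx[i] = tx[i - 1];
  for (int j = 1; j < C_; j++) cy[j] = ty[j - 1];
  double nll = 0.0;
  for (int i = 0; i < R_; i++) {
    for (int j = 0; j < C_; j++) {
      double n = tab(i, j);
      if (n <= 0) continue;
      double p = binorm_rect_cpp(cx[i], cx[i + 1], cy[j], cy[j + 1], rho);
      if (p < 1e-300) p = 1e-300;
      nll -= n * std::log(p);
    }
  }
  return nll;
}
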