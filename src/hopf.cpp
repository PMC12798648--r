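#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Euler-Maruyama integration of N coupled Stuart-Landau oscillators in
// Cartesian form.  For node j with bifurcation a_j, angular frequency w_j
// (rad/s) and per-node coupling scale g_j acting on the incoming difference
// coupling through the structural matrix C:
//
//   dx_j = [(a_j - x_j^2 - y_j^2) x_j - w_j y_j
//            + g_j * sum_i C_ij (x_i - x_j) + F0 cos(w0 t) * 1{j = forced}] dt
//            + beta sqrt(dt) eta
//   dy_j = [(a_j - x_j^2 - y_j^2) y_j + w_j x_j
//            + g_j * sum_i C_ij (y_i - y_j)] dt + beta sqrt(dt) eta'
//
// The additive periodic forcing enters the real part only.  Noise draws come
// from R's RNG (norm_rand), so set.seed() upstream makes runs bit-identical.
// The real and imaginary parts are carried as the two columns of one N x 2
// state matrix so the coupling term is a single GEMM per step.
//
// Output: n_keep x N matrix of x, sampled every `decim` steps after
// discarding `n_burn` integration steps.

// [[Rcpp::export(name = ".hopf_integrate")]]
arma::mat hopf_integrate(const arma::vec& a,
                         const arma::vec& g,
                         const arma::vec& omega,
                         const arma::mat& C,
                         const double beta,
                         const double dt,
                         const int n_burn,
                         const int n_keep,
                         const int decim,
                         const int force_node,   // 1-based; 0 = none
                         const double force_amp,
                         const double force_freq) {
  const arma::uword N = a.n_elem;
  if (C.n_rows != N || C.n_cols != N)
    stop("structural matrix dimension does not match parameter length");

  arma::mat S(N, 2);
  for (arma::uword j = 0; j < N; ++j) {
    S(j, 0) = 0.01 * norm_rand();
    S(j, 1) = 0.01 * norm_rand();
  }

  const arma::vec rowsum = arma::sum(C, 1);
  const double sdt = beta * std::sqrt(dt);
  const int fj = force_node - 1;
  const int n_steps = n_burn + n_keep * decim;

  arma::mat out(n_keep, N);
  arma::mat CS(N, 2);
  int kept = 0;

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const double force = (fj >= 0) ? force_amp * std::cos(force_freq * t) : 0.0;
    CS = C * S;
    double guard = 0.0;
    for (arma::uword j = 0; j < N; ++j) {
      const double x = S(j, 0), y = S(j, 1);
      const double shrink = a[j] - x * x - y * y;
      double dx = shrink * x - omega[j] * y + g[j] * (CS(j, 0) - rowsum[j] * x);
      double dy = shrink * y + omega[j] * x + g[j] * (CS(j, 1) - rowsum[j] * y);
      if ((int)j == fj) dx += force;
      const double xn = x + dt * dx + sdt * norm_rand();
      const double yn = y + dt * dy + sdt * norm_rand();
      S(j, 0) = xn;
      S(j, 1) = yn;
      guard = std::max(guard, std::max(std::abs(xn), std::abs(yn)));
    }
    if (guard > 1e6)
      stop("numerical blow-up during integration (|state| > 1e6); use a smaller dt");
    if (s >= n_burn && ((s - n_burn) % decim) == (decim - 1)) {
      out.row(kept) = S.col(0).t();
      ++kept;
    }
  }
  return out;
}

// Zero-phase forward-backward IIR filtering of each column of X with the
// transfer function b/a (Direct Form II transposed).  Edges are handled by
// odd-reflection padding of 3 * (n_coef - 1) samples at both ends, so the
// two passes leave no phase lag and only small edge transients.

static void df2t_filter(const std::vector<double>& b,
                        const std::vector<double>& a,
                        std::vector<double>& x) {
  const size_t n = x.size(), nc = b.size();
  std::vector<double> z(nc - 1, 0.0);
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (size_t k = 1; k < nc - 1; ++k)
      z[k - 1] = b[k] * xi + z[k] - a[k] * yi;
    z[nc - 2] = b[nc - 1] * xi - a[nc - 1] * yi;
    x[i] = yi;
  }
}

// [[Rcpp::export(name = ".iir_filtfilt")]]
arma::mat iir_filtfilt(const std::vector<double>& b,
                       const std::vector<double>& a,
                       const arma::mat& X) {
  const arma::uword T = X.n_rows, N = X.n_cols;
  const int npad = 3 * ((int)std::max(a.size(), b.size()) - 1);
  if ((int)T <= npad + 1)
    stop("series too short for zero-phase filtering");
  arma::mat out(T, N);
  std::vector<double> buf(T + 2 * npad);
  for (arma::uword j = 0; j < N; ++j) {
    // odd reflection padding
    for (int i = 0; i < npad; ++i)
      buf[i] = 2.0 * X(0, j) - X(npad - i, j);
    for (arma::uword i = 0; i < T; ++i)
      buf[npad + i] = X(i, j);
    for (int i = 0; i < npad; ++i)
      buf[npad + T + i] = 2.0 * X(T - 1, j) - X(T - 2 - i, j);
    df2t_filter(b, a, buf);
    std::reverse(buf.begin(), buf.end());
    df2t_filter(b, a, buf);
    std::reverse(buf.begin(), buf.end());
    for (arma::uword i = 0; i < T; ++i)
      out(i, j) = buf[npad + i];
  }
  return out;
}
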