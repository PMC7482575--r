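// Time-stepping cores for the VN and AE models.
//
// Noise is drawn from R's RNG (unif_rand) one value per agent per step,
// in agent order, so the R single-step reference implementations consume
// an identical stream and trajectories match bitwise for a given seed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_angle(double t) {
  // wrap to (-pi, pi]
  double w = t + M_PI;
  w -= 2.0 * M_PI * std::floor(w / (2.0 * M_PI));
  if (w <= 0.0) w += 2.0 * M_PI;
  return w - M_PI;
}

static inline double polarization_of(const std::vector<double>& cx,
                                     const std::vector<double>& cy) {
  double sx = 0.0, sy = 0.0;
  const int n = cx.size();
  for (int i = 0; i < n; ++i) { sx += cx[i]; sy += cy[i]; }
  return std::sqrt(sx * sx + sy * sy) / n;
}

// Vicsek-Network run. adj_ptr / adj_idx: 0-based CSR adjacency (self not
// included; the update adds the focal agent's own unit vector). Returns
// the polarization at steps 0, stride, 2*stride, ... and the final
// headings.
// [[Rcpp::export]]
List vn_run_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                NumericVector theta0, double eta, int n_steps, int stride) {
  const int n = theta0.size();
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> tnew(n), cx(n), cy(n);
  const int n_rec = n_steps / stride + 1;
  NumericVector psi(n_rec);
  IntegerVector psi_step(n_rec);
  RNGScope scope;

  for (int i = 0; i < n; ++i) { cx[i] = std::cos(theta[i]); cy[i] = std::sin(theta[i]); }
  psi[0] = polarization_of(cx, cy);
  psi_step[0] = 0;
  int rec = 1;

  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double sx = cx[i], sy = cy[i]; // self-inclusion
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) {
        const int j = adj_idx[e];
        sx += cx[j]; sy += cy[j];
      }
      double ang;
      if (std::fabs(sx) < 1e-14 && std::fabs(sy) < 1e-14)
        ang = theta[i]; // exact cancellation: keep previous heading
      else
        ang = std::atan2(sy, sx);
      tnew[i] = ang;
    }
    for (int i = 0; i < n; ++i) {
      const double xi = unif_rand() - 0.5;
      theta[i] = wrap_angle(tnew[i] + eta * xi);
    }
    for (int i = 0; i < n; ++i) { cx[i] = std::cos(theta[i]); cy[i] = std::sin(theta[i]); }
    if (t % stride == 0) {
      psi[rec] = polarization_of(cx, cy);
      psi_step[rec] = t;
      ++rec;
    }
  }
  return List::create(_["psi"] = psi, _["step"] = psi_step,
                      _["theta"] = NumericVector(theta.begin(), theta.end()));
}

// Active-Elastic run (overdamped forward Euler). edges: K x 2, 0-based;
// rest: natural spring lengths per edge. Coincident linked agents
// contribute zero force for that step (direction undefined); the count
// of such skips is returned.
// [[Rcpp::export]]
List ae_run_cpp(NumericVector x0, NumericVector y0, NumericVector theta0,
                IntegerMatrix edges, NumericVector rest,
                double v0, double alpha, double beta, double kappa,
                double eta, double dt, int n_steps, int stride) {
  const int n = theta0.size();
  const int K = edges.nrow();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> fx(n), fy(n), cx(n), cy(n);
  const int n_rec = n_steps / stride + 1;
  NumericVector psi(n_rec);
  IntegerVector psi_step(n_rec);
  int skipped = 0;
  RNGScope scope;

  for (int i = 0; i < n; ++i) { cx[i] = std::cos(theta[i]); cy[i] = std::sin(theta[i]); }
  psi[0] = polarization_of(cx, cy);
  psi_step[0] = 0;
  int rec = 1;

  for (int t = 1; t <= n_steps; ++t) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int e = 0; e < K; ++e) {
      const int i = edges(e, 0), j = edges(e, 1);
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < 1e-12) { ++skipped; continue; }
      const double f = kappa * (d - rest[e]) / d;
      fx[i] += f * dx; fy[i] += f * dy;
      fx[j] -= f * dx; fy[j] -= f * dy;
    }
    for (int i = 0; i < n; ++i) {
      const double nx = cx[i], ny = cy[i];
      const double fpar = fx[i] * nx + fy[i] * ny;
      const double fperp = -fx[i] * ny + fy[i] * nx; // n_perp = (-sin, cos)
      const double sp = v0 + alpha * fpar;
      x[i] += dt * sp * nx;
      y[i] += dt * sp * ny;
      const double xi = unif_rand() - 0.5;
      theta[i] = wrap_angle(theta[i] + dt * (beta * fperp + eta * xi));
    }
    for (int i = 0; i < n; ++i) { cx[i] = std::cos(theta[i]); cy[i] = std::sin(theta[i]); }
    if (t % stride == 0) {
      const double p = polarization_of(cx, cy);
      if (!std::isfinite(p))
        stop("numerical blow-up: non-finite state at step %d", t);
      psi[rec] = p;
      psi_step[rec] = t;
      ++rec;
    }
  }
  return List::create(_["psi"] = psi, _["step"] = psi_step,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["theta"] = NumericVector(theta.begin(), theta.end()),
                      _["skipped_pairs"] = skipped);
}
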