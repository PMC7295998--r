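#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of diffusively coupled Stuart-Landau
// oscillators:
//   dx_j = ([a_j - x_j^2 - y_j^2] x_j - w_j y_j + G sum_i D_ij (x_i - x_j)) dt
//          + xi sqrt(dt) N(0,1)
//   dy_j = ([a_j - x_j^2 - y_j^2] y_j + w_j x_j + G sum_i D_ij (y_i - y_j)) dt
//          + xi sqrt(dt) N(0,1)
// Noise is drawn independently for x and y. Uses R's RNG so set.seed()
// controls reproducibility.
// [[Rcpp::export]]
List hopf_euler(NumericVector a, NumericVector omega, double G, double xi,
                NumericMatrix D, double dt, int n_steps,
                NumericVector x0, NumericVector y0, int store_every) {
  int n = a.size();
  if (omega.size() != n || x0.size() != n || y0.size() != n ||
      D.nrow() != n || D.ncol() != n)
    stop("dimension mismatch in hopf_euler inputs");
  int n_store = n_steps / store_every;
  NumericMatrix xs(n, n_store), ys(n, n_store);
  std::vector<double> x(n), y(n), strength(n), cx(n), cy(n);
  for (int j = 0; j < n; ++j) {
    x[j] = x0[j];
    y[j] = y0[j];
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, j);
    strength[j] = s;
  }
  double sq_dt = std::sqrt(dt);
  int stored = 0;
  bool coupled = (G != 0.0);
  for (int step = 1; step <= n_steps; ++step) {
    if (coupled) {
      for (int j = 0; j < n; ++j) {
        double sx = 0.0, sy = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = D(i, j);
          if (d != 0.0) {
            sx += d * x[i];
            sy += d * y[i];
          }
        }
        cx[j] = G * (sx - strength[j] * x[j]);
        cy[j] = G * (sy - strength[j] * y[j]);
      }
    } else {
      std::fill(cx.begin(), cx.end(), 0.0);
      std::fill(cy.begin(), cy.end(), 0.0);
    }
    NumericVector etax = (xi > 0.0) ? rnorm(n) : NumericVector(n);
    NumericVector etay = (xi > 0.0) ? rnorm(n) : NumericVector(n);
    for (int j = 0; j < n; ++j) {
      double r2 = x[j] * x[j] + y[j] * y[j];
      double drift = a[j] - r2;
      double nx = x[j] + dt * (drift * x[j] - omega[j] * y[j] + cx[j]) +
                  xi * sq_dt * etax[j];
      double ny = y[j] + dt * (drift * y[j] + omega[j] * x[j] + cy[j]) +
                  xi * sq_dt * etay[j];
      x[j] = nx;
      y[j] = ny;
      if (nx * nx + ny * ny > 1e6)
        stop("numerical blow-up (|u| > 1e3); use a smaller dt");
    }
    if (step % store_every == 0) {
      for (int j = 0; j < n; ++j) {
        xs(j, stored) = x[j];
        ys(j, stored) = y[j];
      }
      ++stored;
    }
  }
  return List::create(Named("x") = xs, Named("y") = ys);
}
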