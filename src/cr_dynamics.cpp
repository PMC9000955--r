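// Core serial-dilution consumer-resource integrator.
//
// Batch dynamics:  dX_i/dt =  X_i sum_j R_ij f(Y_j)
//                  dY_j/dt = -f(Y_j) sum_i R_ij X_i
// with f(Y) = Y (linear kinetics) or f(Y) = Y/(Ys+Y) (Monod saturation).
// Growth and consumption share f, so sum(X) + sum(Y) is exactly conserved.
//
// A batch runs until every resource is depleted below ytol; a sampling
// interval repeats [grow -> dilute by D -> replenish] until the per-consumer
// growth ratios stabilize to within steady_frac * D between cycles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double X_FLOOR = 1e-300;

static inline void cr_deriv(const vec &X, const vec &Y, const mat &R,
                            double Ys, vec &dX, vec &dY) {
  if (Ys > 0.0) {
    vec phi = Y / (Ys + Y);
    dX = X % (R * phi);
    dY = -phi % (R.t() * X);
  } else {
    dX = X % (R * Y);
    dY = -Y % (R.t() * X);
  }
}

// Dormand-Prince 5(4) with FSAL, PI-free standard step control.
// State is (X, Y) concatenated conceptually but kept as two vectors.
struct BatchResult {
  vec X;
  vec Y;
  long n_steps;
};

static BatchResult integrate_batch_core(vec X, vec Y, const mat &R, double Ys,
                                        double rtol, double atol, double ytol,
                                        long max_steps, bool strict) {
  const uword N = X.n_elem, M = Y.n_elem;

  // A resource consumed by nobody is stationary (dY/dt = 0): it can never
  // be depleted, but it also never settles further. Under the literal
  // stopping rule (dY/dt = 0 for all j) such inert resources are already
  // settled and are excluded from the depletion criterion; with `strict`
  // they are an error instead.
  rowvec colrate = sum(R, 0);
  uvec active = find(colrate > 0.0);
  if (strict) {
    for (uword j = 0; j < M; ++j) {
      if (Y(j) >= ytol && colrate(j) <= 0.0)
        Rcpp::stop("undepletable resource: resource %d has positive amount "
                   "but no consumer with a positive consumption rate",
                   (int)(j + 1));
    }
  }
  if (active.n_elem == 0 || vec(Y(active)).max() < ytol) return {X, Y, 0};

  // Dormand-Prince coefficients.
  const double a21 = 1.0 / 5;
  const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
               a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
               b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
               e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  vec k1X(N), k1Y(M), k2X(N), k2Y(M), k3X(N), k3Y(M), k4X(N), k4Y(M);
  vec k5X(N), k5Y(M), k6X(N), k6Y(M), k7X(N), k7Y(M);
  vec Xs(N), Ys_(M), Xn(N), Yn(M);

  cr_deriv(X, Y, R, Ys, k1X, k1Y);

  // Initial step: crude inverse of the fastest relative rate.
  double rate = 0.0;
  for (uword i = 0; i < N; ++i)
    rate = std::max(rate, std::abs(k1X(i)) / (std::abs(X(i)) + atol));
  for (uword j = 0; j < M; ++j)
    rate = std::max(rate, std::abs(k1Y(j)) / (std::abs(Y(j)) + atol));
  double h = (rate > 0.0) ? 0.01 / rate : 1e-6;

  long steps = 0;
  while (true) {
    if (++steps > max_steps)
      Rcpp::stop("batch integration exceeded the step budget (%ld steps)",
                 max_steps);
    if (h < 1e-14)
      Rcpp::stop("batch integration step size underflow");

    Xs = X + h * a21 * k1X;                 Ys_ = Y + h * a21 * k1Y;
    cr_deriv(Xs, Ys_, R, Ys, k2X, k2Y);
    Xs = X + h * (a31 * k1X + a32 * k2X);   Ys_ = Y + h * (a31 * k1Y + a32 * k2Y);
    cr_deriv(Xs, Ys_, R, Ys, k3X, k3Y);
    Xs = X + h * (a41 * k1X + a42 * k2X + a43 * k3X);
    Ys_ = Y + h * (a41 * k1Y + a42 * k2Y + a43 * k3Y);
    cr_deriv(Xs, Ys_, R, Ys, k4X, k4Y);
    Xs = X + h * (a51 * k1X + a52 * k2X + a53 * k3X + a54 * k4X);
    Ys_ = Y + h * (a51 * k1Y + a52 * k2Y + a53 * k3Y + a54 * k4Y);
    cr_deriv(Xs, Ys_, R, Ys, k5X, k5Y);
    Xs = X + h * (a61 * k1X + a62 * k2X + a63 * k3X + a64 * k4X + a65 * k5X);
    Ys_ = Y + h * (a61 * k1Y + a62 * k2Y + a63 * k3Y + a64 * k4Y + a65 * k5Y);
    cr_deriv(Xs, Ys_, R, Ys, k6X, k6Y);

    Xn = X + h * (b1 * k1X + b3 * k3X + b4 * k4X + b5 * k5X + b6 * k6X);
    Yn = Y + h * (b1 * k1Y + b3 * k3Y + b4 * k4Y + b5 * k5Y + b6 * k6Y);
    cr_deriv(Xn, Yn, R, Ys, k7X, k7Y);

    // Error estimate against the embedded 4th-order solution.
    double err2 = 0.0;
    for (uword i = 0; i < N; ++i) {
      double e = h * (e1 * k1X(i) + e3 * k3X(i) + e4 * k4X(i) + e5 * k5X(i) +
                      e6 * k6X(i) + e7 * k7X(i));
      double sc = atol + rtol * std::max(std::abs(X(i)), std::abs(Xn(i)));
      err2 += (e / sc) * (e / sc);
    }
    for (uword j = 0; j < M; ++j) {
      double e = h * (e1 * k1Y(j) + e3 * k3Y(j) + e4 * k4Y(j) + e5 * k5Y(j) +
                      e6 * k6Y(j) + e7 * k7Y(j));
      double sc = atol + rtol * std::max(std::abs(Y(j)), std::abs(Yn(j)));
      err2 += (e / sc) * (e / sc);
    }
    double err = std::sqrt(err2 / (N + M));

    if (err <= 1.0) {
      X = Xn;
      Y = Yn;
      // Clamp each resource to zero once it crosses the depletion
      // threshold (it would otherwise keep decaying exponentially and pin
      // the step size far below the remaining dynamics' time scale).
      bool clamped = false;
      for (uword j = 0; j < M; ++j) {
        if (colrate(j) > 0.0 && Y(j) < ytol && Y(j) != 0.0) {
          Y(j) = 0.0;
          clamped = true;
        }
      }
      if (vec(Y(active)).max() < ytol) break;
      if (clamped) {
        cr_deriv(X, Y, R, Ys, k1X, k1Y);
      } else {  // FSAL
        k1X = k7X;
        k1Y = k7Y;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    h *= std::min(5.0, std::max(0.2, fac));
  }
  return {X, Y, steps};
}

// [[Rcpp::export(name = ".cr_batch_cpp")]]
Rcpp::List cr_batch_cpp(arma::vec X, arma::vec Y, const arma::mat &R,
                        double Ys, double rtol, double atol, double ytol,
                        long max_steps, bool strict) {
  BatchResult out = integrate_batch_core(X, Y, R, Ys, rtol, atol, ytol,
                                         max_steps, strict);
  return Rcpp::List::create(Rcpp::Named("X") = out.X,
                            Rcpp::Named("Y") = out.Y,
                            Rcpp::Named("n_steps") = (double)out.n_steps);
}

struct SteadyResult {
  vec x;
  vec growth_ratios;
  int n_cycles;      // growth cycles performed (>= 2)
  double generations; // cumulative log2 community growth over the
                      // dilution-initiated cycles (cycles 2..n_cycles)
};

static SteadyResult run_steady_core(const mat &R, const vec &Y0, double D,
                                    double steady_frac, double reservoir,
                                    double Ys, double rtol, double atol,
                                    double ytol_frac, int cycles_max,
                                    long max_steps) {
  const uword N = R.n_rows;
  double supply = accu(Y0);
  if (!(supply > 0.0)) Rcpp::stop("total resource supply must be positive");
  double ytol = ytol_frac * Y0.max();

  // Reservoir seeding: all consumers at equal abundance, sized so that the
  // serial-dilution fixed point has growth ratio exactly D.
  double x_total0 = reservoir * supply / (D - 1.0);
  vec X(N, fill::value(x_total0 / N));

  vec g_prev(N, fill::zeros);
  double generations = 0.0;
  for (int c = 1; c <= cycles_max; ++c) {
    vec X_init = X;
    for (uword i = 0; i < N; ++i)
      if (X_init(i) < X_FLOOR) X_init(i) = X_FLOOR;
    BatchResult b = integrate_batch_core(X_init, Y0, R, Ys, rtol, atol, ytol,
                                         max_steps, false);
    vec g = b.X / X_init;
    if (c >= 2) generations += std::log2(accu(b.X) / accu(X_init));
    if (c >= 2 && abs(g - g_prev).max() < steady_frac * D) {
      vec x = b.X / accu(b.X);
      return {x, g, c, generations};
    }
    g_prev = g;
    X = b.X / D;
  }
  uword worst = abs(g_prev).index_max();
  Rcpp::stop("steady state not reached within %d dilution cycles "
             "(worst-converging consumer: %d)", cycles_max, (int)(worst + 1));
}

// [[Rcpp::export(name = ".cr_steady_cpp")]]
Rcpp::List cr_steady_cpp(const arma::mat &R, const arma::vec &Y0, double D,
                         double steady_frac, double reservoir, double Ys,
                         double rtol, double atol, double ytol_frac,
                         int cycles_max, long max_steps) {
  SteadyResult out = run_steady_core(R, Y0, D, steady_frac, reservoir, Ys,
                                     rtol, atol, ytol_frac, cycles_max,
                                     max_steps);
  return Rcpp::List::create(Rcpp::Named("x") = out.x,
                            Rcpp::Named("growth_ratios") = out.growth_ratios,
                            Rcpp::Named("n_cycles") = out.n_cycles,
                            Rcpp::Named("generations") = out.generations);
}

// Whole sampling series: one steady-state community per supply column.
// [[Rcpp::export(name = ".cr_series_cpp")]]
Rcpp::List cr_series_cpp(const arma::mat &R, const arma::mat &supply, double D,
                         double steady_frac, double reservoir, double Ys,
                         double rtol, double atol, double ytol_frac,
                         int cycles_max, long max_steps) {
  const uword N = R.n_rows, T = supply.n_cols;
  mat x(N, T);
  ivec ncyc(T);
  vec gens(T);
  for (uword t = 0; t < T; ++t) {
    SteadyResult out = run_steady_core(R, supply.col(t), D, steady_frac,
                                       reservoir, Ys, rtol, atol, ytol_frac,
                                       cycles_max, max_steps);
    x.col(t) = out.x;
    ncyc(t) = out.n_cycles;
    gens(t) = out.generations;
    if (t % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("n_cycles") = ncyc,
                            Rcpp::Named("generations") = gens);
}
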