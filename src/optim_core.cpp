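#include <Rcpp.h>
using namespace Rcpp;

// Tight inner loops for the three from-scratch optimizers fitting the
// two-parameter linear model H(x) = theta0 + theta1 * x by minimising
// Q(theta0, theta1) = (1/m) * sum_i (theta0 + theta1 x_i - y_i)^2.
//
// All randomness (parameter initialisation, per-epoch shuffles) is drawn on
// the R side and passed in, so a pure-R transcription of the update rules
// can replay these loops step for step.

// Full-data objective and gradient; gradient is
// ((2/m) sum r_i, (2/m) sum x_i r_i) with r_i the residual.
static void objective_grad(const NumericVector &x, const NumericVector &y,
                           double t0, double t1,
                           double &Q, double &g0, double &g1) {
  const int m = x.size();
  double q = 0.0, s0 = 0.0, s1 = 0.0;
  for (int i = 0; i < m; ++i) {
    const double r = t0 + t1 * x[i] - y[i];
    q += r * r;
    s0 += r;
    s1 += r * x[i];
  }
  Q = q / m;
  g0 = 2.0 * s0 / m;
  g1 = 2.0 * s1 / m;
}

static List finish(double t0, double t1, int epochs, double gnorm,
                   bool converged, const std::vector<double> &trace,
                   int diverged_epoch) {
  return List::create(
      _["theta0"] = t0, _["theta1"] = t1, _["epochs_run"] = epochs,
      _["final_grad_norm"] = gnorm, _["converged"] = converged,
      _["objective_trace"] = NumericVector(trace.begin(), trace.end()),
      _["diverged_epoch"] = diverged_epoch);
}

// order: m x max_iters matrix of 1-based indices, column e = shuffle of
// epoch e. Stopping rule (shared by all three cores): after each full pass,
// stop when the Euclidean norm of the full-data gradient drops to grad_tol
// or the epoch budget is spent.

// [[Rcpp::export(name = ".sgd_core")]]
List sgd_core(NumericVector x, NumericVector y, double t0, double t1,
              double eta, int max_iters, double grad_tol,
              IntegerMatrix order) {
  const int m = x.size();
  std::vector<double> trace;
  trace.reserve(max_iters);
  double Q, g0, g1, gnorm = R_PosInf;
  int epochs = 0;
  for (int e = 0; e < max_iters; ++e) {
    for (int k = 0; k < m; ++k) {
      const int i = order(k, e) - 1;
      // simultaneous update: both coordinates use the start-of-step theta
      const double r = t0 + t1 * x[i] - y[i];
      t0 -= eta * 2.0 * r;
      t1 -= eta * 2.0 * r * x[i];
    }
    epochs = e + 1;
    if (!R_finite(t0) || !R_finite(t1))
      return finish(t0, t1, epochs, R_PosInf, false, trace, epochs);
    objective_grad(x, y, t0, t1, Q, g0, g1);
    trace.push_back(Q);
    gnorm = std::sqrt(g0 * g0 + g1 * g1);
    if (gnorm <= grad_tol) break;
  }
  return finish(t0, t1, epochs, gnorm, gnorm <= grad_tol, trace, NA_INTEGER);
}

// Mini-batch gradient (2/|S|) sum over the batch.
static void batch_grad(const NumericVector &x, const NumericVector &y,
                       const IntegerMatrix &order, int epoch, int from,
                       int to, double t0, double t1, double &g0, double &g1) {
  double s0 = 0.0, s1 = 0.0;
  for (int k = from; k < to; ++k) {
    const int i = order(k, epoch) - 1;
    const double r = t0 + t1 * x[i] - y[i];
    s0 += r;
    s1 += r * x[i];
  }
  const double n = to - from;
  g0 = 2.0 * s0 / n;
  g1 = 2.0 * s1 / n;
}

// [[Rcpp::export(name = ".rmsprop_core")]]
List rmsprop_core(NumericVector x, NumericVector y, double t0, double t1,
                  double eta, int max_iters, double grad_tol, double beta,
                  double eps, int batch_size, IntegerMatrix order) {
  const int m = x.size();
  std::vector<double> trace;
  trace.reserve(max_iters);
  double Q, g0, g1, gnorm = R_PosInf;
  double v0 = 0.0, v1 = 0.0;
  int epochs = 0;
  for (int e = 0; e < max_iters; ++e) {
    for (int from = 0; from < m; from += batch_size) {
      const int to = std::min(from + batch_size, m);
      batch_grad(x, y, order, e, from, to, t0, t1, g0, g1);
      v0 = beta * v0 + (1.0 - beta) * g0 * g0;
      v1 = beta * v1 + (1.0 - beta) * g1 * g1;
      // epsilon sits inside the square root for this optimizer
      t0 -= eta / std::sqrt(v0 + eps) * g0;
      t1 -= eta / std::sqrt(v1 + eps) * g1;
    }
    epochs = e + 1;
    if (!R_finite(t0) || !R_finite(t1))
      return finish(t0, t1, epochs, R_PosInf, false, trace, epochs);
    objective_grad(x, y, t0, t1, Q, g0, g1);
    trace.push_back(Q);
    gnorm = std::sqrt(g0 * g0 + g1 * g1);
    if (gnorm <= grad_tol) break;
  }
  return finish(t0, t1, epochs, gnorm, gnorm <= grad_tol, trace, NA_INTEGER);
}

// [[Rcpp::export(name = ".adam_core")]]
List adam_core(NumericVector x, NumericVector y, double t0, double t1,
               double eta, int max_iters, double grad_tol, double beta1,
               double beta2, double eps, int batch_size, bool time_scaled,
               IntegerMatrix order) {
  const int m = x.size();
  std::vector<double> trace;
  trace.reserve(max_iters);
  double Q, g0, g1, gnorm = R_PosInf;
  double m0 = 0.0, m1 = 0.0, v0 = 0.0, v1 = 0.0;
  long long t = 0;
  int epochs = 0;
  for (int e = 0; e < max_iters; ++e) {
    for (int from = 0; from < m; from += batch_size) {
      const int to = std::min(from + batch_size, m);
      batch_grad(x, y, order, e, from, to, t0, t1, g0, g1);
      ++t;
      m0 = beta1 * m0 + (1.0 - beta1) * g0;
      m1 = beta1 * m1 + (1.0 - beta1) * g1;
      v0 = beta2 * v0 + (1.0 - beta2) * g0 * g0;
      v1 = beta2 * v1 + (1.0 - beta2) * g1 * g1;
      // bias correction: either the literal constant denominators
      // (1 - beta) or the reference time-scaled (1 - beta^t)
      const double c1 = time_scaled ? 1.0 - std::pow(beta1, (double)t)
                                    : 1.0 - beta1;
      const double c2 = time_scaled ? 1.0 - std::pow(beta2, (double)t)
                                    : 1.0 - beta2;
      const double mh0 = m0 / c1, mh1 = m1 / c1;
      const double vh0 = v0 / c2, vh1 = v1 / c2;
      // epsilon sits outside the square root here
      t0 -= eta / (std::sqrt(vh0) + eps) * mh0;
      t1 -= eta / (std::sqrt(vh1) + eps) * mh1;
    }
    epochs = e + 1;
    if (!R_finite(t0) || !R_finite(t1))
      return finish(t0, t1, epochs, R_PosInf, false, trace, epochs);
    objective_grad(x, y, t0, t1, Q, g0, g1);
    trace.push_back(Q);
    gnorm = std::sqrt(g0 * g0 + g1 * g1);
    if (gnorm <= grad_tol) break;
  }
  return finish(t0, t1, epochs, gnorm, gnorm <= grad_tol, trace, NA_INTEGER);
}
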