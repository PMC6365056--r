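#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of a constant-drift diffusion between an
// absorbing lower bound at 0 and upper bound at a, started at z.
// Per-step increment: mu*dt + s*sqrt(dt)*N(0,1).
// Returns, per trial, the absorbing boundary (+1 upper, -1 lower, 0 none
// within t_max) and the decision time (NA when no crossing). Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(int n, double mu, double a, double z, double s,
                 double dt, double t_max) {
  if (n < 0) stop("n must be non-negative");
  if (dt <= 0) stop("dt must be positive");
  if (a <= 0) stop("boundary separation must be positive");
  if (z <= 0 || z >= a) stop("starting point must lie strictly between bounds");
  IntegerVector bound(n);
  NumericVector dtime(n);
  const double drift = mu * dt;
  const double sig = s * std::sqrt(dt);
  const long max_steps = (long)std::ceil(t_max / dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double y = z;
    long step = 0;
    int b = 0;
    while (step < max_steps) {
      ++step;
      y += drift + sig * norm_rand();
      if (y >= a) { b = 1; break; }
      if (y <= 0) { b = -1; break; }
    }
    bound[i] = b;
    dtime[i] = (b == 0) ? NA_REAL : step * dt;
  }
  return List::create(_["bound"] = bound, _["dtime"] = dtime);
}

// Same process but with a per-trial drift vector (used when the drift bias
// is modulated trial by trial, e.g. coupled to a neural scalar).
// [[Rcpp::export(name = ".ddm_sim_vec_cpp")]]
List ddm_sim_vec_cpp(NumericVector mu, double a, double z, double s,
                     double dt, double t_max) {
  const int n = mu.size();
  if (dt <= 0) stop("dt must be positive");
  if (a <= 0) stop("boundary separation must be positive");
  if (z <= 0 || z >= a) stop("starting point must lie strictly between bounds");
  IntegerVector bound(n);
  NumericVector dtime(n);
  const double sig = s * std::sqrt(dt);
  const long max_steps = (long)std::ceil(t_max / dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const double drift = mu[i] * dt;
    double y = z;
    long step = 0;
    int b = 0;
    while (step < max_steps) {
      ++step;
      y += drift + sig * norm_rand();
      if (y >= a) { b = 1; break; }
      if (y <= 0) { b = -1; break; }
    }
    bound[i] = b;
    dtime[i] = (b == 0) ? NA_REAL : step * dt;
  }
  return List::create(_["bound"] = bound, _["dtime"] = dtime);
}
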