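#include <Rcpp.h>
#include <cmath>

// Parameter vector layout (see param_vector() on the R side):
// 0 C_T, 1 Q0, 2 p, 3 alpha_v, 4 alpha_g, 5 alpha_max, 6 alpha_min,
// 7 T_alpha_l, 8 T_alpha_u, 9 B0, 10 B1, 11 T_opt, 12 k, 13 gamma

namespace {

struct Par {
  double C_T, Q0, p, a_v, a_g, a_max, a_min, T_l, T_u, B0, B1, T_opt, k, gamma;
  explicit Par(const Rcpp::NumericVector& v) {
    C_T = v[0]; Q0 = v[1]; p = v[2]; a_v = v[3]; a_g = v[4];
    a_max = v[5]; a_min = v[6]; T_l = v[7]; T_u = v[8];
    B0 = v[9]; B1 = v[10]; T_opt = v[11]; k = v[12]; gamma = v[13];
  }
};

inline double ocean_albedo(double T, const Par& p) {
  if (T <= p.T_l) return p.a_max;
  if (T > p.T_u) return p.a_min;
  return p.a_max + (p.a_min - p.a_max) * (T - p.T_l) / (p.T_u - p.T_l);
}

inline double albedo(double T, double A, const Par& p) {
  return (1.0 - p.p) * ocean_albedo(T, p) +
         p.p * (p.a_v * A + p.a_g * (1.0 - A));
}

inline double beta(double T, const Par& p) {
  double b = 1.0 - p.k * (T - p.T_opt) * (T - p.T_opt);
  return b > 0.0 ? b : 0.0;
}

inline double drift_T(double T, double A, const Par& p) {
  return ((1.0 - albedo(T, A, p)) * p.Q0 -
          (p.B0 + p.B1 * (T - p.T_opt))) / p.C_T;
}

inline double drift_A(double T, double A, const Par& p) {
  return beta(T, p) * A * (1.0 - A) - p.gamma * A;
}

}  // namespace

// Fixed-step RK4 for the deterministic system; A clamped to [0,1] after
// each full step.  Records every `stride`-th point (including t = 0).
// [[Rcpp::export]]
Rcpp::NumericMatrix rk4_cpp(double T0, double A0, double dt, int n_steps,
                            int stride, Rcpp::NumericVector par) {
  Par p(par);
  if (n_steps % stride != 0)
    Rcpp::stop("n_steps must be a multiple of stride");
  int n_rec = n_steps / stride + 1;
  Rcpp::NumericMatrix out(n_rec, 3);
  double T = T0, A = A0;
  out(0, 0) = 0.0; out(0, 1) = T; out(0, 2) = A;
  int r = 1;
  for (int s = 1; s <= n_steps; ++s) {
    double k1T = drift_T(T, A, p), k1A = drift_A(T, A, p);
    double k2T = drift_T(T + 0.5 * dt * k1T, A + 0.5 * dt * k1A, p);
    double k2A = drift_A(T + 0.5 * dt * k1T, A + 0.5 * dt * k1A, p);
    double k3T = drift_T(T + 0.5 * dt * k2T, A + 0.5 * dt * k2A, p);
    double k3A = drift_A(T + 0.5 * dt * k2T, A + 0.5 * dt * k2A, p);
    double k4T = drift_T(T + dt * k3T, A + dt * k3A, p);
    double k4A = drift_A(T + dt * k3T, A + dt * k3A, p);
    T += dt / 6.0 * (k1T + 2.0 * k2T + 2.0 * k3T + k4T);
    A += dt / 6.0 * (k1A + 2.0 * k2A + 2.0 * k3A + k4A);
    if (A < 0.0) A = 0.0;
    if (A > 1.0) A = 1.0;
    if (!std::isfinite(T) || !std::isfinite(A))
      Rcpp::stop("non-finite state at step %d (t = %g)", s, s * dt);
    if (s % stride == 0) {
      out(r, 0) = s * dt; out(r, 1) = T; out(r, 2) = A; ++r;
    }
  }
  return out;
}

// Euler-Maruyama step for the stochastic system (Ito interpretation):
// plain Euler on T (no noise there), and
//   A += (beta(T) A (1-A) - gamma A) dt + eps A (1-A) sqrt(dt) Z,
// Z ~ N(0,1) drawn from R's RNG (one deviate per step), then A clamped to
// [0,1].  With eps = 0 this is exactly the deterministic Euler scheme.
// Returns the recorded trajectory plus the number of clamp activations.
// [[Rcpp::export]]
Rcpp::List em_cpp(double T0, double A0, double dt, int n_steps, int stride,
                  Rcpp::NumericVector par, double eps) {
  Par p(par);
  if (n_steps % stride != 0)
    Rcpp::stop("n_steps must be a multiple of stride");
  int n_rec = n_steps / stride + 1;
  Rcpp::NumericMatrix out(n_rec, 3);
  double T = T0, A = A0;
  double sdt = std::sqrt(dt);
  out(0, 0) = 0.0; out(0, 1) = T; out(0, 2) = A;
  int r = 1;
  long n_clamp = 0;
  Rcpp::RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    double z = ::norm_rand();
    double Tn = T + drift_T(T, A, p) * dt;
    double An = A + drift_A(T, A, p) * dt +
                eps * A * (1.0 - A) * sdt * z;
    if (An < 0.0) { An = 0.0; ++n_clamp; }
    if (An > 1.0) { An = 1.0; ++n_clamp; }
    T = Tn; A = An;
    if (!std::isfinite(T) || !std::isfinite(A))
      Rcpp::stop("non-finite state at step %d (t = %g)", s, s * dt);
    if (s % stride == 0) {
      out(r, 0) = s * dt; out(r, 1) = T; out(r, 2) = A; ++r;
    }
  }
  return Rcpp::List::create(Rcpp::Named("traj") = out,
                            Rcpp::Named("n_clamp") = (double)n_clamp,
                            Rcpp::Named("n_steps") = (double)n_steps);
}

// First-passage time of the Euler-Maruyama trajectory below T_threshold;
// returns -1 if the threshold is never crossed within n_steps.  Identical
// stepping to em_cpp (same RNG consumption per step) but stores nothing
// and stops at the first crossing.
// [[Rcpp::export]]
double em_first_passage_cpp(double T0, double A0, double dt, int n_steps,
                            Rcpp::NumericVector par, double eps,
                            double T_threshold) {
  Par p(par);
  double T = T0, A = A0;
  double sdt = std::sqrt(dt);
  if (T < T_threshold) return 0.0;
  Rcpp::RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    double z = ::norm_rand();
    double Tn = T + drift_T(T, A, p) * dt;
    double An = A + drift_A(T, A, p) * dt +
                eps * A * (1.0 - A) * sdt * z;
    if (An < 0.0) An = 0.0;
    if (An > 1.0) An = 1.0;
    T = Tn; A = An;
    if (!std::isfinite(T) || !std::isfinite(A))
      Rcpp::stop("non-finite state at step %d (t = %g)", s, s * dt);
    if (T < T_threshold) return s * dt;
  }
  return -1.0;
}
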