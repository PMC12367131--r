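#include <Rcpp.h>
using namespace Rcpp;

// Scalar Kalman filter for the PG-augmented criterion chain.
//
// State:        x_t = b + a x_{t-1} + eps_t,  eps_t ~ N(0, sigma2)
// Pseudo-obs:   z_t = kappa_t / omega_t - psi_u_t, noise variance 1/omega_t,
//               where kappa_t = y_t - 1/2 and psi_u_t = w'u_t.
// The update is written in terms of h_t = omega_t * z_t = kappa_t -
// omega_t * psi_u_t, which stays finite as omega_t -> 0 (uninformative trial).
//
// Variances are floored at 1e-12 to avoid degenerate division downstream.

static const double VAR_FLOOR = 1e-12;

// [[Rcpp::export(name = ".forward_filter_cpp")]]
List forward_filter_cpp(NumericVector kappa, NumericVector omega,
                        NumericVector psi_u, double a, double b,
                        double sigma2, double m0, double P0) {
  int T = kappa.size();
  NumericVector m(T), P(T);
  for (int t = 0; t < T; ++t) {
    double mp, Pp;
    if (t == 0) {
      mp = m0;
      Pp = P0;
    } else {
      mp = b + a * m[t - 1];
      Pp = a * a * P[t - 1] + sigma2;
    }
    double h = kappa[t] - omega[t] * psi_u[t];
    double denom = 1.0 + omega[t] * Pp;
    double Pt = Pp / denom;
    m[t] = (mp + Pp * h) / denom;
    P[t] = (Pt < VAR_FLOOR) ? VAR_FLOOR : Pt;
  }
  return List::create(Named("means") = m, Named("variances") = P);
}

// [[Rcpp::export(name = ".backward_sample_cpp")]]
NumericVector backward_sample_cpp(NumericVector m, NumericVector P, double a,
                                  double b, double sigma2) {
  int T = m.size();
  NumericVector x(T);
  x[T - 1] = m[T - 1] + std::sqrt(P[T - 1]) * R::norm_rand();
  for (int t = T - 2; t >= 0; --t) {
    double mean, var;
    if (a == 0.0 || sigma2 <= 0.0) {
      // no information flows backward through a deterministic or
      // memory-free transition
      if (a == 0.0) {
        mean = m[t];
        var = P[t];
      } else {
        // sigma2 == 0 with a != 0: x_t determined by x_{t+1}
        mean = (x[t + 1] - b) / a;
        var = 0.0;
      }
    } else {
      double prec = 1.0 / P[t] + a * a / sigma2;
      var = 1.0 / prec;
      mean = var * (m[t] / P[t] + a * (x[t + 1] - b) / sigma2);
    }
    x[t] = mean + ((var > 0.0) ? std::sqrt(var) * R::norm_rand() : 0.0);
  }
  return x;
}
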