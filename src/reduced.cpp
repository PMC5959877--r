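#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Low-dimensional bump + facilitation model.
// State: bump position theta (rad), facilitation center theta_q (rad),
// facilitation amplitudes A_prev (previous trial) and A_curr (current trial).
// Drift of theta is the Heaviside-limit potential gradient of the
// facilitation footprint; time in ms, drift and noise expressed per tau_u
// time unit and rescaled to ms inside the integrator.

namespace {

inline double wrap_pi(double a) {
  // floor-based wrap (avoids fmod): result in [-pi, pi)
  double t = (a + M_PI) / (2.0 * M_PI);
  return (t - std::floor(t)) * 2.0 * M_PI - M_PI;
}

// minus dUbar/dtheta at wrapped offset delta (rad); zero outside |delta|<2a
inline double grad_drift(double delta, double c0, double tan_a, double two_a) {
  double ad = std::fabs(delta);
  if (ad >= two_a || ad == 0.0) return 0.0;
  double sgn = delta > 0 ? 1.0 : -1.0;
  return c0 * (sgn * (1.0 - std::cos(delta)) - tan_a * std::sin(delta));
}

} // namespace

// [[Rcpp::export]]
List red_run_trials(NumericVector theta, NumericVector TC, NumericVector TD,
                    NumericVector TA, NumericVector TI,
                    double a, double beta, double qp, double tau,
                    double tau_u, double sigma, double dt,
                    double record_every) {
  RNGScope rng;
  int ntr = theta.size();
  double tan_a = std::tan(a), two_a = 2.0 * a;
  double c0 = beta * qp / (2.0 * (1.0 + beta) * tan_a);
  double nf = sigma * std::sqrt(dt);   // sigma in rad/sqrt(ms)
  NumericVector resp(ntr), thq_out(ntr), Aprev_out(ntr), Acurr_out(ntr);
  List traj(record_every > 0 ? ntr : 0);

  double A_prev0 = 0.0, th_prev = 0.0;   // no trial precedes trial 1
  for (int n = 0; n < ntr; ++n) {
    double th = theta[n];
    double th_q = theta[n];              // facilitation of this trial starts at the cue
    int cue_steps = (int)std::lround(TC[n] / dt);
    int delay_steps = (int)std::lround(TD[n] / dt);
    int rec_stride = record_every > 0 ? std::max(1, (int)std::lround(record_every / dt)) : 0;
    std::vector<double> rt, rth, rq;
    double A_prev = A_prev0, A_curr = 0.0;
    // cue period: theta clamped to the target, facilitation builds
    for (int s = 0; s < cue_steps; ++s) {
      double t = (s + 1) * dt;
      A_curr = 1.0 - std::exp(-t / tau);
      A_prev = A_prev0 * std::exp(-t / tau);
      th_q += dt * (-(1.0 + beta) * wrap_pi(th_q - th)) / tau;
    }
    // delay period
    for (int s = 0; s < delay_steps; ++s) {
      double t = TC[n] + (s + 1) * dt;
      A_curr = 1.0 - std::exp(-t / tau);
      A_prev = A_prev0 * std::exp(-t / tau);
      double drift = (n > 0 ? A_prev * grad_drift(wrap_pi(th - th_prev), c0, tan_a, two_a) : 0.0)
                   + A_curr * grad_drift(wrap_pi(th - th_q), c0, tan_a, two_a);
      double dW = sigma > 0 ? nf * norm_rand() : 0.0;
      th = wrap_pi(th + drift * dt / tau_u + dW);
      th_q = wrap_pi(th_q + dt * (-(1.0 + beta) * wrap_pi(th_q - th)) / tau);
      if (rec_stride > 0 && (s + 1) % rec_stride == 0) {
        rt.push_back((s + 1) * dt); rth.push_back(th); rq.push_back(th_q);
      }
    }
    resp[n] = th;
    thq_out[n] = th_q;
    Aprev_out[n] = A_prev;
    Acurr_out[n] = A_curr;
    if (rec_stride > 0) {
      NumericMatrix m(rt.size(), 3);
      for (size_t k = 0; k < rt.size(); ++k) { m(k,0)=rt[k]; m(k,1)=rth[k]; m(k,2)=rq[k]; }
      traj[n] = m;
    }
    // carry facilitation into the next trial: amplitude at next trial start.
    // The intertrial decay spans the full response-to-cue gap, i.e. the
    // inactivation period plus the scheduled intertrial interval.
    A_prev0 = (1.0 - std::exp(-(TC[n] + TD[n]) / tau)) * std::exp(-(TA[n] + TI[n]) / tau);
    th_prev = theta[n];                  // carry the target, not the response
    if (n % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["response"] = resp, _["theta_q"] = thq_out,
                      _["A_prev"] = Aprev_out, _["A_curr"] = Acurr_out,
                      _["traj"] = traj);
}
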