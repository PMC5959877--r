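#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ring neural-field integrator with short-term facilitation.
// Internal units: space in radians on [-pi, pi), time in ms.
// Coupling w(x) = sum_n alpha[n-1] cos(n x); convolution by harmonic
// projection (exact for cosine-series kernels). Noise increments are rank-2:
// sigW (cos(x) xi1 + sin(x) xi2) sqrt(dt), giving covariance
// sigW^2 cos(x - y) dt.

namespace {

struct Field {
  int nx;
  double dxr;          // radian spacing
  double tau_u, tau, beta, qp, gamma, kappa, sigW;
  bool heaviside;
  std::vector<double> x;
  std::vector<std::vector<double>> cn, sn;   // per harmonic
  std::vector<double> alpha;
  std::vector<double> u, q, rate, conv;

  Field(int nx_, double tau_u_, double tau_, double beta_, double qp_,
        double gamma_, double kappa_, double sigW_, NumericVector alpha_,
        bool heaviside_)
      : nx(nx_), dxr(2.0 * M_PI / nx_), tau_u(tau_u_), tau(tau_),
        beta(beta_), qp(qp_), gamma(gamma_), kappa(kappa_), sigW(sigW_),
        heaviside(heaviside_), x(nx_), alpha(alpha_.begin(), alpha_.end()),
        u(nx_, 0.0), q(nx_, 0.0), rate(nx_), conv(nx_) {
    for (int i = 0; i < nx; ++i) x[i] = -M_PI + i * dxr;
    int H = alpha.size();
    if (H < 1 || H > 8) stop("coupling kernel must have 1..8 harmonics");
    cn.resize(H); sn.resize(H);
    for (int h = 0; h < H; ++h) {
      cn[h].resize(nx); sn[h].resize(nx);
      for (int i = 0; i < nx; ++i) {
        cn[h][i] = std::cos((h + 1) * x[i]);
        sn[h][i] = std::sin((h + 1) * x[i]);
      }
    }
  }

  void reset() {
    std::fill(u.begin(), u.end(), 0.0);
    std::fill(q.begin(), q.end(), 0.0);
  }

  inline void firing() {
    if (heaviside) {
      for (int i = 0; i < nx; ++i) rate[i] = u[i] > kappa ? 1.0 : 0.0;
    } else {
      for (int i = 0; i < nx; ++i)
        rate[i] = 1.0 / (1.0 + std::exp(-gamma * (u[i] - kappa)));
    }
  }

  // one Euler-Maruyama step with stimulus field I (may be null => 0)
  void step(const double* I, double Iconst, double dt) {
    firing();
    // effective presynaptic drive (1+q) F(u)
    for (int i = 0; i < nx; ++i) conv[i] = (1.0 + q[i]) * rate[i];
    // harmonic projection
    int H = alpha.size();
    double acc_c[8], acc_s[8];
    for (int h = 0; h < H; ++h) {
      double c = 0.0, s = 0.0;
      const double* ch = cn[h].data();
      const double* sh = sn[h].data();
      for (int i = 0; i < nx; ++i) { c += ch[i] * conv[i]; s += sh[i] * conv[i]; }
      acc_c[h] = alpha[h] * c * dxr;
      acc_s[h] = alpha[h] * s * dxr;
    }
    double xi1 = 0.0, xi2 = 0.0, nf = 0.0;
    if (sigW > 0) {
      xi1 = norm_rand();
      xi2 = norm_rand();
      nf = sigW * std::sqrt(dt / tau_u);
    }
    double du_fac = dt / tau_u;
    double dq_fac = dt / tau;
    for (int i = 0; i < nx; ++i) {
      double w = 0.0;
      for (int h = 0; h < H; ++h)
        w += acc_c[h] * cn[h][i] + acc_s[h] * sn[h][i];
      double stim = I ? I[i] : Iconst;
      // noise convention: time is nondimensionalized by tau_u, so the
      // increment enters u with variance sigW^2 dt / tau_u
      double dW = nf * (cn[0][i] * xi1 + sn[0][i] * xi2);
      u[i] += du_fac * (-u[i] + w + stim) + dW;
      double qn = q[i] + dq_fac * (-q[i] + beta * rate[i] * (qp - q[i]));
      if (qn < 0.0) qn = 0.0;
      if (qn > qp) qn = qp;
      q[i] = qn;
    }
  }

  // argmax readout; ties resolved by circular centroid of the argmax set
  double center(bool& valid) const {
    double m = u[0];
    for (int i = 1; i < nx; ++i) if (u[i] > m) m = u[i];
    valid = (m >= kappa) && std::isfinite(m);
    double cs = 0.0, ss = 0.0;
    int cnt = 0;
    for (int i = 0; i < nx; ++i) {
      if (u[i] >= m - 1e-12) { cs += std::cos(x[i]); ss += std::sin(x[i]); ++cnt; }
    }
    if (cnt == 0) { valid = false; return NA_REAL; }
    return std::atan2(ss, cs);
  }

  void check_finite(const char* where) const {
    for (int i = 0; i < nx; ++i) {
      if (!std::isfinite(u[i]) || !std::isfinite(q[i]))
        stop("numerical blow-up in %s: non-finite field state", where);
    }
  }
};

inline double wrap_pi(double a) {
  // floor-based wrap (avoids fmod): result in [-pi, pi)
  double t = (a + M_PI) / (2.0 * M_PI);
  return (t - std::floor(t)) * 2.0 * M_PI - M_PI;
}

} // namespace

// [[Rcpp::export]]
List nf_run_trials(NumericVector theta, NumericVector TC, NumericVector TD,
                   NumericVector TA, NumericVector TI,
                   double I0, double I1, double IR,
                   int nx, double tau_u, double tau, double beta, double qp,
                   double gamma, double kappa, double sigW,
                   NumericVector alpha, bool heaviside,
                   double dt, double burn_ms, double record_every) {
  RNGScope rng;
  int ntr = theta.size();
  Field f(nx, tau_u, tau, beta, qp, gamma, kappa, sigW, alpha, heaviside);
  std::vector<double> stim(nx);
  NumericVector resp(ntr);
  LogicalVector valid(ntr);
  List traj(record_every > 0 ? ntr : 0);

  int burn_steps = (int)std::lround(burn_ms / dt);
  for (int s = 0; s < burn_steps; ++s) f.step(nullptr, 0.0, dt);
  // the burn-in ends like a trial: global inactivation clears any
  // spontaneously nucleated bump before the first cue
  if (burn_steps > 0) {
    int ta0 = (int)std::lround(TA[0] / dt);
    for (int s = 0; s < ta0; ++s) f.step(nullptr, -IR, dt);
  }
  f.check_finite("burn-in");

  for (int n = 0; n < ntr; ++n) {
    // cue
    for (int i = 0; i < nx; ++i)
      stim[i] = I0 * std::exp(I1 * (std::cos(f.x[i] - theta[n]) - 1.0));
    int cue_steps = (int)std::lround(TC[n] / dt);
    for (int s = 0; s < cue_steps; ++s) f.step(stim.data(), 0.0, dt);
    // delay (optionally record center trajectory)
    int delay_steps = (int)std::lround(TD[n] / dt);
    int rec_stride = record_every > 0 ? std::max(1, (int)std::lround(record_every / dt)) : 0;
    std::vector<double> rt, rc, rd;
    bool ok0; double c_prev = f.center(ok0), disp = 0.0;
    if (rec_stride > 0) { rt.push_back(0.0); rc.push_back(c_prev); rd.push_back(0.0); }
    for (int s = 0; s < delay_steps; ++s) {
      f.step(nullptr, 0.0, dt);
      if (rec_stride > 0 && (s + 1) % rec_stride == 0) {
        bool ok; double c = f.center(ok);
        double inc = wrap_pi(c - c_prev);
        disp += inc; c_prev = c;
        rt.push_back((s + 1) * dt); rc.push_back(c); rd.push_back(disp);
      }
    }
    f.check_finite("delay");
    bool ok; double c = f.center(ok);
    resp[n] = c;
    valid[n] = ok;
    if (rec_stride > 0) {
      NumericMatrix m(rt.size(), 3);
      for (size_t k = 0; k < rt.size(); ++k) { m(k,0)=rt[k]; m(k,1)=rc[k]; m(k,2)=rd[k]; }
      traj[n] = m;
    }
    // post-response inactivation, held through the intertrial interval so
    // the network is quiescent until the next cue (facilitation alone
    // carries the trial history)
    int off_steps = (int)std::lround((TA[n] + TI[n]) / dt);
    for (int s = 0; s < off_steps; ++s) f.step(nullptr, -IR, dt);
    if (n % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["response"] = resp, _["valid"] = valid, _["traj"] = traj);
}

// [[Rcpp::export]]
NumericMatrix nf_delay_ensemble(int n_paths, double duration, double record_every,
                                double TC, int nx, double tau_u, double tau,
                                double beta, double qp, double gamma,
                                double kappa, double sigW, NumericVector alpha,
                                bool heaviside, double dt, double burn_ms) {
  RNGScope rng;
  Field f(nx, tau_u, tau, beta, qp, gamma, kappa, sigW, alpha, heaviside);
  std::vector<double> stim(nx);
  for (int i = 0; i < nx; ++i)
    stim[i] = std::exp(std::cos(f.x[i]) - 1.0);   // cue at 0 rad, I0 = I1 = 1
  int delay_steps = (int)std::lround(duration / dt);
  int rec_stride = std::max(1, (int)std::lround(record_every / dt));
  int nt = delay_steps / rec_stride + 1;
  NumericMatrix out(n_paths, nt);
  // each path starts like a trial: briefly suppressed, then cued
  int settle_steps = (int)std::lround(burn_ms / dt);
  int cue_steps = (int)std::lround(TC / dt);
  for (int p = 0; p < n_paths; ++p) {
    f.reset();
    for (int s = 0; s < settle_steps; ++s) f.step(nullptr, -2.0, dt);
    for (int s = 0; s < cue_steps; ++s) f.step(stim.data(), 0.0, dt);
    bool ok; double c_prev = f.center(ok), disp = 0.0;
    out(p, 0) = 0.0;
    int k = 1;
    for (int s = 0; s < delay_steps; ++s) {
      f.step(nullptr, 0.0, dt);
      if ((s + 1) % rec_stride == 0) {
        double c = f.center(ok);
        disp += wrap_pi(c - c_prev);
        c_prev = c;
        if (k < nt) out(p, k++) = disp;
      }
    }
    f.check_finite("delay ensemble");
    Rcpp::checkUserInterrupt();
  }
  return out;
}
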