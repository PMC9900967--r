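#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled fast/slow system on the quartic
// double-well family:
//   dx = [ -4 s^2 x (x^2 - 1) / tau_x + tilt(t) ] dt + sqrt(2 Tx / tau_x) dWx
//   ds = -(s - mu_s(t)) / tau_s dt + sqrt(2 Ts / tau_s) dWs
// mu_s and tilt may be length-1 (constant) or length n_steps (schedules).
// The frozen-s limit is obtained with Ts = 0, tau_s = Inf.
// [[Rcpp::export]]
List cpp_em_coupled(int n_steps, int keep_every, double dt,
                    double Tx, double Ts, double tau_s, double tau_x,
                    double x0, double s0,
                    NumericVector mu_s, NumericVector tilt) {
  int n_keep = n_steps / keep_every + 1;
  NumericVector xout(n_keep), sout(n_keep);
  double x = x0, s = s0;
  double sig_x = std::sqrt(2.0 * Tx * dt / tau_x);
  double sig_s = (Ts > 0.0 && R_finite(tau_s)) ? std::sqrt(2.0 * Ts * dt / tau_s) : 0.0;
  bool mu_const = (mu_s.size() == 1), tilt_const = (tilt.size() == 1);
  xout[0] = x; sout[0] = s;
  int k = 1;
  for (int i = 0; i < n_steps; ++i) {
    double mu = mu_const ? mu_s[0] : mu_s[i];
    double a  = tilt_const ? tilt[0] : tilt[i];
    double fx = (-4.0 * s * s * x * (x * x - 1.0)) / tau_x + a;
    double fs = R_finite(tau_s) ? (-(s - mu) / tau_s) : 0.0;
    x += fx * dt + sig_x * norm_rand();
    s += fs * dt + sig_s * norm_rand();
    if (!R_finite(x) || !R_finite(s)) {
      List bad = List::create(_["x"] = NumericVector(0), _["s"] = NumericVector(0),
                              _["bad_step"] = i + 1);
      return bad;
    }
    if ((i + 1) % keep_every == 0) { xout[k] = x; sout[k] = s; ++k; }
  }
  return List::create(_["x"] = xout, _["s"] = sout, _["bad_step"] = -1);
}

// Ornstein-Uhlenbeck path by Euler-Maruyama (test utilities and posture-like
// fast channels): dx = -(x - mu)/tau dt + sqrt(2 T / tau) dW.
// [[Rcpp::export]]
NumericVector cpp_em_ou(int n_steps, int keep_every, double dt,
                        double tau, double mu, double T, double x0) {
  int n_keep = n_steps / keep_every + 1;
  NumericVector out(n_keep);
  double x = x0, sig = std::sqrt(2.0 * T * dt / tau);
  out[0] = x;
  int k = 1;
  for (int i = 0; i < n_steps; ++i) {
    x += -(x - mu) / tau * dt + sig * norm_rand();
    if ((i + 1) % keep_every == 0) out[k++] = x;
  }
  return out;
}

// Complete dwell times of a two-state continuous-time Markov chain observed
// on [0, duration], starting freshly entered in state0 (0 or 1). The final
// (censored) interval is excluded and counted.
// [[Rcpp::export]]
List cpp_telegraph_dwells(double rate0, double rate1, double duration, int state0) {
  std::vector<double> dw;
  std::vector<int> st;
  double t = 0.0;
  int s = state0;
  int censored = 0;
  while (true) {
    double rate = (s == 0) ? rate0 : rate1;
    double d = exp_rand() / rate;
    if (t + d > duration) { censored = 1; break; }
    dw.push_back(d);
    st.push_back(s);
    t += d;
    s = 1 - s;
  }
  return List::create(_["durations"] = wrap(dw), _["state"] = wrap(st),
                      _["censored"] = censored);
}

// Two-state chain sampled on a regular grid of n_samples points spaced dt.
// [[Rcpp::export]]
IntegerVector cpp_telegraph_sample(double rate0, double rate1,
                                   int n_samples, double dt, int state0) {
  IntegerVector out(n_samples);
  double t_next;
  int s = state0;
  double rate = (s == 0) ? rate0 : rate1;
  t_next = exp_rand() / rate;
  for (int i = 0; i < n_samples; ++i) {
    double t = i * dt;
    while (t >= t_next) {
      s = 1 - s;
      rate = (s == 0) ? rate0 : rate1;
      t_next += exp_rand() / rate;
    }
    out[i] = s;
  }
  return out;
}

// Inhomogeneous Poisson events on [0, n*dt) by thinning against the maximum
// of the piecewise-constant rate path.
// [[Rcpp::export]]
NumericVector cpp_poisson_thinning(NumericVector rate, double dt) {
  int n = rate.size();
  double tmax = n * dt;
  double lmax = 0.0;
  for (int i = 0; i < n; ++i) if (rate[i] > lmax) lmax = rate[i];
  std::vector<double> ev;
  if (lmax <= 0.0) return NumericVector(0);
  double t = exp_rand() / lmax;
  while (t < tmax) {
    int i = (int)(t / dt);
    if (i >= n) break;
    if (unif_rand() * lmax < rate[i]) ev.push_back(t);
    t += exp_rand() / lmax;
  }
  return wrap(ev);
}

// Lag-domain autocovariance at arbitrary integer lags:
// value[L] = mean over t of (x[t]-m)(x[t+L]-m), m = sample mean if demean.
// [[Rcpp::export]]
NumericVector cpp_acf_lags(NumericVector x, IntegerVector lags, bool demean) {
  int n = x.size(), nl = lags.size();
  double m = 0.0;
  if (demean) { for (int i = 0; i < n; ++i) m += x[i]; m /= n; }
  NumericVector out(nl);
  for (int j = 0; j < nl; ++j) {
    int L = lags[j];
    if (L >= n) { out[j] = NA_REAL; continue; }
    double acc = 0.0;
    for (int t = 0; t + L < n; ++t) acc += (x[t] - m) * (x[t + L] - m);
    out[j] = acc / (n - L);
  }
  return out;
}

// Local-linear weighted moments with an Epanechnikov kernel.
// For each grid point g: weights w_i = 1 - ((X_i - g)/h)^2 over |X_i-g|<h,
// u_i = X_i - g. Returns the sums needed to solve the weighted linear fit
// y ~ a + b u at each grid point and its residual variance, plus counts.
// [[Rcpp::export]]
List cpp_nw_moments(NumericVector X, NumericVector DX,
                    NumericVector grid, double h) {
  int n = X.size(), ng = grid.size();
  NumericVector Sw(ng), Sx(ng), Sxx(ng), Sy(ng), Sxy(ng), Syy(ng);
  IntegerVector cnt(ng);
  double g0 = grid[0];
  double dg = ng > 1 ? grid[1] - grid[0] : 1.0;
  for (int i = 0; i < n; ++i) {
    double xi = X[i], yi = DX[i];
    int jlo = (int)std::ceil((xi - h - g0) / dg);
    int jhi = (int)std::floor((xi + h - g0) / dg);
    if (jlo < 0) jlo = 0;
    if (jhi >= ng) jhi = ng - 1;
    for (int j = jlo; j <= jhi; ++j) {
      double u = xi - grid[j];
      double v = u / h;
      double w = 1.0 - v * v;
      if (w <= 0.0) continue;
      Sw[j] += w; Sx[j] += w * u; Sxx[j] += w * u * u;
      Sy[j] += w * yi; Sxy[j] += w * u * yi; Syy[j] += w * yi * yi;
      cnt[j] += 1;
    }
  }
  return List::create(_["Sw"] = Sw, _["Sx"] = Sx, _["Sxx"] = Sxx,
                      _["Sy"] = Sy, _["Sxy"] = Sxy, _["Syy"] = Syy,
                      _["count"] = cnt);
}

// Euler-Maruyama simulation of an inferred Kramers-Moyal model with linear
// interpolation of F and D on the grid, piecewise-constant in time across
// windows (win_id, 0-based, length n_steps or 1), reflecting at grid edges.
// Returns path sampled every keep_every plus the out-of-range step count.
// [[Rcpp::export]]
List cpp_sim_km(NumericVector grid, NumericMatrix F, NumericMatrix D,
                IntegerVector win_id, int n_steps, double dt,
                double x0, int keep_every) {
  int ng = grid.size();
  double lo = grid[0], hi = grid[ng - 1];
  double dg = grid[1] - grid[0];
  int n_keep = n_steps / keep_every + 1;
  NumericVector out(n_keep);
  bool wconst = (win_id.size() == 1);
  double x = x0;
  int n_out = 0, k = 1;
  out[0] = x;
  for (int i = 0; i < n_steps; ++i) {
    int w = wconst ? win_id[0] : win_id[i];
    int j = (int)((x - lo) / dg);
    if (j < 0) j = 0;
    if (j >= ng - 1) j = ng - 2;
    double a = (x - grid[j]) / dg;
    if (a < 0.0) a = 0.0;
    if (a > 1.0) a = 1.0;
    double f = (1.0 - a) * F(j, w) + a * F(j + 1, w);
    double d = (1.0 - a) * D(j, w) + a * D(j + 1, w);
    if (d < 0.0) d = 0.0;
    x += f * dt + std::sqrt(2.0 * d * dt) * norm_rand();
    if (x < lo) { x = 2.0 * lo - x; ++n_out; }
    if (x > hi) { x = 2.0 * hi - x; ++n_out; }
    if (x < lo) x = lo;  // pathological double reflection
    if (x > hi) x = hi;
    if ((i + 1) % keep_every == 0) out[k++] = x;
  }
  return List::create(_["x"] = out, _["n_out"] = n_out);
}
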