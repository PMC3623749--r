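// Compiled inner loops: spiking-network and single-cell integrators,
// reduced rate-model RK4, Lyapunov estimators and the scalar SDE test
// integrator.  All stochastic draws go through R's RNG so seeds set with
// set.seed() in R are honoured.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct CellPar {
  double C, gL, EL, gNa, ENa, gK, EK, Vmh, km, Vwh, kw, tauw;
};

static CellPar unpack_cell(const NumericVector& p) {
  CellPar c;
  c.C = p["C"];     c.gL = p["gL"];   c.EL = p["EL"];
  c.gNa = p["gNa"]; c.ENa = p["ENa"]; c.gK = p["gK"]; c.EK = p["EK"];
  c.Vmh = p["Vm_half"]; c.km = p["km"];
  c.Vwh = p["Vw_half"]; c.kw = p["kw"]; c.tauw = p["tau_w"];
  return c;
}

static inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((vh - v) / k));
}

// membrane vector field for one cell given total input current I
static inline void cell_deriv(const CellPar& P, double v, double w, double I,
                              double& dv, double& dw) {
  double m = boltz(v, P.Vmh, P.km);
  double winf = boltz(v, P.Vwh, P.kw);
  dv = (-P.gL * (v - P.EL) - P.gNa * m * (v - P.ENa)
        - P.gK * w * (v - P.EK) + I) / P.C;
  dw = (winf - w) / P.tauw;
}

// ---------------------------------------------------------------------------
// Single-cell deterministic simulation (Heun).  Optional presynaptic
// alpha-pulse: a Heaviside release pulse of width pulse_w at pulse_t feeding
// a conductance g_syn with reversal E_inh and decay tau_alpha -- this is the
// unitary IPSP probe input.  Records the voltage trace every record_every
// steps when record_every > 0.
// [[Rcpp::export]]
List cpp_cell_sim(NumericVector cellpar, double I0, double dt, double T_ms,
                  double v0, double w0,
                  double g_syn, double E_inh, double tau_alpha,
                  double pulse_t, double pulse_w,
                  int record_every) {
  CellPar P = unpack_cell(cellpar);
  int nsteps = (int)std::ceil(T_ms / dt);
  double v = v0, w = w0, a = 0.0;
  std::vector<double> spikes, widths;
  std::vector<double> rec_t, rec_v, rec_w;
  double above = 0.0;
  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    double th1 = (t >= pulse_t && t < pulse_t + pulse_w) ? 1.0 : 0.0;
    double th2 = (t + dt >= pulse_t && t + dt < pulse_t + pulse_w) ? 1.0 : 0.0;
    double I1 = I0 + g_syn * a * (E_inh - v);
    double dv1, dw1;
    cell_deriv(P, v, w, I1, dv1, dw1);
    double da1 = th1 - a / tau_alpha;
    double vp = v + dt * dv1, wp = w + dt * dw1, ap = a + dt * da1;
    double I2 = I0 + g_syn * ap * (E_inh - vp);
    double dv2, dw2;
    cell_deriv(P, vp, wp, I2, dv2, dw2);
    double da2 = th2 - ap / tau_alpha;
    double vn = v + 0.5 * dt * (dv1 + dv2);
    double wn = w + 0.5 * dt * (dw1 + dw2);
    double an = a + 0.5 * dt * (da1 + da2);
    if (an < 0) an = 0;
    if (!std::isfinite(vn) || std::fabs(vn) > 200.0)
      stop("numerical blow-up at step %d (t = %.3f ms)", s, t);
    if (v < 0.0 && vn >= 0.0) {
      double frac = -v / (vn - v);
      double ts = t + frac * dt;
      spikes.push_back(std::round(ts * 100.0) / 100.0);
    }
    // time above 0 mV per spike (spike width)
    if (vn >= 0.0) {
      above += dt;
    } else if (above > 0.0) {
      widths.push_back(above);
      above = 0.0;
    }
    v = vn; w = wn; a = an;
    if (record_every > 0 && (s % record_every) == 0) {
      rec_t.push_back(t + dt);
      rec_v.push_back(v);
      rec_w.push_back(w);
    }
  }
  return List::create(_["spikes"] = wrap(spikes),
                      _["widths"] = wrap(widths),
                      _["t"] = wrap(rec_t), _["v"] = wrap(rec_v),
                      _["w"] = wrap(rec_w),
                      _["v_end"] = v, _["w_end"] = w);
}

// ---------------------------------------------------------------------------
// Full network integrator.
//
// State per cell: membrane potential v, K-activation w, presynaptic bound
// neurotransmitter alpha.  Drift advanced with a Heun predictor-corrector
// (deterministic second order); the aggregate excitatory fluctuation is an
// exponentially correlated (OU) process updated exactly once per step and
// held constant across the two stages, so in deterministic mode the scheme
// is exactly deterministic Heun.  The inhibitory field sum_j g_ij alpha_j is
// evaluated once per step from the pre-step alpha (alpha varies on the
// tau_alpha timescale, hundreds of steps, so the induced error is far below
// the O(dt^2) truncation term); its voltage factor (E_inh - v) is kept
// stage-dependent.
//
// G: N x N conductance matrix, rows = postsynaptic cell.
// mean_cur, sd_cur: N x S per-stimulus aggregate drive (nA at v = v_ref).
// seg_stim (0-based), seg_end_ms: the stimulus schedule.
// [[Rcpp::export]]
List cpp_network_sim(NumericMatrix G, NumericVector cellpar,
                     double tau_alpha, double v_release, double E_inh,
                     NumericMatrix mean_cur, NumericMatrix sd_cur,
                     double E_exc, double v_ref, double tau_eps,
                     IntegerVector seg_stim, NumericVector seg_end_ms,
                     double dt, double T_ms, bool deterministic,
                     NumericVector v0, NumericVector w0, NumericVector a0,
                     int record_every, IntegerVector record_cells) {
  CellPar P = unpack_cell(cellpar);
  int N = G.nrow();
  int nsteps = (int)std::ceil(T_ms / dt);
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> eta(N, 0.0);
  std::vector<double> S(N), vp(N), wp(N), ap(N), th1(N), th2(N);
  std::vector<int> sp_cell;
  std::vector<double> sp_time;
  const double* Gp = &G(0, 0);
  double ou_decay = std::exp(-dt / tau_eps);
  double ou_diff = std::sqrt(1.0 - ou_decay * ou_decay);
  int seg = 0, nseg = seg_stim.size();
  int nrec = record_cells.size();
  std::vector<double> rec_t;
  std::vector<double> rec_v;  // row-major nrec per sample
  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    while (seg < nseg - 1 && t >= seg_end_ms[seg]) ++seg;
    int st = seg_stim[seg];
    // OU fluctuation, exact update, frozen within the step
    if (!deterministic) {
      for (int i = 0; i < N; ++i)
        eta[i] = eta[i] * ou_decay + sd_cur(i, st) * ou_diff * norm_rand();
    }
    // inhibitory field from pre-step alpha
    std::fill(S.begin(), S.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      double aj = a[j];
      if (aj > 1e-14) {
        const double* col = Gp + (size_t)N * j;
        for (int i = 0; i < N; ++i) S[i] += col[i] * aj;
      }
    }
    double inv_fac = 1.0 / (E_exc - v_ref);
    // stage 1
    for (int i = 0; i < N; ++i) {
      th1[i] = (v[i] > v_release) ? 1.0 : 0.0;
      double Iexc = (mean_cur(i, st) + eta[i]) * (E_exc - v[i]) * inv_fac;
      double I = Iexc + S[i] * (E_inh - v[i]);
      double dv, dw;
      cell_deriv(P, v[i], w[i], I, dv, dw);
      vp[i] = v[i] + dt * dv;
      wp[i] = w[i] + dt * dw;
      ap[i] = a[i] + dt * (th1[i] - a[i] / tau_alpha);
    }
    // stage 2
    for (int i = 0; i < N; ++i) {
      th2[i] = (vp[i] > v_release) ? 1.0 : 0.0;
      double Iexc = (mean_cur(i, st) + eta[i]) * (E_exc - vp[i]) * inv_fac;
      double I = Iexc + S[i] * (E_inh - vp[i]);
      double dv2, dw2;
      cell_deriv(P, vp[i], wp[i], I, dv2, dw2);
      double dv1 = (vp[i] - v[i]) / dt, dw1 = (wp[i] - w[i]) / dt;
      double vn = v[i] + 0.5 * dt * (dv1 + dv2);
      double wn = w[i] + 0.5 * dt * (dw1 + dw2);
      double da1 = th1[i] - a[i] / tau_alpha;
      double da2 = th2[i] - ap[i] / tau_alpha;
      double an = a[i] + 0.5 * dt * (da1 + da2);
      if (an < 0) an = 0;
      if (!std::isfinite(vn) || std::fabs(vn) > 200.0)
        stop("numerical blow-up at step %d, cell %d (t = %.3f ms)",
             s, i + 1, t);
      if (v[i] < 0.0 && vn >= 0.0) {
        double frac = -v[i] / (vn - v[i]);
        sp_cell.push_back(i + 1);
        sp_time.push_back(std::round((t + frac * dt) * 100.0) / 100.0);
      }
      v[i] = vn; w[i] = wn; a[i] = an;
    }
    if (record_every > 0 && (s % record_every) == 0) {
      rec_t.push_back(t + dt);
      for (int k = 0; k < nrec; ++k) rec_v.push_back(v[record_cells[k] - 1]);
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["spike_cell"] = wrap(sp_cell),
                          _["spike_time"] = wrap(sp_time),
                          _["v"] = wrap(v), _["w"] = wrap(w),
                          _["alpha"] = wrap(a));
  if (record_every > 0) {
    int ns = rec_t.size();
    NumericMatrix tr(ns, nrec);
    for (int r = 0; r < ns; ++r)
      for (int k = 0; k < nrec; ++k) tr(r, k) = rec_v[(size_t)r * nrec + k];
    out["trace_t"] = wrap(rec_t);
    out["trace_v"] = tr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Reduced rate model: dalpha_i/dt = -alpha_i/tau + dts * f(I_i) with
// I_i = VE * Iexc_i + VI * sum_j J_ij alpha_j and
// f(I) = kf * sqrt(I - Ith) for I > Ith else 0 (kf in spikes/ms/sqrt(nA)).
static void rate_deriv(const NumericMatrix& J, const std::vector<double>& Iin,
                       double VE, double VI, double tau, double dts,
                       double kf, double Ith,
                       const std::vector<double>& al, std::vector<double>& d) {
  int N = al.size();
  const double* Jp = &J(0, 0);
  std::fill(d.begin(), d.end(), 0.0);
  for (int j = 0; j < N; ++j) {
    double aj = al[j];
    if (aj > 1e-14) {
      const double* col = Jp + (size_t)N * j;
      for (int i = 0; i < N; ++i) d[i] += col[i] * aj;
    }
  }
  for (int i = 0; i < N; ++i) {
    double I = VE * Iin[i] + VI * d[i];
    double f = (I > Ith) ? kf * std::sqrt(I - Ith) : 0.0;
    d[i] = -al[i] / tau + dts * f;
  }
}

static void rk4_rate_step(const NumericMatrix& J, const std::vector<double>& I,
                          double VE, double VI, double tau, double dts,
                          double kf, double Ith, double dt,
                          std::vector<double>& al,
                          std::vector<double>& k1, std::vector<double>& k2,
                          std::vector<double>& k3, std::vector<double>& k4,
                          std::vector<double>& tmp) {
  int N = al.size();
  rate_deriv(J, I, VE, VI, tau, dts, kf, Ith, al, k1);
  for (int i = 0; i < N; ++i) tmp[i] = al[i] + 0.5 * dt * k1[i];
  rate_deriv(J, I, VE, VI, tau, dts, kf, Ith, tmp, k2);
  for (int i = 0; i < N; ++i) tmp[i] = al[i] + 0.5 * dt * k2[i];
  rate_deriv(J, I, VE, VI, tau, dts, kf, Ith, tmp, k3);
  for (int i = 0; i < N; ++i) tmp[i] = al[i] + dt * k3[i];
  rate_deriv(J, I, VE, VI, tau, dts, kf, Ith, tmp, k4);
  for (int i = 0; i < N; ++i) {
    al[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    if (al[i] < 0) al[i] = 0;  // rectification: alpha >= 0 forward-invariant
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_rate_integrate(NumericMatrix J, NumericVector Iexc,
                                 double VE, double VI, double tau, double dts,
                                 double kf, double Ith, NumericVector alpha0,
                                 double dt, int nsteps, int sample_every) {
  int N = alpha0.size();
  std::vector<double> al(alpha0.begin(), alpha0.end());
  std::vector<double> I(Iexc.begin(), Iexc.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N);
  int nsamp = nsteps / sample_every;
  NumericMatrix out(nsamp, N);
  int r = 0;
  for (int s = 1; s <= nsteps; ++s) {
    rk4_rate_step(J, I, VE, VI, tau, dts, kf, Ith, dt, al, k1, k2, k3, k4, tmp);
    if (!std::isfinite(al[0]))
      stop("non-finite rate state at step %d", s);
    if (s % sample_every == 0 && r < nsamp) {
      for (int i = 0; i < N; ++i) out(r, i) = al[i];
      ++r;
    }
    if ((s & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Two-trajectory maximal Lyapunov exponent with periodic renormalisation.
// Returns the exponent in 1/ms.
// [[Rcpp::export]]
double cpp_rate_lyapunov(NumericMatrix J, NumericVector Iexc,
                         double VE, double VI, double tau, double dts,
                         double kf, double Ith, NumericVector alpha0,
                         double dt, int nsteps, int renorm_every, double d0) {
  int N = alpha0.size();
  std::vector<double> x(alpha0.begin(), alpha0.end()), y(x);
  std::vector<double> I(Iexc.begin(), Iexc.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N);
  // random initial perturbation direction
  double nrm = 0;
  std::vector<double> pert(N);
  for (int i = 0; i < N; ++i) { pert[i] = norm_rand(); nrm += pert[i] * pert[i]; }
  nrm = std::sqrt(nrm);
  for (int i = 0; i < N; ++i) y[i] += d0 * pert[i] / nrm;
  double lsum = 0.0;
  int nren = 0;
  for (int s = 1; s <= nsteps; ++s) {
    rk4_rate_step(J, I, VE, VI, tau, dts, kf, Ith, dt, x, k1, k2, k3, k4, tmp);
    rk4_rate_step(J, I, VE, VI, tau, dts, kf, Ith, dt, y, k1, k2, k3, k4, tmp);
    if (s % renorm_every == 0) {
      double d = 0;
      for (int i = 0; i < N; ++i) {
        double di = y[i] - x[i];
        d += di * di;
      }
      d = std::sqrt(d);
      if (d <= 0.0)
        stop("perturbation collapsed to zero: degenerate start");
      lsum += std::log(d / d0);
      ++nren;
      double fac = d0 / d;
      for (int i = 0; i < N; ++i) y[i] = x[i] + (y[i] - x[i]) * fac;
    }
    if ((s & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return lsum / (nren * renorm_every * dt);
}

// Same renormalisation machinery on the Lorenz flow: estimator benchmark.
// Returns the exponent per unit model time (literature value ~0.9056 for
// sigma=10, rho=28, beta=8/3).
// [[Rcpp::export]]
double cpp_lorenz_lyapunov(double sigma, double rho, double beta,
                           double T, double dt, int renorm_every, double d0,
                           double T_transient) {
  auto deriv = [&](const double* u, double* d) {
    d[0] = sigma * (u[1] - u[0]);
    d[1] = u[0] * (rho - u[2]) - u[1];
    d[2] = u[0] * u[1] - beta * u[2];
  };
  auto rk4 = [&](double* u) {
    double k1[3], k2[3], k3[3], k4[3], tmp[3];
    deriv(u, k1);
    for (int i = 0; i < 3; ++i) tmp[i] = u[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < 3; ++i) tmp[i] = u[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < 3; ++i) tmp[i] = u[i] + dt * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i < 3; ++i)
      u[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  };
  double x[3] = {1.0, 1.0, 1.0};
  int ntrans = (int)(T_transient / dt);
  for (int s = 0; s < ntrans; ++s) rk4(x);
  double y[3] = {x[0] + d0, x[1], x[2]};
  int nsteps = (int)(T / dt);
  double lsum = 0;
  int nren = 0;
  for (int s = 1; s <= nsteps; ++s) {
    rk4(x);
    rk4(y);
    if (s % renorm_every == 0) {
      double d = 0;
      for (int i = 0; i < 3; ++i) d += (y[i] - x[i]) * (y[i] - x[i]);
      d = std::sqrt(d);
      lsum += std::log(d / d0);
      ++nren;
      for (int i = 0; i < 3; ++i) y[i] = x[i] + (y[i] - x[i]) * d0 / d;
    }
  }
  return lsum / (nren * renorm_every * dt);
}

// ---------------------------------------------------------------------------
// Heun stochastic integrator on the scalar linear SDE dX = mu X dt + sigma dW
// over antithetic pairs; returns the sample mean of X_T.  Used for the
// weak-order check of the predictor-corrector scheme: for the linear test
// problem antithetic averaging removes the Monte-Carlo noise from the mean
// exactly, exposing the O(dt^2) weak bias.
// [[Rcpp::export]]
double cpp_srk2_linear_mean(double mu, double sigma, double x0,
                            double T, double dt, int npairs) {
  int nsteps = (int)std::round(T / dt);
  double sq = std::sqrt(dt);
  double acc = 0.0;
  for (int r = 0; r < npairs; ++r) {
    double xa = x0, xb = x0;
    for (int s = 0; s < nsteps; ++s) {
      double dW = sq * norm_rand();
      double pa = xa + mu * xa * dt + sigma * dW;
      xa += 0.5 * dt * (mu * xa + mu * pa) + sigma * dW;
      double pb = xb + mu * xb * dt - sigma * dW;
      xb += 0.5 * dt * (mu * xb + mu * pb) - sigma * dW;
    }
    acc += 0.5 * (xa + xb);
  }
  return acc / npairs;
}
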