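#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Right-hand side of the compartment ODEs.
//
// 4CCr (nstate = 4): s = (MA, MR, MFP, MFC)
//   dMA/dt  = -FP*MA - FC*MA + C(t)
//   dMR/dt  =  RP*MFP + RC*MFC - C(t)
//   dMFP/dt = -RP*MFP + FP*MA
//   dMFC/dt = -RC*MFC + FC*MA
// with C(t) = L * min(TL - MA, MR).
//
// 3CCr reference (nstate = 3): s = (MA, MR, MF); the single fatigue and
// recovery rates travel in the FC and RC slots (FP, RP unused).
static inline void ccr_rhs(int nstate, const double* s, double TL, double L,
                           double FP, double FC, double RP, double RC,
                           double* d) {
  double C = L * std::min(TL - s[0], s[1]);
  if (nstate == 4) {
    d[0] = -FP * s[0] - FC * s[0] + C;
    d[1] =  RP * s[2] + RC * s[3] - C;
    d[2] = -RP * s[2] + FP * s[0];
    d[3] = -RC * s[3] + FC * s[0];
  } else {
    d[0] = -FC * s[0] + C;
    d[1] =  RC * s[2] - C;
    d[2] = -RC * s[2] + FC * s[0];
  }
}

static inline void take_step(int nstate, double* s, double h, double TL,
                             double L, double FP, double FC, double RP,
                             double RC, int order) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  ccr_rhs(nstate, s, TL, L, FP, FC, RP, RC, k1);
  if (order == 1) {
    for (int i = 0; i < nstate; ++i) s[i] += h * k1[i];
    return;
  }
  for (int i = 0; i < nstate; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
  ccr_rhs(nstate, tmp, TL, L, FP, FC, RP, RC, k2);
  for (int i = 0; i < nstate; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
  ccr_rhs(nstate, tmp, TL, L, FP, FC, RP, RC, k3);
  for (int i = 0; i < nstate; ++i) tmp[i] = s[i] + h * k3[i];
  ccr_rhs(nstate, tmp, TL, L, FP, FC, RP, RC, k4);
  for (int i = 0; i < nstate; ++i)
    s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Clip tiny numerical excursions back into [0, 1] and renormalize the pool
// when drift exceeds 1e-12; abort on genuine instability (excursion beyond
// 1e-6, which at these rate scales only happens when dt fails to resolve the
// controller gain L).
static inline void clip_state(int nstate, double* s, double t, double dt,
                              double L) {
  for (int i = 0; i < nstate; ++i) {
    if (s[i] < -1e-6 || s[i] > 1.0 + 1e-6)
      stop("integration unstable at t = %g (compartment %d = %g); "
           "dt = %g is too large for controller gain L = %g",
           t, i + 1, s[i], dt, L);
    if (s[i] < 0.0) s[i] = 0.0;
    if (s[i] > 1.0) s[i] = 1.0;
  }
  double sum = 0.0;
  for (int i = 0; i < nstate; ++i) sum += s[i];
  if (std::fabs(sum - 1.0) > 1e-12)
    for (int i = 0; i < nstate; ++i) s[i] /= sum;
}

// Integrate the compartment model over piecewise-constant (TL, V) segments.
//
// seg_* give, per segment, the interval [t0, t1) and the rate coefficients
// (already resolved from velocity and load on the R side, so this routine is
// agnostic of Eqs for FP/FC/RC). Steps never straddle segment boundaries.
//
// rec_times (sorted, within [t0[0], t1[last]]) are additional knots at which
// the state is recorded exactly; with record_all = true every grid point is
// recorded instead and rec_times must be empty.
// [[Rcpp::export(name = ".integrate_ccr_cpp")]]
List integrate_ccr_cpp(NumericVector seg_t0, NumericVector seg_t1,
                       NumericVector seg_TL, NumericVector seg_FP,
                       NumericVector seg_FC, NumericVector seg_RP,
                       NumericVector seg_RC, double L, NumericVector init,
                       double dt, int order, NumericVector rec_times,
                       bool record_all) {
  const int nseg = seg_t0.size();
  const int nstate = init.size();
  const double tol = 1e-9;
  if (nstate != 3 && nstate != 4) stop("state must have 3 or 4 compartments");
  if (dt <= 0) stop("dt must be positive");
  if (order != 1 && order != 4) stop("order must be 1 (Euler) or 4 (RK4)");

  // guard against absurd full-trajectory recordings
  if (record_all) {
    double total = 0.0;
    for (int k = 0; k < nseg; ++k) total += seg_t1[k] - seg_t0[k];
    if (total / dt > 2e7)
      stop("full-grid recording would exceed 2e7 points; sample instead");
  }

  double s[4];
  for (int i = 0; i < nstate; ++i) s[i] = init[i];

  std::vector<double> out_t;
  std::vector<double> out_s;
  const int nrec = rec_times.size();
  int ri = 0;

  double t = seg_t0[0];
  if (record_all) {
    out_t.push_back(t);
    for (int i = 0; i < nstate; ++i) out_s.push_back(s[i]);
  }
  while (ri < nrec && rec_times[ri] <= t + tol) {
    out_t.push_back(rec_times[ri]);
    for (int i = 0; i < nstate; ++i) out_s.push_back(s[i]);
    ++ri;
  }

  for (int k = 0; k < nseg; ++k) {
    t = seg_t0[k];
    const double TL = seg_TL[k], FP = seg_FP[k], FC = seg_FC[k];
    const double RP = seg_RP[k], RC = seg_RC[k];
    while (t < seg_t1[k] - tol) {
      double target = seg_t1[k];
      if (ri < nrec && rec_times[ri] > t + tol && rec_times[ri] < target - tol)
        target = rec_times[ri];
      double len = target - t;
      int nst = (int)std::ceil(len / dt - 1e-9);
      if (nst < 1) nst = 1;
      for (int j = 0; j < nst; ++j) {
        double h = (j == nst - 1) ? (len - dt * (nst - 1)) : dt;
        take_step(nstate, s, h, TL, L, FP, FC, RP, RC, order);
        clip_state(nstate, s, t, dt, L);
        t = (j == nst - 1) ? target : t + h;
        if (record_all) {
          out_t.push_back(t);
          for (int i = 0; i < nstate; ++i) out_s.push_back(s[i]);
        }
      }
      while (ri < nrec && rec_times[ri] <= t + tol) {
        out_t.push_back(rec_times[ri]);
        for (int i = 0; i < nstate; ++i) out_s.push_back(s[i]);
        ++ri;
      }
    }
    // boundary-coincident record times (e.g. segment start == record time)
    while (ri < nrec && rec_times[ri] <= seg_t1[k] + tol) {
      out_t.push_back(rec_times[ri]);
      for (int i = 0; i < nstate; ++i) out_s.push_back(s[i]);
      ++ri;
    }
  }

  const int n = out_t.size();
  NumericVector time(n);
  NumericMatrix state(n, nstate);
  for (int p = 0; p < n; ++p) {
    time[p] = out_t[p];
    for (int i = 0; i < nstate; ++i) state(p, i) = out_s[p * nstate + i];
  }
  return List::create(_["time"] = time, _["state"] = state);
}
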