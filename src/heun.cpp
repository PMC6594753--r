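#include <Rcpp.h>
using namespace Rcpp;

// Right-hand sides of the four drug-partition/binding schemes.
// State conventions (concentrations, M):
//   scheme 1: x1 free drug in membrane, x2 unliganded channels
//   scheme 2: x1 drug in inner leaflet, x2 drug in outer leaflet,
//             x3 unliganded channels (outer leaflet)
//   scheme 3: x1 free drug in membrane, x2 unliganded, x3 monoliganded
//   scheme 4: x1 inner-leaflet drug, x2 outer-leaflet drug,
//             x3 unliganded, x4 monoliganded (outer leaflet)
// Diliganded channel concentration is implicit (Ct - unliganded - mono),
// so channel mass is conserved structurally.
static inline void scheme_rhs(const int scheme, const double* x, double* dx,
                              const double kin, const double kout,
                              const double kon, const double koff,
                              const double kflip, const double Ct,
                              const double Vc) {
  switch (scheme) {
  case 1: {
    const double x1 = x[0], x2 = x[1];
    dx[0] = kin * Vc - 2.0 * kout * x1 - kon * x1 * x2 + koff * (Ct - x2);
    dx[1] = -kon * x1 * x2 + koff * (Ct - x2);
    break;
  }
  case 2: {
    const double x1 = x[0], x2 = x[1], x3 = x[2];
    dx[0] = kin * Vc - (kout + kflip) * x1 + kflip * x2;
    dx[1] = kflip * x1 - (kout + kflip) * x2 - kon * x2 * x3 + koff * (Ct - x3);
    dx[2] = -kon * x2 * x3 + koff * (Ct - x3);
    break;
  }
  case 3: {
    const double x1 = x[0], x2 = x[1], x3 = x[2];
    dx[0] = kin * Vc - 2.0 * kout * x1 - kon * (2.0 * x2 + x3) * x1
            + koff * (2.0 * (Ct - x2 - x3) + x3);
    dx[1] = -2.0 * kon * x1 * x2 + koff * x3;
    dx[2] = 2.0 * kon * x1 * x2 + 2.0 * koff * (Ct - x2 - x3)
            - (koff + kon * x1) * x3;
    break;
  }
  default: { // scheme 4
    const double x1 = x[0], x2 = x[1], x3 = x[2], x4 = x[3];
    dx[0] = kin * Vc - (kout + kflip) * x1 + kflip * x2;
    dx[1] = kflip * x1 - (kout + kflip) * x2 - kon * (2.0 * x3 + x4) * x2
            + koff * (2.0 * (Ct - x3 - x4) + x4);
    dx[2] = -2.0 * kon * x2 * x3 + koff * x4;
    dx[3] = 2.0 * kon * x2 * x3 + 2.0 * koff * (Ct - x3 - x4)
            - (koff + kon * x2) * x4;
    break;
  }
  }
}

static inline int scheme_dim(const int scheme) {
  return (scheme == 1) ? 2 : (scheme == 4) ? 4 : 3;
}

// Fraction of channels NOT in the potentiated (fully liganded) class.
static inline double unpot_fraction(const int scheme, const double* x,
                                    const double Ct) {
  switch (scheme) {
  case 1: return x[1] / Ct;
  case 2: return x[2] / Ct;
  case 3: return (x[1] + x[2]) / Ct;
  default: return (x[2] + x[3]) / Ct;
  }
}

// [[Rcpp::export(name = ".heun_rhs")]]
NumericVector heun_rhs(int scheme, NumericVector state, double kin,
                       double kout, double kon, double koff, double kflip,
                       double Ct, double Vc) {
  const int n = scheme_dim(scheme);
  NumericVector dx(n);
  scheme_rhs(scheme, state.begin(), dx.begin(), kin, kout, kon, koff, kflip,
             Ct, Vc);
  return dx;
}

// Heun predictor-corrector over a piecewise-constant drug protocol.
// seg_dur / seg_conc: protocol segments; x0: initial state; sampling every
// `thin` steps. Returns sampled times, normalized current, states, and the
// final state; aborts if any component drops below -1e-9 * Ct.
// [[Rcpp::export(name = ".heun_integrate")]]
List heun_integrate(int scheme, NumericVector x0, NumericVector seg_dur,
                    NumericVector seg_conc, double kin, double kout,
                    double kon, double koff, double kflip, double Ct,
                    double po_ratio, double dt, int thin) {
  const int n = scheme_dim(scheme);
  if (x0.size() != n) stop("state vector has length %d; scheme %d needs %d",
                           (int)x0.size(), scheme, n);
  const int nseg = seg_dur.size();
  double total = 0.0;
  for (int s = 0; s < nseg; ++s) total += seg_dur[s];
  const long nstep = (long)std::ceil(total / dt - 1e-9);
  const long nout = nstep / thin + 2;

  NumericVector t_out(nout), i_out(nout);
  NumericMatrix x_out(nout, n);
  double x[4], xp[4], k1[4], k2[4];
  for (int j = 0; j < n; ++j) x[j] = x0[j];

  const double neg_tol = -1e-9 * Ct;
  long iout = 0;
  double t = 0.0;
  int seg = 0;
  double seg_end = seg_dur[0];

  // record a sample
  auto record = [&](double tt) {
    t_out[iout] = tt;
    const double f = unpot_fraction(scheme, x, Ct);
    i_out[iout] = f + (1.0 - f) * po_ratio;
    for (int j = 0; j < n; ++j) x_out(iout, j) = x[j];
    ++iout;
  };
  record(0.0);

  for (long step = 0; step < nstep; ++step) {
    // piecewise-constant Vc: use the segment the step starts in
    while (seg < nseg - 1 && t >= seg_end - 1e-12) {
      ++seg;
      seg_end += seg_dur[seg];
    }
    const double Vc = seg_conc[seg];
    const double h = std::min(dt, total - t);

    scheme_rhs(scheme, x, k1, kin, kout, kon, koff, kflip, Ct, Vc);
    for (int j = 0; j < n; ++j) xp[j] = x[j] + h * k1[j];
    scheme_rhs(scheme, xp, k2, kin, kout, kon, koff, kflip, Ct, Vc);
    for (int j = 0; j < n; ++j) x[j] += 0.5 * h * (k1[j] + k2[j]);
    t += h;

    for (int j = 0; j < n; ++j) {
      if (x[j] < neg_tol)
        stop("integration unstable at t = %g s (state component %d = %g); "
             "reduce dt", t, j + 1, x[j]);
    }

    if ((step + 1) % thin == 0 || step == nstep - 1) record(t);
  }

  NumericVector xf(n);
  for (int j = 0; j < n; ++j) xf[j] = x[j];

  IntegerVector keep = seq(0, (int)iout - 1);
  NumericMatrix xs((int)iout, n);
  for (int r = 0; r < (int)iout; ++r)
    for (int j = 0; j < n; ++j) xs(r, j) = x_out(r, j);

  return List::create(_["t"] = t_out[keep], _["i_norm"] = i_out[keep],
                      _["states"] = xs, _["final_state"] = xf);
}
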