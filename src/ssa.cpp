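#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie simulation of the 4-channel circuit reaction
// network: production and first-order removal of each of the two module
// proteins. Propensities are evaluated at concentrations N / omega with the
// same functional form as the deterministic right-hand side. Doses are
// piecewise constant: C6 switches on at t_c6, so propensities are constant
// between reactions within an epoch; the pending waiting time is truncated
// at the epoch boundary and redrawn (memorylessness makes this exact).
//
// Uses R's RNG (unif_rand via R::runif) so results are reproducible under
// set.seed().

static inline double hillA(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x / K, n);
  return xn / (1.0 + xn);
}

struct CircuitPars {
  double alpha1, alpha2, beta1, beta2, K1, K2, n1, n2, delta1, delta2;
  double c12eff, c21, lambda1, lambda2, copy_scale;
  bool two_strain;
};

static inline void propensities(const CircuitPars &p, double uA, double uC,
                                double N1, double N2, double omega,
                                double a[4]) {
  double m1 = N1 / omega, m2 = N2 / omega;
  double in1 = m1 * uA * (1.0 + p.c21 * m2);
  double in2 = m2 * (uC + p.c12eff * m1 * uA);
  double a1 = p.beta1 + (1.0 - p.beta1) * hillA(in1, p.K1, p.n1);
  double a2 = p.beta2 + (1.0 - p.beta2) * hillA(in2, p.K2, p.n2);
  double r1, r2;
  if (p.two_strain) {
    r1 = 1.0 / (1.0 + p.lambda1 * a1);
    r2 = 1.0 / (1.0 + p.lambda2 * a2);
  } else {
    double shared = 1.0 / (1.0 + p.lambda1 * a1 + p.lambda2 * a2);
    r1 = shared; r2 = shared;
  }
  a[0] = omega * p.copy_scale * p.alpha1 * r1 * a1;  // production of N1
  a[1] = omega * p.copy_scale * p.alpha2 * r2 * a2;  // production of N2
  a[2] = p.delta1 * N1;                              // removal of N1
  a[3] = p.delta2 * N2;                              // removal of N2
}

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(NumericVector par, double uA, double uC, double t_c6,
                 double t_end, double omega, double N1_0, double N2_0,
                 NumericVector sample_times, int occ_max1, int occ_max2,
                 double max_events) {
  CircuitPars p;
  p.alpha1 = par["alpha1"];  p.alpha2 = par["alpha2"];
  p.beta1  = par["beta1"];   p.beta2  = par["beta2"];
  p.K1 = par["K1"]; p.K2 = par["K2"]; p.n1 = par["n1"]; p.n2 = par["n2"];
  p.delta1 = par["delta1"]; p.delta2 = par["delta2"];
  p.c12eff = par["c12eff"]; p.c21 = par["c21"];
  p.lambda1 = par["lambda1"]; p.lambda2 = par["lambda2"];
  p.copy_scale = par["copy_scale"];
  p.two_strain = par["two_strain"] > 0.5;

  int ns = sample_times.size();
  NumericVector out1(ns), out2(ns);
  bool track_occ = occ_max1 > 0 && occ_max2 > 0;
  NumericMatrix occ(track_occ ? occ_max1 + 1 : 1,
                    track_occ ? occ_max2 + 1 : 1);

  double t = 0.0, N1 = N1_0, N2 = N2_0;
  double uC_now = (t_c6 <= 0.0) ? uC : 0.0;
  double a[4];
  int si = 0;
  double n_events = 0.0;
  bool c6_pending = t_c6 > 0.0 && uC > 0.0;

  while (t < t_end) {
    propensities(p, uA, uC_now, N1, N2, omega, a);
    double a0 = a[0] + a[1] + a[2] + a[3];
    double t_next;
    if (a0 <= 0.0) {
      t_next = R_PosInf;
    } else {
      t_next = t + R::exp_rand() / a0;
    }
    // epoch boundary: truncate and redraw with the new dose in force
    if (c6_pending && t_next > t_c6) {
      while (si < ns && sample_times[si] <= t_c6) {
        out1[si] = N1; out2[si] = N2; ++si;
      }
      if (track_occ) {
        int i1 = (int)std::min(N1, (double)occ_max1);
        int i2 = (int)std::min(N2, (double)occ_max2);
        occ(i1, i2) += t_c6 - t;
      }
      t = t_c6;
      uC_now = uC;
      c6_pending = false;
      continue;
    }
    if (t_next > t_end) {
      while (si < ns && sample_times[si] <= t_end) {
        out1[si] = N1; out2[si] = N2; ++si;
      }
      if (track_occ) {
        int i1 = (int)std::min(N1, (double)occ_max1);
        int i2 = (int)std::min(N2, (double)occ_max2);
        occ(i1, i2) += t_end - t;
      }
      t = t_end;
      break;
    }
    // record samples falling inside the holding interval
    while (si < ns && sample_times[si] < t_next) {
      out1[si] = N1; out2[si] = N2; ++si;
    }
    if (track_occ) {
      int i1 = (int)std::min(N1, (double)occ_max1);
      int i2 = (int)std::min(N2, (double)occ_max2);
      occ(i1, i2) += t_next - t;
    }
    t = t_next;
    double r = R::unif_rand() * a0;
    if (r < a[0]) N1 += 1.0;
    else if (r < a[0] + a[1]) N2 += 1.0;
    else if (r < a[0] + a[1] + a[2]) N1 -= 1.0;
    else N2 -= 1.0;
    n_events += 1.0;
    if (n_events >= max_events)
      stop("SSA exceeded max_events (%.0f); raise the cap or shorten t_end",
           max_events);
  }
  while (si < ns) { out1[si] = N1; out2[si] = N2; ++si; }

  List res = List::create(_["N1"] = out1, _["N2"] = out2,
                          _["final"] = NumericVector::create(N1, N2),
                          _["n_events"] = n_events);
  if (track_occ) res["occupancy"] = occ;
  return res;
}
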