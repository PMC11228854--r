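#include <Rcpp.h>
using namespace Rcpp;

// One generation of the exact recursion.  par layout:
// 0:u 1:z 2:u_prime 3:t1 4:t2 5:m1 6:m2 7:f
// 8:wAA 9:wAB 10:wAa 11:wBB 12:wBa 13:waa
static inline void step(double &pA, double &pB, double &pa,
                        const double *par, double &wbar) {
  const double f = par[7], omf = 1.0 - f;
  // mating
  double gAA = pA * pA * omf + pA * f;
  double gBB = pB * pB * omf + pB * f;
  double gaa = pa * pa * omf + pa * f;
  double gAB = 2.0 * pA * pB * omf;
  double gAa = 2.0 * pA * pa * omf;
  double gBa = 2.0 * pB * pa * omf;
  // paramutation
  gBB += par[5] * gAB; gAB *= (1.0 - par[5]);
  gBa += par[6] * gAa; gAa *= (1.0 - par[6]);
  // selection
  wbar = par[8] * gAA + par[9] * gAB + par[10] * gAa +
         par[11] * gBB + par[12] * gBa + par[13] * gaa;
  gAA = par[8] * gAA / wbar;  gAB = par[9] * gAB / wbar;
  gAa = par[10] * gAa / wbar; gBB = par[11] * gBB / wbar;
  gBa = par[12] * gBa / wbar; gaa = par[13] * gaa / wbar;
  // gamete frequencies
  double qA = gAA + 0.5 * (gAB + gAa);
  double qB = gBB + 0.5 * (gAB + gBa);
  double qa = gaa + 0.5 * (gAa + gBa);
  // spontaneous epimutation
  double rA = (1.0 - par[3]) * qA + par[4] * qB;
  double rB = (1.0 - par[4]) * qB + par[3] * qA;
  // mutation
  pA = rA * (1.0 - par[0]) + par[1] * qa;
  pB = rB * (1.0 - par[2]);
  pa = qa * (1.0 - par[1]) + par[0] * rA + par[2] * rB;
  double s = pA + pB + pa;
  if (std::abs(s - 1.0) > 1e-12) { pA /= s; pB /= s; pa /= s; }
}

static inline double wbar_of(double pA, double pB, double pa,
                             const double *par) {
  const double f = par[7], omf = 1.0 - f;
  double gAA = pA * pA * omf + pA * f;
  double gBB = pB * pB * omf + pB * f;
  double gaa = pa * pa * omf + pa * f;
  double gAB = 2.0 * pA * pB * omf;
  double gAa = 2.0 * pA * pa * omf;
  double gBa = 2.0 * pB * pa * omf;
  gBB += par[5] * gAB; gAB *= (1.0 - par[5]);
  gBa += par[6] * gAa; gAa *= (1.0 - par[6]);
  return par[8] * gAA + par[9] * gAB + par[10] * gAa +
         par[11] * gBB + par[12] * gBa + par[13] * gaa;
}

// Iterate the recursion with streaming convergence and cycling
// diagnostics.  Returns final state, generation count, converged flag,
// cycling statistics, and (optionally) the recorded trajectory.
// [[Rcpp::export]]
List cpp_iterate(NumericVector p0, NumericVector par, double tol,
                 int patience, double max_gens, int record_every,
                 double cycle_eps) {
  double pA = p0[0], pB = p0[1], pa = p0[2];
  const double *pp = REAL(par);
  long long maxg = (long long)max_gens;

  std::vector<double> rec_gen, rec_A, rec_B, rec_a, rec_w;
  bool record = record_every > 0;
  if (record) {
    rec_gen.reserve(1024); rec_A.reserve(1024); rec_B.reserve(1024);
    rec_a.reserve(1024); rec_w.reserve(1024);
  }

  int stable_run = 0;
  bool converged = false;
  long long gen = 0;
  // cycling diagnostics on increments of p_a
  long long n_flips = 0, last_flip = 0;
  int prev_sign = 0;
  double pa_min = pa, pa_max = pa;

  if (record) {
    rec_gen.push_back(0); rec_A.push_back(pA); rec_B.push_back(pB);
    rec_a.push_back(pa); rec_w.push_back(wbar_of(pA, pB, pa, pp));
  }

  while (gen < maxg) {
    double oA = pA, oB = pB, oa = pa, wbar;
    step(pA, pB, pa, pp, wbar);
    ++gen;
    if (!R_finite(pA) || !R_finite(pB) || !R_finite(pa))
      stop("non-finite frequency at generation %lld", gen);

    double d = pa - oa;
    if (std::abs(d) >= cycle_eps && d != 0.0) {
      int sgn = d > 0 ? 1 : -1;
      if (prev_sign != 0 && sgn != prev_sign) { ++n_flips; last_flip = gen; }
      prev_sign = sgn;
    }
    if (pa < pa_min) pa_min = pa;
    if (pa > pa_max) pa_max = pa;

    if (record && (gen % record_every == 0)) {
      rec_gen.push_back((double)gen); rec_A.push_back(pA);
      rec_B.push_back(pB); rec_a.push_back(pa); rec_w.push_back(wbar);
    }

    double delta = std::max(std::abs(pA - oA),
                   std::max(std::abs(pB - oB), std::abs(pa - oa)));
    if (delta < tol) {
      if (++stable_run >= patience) { converged = true; break; }
    } else {
      stable_run = 0;
    }
  }

  if (record && (rec_gen.empty() || rec_gen.back() != (double)gen)) {
    rec_gen.push_back((double)gen); rec_A.push_back(pA);
    rec_B.push_back(pB); rec_a.push_back(pa);
    rec_w.push_back(wbar_of(pA, pB, pa, pp));
  }

  double amp = std::max(pa_max - pa, pa - pa_min);
  List out = List::create(
    _["p"] = NumericVector::create(pA, pB, pa),
    _["generations"] = (double)gen,
    _["converged"] = converged,
    _["oscillations"] = (double)n_flips,
    _["cycling_duration"] = (double)last_flip,
    _["amplitude"] = amp);
  if (record)
    out["trajectory"] = DataFrame::create(
      _["generation"] = rec_gen, _["p_A"] = rec_A, _["p_B"] = rec_B,
      _["p_a"] = rec_a, _["mean_fitness"] = rec_w);
  return out;
}

// Single generation step (compiled path), used for cross-checking
// against the R-level stage composition.
// [[Rcpp::export]]
NumericVector cpp_step(NumericVector p0, NumericVector par) {
  double pA = p0[0], pB = p0[1], pa = p0[2], wbar;
  step(pA, pB, pa, REAL(par), wbar);
  NumericVector out = NumericVector::create(pA, pB, pa);
  out.attr("mean_fitness") = wbar;
  return out;
}
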