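#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step forward-Euler integration of a tree of electrically coupled
// Izhikevich compartments. All validation and unit conversion happens on the
// R side; this routine assumes consistent internal units (mV, ms, pA, pF, nS).
//
// par: ncomp x 9 matrix, columns C, k, Vr, Vt, Vpeak, Vmin, a, b, d.
// edges: prox/dist are 1-based compartment indices; per-edge coupling G (nS)
//   and asymmetry P in [0,1].
// steps: nstim x 4 matrix (target, amplitude_pA, onset_ms, duration_ms).
// syn: list of synaptic drives, each list(target, g_inc, tau, erev, events).
//   Single-exponential conductance: g += g_inc at each event, decays with tau,
//   current g * (erev - V) enters the target compartment.
//
// A spike is stamped at the first step whose updated V reaches Vpeak; V is
// reset to Vmin and U incremented by d at that same step, so the stored series
// satisfies V == Vmin immediately after every recorded spike.
// [[Rcpp::export]]
List sim_izhi_cpp(NumericMatrix par,
                  IntegerVector edge_prox, IntegerVector edge_dist,
                  NumericVector edge_G, NumericVector edge_P,
                  NumericMatrix steps, List syn,
                  double dt, double total_time,
                  NumericVector v0, NumericVector u0,
                  bool record) {
  const int ncomp = par.nrow();
  const int nedge = edge_prox.size();
  const int nstim = steps.nrow();
  const int nsyn = syn.size();
  const int nt = (int)std::lround(total_time / dt);

  std::vector<double> V(ncomp), U(ncomp), I(ncomp);
  for (int j = 0; j < ncomp; ++j) { V[j] = v0[j]; U[j] = u0[j]; }

  NumericMatrix Vs, Us;
  if (record) {
    Vs = NumericMatrix(nt + 1, ncomp);
    Us = NumericMatrix(nt + 1, ncomp);
    for (int j = 0; j < ncomp; ++j) { Vs(0, j) = V[j]; Us(0, j) = U[j]; }
  }

  // synaptic state: conductance per drive + event schedule as step indices
  std::vector<double> g(nsyn, 0.0), gdecay(nsyn), ginc(nsyn), erev(nsyn);
  std::vector<int> starget(nsyn);
  std::vector<std::vector<int> > events(nsyn);
  std::vector<size_t> next_ev(nsyn, 0);
  for (int s = 0; s < nsyn; ++s) {
    List sp = syn[s];
    starget[s] = as<int>(sp["target"]) - 1;
    ginc[s] = as<double>(sp["g_inc"]);
    gdecay[s] = std::exp(-dt / as<double>(sp["tau"]));
    erev[s] = as<double>(sp["erev"]);
    NumericVector ev = sp["events"];
    for (int e = 0; e < ev.size(); ++e)
      events[s].push_back((int)std::ceil(ev[e] / dt - 1e-9));
  }

  std::vector<std::vector<double> > spikes(ncomp);
  bool ok = true;
  int n_bad = -1;

  // hoist per-compartment parameters out of the time loop
  std::vector<double> pC(ncomp), pk(ncomp), pVr(ncomp), pVt(ncomp),
      pVpeak(ncomp), pVmin(ncomp), pa(ncomp), pb(ncomp), pd(ncomp);
  for (int j = 0; j < ncomp; ++j) {
    pC[j] = par(j, 0); pk[j] = par(j, 1); pVr[j] = par(j, 2);
    pVt[j] = par(j, 3); pVpeak[j] = par(j, 4); pVmin[j] = par(j, 5);
    pa[j] = par(j, 6); pb[j] = par(j, 7); pd[j] = par(j, 8);
  }
  std::vector<int> st_t(nstim);
  std::vector<double> st_a(nstim), st_on(nstim), st_off(nstim);
  for (int s = 0; s < nstim; ++s) {
    st_t[s] = (int)steps(s, 0) - 1;
    st_a[s] = steps(s, 1);
    st_on[s] = steps(s, 2) - 1e-9;
    st_off[s] = steps(s, 2) + steps(s, 3) - 1e-9;
  }
  std::vector<int> e_p(nedge), e_d(nedge);
  std::vector<double> e_f(nedge), e_b(nedge);
  for (int e = 0; e < nedge; ++e) {
    e_p[e] = edge_prox[e] - 1; e_d[e] = edge_dist[e] - 1;
    e_f[e] = edge_G[e] * edge_P[e];
    e_b[e] = edge_G[e] * (1.0 - edge_P[e]);
  }

  for (int n = 0; n < nt && ok; ++n) {
    const double t = n * dt;
    for (int j = 0; j < ncomp; ++j) I[j] = 0.0;
    for (int s = 0; s < nstim; ++s) {
      if (t >= st_on[s] && t < st_off[s]) I[st_t[s]] += st_a[s];
    }
    for (int s = 0; s < nsyn; ++s) {
      while (next_ev[s] < events[s].size() && events[s][next_ev[s]] <= n) {
        g[s] += ginc[s];
        ++next_ev[s];
      }
      I[starget[s]] += g[s] * (erev[s] - V[starget[s]]);
      g[s] *= gdecay[s];
    }
    for (int e = 0; e < nedge; ++e) {
      const double dv = V[e_p[e]] - V[e_d[e]];
      I[e_p[e]] -= e_f[e] * dv;      // I_prox = G*P*(Vprox-Vdist)
      I[e_d[e]] -= e_b[e] * (-dv);   // I_dist = G*(1-P)*(Vdist-Vprox)
    }
    for (int j = 0; j < ncomp; ++j) {
      double Vn = V[j] +
        dt * (pk[j] * (V[j] - pVr[j]) * (V[j] - pVt[j]) - U[j] + I[j]) / pC[j];
      double Un = U[j] + dt * pa[j] * (pb[j] * (V[j] - pVr[j]) - U[j]);
      if (Vn >= pVpeak[j]) {
        spikes[j].push_back((n + 1) * dt);
        Vn = pVmin[j];
        Un += pd[j];
      }
      if (!std::isfinite(Vn) || !std::isfinite(Un) || std::fabs(Vn) > 1e8) {
        ok = false;
        n_bad = n + 1;
      }
      V[j] = Vn;
      U[j] = Un;
      if (record) { Vs(n + 1, j) = Vn; Us(n + 1, j) = Un; }
    }
  }

  List spk(ncomp);
  for (int j = 0; j < ncomp; ++j) spk[j] = wrap(spikes[j]);
  return List::create(_["ok"] = ok, _["bad_step"] = n_bad,
                      _["V"] = record ? (SEXP)Vs : R_NilValue,
                      _["U"] = record ? (SEXP)Us : R_NilValue,
                      _["spikes"] = spk, _["nt"] = nt);
}
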