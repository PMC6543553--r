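#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-queue simulation of a fully interconnected leaky integrate-and-fire
// network with alpha-shaped conductance synapses.
//
// Integration is exponential Euler at fixed step dt. Each neuron keeps two
// alpha-synapse state pairs (excitatory / inhibitory reversal); the pair
// (s1, s2) follows the exact recursion
//    s2 <- (s2 + dt * s1) * exp(-dt/taus);  s1 <- s1 * exp(-dt/taus)
// so that an impulse amp/taus added to s1 at the event time contributes the
// exact alpha kernel amp * (t/taus) * exp(-t/taus) to the conductance s2.
//
// Synaptic events are deposited into per-step impulse buffers: peripheral
// events up front (already delayed by the caller), cortico-cortical events
// when the presynaptic spike occurs, at spike time + transmission delay.
//
// Membrane: taum dv/dt = (vrest - v) + Rm gE (vE - v) + Rm gI (vI - v) + tonic
// (tonic in mV). On v >= vth: spike, v <- vK (reset/after-hyperpolarization),
// clamp for the refractory period. The simulation is fully deterministic.

// [[Rcpp::export]]
List lifSimulateCpp(NumericMatrix Wamp, IntegerMatrix Wsign,
                    NumericMatrix ccDelay,
                    NumericVector inAmp, IntegerVector inSign,
                    NumericVector inDelay, List inputEvents,
                    double durationMs, List pars, bool traceV,
                    NumericVector v0, NumericVector tonic) {
  const int n = Wamp.nrow();
  const double dt    = as<double>(pars["dt"]);
  const double taum  = as<double>(pars["taum"]);
  const double vrest = as<double>(pars["vrest"]);
  const double Rm    = as<double>(pars["Rm"]);
  const double vE    = as<double>(pars["vE"]);
  const double vI    = as<double>(pars["vI"]);
  const double vK    = as<double>(pars["vK"]);
  const double taus  = as<double>(pars["taus"]);
  const double vth   = as<double>(pars["vth"]);
  const double refr  = as<double>(pars["refractory"]);

  const int nsteps = (int)std::ceil(durationMs / dt);
  const double dS = std::exp(-dt / taus);
  const double eLeak = std::exp(-dt / taum);  // pure-leak fast path

  // impulse buffers indexed [step * n + neuron]
  std::vector<double> pendE((size_t)(nsteps + 1) * n, 0.0);
  std::vector<double> pendI((size_t)(nsteps + 1) * n, 0.0);

  // peripheral events: channel c drives neuron c one-to-one
  for (int c = 0; c < n; ++c) {
    if (inSign[c] == 0) continue;
    NumericVector ev = inputEvents[c];
    std::vector<double> &pend = (inSign[c] > 0) ? pendE : pendI;
    for (int k = 0; k < ev.size(); ++k) {
      long idx = (long)std::llround((ev[k] + inDelay[c]) / dt);
      if (idx >= 0 && idx <= nsteps)
        pend[(size_t)idx * n + c] += inAmp[c];
    }
  }

  // precompute cortico-cortical delay steps and fan-out lists
  std::vector<std::vector<int>> fan(n);
  std::vector<std::vector<int>> fanDelay(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (Wsign(i, j) != 0) {
        fan[i].push_back(j);
        int ds = (int)std::llround(ccDelay(i, j) / dt);
        fanDelay[i].push_back(ds < 0 ? 0 : ds);
      }

  std::vector<double> v(n), s1E(n, 0.0), s2E(n, 0.0), s1I(n, 0.0), s2I(n, 0.0);
  std::vector<double> refrUntil(n, -1.0);
  for (int i = 0; i < n; ++i) v[i] = v0[i];

  std::vector<std::vector<double>> spikes(n);
  NumericMatrix vtr;
  if (traceV) {
    vtr = NumericMatrix(nsteps + 1, n);
    for (int i = 0; i < n; ++i) vtr(0, i) = v[i];
  }

  for (int k = 0; k < nsteps; ++k) {
    const double tNext = (k + 1) * dt;
    for (int i = 0; i < n; ++i) {
      // impulses deposited for time k*dt enter s1 before the decay step,
      // so their conductance is zero at the event time itself
      s1E[i] += pendE[(size_t)k * n + i] / taus;
      s1I[i] += pendI[(size_t)k * n + i] / taus;
      s2E[i] = (s2E[i] + dt * s1E[i]) * dS;  s1E[i] *= dS;
      s2I[i] = (s2I[i] + dt * s1I[i]) * dS;  s1I[i] *= dS;

      if (refrUntil[i] >= tNext) {
        v[i] = vK;
      } else {
        const double gE = Rm * s2E[i], gI = Rm * s2I[i];
        if (gE + gI < 1e-12) {
          const double vinf = vrest + tonic[i];
          v[i] = vinf + (v[i] - vinf) * eLeak;
        } else {
          const double a = (1.0 + gE + gI) / taum;
          const double b = (vrest + tonic[i] + gE * vE + gI * vI) / taum;
          const double vinf = b / a;
          v[i] = vinf + (v[i] - vinf) * std::exp(-a * dt);
        }
        if (v[i] >= vth) {
          spikes[i].push_back(tNext);
          v[i] = vK;
          refrUntil[i] = tNext + refr;
          for (size_t s = 0; s < fan[i].size(); ++s) {
            long idx = (long)(k + 1) + fanDelay[i][s];
            if (idx <= nsteps) {
              int j = fan[i][s];
              if (Wsign(i, j) > 0)
                pendE[(size_t)idx * n + j] += Wamp(i, j);
              else
                pendI[(size_t)idx * n + j] += Wamp(i, j);
            }
          }
        }
      }
      if (traceV) vtr(k + 1, i) = v[i];
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = wrap(spikes[i]);
  return List::create(_["spikes"] = spk,
                      _["vtrace"] = traceV ? vtr : NumericMatrix(0, 0),
                      _["nsteps"] = nsteps);
}
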