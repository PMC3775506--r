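#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stepwise integrator for the conductance-based LIF network.
//
// Per step: (1) decay the summed excitatory/inhibitory conductances and add
// all deliveries (recurrent ring buffer + external events) falling in the
// step; (2) advance V with the exponential update, conductances frozen over
// the step; (3) neurons at or above threshold and out of refractoriness
// spike: V is reset, a refractory clamp starts, and their outgoing weights
// are scheduled delay_steps ahead in the ring buffer.
//
// Indexing is 0-based and global: excitatory neurons first (0..n_exc-1),
// then inhibitory. A spike of a source < n_exc lands on the target's
// excitatory conductance, otherwise on the inhibitory one. External event
// lists are CSR-indexed by step; recurrent synapses CSR-indexed by source.
//
// Units: V mV, g uS, C nF, t ms (mV*uS = nA, nA/nF = mV/ms).

// [[Rcpp::export]]
List sim_core(int n_exc, int n_inh,
              NumericVector v_init,
              List nrn, double dt, int n_steps,
              IntegerVector syn_ptr, IntegerVector syn_tgt,
              NumericVector syn_w, IntegerVector syn_dstep,
              IntegerVector stim_ptr, IntegerVector stim_tgt, double stim_w,
              IntegerVector nxE_ptr, IntegerVector nxE_tgt, double nxE_w,
              IntegerVector nxI_ptr, IntegerVector nxI_tgt, double nxI_w,
              IntegerVector record_idx) {
  const int n = n_exc + n_inh;
  const double Cm = nrn["C_m"], gl = nrn["g_l"], El = nrn["E_l"];
  const double EE = nrn["E_E"], EI = nrn["E_I"];
  const double tauE = nrn["tau_E"], tauI = nrn["tau_I"];
  const double Vth = nrn["V_thresh"], Vreset = nrn["V_reset"];
  const int refrac_steps = (int)nrn["refrac_steps"];
  const double decE = std::exp(-dt / tauE), decI = std::exp(-dt / tauI);

  int max_d = 1;
  for (int k = 0; k < syn_dstep.size(); ++k)
    if (syn_dstep[k] > max_d) max_d = syn_dstep[k];
  const int ring = max_d + 1;

  std::vector<double> bufE((size_t)ring * n, 0.0), bufI((size_t)ring * n, 0.0);
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> gE(n, 0.0), gI(n, 0.0);
  std::vector<int> refrac_until(n, 0);

  std::vector<int> sp_id, sp_step;
  sp_id.reserve(1 << 16);
  sp_step.reserve(1 << 16);

  const int n_rec = record_idx.size();
  NumericMatrix vtrace(n_rec > 0 ? n_steps : 0, n_rec);

  for (int t = 0; t < n_steps; ++t) {
    double* bE = &bufE[(size_t)(t % ring) * n];
    double* bI = &bufI[(size_t)(t % ring) * n];
    for (int i = 0; i < n; ++i) {
      gE[i] = gE[i] * decE + bE[i];
      gI[i] = gI[i] * decI + bI[i];
      bE[i] = 0.0;
      bI[i] = 0.0;
    }
    for (int k = stim_ptr[t]; k < stim_ptr[t + 1]; ++k) gE[stim_tgt[k]] += stim_w;
    for (int k = nxE_ptr[t]; k < nxE_ptr[t + 1]; ++k) gE[nxE_tgt[k]] += nxE_w;
    for (int k = nxI_ptr[t]; k < nxI_ptr[t + 1]; ++k) gI[nxI_tgt[k]] += nxI_w;

    for (int i = 0; i < n; ++i) {
      if (refrac_until[i] > t) {
        V[i] = Vreset;
        continue;
      }
      const double gtot = gl + gE[i] + gI[i];
      const double vinf = (gl * El + gE[i] * EE + gI[i] * EI) / gtot;
      V[i] = vinf + (V[i] - vinf) * std::exp(-dt * gtot / Cm);
      if (!R_finite(V[i])) stop("membrane potential diverged at step %d, neuron %d", t, i + 1);
      if (V[i] >= Vth) {
        sp_id.push_back(i + 1);
        sp_step.push_back(t);
        V[i] = Vreset;
        refrac_until[i] = t + refrac_steps;
        for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k) {
          const size_t slot = (size_t)((t + syn_dstep[k]) % ring) * n + syn_tgt[k];
          if (i < n_exc) bufE[slot] += syn_w[k];
          else bufI[slot] += syn_w[k];
        }
      }
    }
    for (int r = 0; r < n_rec; ++r) vtrace(t, r) = V[record_idx[r]];
  }

  return List::create(_["neuron_id"] = wrap(sp_id),
                      _["step"] = wrap(sp_step),
                      _["vtrace"] = vtrace);
}
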