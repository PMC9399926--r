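// Clock-driven simulator for leaky integrate-and-fire neurons with
// multi-port exponential postsynaptic currents (current-based).
//
// Subthreshold dynamics are linear, so each step uses the exact propagator
// of the (v, i_1..i_P) system:
//
//   tau_m dv/dt = -(v - E_L) + R * sum_p i_p(t),   tau_p di_p/dt = -i_p
//
//   v(t+dt)  = E_L + (v - E_L) e^{-dt/tau_m} + sum_p G_p i_p(t)
//   i_p(t+dt) = i_p(t) e^{-dt/tau_p}
//
// with G_p = (tau_m tau_p / (C_m (tau_m - tau_p))) (e^{-dt/tau_m} - e^{-dt/tau_p})
// (alpha-limit G_p = dt e^{-dt/tau} / C_m when tau_p == tau_m).
//
// Spikes are detected on the grid: a neuron whose propagated v reaches
// threshold emits at the end of the step (time (t+1)*dt), is reset, and is
// clamped at v_reset for its refractory period (synaptic currents keep
// integrating). A spike emitted at time s steps the target's current at
// time s + delay of its port, via one ring buffer per port. Poisson
// generators are sampled per target neuron per step from R's RNG, so a run
// is a pure function of the R random seed and the network description.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Knuth-style Poisson count sampler for small means (mu = rate*dt << 1).
// lexp = exp(-mu) is precomputed by the caller.
inline int rpois_small(double lexp) {
  int k = 0;
  double p = unif_rand();
  while (p > lexp) {
    ++k;
    p *= unif_rand();
  }
  return k;
}

} // namespace

// [[Rcpp::export(name = ".simulate_trial_cpp")]]
List simulate_trial_cpp(
    const IntegerVector& pop,        // population index per neuron (0=A,1=B,2=I)
    const NumericVector& e_l,        // per-neuron leak/resting potential (mV)
    const NumericVector& tau_m,      // per-neuron membrane time constant (ms)
    const NumericVector& c_m,        // per-neuron capacitance (pF)
    const NumericVector& v_th,       // per-neuron threshold (mV)
    const NumericVector& v_reset,    // per-neuron reset (mV)
    const NumericVector& t_ref,      // per-neuron refractory period (ms)
    const NumericVector& tau_syn,    // per-port synaptic time constant (ms)
    const IntegerVector& delay_steps,// per-port delay in steps (>= 1)
    const IntegerVector& conn_src,   // 0-based source per connection
    const IntegerVector& conn_tgt,   // 0-based target per connection
    const IntegerVector& conn_port,  // 0-based port per connection
    const NumericVector& conn_amp,   // signed PSC amplitude per connection (pA)
    const NumericVector& noise_rate, // per-neuron background Poisson rate (Hz)
    const NumericVector& noise_amp,  // per-neuron background PSC amplitude (pA)
    int noise_port,                  // 0-based port of the background input
    const NumericVector& stim_rate_a,// per-step stimulus rate onto pop A (Hz)
    const NumericVector& stim_rate_b,// per-step stimulus rate onto pop B (Hz)
    const NumericVector& stim_amp,   // per-neuron stimulus PSC amplitude (pA)
    int stim_port,                   // 0-based port of the stimulus input
    const NumericMatrix& ext_spikes, // columns (arrival_step, neuron0, port0, amp)
    double dt,                       // step (ms)
    int n_steps,
    const IntegerVector& record_v,   // 0-based neuron ids whose v to record
    const NumericVector& v_init      // initial v per neuron (empty = rest)
) {
  const int n = pop.size();
  const int n_ports = tau_syn.size();
  if (dt <= 0) stop("dt must be positive");
  for (int p = 0; p < n_ports; ++p)
    if (delay_steps[p] < 1) stop("every port delay must be at least one step");

  // propagators
  NumericVector p22(n);
  NumericMatrix g(n_ports, n);            // G_p per neuron
  NumericVector p11(n_ports);
  for (int p = 0; p < n_ports; ++p) p11[p] = std::exp(-dt / tau_syn[p]);
  IntegerVector ref_steps(n);
  for (int i = 0; i < n; ++i) {
    p22[i] = std::exp(-dt / tau_m[i]);
    ref_steps[i] = (int)std::ceil(t_ref[i] / dt - 1e-9);
    for (int p = 0; p < n_ports; ++p) {
      double ts = tau_syn[p], tm = tau_m[i];
      if (std::fabs(tm - ts) < 1e-9) {
        g(p, i) = dt * std::exp(-dt / tm) / c_m[i];
      } else {
        g(p, i) = (tm * ts / (c_m[i] * (tm - ts))) *
                  (std::exp(-dt / tm) - std::exp(-dt / ts));
      }
    }
  }

  // connections in CSR order by source
  const int n_conn = conn_src.size();
  std::vector<int> offset(n + 1, 0);
  for (int k = 0; k < n_conn; ++k) offset[conn_src[k] + 1]++;
  for (int i = 0; i < n; ++i) offset[i + 1] += offset[i];
  std::vector<int> ctgt(n_conn), cport(n_conn);
  std::vector<double> camp(n_conn);
  {
    std::vector<int> pos(offset.begin(), offset.end() - 1);
    for (int k = 0; k < n_conn; ++k) {
      int s = conn_src[k];
      int at = pos[s]++;
      ctgt[at] = conn_tgt[k];
      cport[at] = conn_port[k];
      camp[at] = conn_amp[k];
    }
  }

  // ring buffers: one per port, (delay+1) slots x n neurons; a spike emitted
  // at the end of step t is written into slot t, which next comes up for
  // reading at step t + delay + 1 -- i.e. the current jumps exactly `delay`
  // ms after the emission time (t+1)*dt
  std::vector<std::vector<double>> ring(n_ports);
  std::vector<int> ring_len(n_ports);
  for (int p = 0; p < n_ports; ++p) {
    ring_len[p] = delay_steps[p] + 1;
    ring[p].assign((size_t)ring_len[p] * n, 0.0);
  }

  // externally scheduled arrivals, bucketed by arrival step
  std::vector<std::vector<int>> ext_at(n_steps);
  for (int k = 0; k < ext_spikes.nrow(); ++k) {
    int st = (int)ext_spikes(k, 0);
    if (st >= 0 && st < n_steps) ext_at[st].push_back(k);
  }

  // Poisson count thresholds exp(-mu); noise is constant per neuron,
  // the stimulus is per-step but shared within a population
  std::vector<double> noise_lexp(n, 1.0);
  bool any_noise = false;
  for (int i = 0; i < n; ++i)
    if (noise_rate[i] > 0) {
      noise_lexp[i] = std::exp(-noise_rate[i] * dt * 1e-3);
      any_noise = true;
    }
  std::vector<double> stim_lexp_a(n_steps, 1.0), stim_lexp_b(n_steps, 1.0);
  bool any_stim = false;
  for (int t = 0; t < n_steps; ++t) {
    if (stim_rate_a[t] > 0) { stim_lexp_a[t] = std::exp(-stim_rate_a[t] * dt * 1e-3); any_stim = true; }
    if (stim_rate_b[t] > 0) { stim_lexp_b[t] = std::exp(-stim_rate_b[t] * dt * 1e-3); any_stim = true; }
  }

  // state
  std::vector<double> v(n), isyn((size_t)n_ports * n, 0.0);
  std::vector<int> refr(n, 0);
  if (v_init.size() == n) {
    for (int i = 0; i < n; ++i) v[i] = v_init[i];
  } else {
    for (int i = 0; i < n; ++i) v[i] = e_l[i];
  }

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  const int n_rec = record_v.size();
  NumericMatrix vtrace(n_rec > 0 ? n_steps : 0, n_rec);

  RNGScope rng;

  for (int t = 0; t < n_steps; ++t) {
    // deliver events due this step into the synaptic currents, free the slot
    for (int p = 0; p < n_ports; ++p) {
      int slot = t % ring_len[p];
      double* buf = &ring[p][(size_t)slot * n];
      double* cur = &isyn[(size_t)p * n];
      for (int i = 0; i < n; ++i) {
        cur[i] += buf[i];
        buf[i] = 0.0;
      }
    }
    // externally scheduled arrivals step the current at time t*dt directly
    for (int kk : ext_at[t]) {
      int p = (int)ext_spikes(kk, 2);
      isyn[(size_t)p * n + (int)ext_spikes(kk, 1)] += ext_spikes(kk, 3);
    }

    // generator events drawn over this step are emitted, like neuron spikes,
    // at the end of the step: write into the just-freed slot so they arrive
    // one port delay later
    if (any_noise) {
      int slot = t % ring_len[noise_port];
      double* buf = &ring[noise_port][(size_t)slot * n];
      for (int i = 0; i < n; ++i) {
        if (noise_rate[i] <= 0) continue;
        int k = rpois_small(noise_lexp[i]);
        if (k > 0) buf[i] += k * noise_amp[i];
      }
    }
    if (any_stim && (stim_rate_a[t] > 0 || stim_rate_b[t] > 0)) {
      int slot = t % ring_len[stim_port];
      double* buf = &ring[stim_port][(size_t)slot * n];
      double la = stim_lexp_a[t], lb = stim_lexp_b[t];
      bool sa = stim_rate_a[t] > 0, sb = stim_rate_b[t] > 0;
      for (int i = 0; i < n; ++i) {
        if (pop[i] == 0 && sa) {
          int k = rpois_small(la);
          if (k > 0) buf[i] += k * stim_amp[i];
        } else if (pop[i] == 1 && sb) {
          int k = rpois_small(lb);
          if (k > 0) buf[i] += k * stim_amp[i];
        }
      }
    }

    // propagate one step; detect threshold crossings
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) {
        --refr[i];
        v[i] = v_reset[i];
      } else {
        double vv = e_l[i] + (v[i] - e_l[i]) * p22[i];
        for (int p = 0; p < n_ports; ++p) vv += g(p, i) * isyn[(size_t)p * n + i];
        v[i] = vv;
      }
      for (int p = 0; p < n_ports; ++p) isyn[(size_t)p * n + i] *= p11[p];
      if (refr[i] == 0 && v[i] >= v_th[i]) {
        spike_t.push_back((t + 1) * dt);
        spike_id.push_back(i + 1);
        v[i] = v_reset[i];
        refr[i] = ref_steps[i];
        for (int k = offset[i]; k < offset[i + 1]; ++k) {
          int p = cport[k];
          ring[p][(size_t)(t % ring_len[p]) * n + ctgt[k]] += camp[k];
        }
      }
    }

    if (n_rec > 0)
      for (int r = 0; r < n_rec; ++r) vtrace(t, r) = v[record_v[r]];

    if ((t & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["time_ms"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["neuron_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["v_trace"] = vtrace);
}
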