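#include <Rcpp.h>
using namespace Rcpp;

// Conductance-based leaky integrate-and-fire network, fixed-step Euler.
// Weight matrices are target-major: column j holds the conductance
// increments delivered to every neuron when presynaptic neuron j fires.
// External drive is an independent Poisson excitatory input per neuron
// whose rate steps from `ext_rate_base` to `ext_rate_step` inside
// [step_start, step_end) ms; events are drawn from the superposed
// population process and assigned uniformly, which preserves per-neuron
// independence.  Uses the R RNG, so results are reproducible via set.seed.

// [[Rcpp::export(name = ".lif_simulate")]]
List lif_simulate(NumericMatrix w_exc, NumericMatrix w_inh,
                  LogicalVector is_e,
                  double duration_ms, double dt,
                  double tau_m_e, double tau_m_i,
                  double v_rest, double v_th, double v_reset,
                  double e_exc, double e_inh,
                  double tau_syn_e, double tau_syn_i,
                  double refractory_ms,
                  double ext_rate_base, double ext_rate_step,
                  double step_start, double step_end,
                  double w_ext, double rate_ceiling) {
  const int n = w_exc.nrow();
  std::vector<double> v(n, v_rest), ge(n, 0.0), gi(n, 0.0), refrac(n, 0.0);
  const double dec_e = std::exp(-dt / tau_syn_e);
  const double dec_i = std::exp(-dt / tau_syn_i);
  std::vector<double> inv_tau(n);
  for (int i = 0; i < n; ++i)
    inv_tau[i] = 1.0 / (is_e[i] ? tau_m_e : tau_m_i);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  const int n_steps = (int)std::round(duration_ms / dt);
  // external population event queue
  double next_ext = R::exp_rand() / (n * ext_rate_base / 1000.0);
  bool in_step_prev = false;
  // runaway guard: spike count in a sliding 100-ms window
  int win_steps = (int)std::round(100.0 / dt);
  std::vector<int> spikes_per_step(n_steps, 0);
  long win_count = 0;
  bool aborted = false;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    bool in_step = (t >= step_start && t < step_end);
    double ext_rate = in_step ? ext_rate_step : ext_rate_base;
    if (in_step != in_step_prev) {
      // restart the exponential clock at the new total rate
      next_ext = t + R::exp_rand() / (n * ext_rate / 1000.0);
      in_step_prev = in_step;
    }
    while (next_ext < t + dt) {
      int target = (int)std::floor(R::unif_rand() * n);
      if (target >= n) target = n - 1;
      ge[target] += w_ext;
      next_ext += R::exp_rand() / (n * ext_rate / 1000.0);
    }
    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) {
        refrac[i] -= dt;
        ge[i] *= dec_e; gi[i] *= dec_i;
        continue;
      }
      double dv = ((v_rest - v[i]) + ge[i] * (e_exc - v[i]) +
                   gi[i] * (e_inh - v[i])) * dt * inv_tau[i];
      v[i] += dv;
      ge[i] *= dec_e; gi[i] *= dec_i;
    }
    // threshold crossings; deliver synapses at the end of the step
    for (int i = 0; i < n; ++i) {
      if (refrac[i] <= 0 && v[i] >= v_th) {
        spike_t.push_back(t + dt);
        spike_id.push_back(i + 1);
        spikes_per_step[s]++;
        v[i] = v_reset;
        refrac[i] = refractory_ms;
        if (is_e[i]) {
          NumericMatrix::Column col = w_exc(_, i);
          for (int k = 0; k < n; ++k) ge[k] += col[k];
        } else {
          NumericMatrix::Column col = w_inh(_, i);
          for (int k = 0; k < n; ++k) gi[k] += col[k];
        }
      }
    }
    win_count += spikes_per_step[s];
    if (s >= win_steps) win_count -= spikes_per_step[s - win_steps];
    if (s >= win_steps && rate_ceiling > 0) {
      double mean_rate = win_count * 1000.0 / (n * 100.0);
      if (mean_rate > rate_ceiling) { aborted = true; break; }
    }
  }
  return List::create(_["times"] = wrap(spike_t),
                      _["ids"] = wrap(spike_id),
                      _["aborted"] = aborted);
}

// Raw cross-correlogram pair counts between two sorted spike trains.
// Lag bins are centred on multiples of `bin` up to +/- max_lag; a pair
// (r, t) contributes to the bin nearest (t - r).  Lags are first snapped to
// a 0.05-ms grid so that spike times quantised by a fixed integration step
// fall on bin boundaries deterministically (half-away-from-zero), keeping
// raw counts and correction predictors consistent and the counts exactly
// antisymmetric under swapping the trains.

// [[Rcpp::export(name = ".ccg_count")]]
IntegerVector ccg_count(NumericVector ref, NumericVector tgt,
                        double max_lag, double bin) {
  int L = (int)std::round(max_lag / bin);
  IntegerVector counts(2 * L + 1);
  double lim = max_lag + bin;
  int lo = 0;
  for (int i = 0; i < ref.size(); ++i) {
    while (lo < tgt.size() && tgt[lo] < ref[i] - lim) ++lo;
    for (int j = lo; j < tgt.size() && tgt[j] < ref[i] + lim; ++j) {
      double d = std::nearbyint((tgt[j] - ref[i]) * 20.0) / 20.0;
      int b = (int)std::lround(d / bin);
      if (b >= -L && b <= L) counts[b + L]++;
    }
  }
  return counts;
}
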