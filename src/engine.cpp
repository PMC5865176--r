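#include <Rcpp.h>
#include <deque>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Event-driven core for the LIF perceptron with pair-based plasticity.
// All voltages are in scaled units (V_st = 0, V_th = 1); times in ms.
// The input to the output neuron is a Dirac comb, so the membrane
// trajectory is piecewise exponential decay with instantaneous jumps at
// arrivals: the engine only ever evaluates the closed-form leak between
// consecutive arrivals.

namespace {

const double EPS = 1e-9;

struct PastEv {
  double time;
  int input;
  int dend;
};

// STDP window: amp * exp(-|d|/tauL) * sign(d), zero at d = 0 and beyond
// the cutoff (cutoff boundary inclusive).
inline double learn_step(double delta, double amp, double tauL, double cutoff) {
  double a = std::fabs(delta);
  if (a <= EPS) return 0.0;
  if (a > cutoff + EPS) return 0.0;
  double m = amp * std::exp(-a / tauL);
  return delta > 0 ? m : -m;
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector delays, IntegerVector dendrite_of0,
                NumericVector w_syn0, NumericVector w_dend0,
                int mode_dendritic, double tau, double refractory,
                double rate, double duration_s,
                double amp, double tau_learn, double cutoff, double floor_w,
                bool pair_refractory, bool nearest_only, bool record_events) {
  const int N = delays.size();
  const int ND = w_dend0.size();
  const double period = 1000.0 / rate;
  const int K = (int)std::floor(rate * duration_s + EPS);
  if (K < 1) stop("stimulation protocol yields zero cycles");

  // Merged arrival schedule: one arrival per (cycle, input), sorted by
  // time with ties broken by ascending input index.
  const long n_arr = (long)K * N;
  std::vector<double> at(n_arr);
  std::vector<int> ai(n_arr);
  {
    std::vector<long> ord(n_arr);
    long p = 0;
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < N; ++i) {
        at[p] = k * period + delays[i];
        ai[p] = i;
        ++p;
      }
    for (long q = 0; q < n_arr; ++q) ord[q] = q;
    std::stable_sort(ord.begin(), ord.end(), [&](long a, long b) {
      if (at[a] != at[b]) return at[a] < at[b];
      return ai[a] < ai[b];
    });
    std::vector<double> at2(n_arr);
    std::vector<int> ai2(n_arr);
    for (long q = 0; q < n_arr; ++q) {
      at2[q] = at[ord[q]];
      ai2[q] = ai[ord[q]];
    }
    at.swap(at2);
    ai.swap(ai2);
  }

  std::vector<double> w_syn(w_syn0.begin(), w_syn0.end());
  std::vector<double> w_dend(w_dend0.begin(), w_dend0.end());

  double v = 0.0, t_v = 0.0, refr_end = -1e300;

  std::deque<PastEv> spikes_q, subs_q;

  // records
  std::vector<double> a_time, a_eff;
  std::vector<int> a_input, a_dend, a_caused, a_refr;
  std::vector<double> s_time;
  std::vector<int> s_input, s_dend;
  std::vector<double> p_ts, p_tu, p_delta, p_dw, p_neww;
  std::vector<int> p_target;
  NumericMatrix snap(K, N + ND);
  int snap_idx = 0;

  if (record_events) {
    a_time.reserve(n_arr);
    a_input.reserve(n_arr);
  }

  auto take_snapshot = [&](int row) {
    for (int i = 0; i < N; ++i) snap(row, i) = w_syn[i];
    for (int d = 0; d < ND; ++d) snap(row, N + d) = w_dend[d];
  };

  auto apply_pair = [&](double t_spike, double t_sub, int target) {
    double delta = t_sub - t_spike;
    double dW = learn_step(delta, amp, tau_learn, cutoff);
    double *w = mode_dendritic ? &w_dend[target] : &w_syn[target];
    *w *= (1.0 + dW);
    if (*w < floor_w) *w = floor_w;
    if (record_events) {
      p_ts.push_back(t_spike);
      p_tu.push_back(t_sub);
      p_delta.push_back(delta);
      p_target.push_back(target);
      p_dw.push_back(dW);
      p_neww.push_back(*w);
    }
  };

  // A new sub-threshold stimulation pairs with every earlier spike inside
  // the cutoff window (excluding same input / same dendrite); updates are
  // applied immediately, i.e. at the time of the later event.
  auto pair_new_sub = [&](double t, int i, int d) {
    while (!spikes_q.empty() && spikes_q.front().time < t - cutoff - EPS)
      spikes_q.pop_front();
    int target = mode_dendritic ? d : i;
    if (nearest_only) {
      for (auto it = spikes_q.rbegin(); it != spikes_q.rend(); ++it) {
        bool same = mode_dendritic ? (it->dend == d) : (it->input == i);
        if (same) continue;
        apply_pair(it->time, t, target);
        break;
      }
    } else {
      for (const PastEv &s : spikes_q) {
        bool same = mode_dendritic ? (s.dend == d) : (s.input == i);
        if (same) continue;
        apply_pair(s.time, t, target);
      }
    }
  };

  // A new spike pairs with every earlier sub-threshold stimulation inside
  // the window; the target is always the sub's own weight/dendrite.
  auto pair_new_spike = [&](double t, int i, int d) {
    while (!subs_q.empty() && subs_q.front().time < t - cutoff - EPS)
      subs_q.pop_front();
    if (nearest_only) {
      for (auto it = subs_q.rbegin(); it != subs_q.rend(); ++it) {
        bool same = mode_dendritic ? (it->dend == d) : (it->input == i);
        if (same) continue;
        apply_pair(t, it->time, mode_dendritic ? it->dend : it->input);
        break;
      }
    } else {
      for (const PastEv &u : subs_q) {
        bool same = mode_dendritic ? (u.dend == d) : (u.input == i);
        if (same) continue;
        apply_pair(t, u.time, mode_dendritic ? u.dend : u.input);
      }
    }
  };

  for (long q = 0; q < n_arr; ++q) {
    double t = at[q];
    int i = ai[q];
    int d = dendrite_of0[i];

    while (snap_idx < K - 1 && t >= (snap_idx + 1) * period - EPS) {
      take_snapshot(snap_idx);
      ++snap_idx;
    }

    double eff = w_syn[i] * w_dend[d];
    bool in_refr = (refr_end - t > EPS);

    if (in_refr) {
      // Voltage clamped at V_st; recorded as a sub-threshold stimulation
      // and (by default) eligible for pairing.
      if (record_events) {
        a_time.push_back(t);
        a_input.push_back(i);
        a_dend.push_back(d);
        a_eff.push_back(eff);
        a_caused.push_back(0);
        a_refr.push_back(1);
      }
      if (pair_refractory) {
        pair_new_sub(t, i, d);
        subs_q.push_back({t, i, d});
      }
      continue;
    }

    v *= std::exp(-(t - t_v) / tau);
    t_v = t;
    v += eff;

    if (v >= 1.0) {
      s_time.push_back(t);
      s_input.push_back(i);
      s_dend.push_back(d);
      if (record_events) {
        a_time.push_back(t);
        a_input.push_back(i);
        a_dend.push_back(d);
        a_eff.push_back(eff);
        a_caused.push_back(1);
        a_refr.push_back(0);
      }
      v = 0.0;
      refr_end = t + refractory;
      pair_new_spike(t, i, d);
      spikes_q.push_back({t, i, d});
    } else {
      if (record_events) {
        a_time.push_back(t);
        a_input.push_back(i);
        a_dend.push_back(d);
        a_eff.push_back(eff);
        a_caused.push_back(0);
        a_refr.push_back(0);
      }
      pair_new_sub(t, i, d);
      subs_q.push_back({t, i, d});
    }
  }

  while (snap_idx < K) {
    take_snapshot(snap_idx);
    ++snap_idx;
  }

  List out = List::create(
      _["spike_time"] = wrap(s_time), _["spike_input"] = wrap(s_input),
      _["spike_dend"] = wrap(s_dend), _["snapshots"] = snap,
      _["final_w_syn"] = wrap(w_syn), _["final_w_dend"] = wrap(w_dend));
  if (record_events) {
    out["arr_time"] = wrap(a_time);
    out["arr_input"] = wrap(a_input);
    out["arr_dend"] = wrap(a_dend);
    out["arr_eff"] = wrap(a_eff);
    out["arr_caused"] = wrap(a_caused);
    out["arr_refr"] = wrap(a_refr);
    out["pair_t_spike"] = wrap(p_ts);
    out["pair_t_sub"] = wrap(p_tu);
    out["pair_delta"] = wrap(p_delta);
    out["pair_target"] = wrap(p_target);
    out["pair_dw"] = wrap(p_dw);
    out["pair_new_w"] = wrap(p_neww);
  }
  return out;
}
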