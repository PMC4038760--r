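#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Sample a Bernoulli(p) connectivity matrix over all ordered (pre, post)
// pairs, including self-pairs, by geometric gap-skipping across the
// row-major pair index: the gap between successive realized synapses is
// Geometric(p), which is distributionally identical to independent per-pair
// coin flips. Uses R's RNG, so results are reproducible under set.seed().
// Returns 0-based pre/post indices.
// [[Rcpp::export]]
List cpp_sample_pairs(int n_pre, int n_post, double p) {
  if (n_pre <= 0 || n_post <= 0)
    stop("population sizes must be positive");
  if (p < 0.0 || p > 1.0)
    stop("connection probability must lie in [0, 1]");
  std::vector<int> pre, post;
  if (p > 0.0) {
    const long long n_pairs = (long long)n_pre * (long long)n_post;
    pre.reserve((size_t)(n_pairs * p * 1.05) + 16);
    post.reserve(pre.capacity());
    if (p >= 1.0) {
      for (long long k = 0; k < n_pairs; ++k) {
        pre.push_back((int)(k / n_post));
        post.push_back((int)(k % n_post));
      }
    } else {
      long long k = (long long)R::rgeom(p);
      while (k < n_pairs) {
        pre.push_back((int)(k / n_post));
        post.push_back((int)(k % n_post));
        k += 1 + (long long)R::rgeom(p);
      }
    }
  }
  return List::create(_["pre"] = wrap(pre), _["post"] = wrap(post));
}

// Clock-driven simulation of the LIF network on a fixed dt grid.
//
// param_index: per-neuron 0-based row of `params`, or -1 for Poisson source
//   neurons (never integrated; they only relay the supplied stimulus
//   spikes through their outgoing synapses).
// params: one row per parameter set, columns
//   (E_L, V_reset, V_theta, tau_m, R_m, tau_se, tau_si, t_ref).
// projections: list of lists with integer vectors `pre`, `post` (0-based
//   global indices) and scalar `w` (nA, signed; sign selects the target
//   accumulator).
// stim_times/stim_ids: stimulus spikes sorted by time (ms, 0-based steps).
//
// Per-step contract, step t = 0..n_steps-1:
//   1. deliver stimulus spikes stamped t and network spikes stamped t-1
//   2. advance each cortical neuron: exact propagation of (V, I_e, I_i)
//      over dt (refractory cells: decrement timer, clamp V while positive)
//   3. threshold test (V >= V_theta): reset, start refractory, record
//      a spike stamped t
// [[Rcpp::export]]
List cpp_run(IntegerVector param_index, NumericMatrix params, List projections,
             IntegerVector stim_times, IntegerVector stim_ids,
             int n_steps, double dt, NumericVector i_offset,
             NumericVector v_init) {
  const int n = param_index.size();
  if (n_steps <= 0) stop("duration must be positive");
  if (dt <= 0.0) stop("dt must be positive");
  if (stim_times.size() != stim_ids.size())
    stop("stimulus times and ids must have equal length");

  // --- flatten projections into CSR keyed by (global) source neuron
  const int n_proj = projections.size();
  std::vector<int64_t> deg(n + 1, 0);
  int64_t n_syn = 0;
  for (int g = 0; g < n_proj; ++g) {
    List pr = projections[g];
    IntegerVector pv = pr["pre"];
    n_syn += pv.size();
    for (R_xlen_t k = 0; k < pv.size(); ++k) {
      int s = pv[k];
      if (s < 0 || s >= n) stop("projection pre index out of range");
      ++deg[s + 1];
    }
  }
  std::vector<int64_t> row_ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) row_ptr[i + 1] = row_ptr[i] + deg[i + 1];
  std::vector<int> targets((size_t)n_syn);
  std::vector<float> wsyn((size_t)n_syn);
  {
    std::vector<int64_t> fill(row_ptr.begin(), row_ptr.end() - 1);
    for (int g = 0; g < n_proj; ++g) {
      List pr = projections[g];
      IntegerVector pv = pr["pre"], qv = pr["post"];
      if (qv.size() != pv.size()) stop("pre/post length mismatch");
      double w = as<double>(pr["w"]);
      for (R_xlen_t k = 0; k < pv.size(); ++k) {
        int t = qv[k];
        if (t < 0 || t >= n) stop("projection post index out of range");
        int64_t pos = fill[pv[k]]++;
        targets[(size_t)pos] = t;
        wsyn[(size_t)pos] = (float)w;
      }
    }
  }

  // --- per-parameter-set propagator constants
  const int n_sets = params.nrow();
  std::vector<double> em(n_sets), ee(n_sets), ei(n_sets),
      ce(n_sets), ci(n_sets), r1em(n_sets),
      eL(n_sets), vReset(n_sets), vTheta(n_sets), tRef(n_sets);
  for (int s = 0; s < n_sets; ++s) {
    double tau_m = params(s, 3), R_m = params(s, 4);
    double tau_se = params(s, 5), tau_si = params(s, 6);
    eL[s] = params(s, 0);
    vReset[s] = params(s, 1);
    vTheta[s] = params(s, 2);
    tRef[s] = params(s, 7);
    em[s] = std::exp(-dt / tau_m);
    ee[s] = std::exp(-dt / tau_se);
    ei[s] = std::exp(-dt / tau_si);
    r1em[s] = R_m * (1.0 - em[s]);
    ce[s] = (std::abs(tau_se - tau_m) < 1e-9 * tau_m)
      ? R_m * (dt / tau_m) * em[s]
      : R_m * tau_se / (tau_se - tau_m) * (ee[s] - em[s]);
    ci[s] = (std::abs(tau_si - tau_m) < 1e-9 * tau_m)
      ? R_m * (dt / tau_m) * em[s]
      : R_m * tau_si / (tau_si - tau_m) * (ei[s] - em[s]);
  }

  // --- state
  std::vector<double> V(n, 0.0), Ie(n, 0.0), Ii(n, 0.0), refr(n, 0.0);
  std::vector<int> cortical;
  cortical.reserve(n);
  for (int i = 0; i < n; ++i) {
    int s = param_index[i];
    if (s >= n_sets) stop("param_index out of range");
    if (s >= 0) {
      V[i] = (v_init.size() == n) ? v_init[i] : params(s, 0);
      cortical.push_back(i);
    }
  }
  const bool has_offset = (i_offset.size() == n);

  std::vector<int> prev_spikes, cur_spikes;
  std::vector<int> out_t, out_id;
  out_t.reserve(1 << 16);
  out_id.reserve(1 << 16);

  R_xlen_t sp = 0;
  const R_xlen_t n_stim = stim_times.size();
  for (int t = 0; t < n_steps; ++t) {
    // 1. deliver: stimulus spikes stamped t, network spikes stamped t-1
    while (sp < n_stim && stim_times[sp] < t) ++sp;  // tolerate early tail
    while (sp < n_stim && stim_times[sp] == t) {
      int src = stim_ids[sp++];
      if (src < 0 || src >= n) stop("stimulus neuron id out of range");
      for (int64_t k = row_ptr[src]; k < row_ptr[src + 1]; ++k) {
        float w = wsyn[(size_t)k];
        if (w >= 0.0f) Ie[targets[(size_t)k]] += w;
        else           Ii[targets[(size_t)k]] += w;
      }
    }
    for (size_t j = 0; j < prev_spikes.size(); ++j) {
      int src = prev_spikes[j];
      for (int64_t k = row_ptr[src]; k < row_ptr[src + 1]; ++k) {
        float w = wsyn[(size_t)k];
        if (w >= 0.0f) Ie[targets[(size_t)k]] += w;
        else           Ii[targets[(size_t)k]] += w;
      }
    }
    cur_spikes.clear();

    // 2+3. advance and threshold every cortical neuron
    for (size_t c = 0; c < cortical.size(); ++c) {
      const int i = cortical[c];
      const int s = param_index[i];
      double v = V[i];
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        if (refr[i] < 0.0) refr[i] = 0.0;
      }
      if (refr[i] > 0.0) {
        v = vReset[s];  // clamped at V_reset
      } else {
        v = eL[s] + (v - eL[s]) * em[s]
          + ce[s] * Ie[i] + ci[s] * Ii[i];
        if (has_offset) v += r1em[s] * i_offset[i];
      }
      Ie[i] *= ee[s];
      Ii[i] *= ei[s];
      if (!std::isfinite(v))
        stop("numerical failure at step %d, neuron %d: non-finite membrane potential",
             t, i);
      if (refr[i] <= 0.0 && v >= vTheta[s]) {
        v = vReset[s];
        refr[i] = tRef[s];
        cur_spikes.push_back(i);
        out_t.push_back(t);
        out_id.push_back(i);
      }
      V[i] = v;
    }
    prev_spikes.swap(cur_spikes);
  }

  return List::create(_["time"] = wrap(out_t), _["id"] = wrap(out_id));
}
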