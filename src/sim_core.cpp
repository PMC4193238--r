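// Clock-driven core of the balanced random-network reference simulator.
//
// Connectivity is passed in compressed form: `sources` holds, per target
// neuron, a contiguous block of K source GIDs (the first K_E excitatory);
// `csr_ptr`/`csr_idx` index the same synapse array by source for spike
// delivery.  Neuron state (V, alpha-current pair y1/y2) advances by the
// exact one-step propagator of the linear subthreshold dynamics; spikes
// are exchanged through a ring of pending-delivery slots spanning the
// synaptic delay.  External Poisson input uses one counter-seeded RNG
// stream per neuron so that results are independent of how neurons are
// partitioned into virtual processes.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RngStream {
  uint64_t s;
  RngStream(uint64_t seed, uint64_t id) {
    s = splitmix64(seed * 0x9E3779B97F4A7C15ULL + splitmix64(id + 1));
    if (s == 0) s = 0x1234567887654321ULL;
  }
  inline uint64_t next() {
    uint64_t x = s;
    x ^= x << 13;
    x ^= x >> 7;
    x ^= x << 17;
    s = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  // Knuth multiplication method; adequate for the small per-step means here
  inline int poisson(double exp_neg_lambda) {
    int k = 0;
    double p = 1.0;
    do {
      ++k;
      p *= unif();
    } while (p > exp_neg_lambda);
    return k - 1;
  }
};

// [[Rcpp::export]]
IntegerVector ext_poisson_counts(int n_steps, double mean, double seed,
                                 double gid) {
  IntegerVector out(n_steps);
  if (mean <= 0) return out;
  RngStream rng((uint64_t)seed, (uint64_t)gid);
  double enl = std::exp(-mean);
  for (int t = 0; t < n_steps; ++t) out[t] = rng.poisson(enl);
  return out;
}

// [[Rcpp::export]]
List simulate_core(int n, int n_exc, int K, int K_E,
                   IntegerVector sources, NumericVector weight_in,
                   IntegerVector csr_ptr, IntegerVector csr_idx,
                   int n_steps, int delay_steps, int ref_steps,
                   NumericVector prop,   // e_s, hs, e_m, p31, p32
                   double psc_norm, double v_th, double v_reset,
                   NumericVector v_init,
                   double nu_h, double j_ext,
                   double stdp_lambda, double stdp_mu, double stdp_alpha,
                   double stdp_tau_plus, double stdp_tau_minus,
                   double stdp_w0, double h,
                   double seed, bool threshold_on,
                   bool record_vm, int vm_warmup_steps,
                   bool return_weights,
                   Nullable<IntegerMatrix> ext_counts_in) {
  const double e_s = prop[0], hs = prop[1], e_m = prop[2],
               p31 = prop[3], p32 = prop[4];
  const bool stdp_on = stdp_lambda != 0.0 && n_exc > 0 && K_E > 0;
  const bool have_ext_mat = ext_counts_in.isNotNull();
  IntegerMatrix ext_counts;
  if (have_ext_mat) ext_counts = ext_counts_in.get();

  NumericVector weight = (stdp_on || return_weights)
    ? clone(weight_in) : weight_in;

  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> y1(n, 0.0), y2(n, 0.0), input(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<double> x_pre(n, 0.0), x_post(n, 0.0);
  std::vector<double> vm_sum(n, 0.0);
  const double dec_pre = std::exp(-h / stdp_tau_plus);
  const double dec_post = std::exp(-h / stdp_tau_minus);
  const double pot_fac = stdp_on
    ? stdp_lambda * std::pow(stdp_w0, 1.0 - stdp_mu) : 0.0;

  std::vector<RngStream> streams;
  const bool draw_ext = !have_ext_mat && nu_h > 0;
  if (draw_ext) {
    streams.reserve(n);
    for (int i = 0; i < n; ++i)
      streams.emplace_back((uint64_t)seed, (uint64_t)(i + 1));
  }
  const double enl = nu_h > 0 ? std::exp(-nu_h) : 1.0;

  const int qlen = delay_steps + 1;
  std::vector<std::vector<int>> queue(qlen);

  std::vector<int> spike_gid, spike_step;
  std::vector<int> counts(n, 0);
  NumericMatrix vm;
  if (record_vm) vm = NumericMatrix(n, n_steps);

  std::vector<int> emitted;
  for (int t = 0; t < n_steps; ++t) {
    // deliver spikes emitted delay_steps ago
    std::vector<int> &slot = queue[t % qlen];
    for (size_t q = 0; q < slot.size(); ++q) {
      const int src = slot[q];               // 0-based
      const bool src_exc = src < n_exc;
      const int lo = csr_ptr[src], hi = csr_ptr[src + 1];
      for (int p = lo; p < hi; ++p) {
        const int j = csr_idx[p] - 1;        // natural synapse index
        const int tgt = j / K;               // 0-based target
        if (stdp_on && src_exc && tgt < n_exc) {
          double w = weight[j] * (1.0 - stdp_lambda * stdp_alpha * x_post[tgt]);
          if (w < 0.0) w = 0.0;
          weight[j] = w;
        }
        input[tgt] += weight[j];
      }
      if (stdp_on && src_exc) x_pre[src] += 1.0;
    }
    slot.clear();

    // external Poisson drive, one stream per neuron
    if (draw_ext) {
      for (int i = 0; i < n; ++i) {
        int c = streams[i].poisson(enl);
        if (c > 0) input[i] += c * j_ext;
      }
    } else if (have_ext_mat) {
      for (int i = 0; i < n; ++i) {
        int c = ext_counts(i, t);
        if (c > 0) input[i] += c * j_ext;
      }
    }

    // exact one-step update of (y1, y2, V); spikes enter y1 at step end
    emitted.clear();
    for (int i = 0; i < n; ++i) {
      const double v_new = e_m * V[i] + p31 * y1[i] + p32 * y2[i];
      y2[i] = e_s * y2[i] + hs * y1[i];
      y1[i] = e_s * y1[i] + psc_norm * input[i];
      input[i] = 0.0;
      if (refr[i] > 0) {
        --refr[i];
        V[i] = v_reset;
      } else {
        V[i] = v_new;
        if (threshold_on && V[i] >= v_th) {
          V[i] = v_reset;
          refr[i] = ref_steps;
          spike_gid.push_back(i + 1);
          spike_step.push_back(t + 1);
          ++counts[i];
          emitted.push_back(i);
        }
      }
      if (record_vm) vm(i, t) = V[i];
      if (t >= vm_warmup_steps) vm_sum[i] += V[i];
    }

    // STDP potentiation at postsynaptic spikes, then post-trace update
    if (stdp_on) {
      for (size_t q = 0; q < emitted.size(); ++q) {
        const int i = emitted[q];
        if (i >= n_exc) continue;
        const long long base = (long long)i * K;
        for (int k = 0; k < K_E; ++k) {
          const long long j = base + k;
          const int s = sources[j] - 1;      // excitatory by construction
          const double w = weight[j];
          weight[j] = w + pot_fac * std::pow(w, stdp_mu) * x_pre[s];
        }
        x_post[i] += 1.0;
      }
    }

    // schedule deliveries and decay traces
    if (!emitted.empty()) {
      std::vector<int> &dst = queue[(t + delay_steps) % qlen];
      dst.insert(dst.end(), emitted.begin(), emitted.end());
    }
    if (stdp_on) {
      for (int i = 0; i < n; ++i) {
        x_pre[i] *= dec_pre;
        x_post[i] *= dec_post;
      }
    }
  }

  const int denom = n_steps - vm_warmup_steps;
  NumericVector vm_mean(n);
  for (int i = 0; i < n; ++i)
    vm_mean[i] = denom > 0 ? vm_sum[i] / denom : NA_REAL;

  List out = List::create(
    _["spike_gid"] = IntegerVector(spike_gid.begin(), spike_gid.end()),
    _["spike_step"] = IntegerVector(spike_step.begin(), spike_step.end()),
    _["counts"] = IntegerVector(counts.begin(), counts.end()),
    _["vm_mean"] = vm_mean);
  if (record_vm) out["vm"] = vm;
  if (return_weights) out["weights"] = weight;
  return out;
}
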