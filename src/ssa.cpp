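// Exact stochastic simulation (direct-method SSA) of the multi-type
// branching process: division (one daughter possibly mutating), death,
// and migration between compartments.  Serves as the independent oracle
// for the PGF-based calculations.
//
// Randomness: each replicate gets its own counter-derived stream
// (splitmix64 seeded with hash(seed, replicate) expanding a xoshiro256++
// state), so ensembles are reproducible and order-independent.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t x;
  explicit SplitMix64(uint64_t seed) : x(seed) {}
  uint64_t next() {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

}  // namespace

// [[Rcpp::export(name = ".ssa_ensemble")]]
List ssa_ensemble(NumericVector birth, NumericVector death,
                  NumericVector mut_rate, IntegerVector mut_target,
                  NumericMatrix mig, NumericVector init,
                  double horizon, NumericVector checkpoints,
                  LogicalVector mask, int n_reps, double seed,
                  double count_cap, bool stop_at_resistance) {
  const int K = birth.size();
  const int C = checkpoints.size();

  std::vector<double> wout(K, 0.0);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < K; ++l) wout[k] += mig(k, l);

  IntegerMatrix presence(n_reps, C);
  NumericVector counts_cp(static_cast<R_xlen_t>(n_reps) * K * C);
  counts_cp.attr("dim") = IntegerVector::create(n_reps, K, C);
  NumericVector first_res(n_reps, NA_REAL);
  NumericMatrix final_counts(n_reps, K);
  LogicalVector truncated(n_reps, false);

  const uint64_t base = static_cast<uint64_t>(seed);

  for (int rep = 0; rep < n_reps; ++rep) {
    Xoshiro256pp rng(base * 0x9e3779b97f4a7c15ULL +
                     static_cast<uint64_t>(rep) + 1ULL);
    std::vector<double> n(K);
    double total = 0.0, mask_total = 0.0;
    for (int k = 0; k < K; ++k) {
      n[k] = init[k];
      total += n[k];
      if (mask[k]) mask_total += n[k];
    }
    double t = 0.0;
    bool seen = mask_total > 0;
    if (seen) first_res[rep] = 0.0;
    int cp = 0;

    auto record_until = [&](double t_event) {
      while (cp < C && checkpoints[cp] < t_event) {
        presence(rep, cp) = mask_total > 0 ? 1 : 0;
        for (int k = 0; k < K; ++k)
          counts_cp[rep + static_cast<R_xlen_t>(n_reps) * (k + K * cp)] =
              n[k];
        ++cp;
      }
    };

    while (true) {
      double R = 0.0;
      for (int k = 0; k < K; ++k)
        R += n[k] * (birth[k] + death[k] + wout[k]);
      if (R <= 0.0) {  // absorbed: record all remaining checkpoints
        record_until(horizon + 1.0);
        break;
      }
      double dt = -std::log(rng.unif()) / R;
      double t_next = t + dt;
      if (t_next > horizon) {
        record_until(horizon + 1.0);
        break;
      }
      record_until(t_next);
      t = t_next;

      // pick the class
      double target = rng.unif() * R;
      int k = 0;
      double acc = 0.0;
      for (; k < K - 1; ++k) {
        acc += n[k] * (birth[k] + death[k] + wout[k]);
        if (target < acc) break;
      }
      // pick the event within the class
      double r = rng.unif() * (birth[k] + death[k] + wout[k]);
      if (r < death[k]) {
        n[k] -= 1.0;
        total -= 1.0;
        if (mask[k]) mask_total -= 1.0;
      } else if (r < death[k] + birth[k]) {
        int dest = k;
        if (mut_rate[k] > 0.0 &&
            rng.unif() < mut_rate[k] / birth[k]) {
          dest = mut_target[k] - 1;  // 1-based from R
        }
        n[dest] += 1.0;
        total += 1.0;
        if (mask[dest]) {
          mask_total += 1.0;
          if (!seen) {
            seen = true;
            first_res[rep] = t;
          }
        }
      } else {
        // migration: pick the destination
        double rm = r - death[k] - birth[k];
        int l = 0;
        double accm = 0.0;
        for (; l < K - 1; ++l) {
          accm += mig(k, l);
          if (rm < accm && mig(k, l) > 0.0) break;
        }
        n[k] -= 1.0;
        n[l] += 1.0;
        if (mask[k]) mask_total -= 1.0;
        if (mask[l]) {
          mask_total += 1.0;
          if (!seen) {
            seen = true;
            first_res[rep] = t;
          }
        }
      }

      if (stop_at_resistance && seen) {
        record_until(horizon + 1.0);  // resistance present from here on
        break;
      }
      if (total > count_cap) {
        truncated[rep] = true;
        record_until(horizon + 1.0);  // carry current state forward
        break;
      }
    }
    for (int k = 0; k < K; ++k) final_counts(rep, k) = n[k];
  }

  return List::create(_["presence"] = presence,
                      _["counts"] = counts_cp,
                      _["first_resistance"] = first_res,
                      _["final_counts"] = final_counts,
                      _["truncated"] = truncated);
}
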