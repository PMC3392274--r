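// Asynchronous Monte Carlo engine for reputation-guided imitation dynamics.
//
// The hot loop is deliberately self-contained: a counter-seeded
// xoshiro256++ generator (seeded via splitmix64) keeps runs bit-identical
// for a given seed independently of R's RNG state, and payoffs are
// recomputed from the current neighbourhood at every event (no caching).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the scalar seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform integer in [0, n): multiply-shift map of a 64-bit draw
  // (bias is O(n / 2^64), far below anything observable here)
  inline int rint(int n) {
    return static_cast<int>(
        (static_cast<unsigned __int128>(next()) * static_cast<uint64_t>(n)) >> 64);
  }
};

// Payoffs on a degree-bounded graph take few discrete values: a player's
// payoff is determined by (own strategy, degree, #cooperating neighbours).
// The Fermi probability for every such pair is precomputed, removing exp()
// from the event loop. Index: s * (D+1)^2 + deg * (D+1) + nC.
struct FermiTable {
  int D;          // max degree covered
  int stride;     // (D+1)^2
  std::vector<double> tab;

  FermiTable(int max_deg, const double M[2][2], double K) : D(max_deg) {
    stride = (D + 1) * (D + 1);
    const int nid = 2 * stride;
    std::vector<double> pay(nid, 0.0);
    for (int s = 0; s < 2; ++s)
      for (int deg = 0; deg <= D; ++deg)
        for (int nC = 0; nC <= deg; ++nC)
          pay[s * stride + deg * (D + 1) + nC] =
              nC * M[s][0] + (deg - nC) * M[s][1];
    tab.resize(static_cast<size_t>(nid) * nid);
    for (int a = 0; a < nid; ++a)
      for (int b = 0; b < nid; ++b) {
        double z = (pay[a] - pay[b]) / K;
        if (z > 700.0) z = 700.0;
        if (z < -700.0) z = -700.0;
        tab[static_cast<size_t>(a) * nid + b] = 1.0 / (1.0 + std::exp(z));
      }
  }

  inline int id(int s, int deg, int nC) const {
    return s * stride + deg * (D + 1) + nC;
  }
  inline double prob(int id_f, int id_d) const {
    return tab[static_cast<size_t>(id_f) * 2 * stride + id_d];
  }
};

// payoff of node i against its neighbours under matrix M[own][other],
// strategies coded 0 = C, 1 = D
inline double node_payoff(int i, const std::vector<uint8_t>& strat,
                          const std::vector<int>& ptr, const std::vector<int>& idx,
                          const double M[2][2]) {
  double pay = 0.0;
  const int a = ptr[i], b = ptr[i + 1];
  const uint8_t si = strat[i];
  for (int k = a; k < b; ++k) pay += M[si][strat[idx[k]]];
  return pay;
}

inline double fermi(double p_focal, double p_donor, double K) {
  double z = (p_focal - p_donor) / K;
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(z));
}

} // namespace

//' @name cpp_run_simulation
//' @title Low-level Monte Carlo driver (internal)
//' @description Runs relaxation + measurement Monte Carlo steps of the
//'   asynchronous imitation dynamics. Not part of the public API; use
//'   [run_simulation()].
//' @keywords internal
// [[Rcpp::export(name = ".cpp_run_simulation")]]
List cpp_run_simulation(IntegerVector adj_ptr, IntegerVector adj_idx,
                        IntegerVector strategy0, NumericVector reputation0,
                        NumericVector infer_p, NumericVector payoff_mat,
                        double K, int rep_mode, double w,
                        int relax_mcs, int measure_mcs,
                        double seed, bool early_stop,
                        int rep_timing = 0) {
  const int n = strategy0.size();
  const int total_mcs = relax_mcs + measure_mcs;

  std::vector<int> ptr(adj_ptr.begin(), adj_ptr.end());
  std::vector<int> idx(adj_idx.begin(), adj_idx.end());
  std::vector<uint8_t> strat(n);
  for (int i = 0; i < n; ++i) strat[i] = static_cast<uint8_t>(strategy0[i]);
  std::vector<double> rep(reputation0.begin(), reputation0.end());
  std::vector<double> pvec(infer_p.begin(), infer_p.end());

  // payoff_mat arrives as c(M[C][C], M[C][D], M[D][C], M[D][D])
  double M[2][2] = {{payoff_mat[0], payoff_mat[1]},
                    {payoff_mat[2], payoff_mat[3]}};

  Xoshiro256pp rng(static_cast<uint64_t>(seed));

  int max_deg = 0;
  for (int i = 0; i < n; ++i) max_deg = std::max(max_deg, ptr[i + 1] - ptr[i]);
  const bool use_table = max_deg <= 8; // keeps the table L2-resident
  FermiTable ftab(use_table ? max_deg : 1, M, K);

  NumericVector rho(total_mcs);
  IntegerVector nh(total_mcs), nhc(total_mcs), nrc(total_mcs);
  std::fill(nh.begin(), nh.end(), NA_INTEGER);
  std::fill(nhc.begin(), nhc.end(), NA_INTEGER);
  std::fill(nrc.begin(), nrc.end(), NA_INTEGER);

  int n_coop = 0;
  for (int i = 0; i < n; ++i) n_coop += (strat[i] == 0);

  int absorbed_at = NA_INTEGER; // MCS index (1-based) after which state was absorbing
  int mcs = 0;

  for (; mcs < total_mcs; ++mcs) {
    int c_nh = 0, c_nhc = 0, c_nrc = 0;

    for (int ev = 0; ev < n; ++ev) {
      const int focal = rng.rint(n);
      const int a = ptr[focal], b = ptr[focal + 1];
      const int deg = b - a;

      // donor selection: highest-reputation branch with prob p, else uniform
      int donor;
      bool high_branch = rng.runif() < pvec[focal];
      if (high_branch) {
        double best = -1.0;
        int n_ties = 0;
        donor = idx[a];
        for (int k = a; k < b; ++k) {
          const int j = idx[k];
          if (rep[j] > best) {
            best = rep[j];
            donor = j;
            n_ties = 1;
          } else if (rep[j] == best) {
            // reservoir sampling: uniform among ties in one pass
            ++n_ties;
            if (rng.rint(n_ties) == 0) donor = j;
          }
        }
        ++c_nh;
        if (strat[donor] == 0) ++c_nhc;
      } else {
        donor = idx[a + rng.rint(deg)];
        if (strat[donor] == 0) ++c_nrc;
      }

      if (strat[donor] != strat[focal]) { // adoption can change the state
        double adopt_prob;
        if (use_table) {
          int nC_f = 0, nC_d = 0;
          for (int k = a; k < b; ++k) nC_f += (strat[idx[k]] == 0);
          const int da = ptr[donor], db = ptr[donor + 1];
          for (int k = da; k < db; ++k) nC_d += (strat[idx[k]] == 0);
          adopt_prob = ftab.prob(ftab.id(strat[focal], deg, nC_f),
                                 ftab.id(strat[donor], db - da, nC_d));
        } else {
          const double pf = node_payoff(focal, strat, ptr, idx, M);
          const double pd = node_payoff(donor, strat, ptr, idx, M);
          adopt_prob = fermi(pf, pd, K);
        }
        if (rng.runif() < adopt_prob) {
          n_coop += (strat[donor] == 0) ? 1 : -1;
          strat[focal] = strat[donor];
        }
      }

      // alternative bookkeeping: the focal player's reputation advances at
      // its own update event, from its post-event strategy
      if (rep_timing == 1) {
        const double dR = (strat[focal] == 0) ? 1.0 : 0.0;
        if (rep_mode == 0) rep[focal] += dR;
        else rep[focal] = (1.0 - w) * rep[focal] + w * dR;
      }
    }

    if (rep_timing == 0) {
      // default: synchronous per-MCS bookkeeping from end-of-step strategies
      if (rep_mode == 0) {
        for (int i = 0; i < n; ++i) rep[i] += (strat[i] == 0) ? 1.0 : 0.0;
      } else {
        for (int i = 0; i < n; ++i)
          rep[i] = (1.0 - w) * rep[i] + (strat[i] == 0 ? w : 0.0);
      }
    }

    rho[mcs] = static_cast<double>(n_coop) / n;
    nh[mcs] = c_nh;
    nhc[mcs] = c_nhc;
    nrc[mcs] = c_nrc;

    if (early_stop && (n_coop == 0 || n_coop == n)) {
      absorbed_at = mcs + 1;
      // absorbing: extend the trajectory value, leave counters missing
      for (int t = mcs + 1; t < total_mcs; ++t) rho[t] = rho[mcs];
      break;
    }
  }

  IntegerVector strat_out(n);
  for (int i = 0; i < n; ++i) strat_out[i] = strat[i];

  return List::create(_["rho"] = rho,
                      _["n_h"] = nh,
                      _["n_hc"] = nhc,
                      _["n_rc"] = nrc,
                      _["strategy"] = strat_out,
                      _["reputation"] = NumericVector(rep.begin(), rep.end()),
                      _["absorbed_at"] = absorbed_at);
}

//' @name cpp_elementary_steps
//' @title Run a fixed number of elementary imitation events (internal)
//' @description Exposes the event-level dynamics for oracle tests: each event
//'   picks a focal player, selects a donor via reputation inference and applies
//'   the Fermi adoption rule. No reputation update is performed.
//' @keywords internal
// [[Rcpp::export(name = ".cpp_elementary_steps")]]
List cpp_elementary_steps(IntegerVector adj_ptr, IntegerVector adj_idx,
                          IntegerVector strategy0, NumericVector reputation,
                          NumericVector infer_p, NumericVector payoff_mat,
                          double K, int n_events, double seed) {
  const int n = strategy0.size();
  std::vector<int> ptr(adj_ptr.begin(), adj_ptr.end());
  std::vector<int> idx(adj_idx.begin(), adj_idx.end());
  std::vector<uint8_t> strat(n);
  for (int i = 0; i < n; ++i) strat[i] = static_cast<uint8_t>(strategy0[i]);
  std::vector<double> rep(reputation.begin(), reputation.end());
  std::vector<double> pvec(infer_p.begin(), infer_p.end());
  double M[2][2] = {{payoff_mat[0], payoff_mat[1]},
                    {payoff_mat[2], payoff_mat[3]}};
  Xoshiro256pp rng(static_cast<uint64_t>(seed));

  IntegerVector focal_out(n_events), donor_out(n_events), branch_out(n_events),
      adopted_out(n_events);

  for (int ev = 0; ev < n_events; ++ev) {
    const int focal = rng.rint(n);
    const int a = ptr[focal], b = ptr[focal + 1];
    int donor;
    bool high_branch = rng.runif() < pvec[focal];
    if (high_branch) {
      double best = -1.0;
      int n_ties = 0;
      donor = idx[a];
      for (int k = a; k < b; ++k) {
        const int j = idx[k];
        if (rep[j] > best) {
          best = rep[j]; donor = j; n_ties = 1;
        } else if (rep[j] == best) {
          ++n_ties;
          if (rng.rint(n_ties) == 0) donor = j;
        }
      }
    } else {
      donor = idx[a + rng.rint(b - a)];
    }
    int adopted = 0;
    const double pf = node_payoff(focal, strat, ptr, idx, M);
    const double pd = node_payoff(donor, strat, ptr, idx, M);
    if (rng.runif() < fermi(pf, pd, K)) {
      adopted = (strat[focal] != strat[donor]);
      strat[focal] = strat[donor];
    }
    focal_out[ev] = focal + 1;
    donor_out[ev] = donor + 1;
    branch_out[ev] = high_branch ? 1L : 0L;
    adopted_out[ev] = adopted;
  }

  IntegerVector strat_out(n);
  for (int i = 0; i < n; ++i) strat_out[i] = strat[i];
  return List::create(_["focal"] = focal_out, _["donor"] = donor_out,
                      _["high_branch"] = branch_out, _["adopted"] = adopted_out,
                      _["strategy"] = strat_out);
}
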