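// Structured coalescent over a fixed universe of deme slots with
// piecewise-constant epochs (coalescence rate per deme, backward
// migration matrix) and boundary transitions: deterministic remaps
// (splits backward-merge child slots into parent slots, deme-count
// reductions collapse slots) and probabilistic pulses (admixture).
//
// One genealogy per block (no intra-block recombination); infinite-sites
// mutations dropped on branches at rate mu_per_gen per lineage.
// Uses its own mt19937_64 stream so results are reproducible from the
// seed alone, independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct Epoch {
  double t0, t1;
  std::vector<double> coal;          // per-pair coalescence rate 1/(2N) per deme
  std::vector<double> mig;           // row-major n x n backward migration rates
  std::vector<double> rowsum;        // outgoing rate per deme
};

struct Transition {
  double time;
  int kind;                          // 0 = remap, 1 = pulse
  std::vector<int> map;              // remap: new deme per old deme (0-based)
  std::vector<int> from, to;         // pulse: lineages in from[i] -> to[i]
  double prob;
};

// [[Rcpp::export(name = ".coalescent_blocks")]]
IntegerMatrix coalescent_blocks(int n_demes, List epochs, List transitions,
                                IntegerVector sample_demes, double mu_per_gen,
                                int n_blocks, double seed) {
  const int n = sample_demes.size();
  if (n < 2) stop("need at least two sampled chromosomes");
  if (n > 64) stop("at most 64 sampled chromosomes are supported");

  std::vector<Epoch> eps(epochs.size());
  for (int i = 0; i < epochs.size(); ++i) {
    List e = epochs[i];
    Epoch& E = eps[i];
    E.t0 = as<double>(e["t0"]);
    E.t1 = as<double>(e["t1"]);
    NumericVector coal = e["coal"];
    NumericMatrix M = e["M"];
    if ((int)coal.size() != n_demes || M.nrow() != n_demes)
      stop("epoch dimensions do not match n_demes");
    E.coal.assign(coal.begin(), coal.end());
    E.mig.resize((size_t)n_demes * n_demes);
    E.rowsum.assign(n_demes, 0.0);
    for (int r = 0; r < n_demes; ++r)
      for (int c = 0; c < n_demes; ++c) {
        double v = M(r, c);
        E.mig[(size_t)r * n_demes + c] = v;
        if (r != c) E.rowsum[r] += v;
      }
  }

  std::vector<Transition> trs(transitions.size());
  for (int i = 0; i < transitions.size(); ++i) {
    List tr = transitions[i];
    Transition& T = trs[i];
    T.time = as<double>(tr["time"]);
    std::string kind = as<std::string>(tr["kind"]);
    if (kind == "remap") {
      T.kind = 0;
      IntegerVector map = tr["map"];               // 1-based from R
      if ((int)map.size() != n_demes) stop("remap length mismatch");
      T.map.resize(n_demes);
      for (int d = 0; d < n_demes; ++d) T.map[d] = map[d] - 1;
    } else {
      T.kind = 1;
      IntegerVector f = tr["from"], t = tr["to"];
      T.from.assign(f.begin(), f.end());
      T.to.assign(t.begin(), t.end());
      for (size_t k = 0; k < T.from.size(); ++k) { T.from[k]--; T.to[k]--; }
      T.prob = as<double>(tr["prob"]);
    }
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int n_nodes = 2 * n - 1;
  std::vector<double> ntime(n_nodes);
  std::vector<int> nparent(n_nodes);
  std::vector<int> ldeme(n_nodes), lnode(n_nodes);  // active lineages
  std::vector<uint64_t> below(n_nodes);             // leaf bitmask per node
  std::vector<int> in_deme;                         // scratch

  std::vector<int> site_block;
  std::vector<uint64_t> site_mask;

  for (int b = 0; b < n_blocks; ++b) {
    for (int i = 0; i < n_nodes; ++i) { nparent[i] = -1; ntime[i] = 0.0; }
    int k = n;                       // live lineages
    for (int i = 0; i < n; ++i) {
      ldeme[i] = sample_demes[i] - 1;
      lnode[i] = i;
      below[i] = (uint64_t)1 << i;
    }
    int next_node = n;
    double t = 0.0;
    size_t ei = 0, ti = 0;
    // skip transitions at time 0 (none should exist)
    long guard = 0;

    while (k > 1) {
      if (++guard > 100000000L) stop("coalescent did not finish (guard hit)");
      const Epoch& E = eps[ei];
      double tb = E.t1;
      if (ti < trs.size() && trs[ti].time < tb) tb = trs[ti].time;

      // total rates
      double R_coal = 0.0, R_mig = 0.0;
      // per-deme counts
      static thread_local std::vector<int> cnt;
      cnt.assign(n_demes, 0);
      for (int i = 0; i < k; ++i) cnt[ldeme[i]]++;
      for (int d = 0; d < n_demes; ++d) {
        if (cnt[d] > 1) R_coal += 0.5 * cnt[d] * (cnt[d] - 1) * E.coal[d];
        if (cnt[d] > 0) R_mig += cnt[d] * E.rowsum[d];
      }
      double R = R_coal + R_mig;

      double tnew = R > 0 ? t - std::log(1.0 - unif(rng)) / R
                          : std::numeric_limits<double>::infinity();
      if (tnew >= tb) {
        if (!std::isfinite(tb))
          stop("lineages cannot coalesce: zero total rate in final epoch");
        t = tb;
        while (ti < trs.size() && trs[ti].time == tb) {
          const Transition& T = trs[ti];
          if (T.kind == 0) {
            for (int i = 0; i < k; ++i) ldeme[i] = T.map[ldeme[i]];
          } else {
            for (int i = 0; i < k; ++i)
              for (size_t p = 0; p < T.from.size(); ++p)
                if (ldeme[i] == T.from[p] && unif(rng) < T.prob) {
                  ldeme[i] = T.to[p];
                  break;
                }
          }
          ++ti;
        }
        while (ei + 1 < eps.size() && eps[ei].t1 <= t) ++ei;
        continue;
      }
      t = tnew;
      double u = unif(rng) * R;
      if (u < R_coal) {
        // choose deme
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < n_demes; ++dd) {
          if (cnt[dd] > 1) {
            acc += 0.5 * cnt[dd] * (cnt[dd] - 1) * E.coal[dd];
            if (u < acc) { d = dd; break; }
          }
        }
        if (d < 0) d = n_demes - 1;
        in_deme.clear();
        for (int i = 0; i < k; ++i) if (ldeme[i] == d) in_deme.push_back(i);
        int a = (int)(unif(rng) * in_deme.size());
        int bsel = (int)(unif(rng) * (in_deme.size() - 1));
        if (bsel >= a) bsel++;
        int ia = in_deme[a], ib = in_deme[bsel];
        int node = next_node++;
        ntime[node] = t;
        nparent[lnode[ia]] = node;
        nparent[lnode[ib]] = node;
        below[node] = below[lnode[ia]] | below[lnode[ib]];
        // replace ia with merged, remove ib (swap with last)
        lnode[ia] = node;
        ldeme[k - 1] = ldeme[k - 1]; // no-op clarity
        if (ib != k - 1) { lnode[ib] = lnode[k - 1]; ldeme[ib] = ldeme[k - 1]; }
        --k;
      } else {
        u -= R_coal;
        // choose migrating lineage by deme
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < n_demes; ++dd) {
          if (cnt[dd] > 0 && E.rowsum[dd] > 0) {
            acc += cnt[dd] * E.rowsum[dd];
            if (u < acc) { d = dd; break; }
          }
        }
        if (d < 0) continue;  // numerical edge: no migration possible
        in_deme.clear();
        for (int i = 0; i < k; ++i) if (ldeme[i] == d) in_deme.push_back(i);
        int il = in_deme[(int)(unif(rng) * in_deme.size())];
        double v = unif(rng) * E.rowsum[d];
        double acc2 = 0.0;
        int dest = -1;
        for (int c = 0; c < n_demes; ++c) {
          if (c == d) continue;
          acc2 += E.mig[(size_t)d * n_demes + c];
          if (v < acc2) { dest = c; break; }
        }
        if (dest >= 0) ldeme[il] = dest;
      }
    }

    // mutations: Poisson(mu * total branch length), uniform on branches
    double Ltot = 0.0;
    for (int i = 0; i < next_node - 1; ++i)
      if (nparent[i] >= 0) Ltot += ntime[nparent[i]] - ntime[i];
    if (Ltot > 0 && mu_per_gen > 0) {
      std::poisson_distribution<int> pois(mu_per_gen * Ltot);
      int nm = pois(rng);
      for (int m = 0; m < nm; ++m) {
        double u = unif(rng) * Ltot, acc = 0.0;
        for (int i = 0; i < next_node - 1; ++i) {
          if (nparent[i] < 0) continue;
          acc += ntime[nparent[i]] - ntime[i];
          if (u < acc) {
            site_block.push_back(b + 1);
            site_mask.push_back(below[i]);
            break;
          }
        }
      }
    }
  }

  const int ns = (int)site_block.size();
  IntegerMatrix out(ns, n + 1);
  for (int s = 0; s < ns; ++s) {
    out(s, 0) = site_block[s];
    for (int i = 0; i < n; ++i)
      out(s, i + 1) = (site_mask[s] >> i) & 1 ? 1 : 0;
  }
  return out;
}
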