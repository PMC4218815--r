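// Seed-and-extend cross-hybridization scorer.
//
// For every probe, finds the longest contiguous exact match shared with a
// foreign-species reference (probe or reverse complement) and the best
// full-length ungapped identity over alignments anchored at shared 12-mer
// seeds. A seed-8 second pass and a per-probe dynamic-programming fallback
// guarantee the reported match length is exact even below the seed size.
//
// Non-ACGT characters never match: reference bases are mapped to code -1
// and probe bases likewise, and code -1 compares unequal to everything
// (including itself).

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

typedef std::unordered_map<std::uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string &ref, int k, KmerIndex &idx) {
  const std::uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < (int)ref.size(); ++i) {
    int c = base_code(ref[i]);
    if (c < 0) {
      run = 0;
      h = 0;
      continue;
    }
    h = ((h << 2) | (std::uint64_t)c) & mask;
    ++run;
    if (run >= k) idx[h].push_back(i - k + 1);
  }
}

static inline bool bases_match(char a, char b) {
  int ca = base_code(a);
  return ca >= 0 && ca == base_code(b);
}

// Length of the maximal exact match containing a k-mer seed at probe
// position pi / reference position ri.
static int extend_match(const std::string &probe, int pi, const std::string &ref,
                        int ri, int k) {
  int left = 0;
  while (pi - left - 1 >= 0 && ri - left - 1 >= 0 &&
         bases_match(probe[pi - left - 1], ref[ri - left - 1]))
    ++left;
  int right = 0;
  while (pi + k + right < (int)probe.size() && ri + k + right < (int)ref.size() &&
         bases_match(probe[pi + k + right], ref[ri + k + right]))
    ++right;
  return k + left + right;
}

// Full-length ungapped identity of the probe anchored so that probe
// position pi aligns with reference position ri. Out-of-range reference
// positions count as mismatches.
static double anchored_identity(const std::string &probe, int pi,
                                const std::string &ref, int ri) {
  int start = ri - pi;
  int matches = 0;
  for (int j = 0; j < (int)probe.size(); ++j) {
    int rj = start + j;
    if (rj < 0 || rj >= (int)ref.size()) continue;
    if (bases_match(probe[j], ref[rj])) ++matches;
  }
  return (double)matches / (double)probe.size();
}

// One seed pass over a probe strand; updates best match length and (for the
// primary seed size) best anchored identity.
static void seed_pass(const std::string &probe, const std::string &ref,
                      const KmerIndex &idx, int k, bool track_identity,
                      int &best_len, double &best_id) {
  if ((int)probe.size() < k) return;
  const std::uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < (int)probe.size(); ++i) {
    int c = base_code(probe[i]);
    if (c < 0) {
      run = 0;
      h = 0;
      continue;
    }
    h = ((h << 2) | (std::uint64_t)c) & mask;
    ++run;
    if (run < k) continue;
    int pi = i - k + 1;
    KmerIndex::const_iterator it = idx.find(h);
    if (it == idx.end()) continue;
    const std::vector<int> &hits = it->second;
    for (size_t j = 0; j < hits.size(); ++j) {
      int len = extend_match(probe, pi, ref, hits[j], k);
      if (len > best_len) best_len = len;
      if (track_identity) {
        double id = anchored_identity(probe, pi, ref, hits[j]);
        if (id > best_id) best_id = id;
      }
    }
  }
}

// Classic longest-common-substring dynamic programme, used only when both
// seed passes find nothing (true maximum is then < the small seed size).
static int lcs_dp(const std::string &probe, const std::string &ref) {
  int n = (int)probe.size(), m = (int)ref.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    char pc = probe[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (bases_match(pc, ref[j - 1])) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_cross_hyb(CharacterVector probes, std::string ref, int seed_len) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  KmerIndex idx_primary;
  build_index(ref, seed_len, idx_primary);
  int small_seed = seed_len > 8 ? 8 : 0;
  KmerIndex idx_small;
  bool small_built = false;

  int np = probes.size();
  IntegerVector max_match(np);
  NumericVector best_identity(np);
  for (int p = 0; p < np; ++p) {
    std::string fwd = as<std::string>(probes[p]);
    std::string rev = revcomp(fwd);
    int best_len = 0;
    double best_id = 0.0;
    seed_pass(fwd, ref, idx_primary, seed_len, true, best_len, best_id);
    seed_pass(rev, ref, idx_primary, seed_len, true, best_len, best_id);
    if (best_len < seed_len && small_seed > 0) {
      if (!small_built) {
        build_index(ref, small_seed, idx_small);
        small_built = true;
      }
      seed_pass(fwd, ref, idx_small, small_seed, false, best_len, best_id);
      seed_pass(rev, ref, idx_small, small_seed, false, best_len, best_id);
    }
    int floor_seed = small_seed > 0 ? small_seed : seed_len;
    if (best_len < floor_seed) {
      int d1 = lcs_dp(fwd, ref);
      int d2 = lcs_dp(rev, ref);
      best_len = d1 > d2 ? d1 : d2;
    }
    max_match[p] = best_len;
    best_identity[p] = best_id;
  }
  return List::create(_["max_match"] = max_match,
                      _["best_identity"] = best_identity);
}
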