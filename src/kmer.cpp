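#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// 2-bit base codes; anything else (N etc.) breaks the current k-mer.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Enumerate valid k-mers of s, calling f(position, forward_code, rc_code).
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
    if (++run >= k) f(i - k + 1, fwd, rc);
  }
}

// ---- strand-agnostic k-mer index + pseudoalignment -------------------------

// For each read the compatible target set is the intersection of the
// target sets of its indexed canonical k-mers (k-mers absent from the
// index are skipped): targets whose support count equals the number of
// present k-mers. When that intersection is empty — on periodic satellite
// targets a single sequencing error routinely produces a k-mer that exists
// in the index but belongs to other targets — the read is rescued instead
// of discarded: its set becomes the targets within one error footprint
// (k k-mers) of the maximal support, which keeps the read on the
// dominantly supported target(s) while leaving near-ties for the EM to
// resolve. Reads with no indexed k-mer are unassigned. Reads with
// identical target sets are pooled into equivalence classes.

// [[Rcpp::export]]
List pseudoalign_cpp(CharacterVector targets, CharacterVector reads, int k) {
  std::unordered_map<uint64_t, std::vector<int>> index;
  for (int t = 0; t < targets.size(); ++t) {
    std::string s = as<std::string>(targets[t]);
    for_each_kmer(s, k, [&](int, uint64_t fwd, uint64_t rc) {
      uint64_t canon = std::min(fwd, rc);
      auto& v = index[canon];
      if (v.empty() || v.back() != t) v.push_back(t);
    });
  }

  std::unordered_map<std::string, int> class_of;
  std::vector<std::vector<int>> class_targets;
  std::vector<int> class_counts;
  IntegerVector read_class(reads.size());
  int n_unassigned = 0;

  const int nt = targets.size();
  std::vector<int> support(nt);
  std::vector<int> cur;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    std::fill(support.begin(), support.end(), 0);
    int n_present = 0;
    for_each_kmer(s, k, [&](int, uint64_t fwd, uint64_t rc) {
      auto it = index.find(std::min(fwd, rc));
      if (it == index.end()) return; // absent k-mers are skipped
      ++n_present;
      for (int t : it->second) ++support[t];
    });
    if (n_present == 0) { read_class[r] = 0; ++n_unassigned; continue; }
    cur.clear();
    for (int t = 0; t < nt; ++t)            // strict intersection first
      if (support[t] == n_present) cur.push_back(t);
    if (cur.empty()) {                      // error rescue
      const int best = *std::max_element(support.begin(), support.end());
      const int floor_sup = std::max(1, best - k);
      for (int t = 0; t < nt; ++t)
        if (support[t] >= floor_sup) cur.push_back(t);
    }
    std::string key;
    for (int t : cur) { key += std::to_string(t); key += ','; }
    auto it = class_of.find(key);
    int ci;
    if (it == class_of.end()) {
      ci = class_targets.size();
      class_of.emplace(key, ci);
      class_targets.push_back(cur);
      class_counts.push_back(0);
    } else ci = it->second;
    ++class_counts[ci];
    read_class[r] = ci + 1;
  }

  List ct(class_targets.size());
  for (size_t i = 0; i < class_targets.size(); ++i) {
    IntegerVector v(class_targets[i].size());
    for (size_t j = 0; j < class_targets[i].size(); ++j)
      v[j] = class_targets[i][j] + 1; // 1-based target indices
    ct[i] = v;
  }
  return List::create(
    _["class_targets"] = ct,
    _["class_counts"] = IntegerVector(class_counts.begin(), class_counts.end()),
    _["read_class"] = read_class,
    _["n_unassigned"] = n_unassigned);
}

// ---- ungapped seed-and-extend anchoring ------------------------------------

// Anchor each read (both orientations) to one transcript by exact shared
// k-mers; candidate diagonals are scored match +1 / mismatch -1 over the
// ungapped overlap, with bases overhanging the transcript ends neither
// rewarded nor penalized (soft-clip semantics: on periodic satellite
// targets a plain matching-base count lets a tail-bearing read anchor one
// repeat period upstream, burying its tail inside the body). Best-scoring
// anchoring wins; ties go to the leftmost transcript offset, then to the
// plus strand. Returns, per read: anchored flag, strand (+1 / -1), 0-based
// offset of read base 0 on the transcript (may be negative), and the
// matching-base count of the winning anchoring.

static void rc_inplace(std::string& s) {
  std::reverse(s.begin(), s.end());
  for (auto& c : s) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
}

// [[Rcpp::export]]
List anchor_reads_cpp(std::string transcript, CharacterVector reads, int k) {
  std::unordered_map<uint64_t, std::vector<int>> pos;
  for_each_kmer(transcript, k, [&](int p, uint64_t fwd, uint64_t) {
    pos[fwd].push_back(p);
  });
  const int tlen = transcript.size();
  const int nr = reads.size();
  LogicalVector anchored(nr);
  IntegerVector strand(nr), offset(nr), matches(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int best_sc = INT_MIN, best_m = 0, best_o = 0, best_s = 0;
    for (int s = 1; s >= -1; s -= 2) {
      std::string rd = fwd;
      if (s < 0) rc_inplace(rd);
      if ((int)rd.size() < k) continue;
      std::unordered_map<int, int> diag;
      for_each_kmer(rd, k, [&](int i, uint64_t f, uint64_t) {
        auto it = pos.find(f);
        if (it == pos.end()) return;
        for (int p : it->second) ++diag[p - i];
      });
      for (auto& kv : diag) {
        const int o = kv.first;
        const int lo = std::max(0, -o), hi = std::min((int)rd.size(), tlen - o);
        int m = 0;
        for (int i = lo; i < hi; ++i)
          if (rd[i] == transcript[o + i]) ++m;
        const int sc = 2 * m - (hi - lo); // matches - mismatches
        if (sc > best_sc ||
            (sc == best_sc && (o < best_o || (o == best_o && s > best_s)))) {
          best_sc = sc; best_m = m; best_o = o; best_s = s;
        }
      }
    }
    if (best_sc == INT_MIN) { anchored[r] = false; strand[r] = NA_INTEGER; }
    else {
      anchored[r] = true; strand[r] = best_s;
      offset[r] = best_o; matches[r] = best_m;
    }
  }
  return List::create(
    _["anchored"] = anchored, _["strand"] = strand,
    _["offset"] = offset, _["matches"] = matches);
}
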