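// Seed-and-extend chained aligner: exact k-mer seeds on a 2-bit index,
// ungapped X-drop extension along diagonals, greedy chaining of segments
// with bounded query/target gaps.  Substitution-aware only (no indels
// inside blocks); inter-block target gaps model introns.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Segment {
  int qstart, qend;     // half-open, query coords (alignment orientation)
  int tstart, tend;     // half-open, target coords
};

struct Chain {
  std::vector<Segment> segs;
  int matches = 0, mismatches = 0;
};

class KmerIndex {
public:
  int k;
  uint32_t mask;
  std::vector<uint32_t> bucket_start;   // size 4^k + 1
  std::vector<uint32_t> pos;            // global positions
  std::vector<uint64_t> offsets;        // per-target start in global coords
  const std::vector<std::string>* targets;

  KmerIndex(const std::vector<std::string>& tgt, int k_) : k(k_), targets(&tgt) {
    mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    size_t nbuck = (size_t)1 << (2 * k);
    offsets.resize(tgt.size() + 1);
    offsets[0] = 0;
    for (size_t i = 0; i < tgt.size(); ++i)
      offsets[i + 1] = offsets[i] + tgt[i].size();
    std::vector<uint32_t> counts(nbuck + 1, 0);
    // first pass: count
    for (size_t t = 0; t < tgt.size(); ++t) {
      const std::string& s = tgt[t];
      if ((int)s.size() < k) continue;
      uint32_t km = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base2code(s[i]);
        if (c < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint32_t)c) & mask;
        if (++run >= k) counts[km + 1]++;
      }
    }
    bucket_start.resize(nbuck + 1);
    uint64_t acc = 0;
    for (size_t b = 0; b <= nbuck; ++b) { acc += counts[b]; bucket_start[b] = (uint32_t)acc; }
    pos.resize(acc);
    std::vector<uint32_t> fill(nbuck, 0);
    for (size_t t = 0; t < tgt.size(); ++t) {
      const std::string& s = tgt[t];
      if ((int)s.size() < k) continue;
      uint32_t km = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base2code(s[i]);
        if (c < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint32_t)c) & mask;
        if (++run >= k)
          pos[bucket_start[km] + fill[km]++] = (uint32_t)(offsets[t] + i - k + 1);
      }
    }
  }

  int tid_of(uint64_t gpos) const {
    // targets are few; linear/binary search over offsets
    int lo = 0, hi = (int)offsets.size() - 2;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (offsets[mid] <= gpos) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

struct SeedHit { int tid; int diag; int qpos; int tpos; };

// ungapped X-drop extension on one diagonal; returns refined segment
static Segment extend_segment(const std::string& q, const std::string& t,
                              int qs, int qe, int ts, int xdrop) {
  int diag = ts - qs;
  // left
  int best = 0, score = 0, bqs = qs;
  for (int i = qs - 1; i >= 0 && i + diag >= 0; --i) {
    score += (q[i] == t[i + diag]) ? 1 : -3;
    if (score > best) { best = score; bqs = i; }
    if (best - score > xdrop) break;
  }
  // right
  best = 0; score = 0; int bqe = qe;
  for (int i = qe; i < (int)q.size() && i + diag < (int)t.size(); ++i) {
    score += (q[i] == t[i + diag]) ? 1 : -3;
    if (score > best) { best = score; bqe = i + 1; }
    if (best - score > xdrop) break;
  }
  Segment s; s.qstart = bqs; s.qend = bqe; s.tstart = bqs + diag; s.tend = bqe + diag;
  return s;
}

static void count_matches(const std::string& q, const std::string& t,
                          const Segment& s, int& m, int& mm) {
  int diag = s.tstart - s.qstart;
  for (int i = s.qstart; i < s.qend; ++i)
    if (q[i] == t[i + diag]) ++m; else ++mm;
}

// chain segments of one (query, target, strand): greedy best-path extraction
static std::vector<Chain> chain_segments(std::vector<Segment> segs,
                                         const std::string& q, const std::string& t,
                                         int max_qgap, int max_tgap, int min_matches) {
  // short noise segments (barely more than a stray seed) are dropped
  segs.erase(std::remove_if(segs.begin(), segs.end(), [](const Segment& s) {
    return s.qend - s.qstart < 16;
  }), segs.end());
  std::sort(segs.begin(), segs.end(), [](const Segment& a, const Segment& b) {
    return a.qstart < b.qstart || (a.qstart == b.qstart && a.tstart < b.tstart);
  });
  int n = (int)segs.size();
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) len[i] = segs[i].qend - segs[i].qstart;
  std::vector<char> used(n, 0);
  std::vector<Chain> chains;
  const int ovl = 10;
  while (true) {
    // DP best-scoring chain over unused segments; joining across a target
    // gap pays an affine penalty so that distant stray seeds do not attach
    std::vector<double> score(n, 0);
    std::vector<int> prev(n, -1);
    int besti = -1; double bests = 0;
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      score[i] = len[i];
      for (int j = 0; j < n; ++j) {
        if (used[j] || j == i) continue;
        const Segment& a = segs[j]; const Segment& b = segs[i];
        if (b.qstart < a.qend - ovl || b.tstart < a.tend - ovl) continue;
        if (a.qend > b.qend || a.tend > b.tend) continue;
        int qg = b.qstart - a.qend, tg = b.tstart - a.tend;
        if (qg > max_qgap || tg > max_tgap) continue;
        double pen = 12.0 + std::max(0, tg) / 2000.0 + std::max(0, qg) / 10.0;
        if (score[j] + len[i] - pen > score[i]) {
          score[i] = score[j] + len[i] - pen; prev[i] = j;
        }
      }
      if (score[i] > bests) { bests = score[i]; besti = i; }
    }
    if (besti < 0 || bests < (double)min_matches) break;
    Chain ch;
    std::vector<int> path;
    for (int i = besti; i >= 0; i = prev[i]) path.push_back(i);
    std::reverse(path.begin(), path.end());
    for (int idx : path) { used[idx] = 1; ch.segs.push_back(segs[idx]); }
    // trim small overlaps between consecutive segments (keep earlier block)
    for (size_t i = 1; i < ch.segs.size(); ++i) {
      Segment& a = ch.segs[i - 1]; Segment& b = ch.segs[i];
      int cut = std::max(a.qend - b.qstart, a.tend - b.tstart);
      if (cut > 0) { b.qstart += cut; b.tstart += cut; }
    }
    ch.segs.erase(std::remove_if(ch.segs.begin(), ch.segs.end(),
                  [](const Segment& s) { return s.qend <= s.qstart; }), ch.segs.end());
    if (ch.segs.empty()) continue;
    ch.matches = 0; ch.mismatches = 0;
    for (const Segment& s : ch.segs) count_matches(q, t, s, ch.matches, ch.mismatches);
    if (ch.matches >= min_matches) chains.push_back(ch);
  }
  return chains;
}

// align one oriented query against the index; appends result records
static void align_oriented(const KmerIndex& idx, const std::string& q,
                           int qid, int qsize, char strand,
                           int maxocc, int min_matches, int max_qgap, int max_tgap,
                           int xdrop, std::vector<List>& out) {
  int k = idx.k;
  if ((int)q.size() < k) return;
  std::vector<SeedHit> hits;
  uint32_t km = 0; int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int c = base2code(q[i]);
    if (c < 0) { run = 0; km = 0; continue; }
    km = ((km << 2) | (uint32_t)c) & idx.mask;
    if (++run < k) continue;
    uint32_t b0 = idx.bucket_start[km], b1 = idx.bucket_start[km + 1];
    if (b1 - b0 == 0 || (int)(b1 - b0) > maxocc) continue;
    int qpos = (int)i - k + 1;
    for (uint32_t b = b0; b < b1; ++b) {
      uint64_t g = idx.pos[b];
      int tid = idx.tid_of(g);
      int tpos = (int)(g - idx.offsets[tid]);
      hits.push_back({tid, tpos - qpos, qpos, tpos});
    }
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
    if (a.tid != b.tid) return a.tid < b.tid;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  // group by (tid, diag) with qpos-gap splitting -> raw segments per tid
  std::vector<std::vector<Segment>> per_tid(idx.targets->size());
  const int split_gap = 500;
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i + 1;
    while (j < hits.size() && hits[j].tid == hits[i].tid &&
           hits[j].diag == hits[i].diag &&
           hits[j].qpos - hits[j - 1].qpos <= split_gap) ++j;
    const std::string& t = (*idx.targets)[hits[i].tid];
    Segment s = extend_segment(q, t, hits[i].qpos, hits[j - 1].qpos + k,
                               hits[i].tpos, xdrop);
    per_tid[hits[i].tid].push_back(s);
    i = j;
  }
  for (size_t tid = 0; tid < per_tid.size(); ++tid) {
    if (per_tid[tid].empty()) continue;
    // merge duplicate/contained segments on the same diagonal
    auto& v = per_tid[tid];
    std::sort(v.begin(), v.end(), [](const Segment& a, const Segment& b) {
      int da = a.tstart - a.qstart, db = b.tstart - b.qstart;
      if (da != db) return da < db;
      return a.qstart < b.qstart;
    });
    std::vector<Segment> merged;
    for (const Segment& s : v) {
      if (!merged.empty()) {
        Segment& m = merged.back();
        if (m.tstart - m.qstart == s.tstart - s.qstart && s.qstart <= m.qend) {
          m.qend = std::max(m.qend, s.qend);
          m.tend = std::max(m.tend, s.tend);
          continue;
        }
      }
      merged.push_back(s);
    }
    const std::string& t = (*idx.targets)[tid];
    std::vector<Chain> chains = chain_segments(merged, q, t, max_qgap, max_tgap,
                                               min_matches);
    for (const Chain& ch : chains) {
      int nb = (int)ch.segs.size();
      IntegerVector qs(nb), ts(nb), bl(nb);
      for (int b = 0; b < nb; ++b) {
        qs[b] = ch.segs[b].qstart;
        ts[b] = ch.segs[b].tstart;
        bl[b] = ch.segs[b].qend - ch.segs[b].qstart;
      }
      out.push_back(List::create(
        _["qid"] = qid + 1, _["tid"] = (int)tid + 1,
        _["strand"] = std::string(1, strand), _["qsize"] = qsize,
        _["matches"] = ch.matches, _["mismatches"] = ch.mismatches,
        _["qstarts"] = qs, _["tstarts"] = ts, _["blocksizes"] = bl));
    }
  }
}

// [[Rcpp::export]]
List cpp_align(std::vector<std::string> targets, std::vector<std::string> queries,
               int k = 12, int maxocc = 64, int min_matches = 30,
               int max_qgap = 60, int max_tgap = 50000, int xdrop = 18,
               bool both_strands = true) {
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  KmerIndex idx(targets, k);
  std::vector<List> out;
  for (size_t qi = 0; qi < queries.size(); ++qi) {
    const std::string& q = queries[qi];
    align_oriented(idx, q, (int)qi, (int)q.size(), '+',
                   maxocc, min_matches, max_qgap, max_tgap, xdrop, out);
    if (both_strands) {
      std::string rc = revcomp(q);
      align_oriented(idx, rc, (int)qi, (int)q.size(), '-',
                     maxocc, min_matches, max_qgap, max_tgap, xdrop, out);
    }
  }
  return List(out.begin(), out.end());
}

// [[Rcpp::export]]
std::vector<std::string> cpp_revcomp(std::vector<std::string> seqs) {
  for (auto& s : seqs) s = revcomp(s);
  return seqs;
}
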