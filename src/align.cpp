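// Seed-and-extend local alignment.
//
// Strategy: exact k-mer seeds (both strands), greedy clustering of seed
// matches into diagonal bands, then a banded local Smith-Waterman (linear
// gap) restricted to each clustered subregion, padded by x_drop + k so
// extension can proceed past the outermost seeds until the score drops.
// Hits are deduplicated by reciprocal overlap, then filtered on length
// and identity.  N never seeds and always scores as a mismatch.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;  // N and anything else
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
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

struct Hit {
  int qs, qe, ts, te;   // 0-based half-open, qs/qe on the original query
  char strand;
  int score, matches, cols;
  double identity;
};

// Optimal local path (linear gap) on q[q0,q1) x t[t0,t1): returns the
// traceback path of the best-scoring cell as a step list from alignment
// start to end, with its start coordinates.  Rolling score rows + full
// byte traceback matrix.
struct SwPath {
  int qs, ts;                 // path start (absolute, 0-based)
  std::vector<uint8_t> steps; // 1 diag, 2 up (q advances), 3 left (t advances)
};

static bool sw_path(const std::string& q, int q0, int q1,
                    const std::string& t, int t0, int t1,
                    int match, int mismatch, int gap, SwPath& out) {
  const int n = q1 - q0, m = t1 - t0;
  if (n <= 0 || m <= 0) return false;
  if ((double)n * (double)m > 8e7) return false;  // guard; not hit at intended scales
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const int qcode = base_code(q[q0 + i - 1]);
    for (int j = 1; j <= m; ++j) {
      const int tcode = base_code(t[t0 + j - 1]);
      const bool is_match = qcode >= 0 && qcode == tcode;
      int d = prev[j - 1] + (is_match ? match : mismatch);
      int u = prev[j] + gap;
      int l = cur[j - 1] + gap;
      int s = d; uint8_t dir = 1;
      if (u > s) { s = u; dir = 2; }
      if (l > s) { s = l; dir = 3; }
      if (s <= 0) { s = 0; dir = 0; }
      cur[j] = s;
      tb[(size_t)i * (m + 1) + j] = dir;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  if (best <= 0) return false;
  int i = bi, j = bj;
  std::vector<uint8_t> rev;
  while (i > 0 && j > 0) {
    uint8_t dir = tb[(size_t)i * (m + 1) + j];
    if (dir == 0) break;
    rev.push_back(dir);
    if (dir == 1) { --i; --j; }
    else if (dir == 2) { --i; }
    else { --j; }
  }
  out.qs = q0 + i; out.ts = t0 + j;
  out.steps.assign(rev.rbegin(), rev.rend());
  return true;
}

// Split an optimal path wherever its running score falls more than x_drop
// below the running maximum (BLAST-style x-drop), emitting one hit per
// well-scoring contiguous piece, each trimmed to end at its score maximum.
static void split_path(const SwPath& p, const std::string& q,
                       const std::string& t, int match, int mismatch,
                       int gap, int x_drop, std::vector<Hit>& out) {
  const int L = (int)p.steps.size();
  // per-step score deltas and coordinate walks
  std::vector<int> delta(L);
  std::vector<int> qpos(L + 1), tpos(L + 1);
  qpos[0] = p.qs; tpos[0] = p.ts;
  for (int i = 0; i < L; ++i) {
    uint8_t d = p.steps[i];
    int qi = qpos[i], ti = tpos[i];
    if (d == 1) {
      int a = base_code(q[qi]), b = base_code(t[ti]);
      delta[i] = (a >= 0 && a == b) ? match : mismatch;
      qpos[i + 1] = qi + 1; tpos[i + 1] = ti + 1;
    } else if (d == 2) {
      delta[i] = gap; qpos[i + 1] = qi + 1; tpos[i + 1] = ti;
    } else {
      delta[i] = gap; qpos[i + 1] = qi; tpos[i + 1] = ti + 1;
    }
  }
  int anchor = 0;
  while (anchor < L) {
    int cum = 0, best = 0, best_idx = anchor;
    int i = anchor;
    for (; i < L; ++i) {
      cum += delta[i];
      if (cum > best) { best = cum; best_idx = i + 1; }
      if (cum - best <= -x_drop) break;
    }
    if (best > 0) {
      Hit h;
      h.qs = qpos[anchor]; h.qe = qpos[best_idx];
      h.ts = tpos[anchor]; h.te = tpos[best_idx];
      h.score = best; h.cols = best_idx - anchor;
      int matches = 0;
      for (int s = anchor; s < best_idx; ++s)
        if (p.steps[s] == 1 && delta[s] == match) ++matches;
      h.matches = matches;
      h.identity = h.cols > 0 ? (double)matches / h.cols : 0.0;
      out.push_back(h);
      anchor = best_idx;
    } else {
      ++anchor;  // leading negative steps: skip forward
    }
    if (i >= L && best_idx >= L) break;
  }
}

struct Seed { int qpos, tpos, diag; };

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string& target, int k) {
  KmerIndex idx;
  const int tlen = (int)target.size();
  idx.reserve(tlen > 16 ? tlen : 16);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0; int run = 0;
  for (int i = 0; i < tlen; ++i) {
    int c = base_code(target[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[kmer].push_back(i - k + 1);
  }
  return idx;
}

static std::vector<Hit> align_query(const std::string& query,
                                    const std::string& target,
                                    const KmerIndex& idx,
                                    int k, int min_len, double min_identity,
                                    int match, int mismatch, int gap,
                                    int x_drop) {
  const int qlen = (int)query.size(), tlen = (int)target.size();
  const int band = 20, max_seed_jump = 200;
  const int pad = x_drop + k;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<Hit> hits;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string qs = strand == 0 ? query : revcomp(query);
    // collect seed matches
    std::vector<Seed> seeds;
    {
      uint64_t kmer = 0; int run = 0;
      for (int i = 0; i < qlen; ++i) {
        int c = base_code(qs[i]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = idx.find(kmer);
          if (it != idx.end()) {
            int qpos = i - k + 1;
            for (int tpos : it->second)
              seeds.push_back({qpos, tpos, tpos - qpos});
          }
        }
      }
    }
    if (seeds.empty()) continue;
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      return a.qpos < b.qpos || (a.qpos == b.qpos && a.diag < b.diag);
    });
    // greedy clustering: open clusters tracked by (last qpos, diag range)
    struct Cluster { int qlo, qhi, tlo, thi, last_q, diag_lo, diag_hi; };
    std::vector<Cluster> open, closed;
    for (const Seed& s : seeds) {
      bool placed = false;
      for (size_t ci = 0; ci < open.size() && !placed; ++ci) {
        Cluster& cl = open[ci];
        if (s.diag >= cl.diag_lo - band && s.diag <= cl.diag_hi + band &&
            s.qpos - cl.last_q <= max_seed_jump) {
          cl.qlo = std::min(cl.qlo, s.qpos);
          cl.qhi = std::max(cl.qhi, s.qpos + k);
          cl.tlo = std::min(cl.tlo, s.tpos);
          cl.thi = std::max(cl.thi, s.tpos + k);
          cl.last_q = std::max(cl.last_q, s.qpos);
          cl.diag_lo = std::min(cl.diag_lo, s.diag);
          cl.diag_hi = std::max(cl.diag_hi, s.diag);
          placed = true;
        }
      }
      if (!placed) {
        // retire stale clusters to bound the open set
        std::vector<Cluster> still;
        for (Cluster& cl : open) {
          if (s.qpos - cl.last_q > max_seed_jump) closed.push_back(cl);
          else still.push_back(cl);
        }
        open = still;
        open.push_back({s.qpos, s.qpos + k, s.tpos, s.tpos + k,
                        s.qpos, s.diag, s.diag});
      }
    }
    for (Cluster& cl : open) closed.push_back(cl);

    // Each seeded cluster defines a work region.  A region is aligned by
    // banded local DP (grown while the optimal path touches the region
    // border); when the path contains an internal x-drop dip it is split
    // and each piece is re-aligned on its own subregion, so that every
    // reported hit is a locally optimal alignment with clean boundaries.
    struct Region { int qlo, qhi, tlo, thi, depth; };
    std::vector<Region> work;
    for (const Cluster& cl : closed)
      work.push_back({cl.qlo, cl.qhi, cl.tlo, cl.thi, 0});
    while (!work.empty()) {
      Region rg = work.back(); work.pop_back();
      int p2 = pad;
      SwPath path;
      bool ok = false;
      for (int iter = 0; iter < 5; ++iter) {
        int q0 = std::max(0, rg.qlo - p2), q1 = std::min(qlen, rg.qhi + p2);
        int t0 = std::max(0, rg.tlo - p2), t1 = std::min(tlen, rg.thi + p2);
        ok = sw_path(qs, q0, q1, target, t0, t1, match, mismatch, gap, path);
        if (!ok) break;
        int dq = 0, dt = 0;
        for (uint8_t d : path.steps) {
          if (d == 1) { ++dq; ++dt; }
          else if (d == 2) { ++dq; }
          else { ++dt; }
        }
        bool touches =
          (path.qs == q0 && q0 > 0) || (path.qs + dq == q1 && q1 < qlen) ||
          (path.ts == t0 && t0 > 0) || (path.ts + dt == t1 && t1 < tlen);
        if (!touches) break;
        p2 *= 4;
      }
      if (!ok) continue;
      std::vector<Hit> pieces;
      split_path(path, qs, target, match, mismatch, gap, x_drop, pieces);
      if (pieces.size() > 1 && rg.depth < 4) {
        for (const Hit& h : pieces)
          work.push_back({h.qs, h.qe, h.ts, h.te, rg.depth + 1});
        continue;
      }
      for (Hit h : pieces) {
        if (strand == 1) {  // map coords back to the original orientation
          int nqs = qlen - h.qe, nqe = qlen - h.qs;
          h.qs = nqs; h.qe = nqe;
        }
        h.strand = strand == 0 ? '+' : '-';
        if (h.cols >= min_len && h.identity >= min_identity)
          hits.push_back(h);
      }
    }
  }

  // dedup: keep best-scoring among hits with >=50% reciprocal overlap
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.score > b.score;
  });
  std::vector<Hit> kept;
  for (const Hit& h : hits) {
    bool dup = false;
    for (const Hit& g : kept) {
      int qov = std::min(h.qe, g.qe) - std::max(h.qs, g.qs);
      int tov = std::min(h.te, g.te) - std::max(h.ts, g.ts);
      int qmin = std::min(h.qe - h.qs, g.qe - g.qs);
      int tmin = std::min(h.te - h.ts, g.te - g.ts);
      if (qov > 0 && tov > 0 && qov * 2 >= qmin && tov * 2 >= tmin) {
        dup = true; break;
      }
    }
    if (!dup) kept.push_back(h);
  }
  return kept;
}

static DataFrame hits_to_df(const std::vector<Hit>& kept) {
  const int nh = (int)kept.size();
  IntegerVector qs(nh), qe(nh), ts(nh), te(nh), score(nh), len(nh);
  CharacterVector strand(nh);
  NumericVector identity(nh);
  for (int i = 0; i < nh; ++i) {
    qs[i] = kept[i].qs; qe[i] = kept[i].qe;
    ts[i] = kept[i].ts; te[i] = kept[i].te;
    strand[i] = std::string(1, kept[i].strand);
    identity[i] = kept[i].identity;
    score[i] = kept[i].score; len[i] = kept[i].cols;
  }
  return DataFrame::create(
    _["qstart"] = qs, _["qend"] = qe, _["tstart"] = ts, _["tend"] = te,
    _["strand"] = strand, _["identity"] = identity, _["score"] = score,
    _["length"] = len, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string target,
                          int k, int min_len, double min_identity,
                          int match, int mismatch, int gap, int x_drop) {
  KmerIndex idx = build_index(target, k);
  return hits_to_df(align_query(query, target, idx, k, min_len, min_identity,
                                match, mismatch, gap, x_drop));
}

// Batch variant: the target is indexed once and reused for every query.
// [[Rcpp::export]]
List cpp_seed_extend_multi(CharacterVector queries, std::string target,
                           int k, int min_len, double min_identity,
                           int match, int mismatch, int gap, int x_drop) {
  KmerIndex idx = build_index(target, k);
  List out(queries.size());
  for (int i = 0; i < queries.size(); ++i) {
    std::string q = as<std::string>(queries[i]);
    out[i] = hits_to_df(align_query(q, target, idx, k, min_len, min_identity,
                                    match, mismatch, gap, x_drop));
  }
  return out;
}
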