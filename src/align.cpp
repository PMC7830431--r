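// Seed-and-extend local alignment core.
//
// A k-mer hash index over the reference (both query strands handled by
// aligning the reverse complement of the query), seed clustering by
// (target, diagonal), and gapless x-drop extension along the dominant
// diagonal. Gapless extension is exact for substitution-only divergence;
// indel tolerance is limited to the diagonal drift allowed when clustering.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1; // N or anything else: breaks k-mers, never matches
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct SeqIndex {
  int k;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  // kmer -> packed (seq_idx << 40) | pos
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
};

// [[Rcpp::export(name = ".yt_index_build")]]
SEXP yt_index_build(CharacterVector ids, CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("k must be between 4 and 31");
  SeqIndex* idx = new SeqIndex();
  idx->k = k;
  bool any_long_enough = false;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string sq = as<std::string>(seqs[s]);
    idx->ids.push_back(as<std::string>(ids[s]));
    if ((int)sq.size() >= k) any_long_enough = true;
    uint64_t kmer = 0;
    int run = 0; // valid bases accumulated
    for (size_t i = 0; i < sq.size(); ++i) {
      int c = base_code(sq[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        uint64_t pos = i + 1 - k;
        idx->table[kmer].push_back(((uint64_t)s << 40) | pos);
      }
    }
    idx->seqs.push_back(std::move(sq));
  }
  if (!any_long_enough) { delete idx; stop("k is larger than every reference sequence"); }
  XPtr<SeqIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".yt_index_info")]]
List yt_index_info(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  IntegerVector lens(idx->ids.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = (int)idx->seqs[i].size();
  return List::create(_["k"] = idx->k,
                      _["ids"] = wrap(idx->ids),
                      _["lengths"] = lens,
                      _["n_kmers"] = (double)idx->table.size());
}

// positions (0-based) of one exact k-mer, for inspection/tests
// [[Rcpp::export(name = ".yt_seed_positions")]]
DataFrame yt_seed_positions(SEXP xp, std::string kmer) {
  XPtr<SeqIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("seed length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) stop("seed contains a non-ACGT character");
    key = (key << 2) | (uint64_t)b;
  }
  std::vector<int> tg, pos;
  auto it = idx->table.find(key);
  if (it != idx->table.end()) {
    for (uint64_t packed : it->second) {
      tg.push_back((int)(packed >> 40) + 1);
      pos.push_back((int)(packed & 0xFFFFFFFFFFULL));
    }
  }
  return DataFrame::create(_["target"] = tg, _["pos"] = pos);
}

struct Seed { int target; long diag; int qpos; };

struct RawHit {
  int target; long diag; int qstart, qend; int matches; int nseeds;
};

static void extend_cluster(const std::string& q, const std::string& t,
                           long diag, int span_lo, int span_hi,
                           int xdrop, int& out_lo, int& out_hi, int& out_matches) {
  // alignment columns pair q[i] with t[i + diag]
  int lo_feas = (int)std::max(0L, -diag);
  int hi_feas = (int)std::min((long)q.size(), (long)t.size() - diag);
  span_lo = std::max(span_lo, lo_feas);
  span_hi = std::min(span_hi, hi_feas);
  // left extension with x-drop
  int best = 0, cur = 0, best_i = span_lo;
  for (int i = span_lo - 1; i >= lo_feas; --i) {
    cur += (q[i] != 'N' && q[i] == t[i + diag]) ? 1 : -1;
    if (cur > best) { best = cur; best_i = i; }
    if (best - cur > xdrop) break;
  }
  int lo = best_i;
  best = 0; cur = 0;
  int best_j = span_hi;
  for (int i = span_hi; i < hi_feas; ++i) {
    cur += (q[i] != 'N' && q[i] == t[i + diag]) ? 1 : -1;
    if (cur > best) { best = cur; best_j = i + 1; }
    if (best - cur > xdrop) break;
  }
  int hi = best_j;
  int matches = 0;
  for (int i = lo; i < hi; ++i)
    if (q[i] != 'N' && q[i] == t[i + diag]) ++matches;
  out_lo = lo; out_hi = hi; out_matches = matches;
}

static void collect_hits(const std::string& q, SeqIndex* idx,
                         int min_seed_chain, int xdrop, int band, int chain_gap,
                         std::vector<RawHit>& out) {
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::vector<Seed> seeds;
  uint64_t kmer = 0; int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = idx->table.find(kmer);
      if (it == idx->table.end()) continue;
      int qpos = (int)(i + 1 - k);
      for (uint64_t packed : it->second) {
        int tg = (int)(packed >> 40);
        long tpos = (long)(packed & 0xFFFFFFFFFFULL);
        seeds.push_back({tg, tpos - qpos, qpos});
      }
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.target != b.target) return a.target < b.target;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  // cluster by (target, nearby diagonal); split clusters on large qpos gaps
  size_t i = 0;
  while (i < seeds.size()) {
    size_t j = i + 1;
    while (j < seeds.size() && seeds[j].target == seeds[i].target &&
           seeds[j].diag - seeds[j - 1].diag <= band) ++j;
    // seeds[i..j) share a diagonal band on one target; order by qpos, split on gaps
    std::vector<Seed> grp(seeds.begin() + i, seeds.begin() + j);
    std::sort(grp.begin(), grp.end(), [](const Seed& a, const Seed& b) {
      return a.qpos < b.qpos;
    });
    size_t a = 0;
    while (a < grp.size()) {
      size_t b = a + 1;
      while (b < grp.size() && grp[b].qpos - grp[b - 1].qpos <= chain_gap) ++b;
      int nseeds = (int)(b - a);
      if (nseeds >= min_seed_chain) {
        // dominant (most-seeded) diagonal; ties -> smallest
        std::unordered_map<long, int> dc;
        for (size_t x = a; x < b; ++x) dc[grp[x].diag]++;
        long diag = grp[a].diag; int bestc = -1;
        for (auto& kv : dc)
          if (kv.second > bestc || (kv.second == bestc && kv.first < diag)) {
            bestc = kv.second; diag = kv.first;
          }
        int span_lo = grp[a].qpos;
        int span_hi = grp[b - 1].qpos + k;
        int lo, hi, matches;
        const std::string& t = idx->seqs[grp[a].target];
        extend_cluster(q, t, diag, span_lo, span_hi, xdrop, lo, hi, matches);
        if (hi > lo) out.push_back({grp[a].target, diag, lo, hi, matches, nseeds});
      }
      a = b;
    }
    i = j;
  }
  // merge overlapping same-diagonal hits (clusters that extended into each other)
  std::sort(out.begin(), out.end(), [](const RawHit& a, const RawHit& b) {
    if (a.target != b.target) return a.target < b.target;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qstart < b.qstart;
  });
  std::vector<RawHit> merged;
  for (const RawHit& h : out) {
    if (!merged.empty()) {
      RawHit& p = merged.back();
      if (p.target == h.target && p.diag == h.diag && h.qstart <= p.qend) {
        int lo = std::min(p.qstart, h.qstart), hi = std::max(p.qend, h.qend);
        const std::string& t = idx->seqs[h.target];
        int matches = 0;
        for (int x = lo; x < hi; ++x)
          if (q[x] != 'N' && q[x] == t[x + h.diag]) ++matches;
        p.qstart = lo; p.qend = hi; p.matches = matches;
        p.nseeds += h.nseeds;
        continue;
      }
    }
    merged.push_back(h);
  }
  out.swap(merged);
}

// [[Rcpp::export(name = ".yt_local_hits")]]
DataFrame yt_local_hits(SEXP xp, std::string query,
                        int min_seed_chain, int xdrop,
                        double min_identity, int min_hit_length,
                        int band, int chain_gap) {
  XPtr<SeqIndex> idx(xp);
  std::vector<int> target, qstart, qend, tstart, tend, length, matches, nseeds;
  std::vector<std::string> strand;

  for (int str = 0; str < 2; ++str) {
    std::string q;
    if (str == 0) q = query;
    else {
      q.resize(query.size());
      for (size_t i = 0; i < query.size(); ++i)
        q[i] = comp_base(query[query.size() - 1 - i]);
    }
    std::vector<RawHit> hits;
    collect_hits(q, idx.get(), min_seed_chain, xdrop, band, chain_gap, hits);
    int qlen = (int)query.size();
    for (const RawHit& h : hits) {
      int len = h.qend - h.qstart;
      if (len < min_hit_length) continue;
      if ((double)h.matches / len < min_identity) continue;
      int qs = h.qstart, qe = h.qend;
      if (str == 1) { qs = qlen - h.qend; qe = qlen - h.qstart; }
      target.push_back(h.target + 1);
      strand.push_back(str == 0 ? "+" : "-");
      qstart.push_back(qs); qend.push_back(qe);
      tstart.push_back((int)(h.qstart + h.diag));
      tend.push_back((int)(h.qend + h.diag));
      length.push_back(len);
      matches.push_back(h.matches);
      nseeds.push_back(h.nseeds);
    }
  }
  return DataFrame::create(
    _["target"] = target, _["strand"] = strand,
    _["qstart"] = qstart, _["qend"] = qend,
    _["tstart"] = tstart, _["tend"] = tend,
    _["length"] = length, _["matches"] = matches,
    _["nseeds"] = nseeds,
    _["stringsAsFactors"] = false);
}

// Maximal tandem arrays of unit size min_unit..max_unit. Runs are scored
// match +1, mismatch -(1/max_impurity - 1) and trimmed at their score
// maximum (so a pure array is never padded with flanking noise); the score
// scheme caps the mismatch fraction of a reported region near
// max_impurity, and the fraction is re-checked exactly before reporting.
// Purity = matched period comparisons / total comparisons in the region.
// [[Rcpp::export(name = ".yt_tandem_scan")]]
DataFrame yt_tandem_scan(std::string s, int min_unit, int max_unit,
                         int min_copies, int min_length, double max_impurity) {
  int n = (int)s.size();
  std::vector<int> out_start, out_end, out_unit;
  std::vector<double> out_purity;
  double penalty = max_impurity > 0 ? 1.0 / max_impurity - 1.0 : (double)n;
  double xdrop = 2.0 * penalty;
  for (int u = min_unit; u <= max_unit; ++u) {
    int i = u;
    while (i < n) {
      if (base_code(s[i]) < 0 || s[i] != s[i - u]) { ++i; continue; }
      int rs = i; // first matching comparison of the run
      double cur = 0, best = 0;
      int best_end = rs;
      for (int j = rs; j < n; ++j) {
        if (base_code(s[j]) < 0) break;
        if (s[j] == s[j - u]) {
          cur += 1.0;
          if (cur > best) { best = cur; best_end = j; }
        } else {
          cur -= penalty;
        }
        if (best - cur > xdrop) break;
      }
      int start = rs - u, end = best_end + 1; // half-open region
      int len = end - start;
      if (len >= min_length && len >= min_copies * u) {
        int mism = 0, cnt = 0;
        for (int j = rs; j <= best_end; ++j) {
          ++cnt;
          if (s[j] != s[j - u]) ++mism;
        }
        double impurity = cnt > 0 ? (double)mism / cnt : 0.0;
        if (impurity <= max_impurity) {
          out_start.push_back(start);
          out_end.push_back(end);
          out_unit.push_back(u);
          out_purity.push_back(1.0 - impurity);
        }
      }
      i = best_end + 1;
    }
  }
  return DataFrame::create(
    _["start"] = out_start, _["end"] = out_end,
    _["unit"] = out_unit, _["purity"] = out_purity);
}
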