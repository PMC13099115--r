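// Native seed-and-extend nucleotide homology search: exact k-mer seeding on
// an indexed genome, ungapped X-drop extension, per-diagonal deduplication
// and colinear chaining of compatible HSPs. Coordinates are 0-based
// half-open on the forward strand of the subject.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct GenomeIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // kmer -> packed (scaffold, position)
  std::unordered_map<uint32_t, std::vector<std::pair<int,int>>> kmap;
  double n_indexed;
};

// [[Rcpp::export]]
SEXP cpp_index_genome(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 8 || k > 15) stop("k must be in [8, 15]");
  if (seqs.size() == 0) stop("empty genome");
  GenomeIndex *gi = new GenomeIndex();
  gi->k = k;
  gi->n_indexed = 0;
  uint32_t mask = (k == 15) ? 0x3FFFFFFFu : ((1u << (2 * k)) - 1u);
  for (int s = 0; s < seqs.size(); ++s) {
    std::string sq = as<std::string>(seqs[s]);
    gi->names.push_back(as<std::string>(names[s]));
    uint32_t kmer = 0;
    int valid = 0;
    for (int i = 0; i < (int)sq.size(); ++i) {
      int b = enc(sq[i]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint32_t)b) & mask;
      if (++valid >= k) {
        gi->kmap[kmer].push_back(std::make_pair(s, i - k + 1));
        gi->n_indexed += 1;
      }
    }
    gi->seqs.push_back(sq);
  }
  XPtr<GenomeIndex> p(gi, true);
  return p;
}

// [[Rcpp::export]]
double cpp_index_size(SEXP ptr) {
  XPtr<GenomeIndex> gi(ptr);
  return gi->n_indexed;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP ptr) {
  XPtr<GenomeIndex> gi(ptr);
  return gi->k;
}

struct Hsp {
  int sc, qs, qe, ss, se;   // half-open
  double score;
  int matches;
  bool alive;
  int diag() const { return ss - qs; }
};

static void extend_seed(const std::string &q, const std::string &s,
                        int qpos, int spos, int k,
                        double match, double mismatch, double xdrop,
                        Hsp &out) {
  // seed is an exact match q[qpos..qpos+k) == s[spos..spos+k)
  double cur = k * match, best = cur;
  int bi = qpos, bj = spos;            // best left ends
  int mleft = 0, mbest_left = 0;
  {
    int i = qpos - 1, j = spos - 1, m = 0;
    while (i >= 0 && j >= 0) {
      bool hit = enc(q[i]) >= 0 && enc(q[i]) == enc(s[j]);
      cur += hit ? match : mismatch;
      if (hit) ++m;
      if (cur > best) { best = cur; bi = i; bj = j; mbest_left = m; }
      if (best - cur > xdrop) break;
      --i; --j;
    }
    mleft = mbest_left;
  }
  double base = best;
  int be_q = qpos + k, be_s = spos + k;
  int mright = 0;
  {
    double cur2 = base, best2 = base;
    int i = qpos + k, j = spos + k, m = 0, mb = 0;
    while (i < (int)q.size() && j < (int)s.size()) {
      bool hit = enc(q[i]) >= 0 && enc(q[i]) == enc(s[j]);
      cur2 += hit ? match : mismatch;
      if (hit) ++m;
      if (cur2 > best2) { best2 = cur2; be_q = i + 1; be_s = j + 1; mb = m; }
      if (best2 - cur2 > xdrop) break;
      ++i; ++j;
    }
    base = best2;
    mright = mb;
  }
  out.qs = bi; out.ss = bj; out.qe = be_q; out.se = be_s;
  out.score = base;
  out.matches = k + mleft + mright;
  out.alive = true;
}

static void search_strand(const GenomeIndex &gi, const std::string &q,
                          double match, double mismatch, double xdrop,
                          double min_seed_score, std::vector<Hsp> &hsps) {
  int k = gi.k;
  int qlen = (int)q.size();
  if (qlen < k) return;
  uint32_t mask = (k == 15) ? 0x3FFFFFFFu : ((1u << (2 * k)) - 1u);
  struct Seed { int sc, diag, spos, qpos; };
  std::vector<Seed> seeds;
  uint32_t kmer = 0;
  int valid = 0;
  for (int i = 0; i < qlen; ++i) {
    int b = enc(q[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)b) & mask;
    if (++valid >= k) {
      auto it = gi.kmap.find(kmer);
      if (it == gi.kmap.end()) continue;
      int qpos = i - k + 1;
      for (auto &pr : it->second) {
        seeds.push_back({pr.first, pr.second - qpos, pr.second, qpos});
      }
    }
  }
  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    if (a.sc != b.sc) return a.sc < b.sc;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.spos < b.spos;
  });
  int last_sc = -1, last_diag = 0, last_end = -1;
  for (auto &sd : seeds) {
    if (sd.sc == last_sc && sd.diag == last_diag && sd.spos < last_end) {
      continue;  // inside the previous HSP on this diagonal
    }
    Hsp h;
    h.sc = sd.sc;
    extend_seed(q, gi.seqs[sd.sc], sd.qpos, sd.spos, k,
                match, mismatch, xdrop, h);
    last_sc = sd.sc; last_diag = sd.diag; last_end = h.se;
    if (h.score >= min_seed_score) hsps.push_back(h);
  }
}

// chain colinear HSPs (same scaffold, bounded gap and diagonal drift)
static std::vector<Hsp> chain_hsps(std::vector<Hsp> v, int band,
                                   int chain_gap, double gap_open,
                                   double gap_extend) {
  std::sort(v.begin(), v.end(), [](const Hsp &a, const Hsp &b) {
    if (a.sc != b.sc) return a.sc < b.sc;
    return a.ss < b.ss;
  });
  std::vector<Hsp> out;
  for (auto &h : v) {
    bool merged = false;
    for (int j = (int)out.size() - 1; j >= 0; --j) {
      Hsp &c = out[j];
      if (c.sc != h.sc || h.ss - c.se > chain_gap) {
        if (c.sc == h.sc && h.ss - c.se > chain_gap) break;
        continue;
      }
      int dshift = std::abs(h.diag() - c.diag());
      int qgap = h.qs - c.qe, sgap = h.ss - c.se;
      if (dshift <= band && qgap >= -20 && sgap >= -20 &&
          qgap <= chain_gap && sgap <= chain_gap) {
        double pen = dshift > 0 ? gap_open + gap_extend * dshift : 0.0;
        c.score += h.score - pen;
        c.matches += h.matches;
        c.qe = std::max(c.qe, h.qe);
        c.qs = std::min(c.qs, h.qs);
        c.se = std::max(c.se, h.se);
        merged = true;
        break;
      }
    }
    if (!merged) out.push_back(h);
  }
  // deduplicate overlapping HSPs on the same diagonal, keeping the best
  std::sort(out.begin(), out.end(), [](const Hsp &a, const Hsp &b) {
    return a.score > b.score;
  });
  for (size_t i = 0; i < out.size(); ++i) {
    if (!out[i].alive) continue;
    for (size_t j = i + 1; j < out.size(); ++j) {
      if (!out[j].alive || out[j].sc != out[i].sc) continue;
      if (out[j].diag() == out[i].diag() &&
          out[j].ss < out[i].se && out[j].se > out[i].ss) {
        out[j].alive = false;
      }
    }
  }
  std::vector<Hsp> kept;
  for (auto &h : out) if (h.alive) kept.push_back(h);
  return kept;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
DataFrame cpp_search(SEXP ptr, std::string query, double match,
                     double mismatch, double xdrop, int band, int chain_gap,
                     double gap_open, double gap_extend,
                     double min_score) {
  XPtr<GenomeIndex> gi(ptr);
  int qlen = (int)query.size();
  if (qlen < gi->k) stop("query shorter than k");
  std::vector<Hsp> fwd, rev;
  search_strand(*gi, query, match, mismatch, xdrop, min_score, fwd);
  std::string qrc = revcomp_str(query);
  search_strand(*gi, qrc, match, mismatch, xdrop, min_score, rev);
  fwd = chain_hsps(fwd, band, chain_gap, gap_open, gap_extend);
  rev = chain_hsps(rev, band, chain_gap, gap_open, gap_extend);

  std::vector<int> qs, qe, ss, se, matches;
  std::vector<double> score;
  std::vector<std::string> scaffold, strand;
  for (auto &h : fwd) {
    qs.push_back(h.qs); qe.push_back(h.qe);
    ss.push_back(h.ss); se.push_back(h.se);
    score.push_back(h.score); matches.push_back(h.matches);
    scaffold.push_back(gi->names[h.sc]); strand.push_back("+");
  }
  for (auto &h : rev) {
    // map query coordinates back to the original (forward) query
    qs.push_back(qlen - h.qe); qe.push_back(qlen - h.qs);
    ss.push_back(h.ss); se.push_back(h.se);
    score.push_back(h.score); matches.push_back(h.matches);
    scaffold.push_back(gi->names[h.sc]); strand.push_back("-");
  }
  return DataFrame::create(
    _["subject_scaffold"] = scaffold, _["strand"] = strand,
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["score"] = score, _["matches"] = matches,
    _["stringsAsFactors"] = false);
}
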