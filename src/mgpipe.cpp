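// Compiled kernels: seed-and-extend mapper, quality trimming, base-composition
// profiling, local alignment scoring for adapter screening, CIGAR arithmetic,
// and pileup construction.  All coordinates crossing the R boundary are
// 1-based inclusive, matching SAM/GFF and R string conventions.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <tuple>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or anything else
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// ---------------------------------------------------------------------------
// Seed index: exact k-mer -> (ref, window start, strand) for both strands.
// Strand '-' entries hold the reverse complement of the forward window, so a
// read k-mer hitting a '-' entry means the read aligns reverse-complemented.
// ---------------------------------------------------------------------------

struct SeedHit {
  int32_t ref;
  int32_t pos;    // 0-based window start on the forward reference
  bool rev;
};

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<SeedHit> > table;
  size_t n_fwd = 0, n_rev = 0;
};

// [[Rcpp::export(name = ".mg_index_build")]]
SEXP mg_index_build(CharacterVector ref_names, CharacterVector ref_seqs, int k) {
  if (k < 8 || k > 31) stop("seed k must be in [8, 31]");
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < ref_names.size(); ++r) {
    idx->names.push_back(as<std::string>(ref_names[r]));
    idx->seqs.push_back(as<std::string>(ref_seqs[r]));
    const std::string &s = idx->seqs.back();
    if ((int)s.size() < k) continue;
    uint64_t fwd = 0, rev = 0;
    int run = 0; // valid (non-N) bases accumulated
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        int32_t p = (int32_t)(i + 1 - k);
        idx->table[fwd].push_back(SeedHit{(int32_t)r, p, false});
        idx->n_fwd++;
        idx->table[rev].push_back(SeedHit{(int32_t)r, p, true});
        idx->n_rev++;
      }
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".mg_index_stats")]]
List mg_index_stats(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["n_refs"] = (int)idx->names.size(),
                      _["n_forward_seeds"] = (double)idx->n_fwd,
                      _["n_reverse_seeds"] = (double)idx->n_rev,
                      _["n_distinct_kmers"] = (double)idx->table.size());
}

// [[Rcpp::export(name = ".mg_index_refnames")]]
CharacterVector mg_index_refnames(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return wrap(idx->names);
}

// ---------------------------------------------------------------------------
// Glocal banded alignment: query end-to-end, free leading/trailing reference
// gaps inside the window.  Linear gap penalty.  Returns score, ref start
// (0-based within window), CIGAR over {M,I,D} and NM (mismatches + indel bp).
// ---------------------------------------------------------------------------

struct AlnResult {
  int score;
  int ref_start;   // 0-based, relative to window start
  std::string cigar;
  int nm;
};

static const int SC_MATCH = 1, SC_MIS = -1, SC_GAP = -2;
static const int NEG_INF = -1000000;

static AlnResult glocal_align(const std::string &q, const std::string &ref,
                              size_t ws, size_t we) {
  const int L = (int)q.size();
  const int W = (int)(we - ws);
  // dp[i][j]: best score aligning q[0..i) with window[.. j) where the query
  // start is pinned but the reference start is free (row 0 all zeros).
  std::vector<std::vector<int> > dp(L + 1, std::vector<int>(W + 1, NEG_INF));
  for (int j = 0; j <= W; ++j) dp[0][j] = 0;
  for (int i = 1; i <= L; ++i) dp[i][0] = i * SC_GAP;
  for (int i = 1; i <= L; ++i) {
    const int qc = base_code(q[i - 1]);
    for (int j = 1; j <= W; ++j) {
      const int rc = base_code(ref[ws + j - 1]);
      const int sub = (qc >= 0 && qc == rc) ? SC_MATCH : SC_MIS;
      int best = dp[i - 1][j - 1] + sub;          // M
      int up = dp[i - 1][j] + SC_GAP;             // I (query base vs ref gap)
      int left = dp[i][j - 1] + SC_GAP;           // D (ref base vs query gap)
      if (up > best) best = up;
      if (left > best) best = left;
      dp[i][j] = best;
    }
  }
  int bj = 0, bscore = NEG_INF;
  for (int j = 0; j <= W; ++j)
    if (dp[L][j] > bscore) { bscore = dp[L][j]; bj = j; }
  // traceback
  std::vector<std::pair<char,int> > ops;
  int i = L, j = bj, nm = 0;
  while (i > 0) {
    const int qc = base_code(q[i - 1]);
    if (j > 0) {
      const int rc = base_code(ref[ws + j - 1]);
      const int sub = (qc >= 0 && qc == rc) ? SC_MATCH : SC_MIS;
      if (dp[i][j] == dp[i - 1][j - 1] + sub) {
        if (sub == SC_MIS) nm++;
        if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
        else ops.push_back(std::make_pair('M', 1));
        i--; j--; continue;
      }
      if (dp[i][j] == dp[i][j - 1] + SC_GAP) {
        nm++;
        if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
        else ops.push_back(std::make_pair('D', 1));
        j--; continue;
      }
    }
    // query gap against reference (insertion to reference == I)
    nm++;
    if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
    else ops.push_back(std::make_pair('I', 1));
    i--;
  }
  std::string cig;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    cig += std::to_string(it->second);
    cig += it->first;
  }
  AlnResult res;
  res.score = bscore;
  res.ref_start = j;
  res.cigar = cig;
  res.nm = nm;
  return res;
}

// ---------------------------------------------------------------------------
// Batch mapping.  One primary alignment per read (best score; ties broken by
// lowest reference index, then leftmost position, then forward strand).
// ---------------------------------------------------------------------------

struct Cand {
  int votes;
  int32_t ref;
  bool rev;
  int32_t diag; // putative 0-based start of the oriented query on the ref
};

// [[Rcpp::export(name = ".mg_map_batch")]]
List mg_map_batch(SEXP xp, CharacterVector reads, int band, int max_hits_per_seed,
                  int seed_stride, int max_candidates) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector ref_i(n, NA_INTEGER), pos(n, NA_INTEGER), nmv(n, NA_INTEGER),
                score(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING), cigar(n, NA_STRING);

  std::unordered_map<uint64_t, int> votes;
  for (int ri = 0; ri < n; ++ri) {
    const std::string q = as<std::string>(reads[ri]);
    const int L = (int)q.size();
    mapped[ri] = false;
    if (L < k) continue;
    // collect seed offsets: stride plus the final offset
    votes.clear();
    std::vector<int> offs;
    for (int o = 0; o + k <= L; o += seed_stride) offs.push_back(o);
    if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
    for (int o : offs) {
      uint64_t code = 0; bool ok = true;
      for (int t = 0; t < k; ++t) {
        int c = base_code(q[o + t]);
        if (c < 0) { ok = false; break; }
        code = ((code << 2) | (uint64_t)c) & mask;
      }
      if (!ok) continue;
      auto it = idx->table.find(code);
      if (it == idx->table.end()) continue;
      if ((int)it->second.size() > max_hits_per_seed) continue;
      for (const SeedHit &h : it->second) {
        int32_t diag = h.rev ? (h.pos - (L - k - o)) : (h.pos - o);
        uint64_t key = ((uint64_t)(uint32_t)h.ref << 34) |
                       ((uint64_t)(h.rev ? 1 : 0) << 33) |
                       (uint64_t)(uint32_t)(diag + (1 << 30));
        votes[key]++;
      }
    }
    if (votes.empty()) continue;
    std::vector<Cand> cands;
    cands.reserve(votes.size());
    for (auto &kv : votes) {
      Cand c;
      c.votes = kv.second;
      c.ref = (int32_t)(kv.first >> 34);
      c.rev = ((kv.first >> 33) & 1) != 0;
      c.diag = (int32_t)((uint32_t)(kv.first & ((1ULL << 33) - 1))) - (1 << 30);
      cands.push_back(c);
    }
    std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
      if (a.votes != b.votes) return a.votes > b.votes;
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.diag != b.diag) return a.diag < b.diag;
      return !a.rev && b.rev;
    });
    // drop candidates on a diagonal within `band` of a stronger kept one
    std::vector<Cand> kept;
    for (const Cand &c : cands) {
      bool dup = false;
      for (const Cand &kc : kept)
        if (kc.ref == c.ref && kc.rev == c.rev && std::abs(kc.diag - c.diag) <= band) {
          dup = true; break;
        }
      if (!dup) kept.push_back(c);
      if ((int)kept.size() >= max_candidates) break;
    }
    const std::string qrc = revcomp(q);
    int b_score = NEG_INF, b_ref = -1, b_pos = -1, b_nm = 0;
    bool b_rev = false;
    std::string b_cig;
    for (const Cand &c : kept) {
      const std::string &oq = c.rev ? qrc : q;
      const std::string &rs = idx->seqs[c.ref];
      int sc, st, nm; std::string cg;
      // fast path: gapless check on the candidate diagonal
      bool fast = false;
      if (c.diag >= 0 && c.diag + L <= (int)rs.size()) {
        int mm = 0;
        for (int t = 0; t < L && mm <= 2; ++t) {
          int a = base_code(oq[t]), b = base_code(rs[c.diag + t]);
          if (a < 0 || a != b) mm++;
        }
        if (mm <= 2) {
          sc = L - 2 * mm; st = c.diag; nm = mm;
          cg = std::to_string(L) + "M";
          fast = true;
        }
      }
      if (!fast) {
        size_t ws = (size_t)std::max(0, c.diag - band);
        size_t we = std::min(rs.size(), (size_t)std::max(0, c.diag) + (size_t)L + (size_t)band);
        if (we <= ws) continue;
        AlnResult ar = glocal_align(oq, rs, ws, we);
        sc = ar.score; st = (int)ws + ar.ref_start; nm = ar.nm; cg = ar.cigar;
      }
      bool better = false;
      if (sc > b_score) better = true;
      else if (sc == b_score) {
        if (c.ref < b_ref) better = true;
        else if (c.ref == b_ref) {
          if (st < b_pos) better = true;
          else if (st == b_pos && !c.rev && b_rev) better = true;
        }
      }
      if (better) {
        b_score = sc; b_ref = c.ref; b_pos = st; b_rev = c.rev;
        b_nm = nm; b_cig = cg;
      }
      if (b_score == L) break; // perfect
    }
    if (b_score <= 0) continue; // nothing alignment-worthy
    mapped[ri] = true;
    ref_i[ri] = b_ref + 1;
    pos[ri] = b_pos + 1;          // 1-based
    strand[ri] = b_rev ? "-" : "+";
    cigar[ri] = b_cig;
    nmv[ri] = b_nm;
    score[ri] = b_score;
  }
  return List::create(_["mapped"] = mapped, _["ref_i"] = ref_i, _["pos"] = pos,
                      _["strand"] = strand, _["cigar"] = cigar, _["nm"] = nmv,
                      _["score"] = score);
}

// ---------------------------------------------------------------------------
// Quality trimming bounds.  mode 0 = longest contiguous segment with all
// qualities passing (5'-most on ties); mode 1 = strip the 3' tail while the
// terminal quality fails.  `inclusive` makes quality q pass at cutoff q.
// Returns 1-based [start, end]; an empty result is (1, 0).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mg_trim_bounds")]]
IntegerMatrix mg_trim_bounds(CharacterVector qual, int offset, int q, int mode,
                             bool inclusive) {
  const int n = qual.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(qual[i]);
    const int L = (int)s.size();
    auto pass = [&](int p) {
      int v = (int)(unsigned char)s[p] - offset;
      return inclusive ? (v >= q) : (v > q);
    };
    int bs = 1, be = 0;
    if (mode == 0) {
      int cs = -1, blen = 0;
      for (int p = 0; p <= L; ++p) {
        if (p < L && pass(p)) { if (cs < 0) cs = p; }
        else if (cs >= 0) {
          if (p - cs > blen) { blen = p - cs; bs = cs + 1; be = p; }
          cs = -1;
        }
      }
    } else {
      int e = L;
      while (e > 0 && !pass(e - 1)) e--;
      bs = 1; be = e;
    }
    out(i, 0) = bs; out(i, 1) = be;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Positional base composition counts over a collection of reads.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mg_base_counts")]]
List mg_base_counts(CharacterVector seqs) {
  int maxlen = 0;
  const int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    int L = LENGTH(STRING_ELT(seqs, i));
    if (L > maxlen) maxlen = L;
  }
  IntegerMatrix counts(maxlen, 5); // A C G T N
  IntegerVector at_pos(maxlen);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = LENGTH(STRING_ELT(seqs, i));
    for (int p = 0; p < L; ++p) {
      int c = base_code(s[p]);
      counts(p, c < 0 ? 4 : c)++;
      at_pos[p]++;
    }
  }
  return List::create(_["counts"] = counts, _["n_at_position"] = at_pos);
}

// ---------------------------------------------------------------------------
// Best local (Smith-Waterman) score of each read against any adapter, both
// orientations.  Linear gap penalty.
// ---------------------------------------------------------------------------

static int sw_score(const std::string &a, const std::string &b,
                    int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const int ac = base_code(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      const int bc = base_code(b[j - 1]);
      int sub = (ac >= 0 && ac == bc) ? match : mismatch;
      int v = prev[j - 1] + sub;
      if (prev[j] + gap > v) v = prev[j] + gap;
      if (cur[j - 1] + gap > v) v = cur[j - 1] + gap;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".mg_sw_best")]]
IntegerVector mg_sw_best(CharacterVector reads, CharacterVector adapters,
                         int match, int mismatch, int gap) {
  const int n = reads.size(), m = adapters.size();
  std::vector<std::string> ads;
  for (int j = 0; j < m; ++j) {
    std::string a = as<std::string>(adapters[j]);
    ads.push_back(a);
    ads.push_back(revcomp(a));
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string r = as<std::string>(reads[i]);
    int best = 0;
    for (const std::string &a : ads) {
      int s = sw_score(r, a, match, mismatch, gap);
      if (s > best) best = s;
    }
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// CIGAR arithmetic: per record, query bases aligned (M+I), reference span
// (M+D), and total query bases accounted for (M+I+S).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mg_cigar_stats")]]
IntegerMatrix mg_cigar_stats(CharacterVector cigars) {
  const int n = cigars.size();
  IntegerMatrix out(n, 3);
  colnames(out) = CharacterVector::create("aligned_q", "ref_span", "query_len");
  for (int i = 0; i < n; ++i) {
    if (cigars[i] == NA_STRING) {
      out(i, 0) = NA_INTEGER; out(i, 1) = NA_INTEGER; out(i, 2) = NA_INTEGER;
      continue;
    }
    const std::string s = as<std::string>(cigars[i]);
    long num = 0; int aq = 0, rs = 0, ql = 0;
    for (char c : s) {
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
      switch (c) {
      case 'M': case '=': case 'X': aq += num; rs += num; ql += num; break;
      case 'I': aq += num; ql += num; break;
      case 'D': case 'N': rs += num; break;
      case 'S': ql += num; break;
      case 'H': case 'P': break;
      default: stop("unknown CIGAR op '%s'", std::string(1, c).c_str());
      }
      num = 0;
    }
    out(i, 0) = aq; out(i, 1) = rs; out(i, 2) = ql;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pileup: per reference position, depth, base counts, deletion observations,
// plus aggregated insertion observations (inserted sequence after a position).
// Invariant: depth(p) = sum(base_counts(p, .)) + deletion_obs(p).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mg_pileup")]]
List mg_pileup(IntegerVector ref_i, IntegerVector pos, CharacterVector cigar,
               CharacterVector seq, IntegerVector ref_lens) {
  const int nref = ref_lens.size();
  std::vector<IntegerMatrix> counts;
  std::vector<IntegerVector> dels;
  for (int r = 0; r < nref; ++r) {
    counts.push_back(IntegerMatrix(ref_lens[r], 5));
    dels.push_back(IntegerVector(ref_lens[r]));
  }
  std::map<std::tuple<int,int,std::string>, int> ins_obs;
  const int n = ref_i.size();
  for (int a = 0; a < n; ++a) {
    const int r = ref_i[a] - 1;
    if (r < 0 || r >= nref) stop("alignment %d references unknown sequence", a + 1);
    const std::string cg = as<std::string>(cigar[a]);
    const std::string sq = as<std::string>(seq[a]);
    int rp = pos[a] - 1;  // 0-based ref cursor
    int qp = 0;           // 0-based query cursor
    long num = 0;
    const int L = ref_lens[r];
    for (char c : cg) {
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
      if (c == 'M' || c == '=' || c == 'X') {
        for (long t = 0; t < num; ++t) {
          if (rp >= 0 && rp < L) {
            int bc = base_code(sq[qp]);
            counts[r](rp, bc < 0 ? 4 : bc)++;
          }
          rp++; qp++;
        }
      } else if (c == 'I') {
        // inserted sequence attaches after the previous consumed ref base
        std::string ins = sq.substr(qp, num);
        if (rp >= 1 && rp <= L)
          ins_obs[std::make_tuple(r, rp, ins)]++; // rp is 1-based "after" pos
        qp += num;
      } else if (c == 'D' || c == 'N') {
        for (long t = 0; t < num; ++t) {
          if (rp >= 0 && rp < L) dels[r][rp]++;
          rp++;
        }
      } else if (c == 'S') {
        qp += num;
      } // H, P consume nothing
      num = 0;
    }
  }
  int ni = (int)ins_obs.size();
  IntegerVector iri(ni), ipos(ni), icnt(ni);
  CharacterVector isq(ni);
  int t = 0;
  for (auto &kv : ins_obs) {
    iri[t] = std::get<0>(kv.first) + 1;
    ipos[t] = std::get<1>(kv.first);
    isq[t] = std::get<2>(kv.first);
    icnt[t] = kv.second;
    t++;
  }
  List cl(nref), dl(nref);
  for (int r = 0; r < nref; ++r) { cl[r] = counts[r]; dl[r] = dels[r]; }
  return List::create(_["base_counts"] = cl, _["deletion_obs"] = dl,
                      _["ins_ref_i"] = iri, _["ins_pos"] = ipos,
                      _["ins_seq"] = isq, _["ins_count"] = icnt);
}
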