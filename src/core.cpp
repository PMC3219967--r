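#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <climits>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<uint8_t> Seq;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default:  return 4;            // N / anything else: never matches
  }
}

static Seq encode_seq(const char *s) {
  size_t n = std::strlen(s);
  Seq out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (uint8_t) base_code(s[i]);
  return out;
}

static Seq revcomp_seq(const Seq &s) {
  size_t n = s.size();
  Seq out(n);
  for (size_t i = 0; i < n; ++i) {
    uint8_t b = s[n - 1 - i];
    out[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed-piece index.  An ungapped alignment passing the seed policy (at most
// max_seed_mm mismatches within the first seed_len read bases) must contain
// at least one of max_seed_mm+1 disjoint seed pieces matching the reference
// exactly (pigeonhole), so exact lookup of the pieces enumerates every
// placement the policy can accept.
// ---------------------------------------------------------------------------

struct SeedIndex {
  int plen;
  // code -> packed (ref << 32) | pos, forward strand of references only
  std::unordered_map<uint32_t, std::vector<uint64_t> > table;
};

static bool piece_code(const Seq &s, int off, int plen, uint32_t &code) {
  uint32_t c = 0;
  for (int i = 0; i < plen; ++i) {
    uint8_t b = s[off + i];
    if (b >= 4) return false;
    c = (c << 2) | b;
  }
  code = c;
  return true;
}

static void build_index(const std::vector<Seq> &refs, int plen, SeedIndex &idx) {
  idx.plen = plen;
  idx.table.clear();
  for (size_t r = 0; r < refs.size(); ++r) {
    const Seq &ref = refs[r];
    if ((int)ref.size() < plen) continue;
    for (int pos = 0; pos + plen <= (int)ref.size(); ++pos) {
      uint32_t code;
      if (!piece_code(ref, pos, plen, code)) continue;
      idx.table[code].push_back(((uint64_t)r << 32) | (uint32_t)pos);
    }
  }
}

struct Hit { int ref; int pos; int strand; int mm; }; // pos = leftmost ref coord

// verify one mate placement; aln is the alignment-oriented sequence (read or
// its reverse complement); quals are in read orientation.
static bool verify_mate(const Seq &ref, const Seq &aln, const int *qual,
                        bool minus, int s, int eff_seed,
                        int max_seed_mm, int max_qual_mm, int &mm_out) {
  int L = (int)aln.size();
  if (s < 0 || s + L > (int)ref.size()) return false;
  int mm = 0, qsum = 0, seed_mm = 0;
  int seed_lo = minus ? L - eff_seed : 0;
  int seed_hi = minus ? L : eff_seed;
  for (int i = 0; i < L; ++i) {
    uint8_t b = aln[i];
    if (b >= 4 || b != ref[s + i]) {
      ++mm;
      qsum += qual[minus ? (L - 1 - i) : i];
      if (qsum > max_qual_mm) return false;
      if (i >= seed_lo && i < seed_hi && ++seed_mm > max_seed_mm) return false;
    }
  }
  mm_out = mm;
  return true;
}

class Mapper {
public:
  std::vector<Seq> refs;
  int seed_len, max_seed_mm, max_qual_mm;
  std::unordered_map<int, SeedIndex> indexes; // by piece length

  Mapper(const CharacterVector &ref_chr, int seed_len_, int max_seed_mm_,
         int max_qual_mm_)
    : seed_len(seed_len_), max_seed_mm(max_seed_mm_), max_qual_mm(max_qual_mm_) {
    refs.reserve(ref_chr.size());
    for (R_xlen_t i = 0; i < ref_chr.size(); ++i)
      refs.push_back(encode_seq(CHAR(STRING_ELT(ref_chr, i))));
  }

  SeedIndex &index_for(int plen) {
    std::unordered_map<int, SeedIndex>::iterator it = indexes.find(plen);
    if (it != indexes.end()) return it->second;
    SeedIndex &idx = indexes[plen];
    build_index(refs, plen, idx);
    return idx;
  }

  // all valid placements of one mate on every reference, both strands
  void collect(const Seq &f, const Seq &rc, const int *qual,
               std::vector<Hit> &out) {
    out.clear();
    int L = (int)f.size();
    if (L == 0) return;
    int eff = std::min(seed_len, L);
    if (eff <= max_seed_mm) { collect_exhaustive(f, rc, qual, eff, out); return; }

    int np = max_seed_mm + 1;
    int base = eff / np, rem = eff % np;
    std::unordered_set<uint64_t> seen;
    int off = 0;
    for (int j = 0; j < np; ++j) {
      int pl = base + (j < rem ? 1 : 0);
      SeedIndex &idx = index_for(pl);
      uint32_t code;
      // forward strand: piece sits at read offset `off`
      if (piece_code(f, off, pl, code)) {
        std::unordered_map<uint32_t, std::vector<uint64_t> >::const_iterator
          hit = idx.table.find(code);
        if (hit != idx.table.end())
          for (size_t h = 0; h < hit->second.size(); ++h) {
            int r = (int)(hit->second[h] >> 32);
            int s = (int)(uint32_t)hit->second[h] - off;
            try_hit(r, s, +1, f, rc, qual, eff, seen, out);
          }
      }
      // reverse strand: the read's first seed_len bases are the 3' end of rc
      int rcoff = L - off - pl;
      if (piece_code(rc, rcoff, pl, code)) {
        std::unordered_map<uint32_t, std::vector<uint64_t> >::const_iterator
          hit = idx.table.find(code);
        if (hit != idx.table.end())
          for (size_t h = 0; h < hit->second.size(); ++h) {
            int r = (int)(hit->second[h] >> 32);
            int s = (int)(uint32_t)hit->second[h] - rcoff;
            try_hit(r, s, -1, f, rc, qual, eff, seen, out);
          }
      }
      off += pl;
    }
  }

private:
  void try_hit(int r, int s, int strand, const Seq &f, const Seq &rc,
               const int *qual, int eff, std::unordered_set<uint64_t> &seen,
               std::vector<Hit> &out) {
    int L = (int)f.size();
    if (s < 0 || s + L > (int)refs[r].size()) return;
    uint64_t key = ((((uint64_t)r << 32) | (uint64_t)(uint32_t)s) << 1) |
      (strand < 0 ? 1u : 0u);
    if (!seen.insert(key).second) return;
    int mm;
    const Seq &aln = (strand > 0) ? f : rc;
    if (verify_mate(refs[r], aln, qual, strand < 0, s, eff,
                    max_seed_mm, max_qual_mm, mm)) {
      Hit h; h.ref = r; h.pos = s; h.strand = strand; h.mm = mm;
      out.push_back(h);
    }
  }

  void collect_exhaustive(const Seq &f, const Seq &rc, const int *qual,
                          int eff, std::vector<Hit> &out) {
    int L = (int)f.size();
    for (size_t r = 0; r < refs.size(); ++r) {
      int rl = (int)refs[r].size();
      for (int s = 0; s + L <= rl; ++s) {
        int mm;
        if (verify_mate(refs[r], f, qual, false, s, eff, max_seed_mm,
                        max_qual_mm, mm)) {
          Hit h; h.ref = (int)r; h.pos = s; h.strand = +1; h.mm = mm;
          out.push_back(h);
        }
        if (verify_mate(refs[r], rc, qual, true, s, eff, max_seed_mm,
                        max_qual_mm, mm)) {
          Hit h; h.ref = (int)r; h.pos = s; h.strand = -1; h.mm = mm;
          out.push_back(h);
        }
      }
    }
  }
};

struct Placement {
  int ref, s1, st1, s2, st2, mm;
  bool better_than(const Placement &o) const {
    if (mm != o.mm) return mm < o.mm;
    if (st1 != o.st1) return st1 > o.st1;   // + before -
    if (s1 != o.s1) return s1 < o.s1;
    return s2 < o.s2;
  }
};

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector refs, CharacterVector seq1, List qual1,
                   Nullable<CharacterVector> seq2_, Nullable<List> qual2_,
                   int seed_len, int max_seed_mm, int max_qual_mm,
                   int min_ins, int max_ins, bool best_single) {
  Mapper mapper(refs, seed_len, max_seed_mm, max_qual_mm);
  bool paired = seq2_.isNotNull();
  CharacterVector seq2;
  List qual2;
  if (paired) { seq2 = seq2_.get(); qual2 = qual2_.get(); }

  R_xlen_t n = seq1.size();
  std::vector<int> out_read, out_ref, out_s1, out_st1, out_s2, out_st2, out_mm;
  std::vector<Hit> h1, h2;
  int nref = (int)refs.size();
  std::vector<Placement> best(nref);
  std::vector<char> have(nref, 0);
  std::vector<int> touched;
  std::vector<Placement> top;

  for (R_xlen_t i = 0; i < n; ++i) {
    Seq f1 = encode_seq(CHAR(STRING_ELT(seq1, i)));
    if (f1.empty()) continue;
    Seq r1 = revcomp_seq(f1);
    IntegerVector q1v = qual1[i];
    mapper.collect(f1, r1, INTEGER(q1v), h1);
    if (h1.empty()) continue;

    touched.clear();
    if (paired) {
      Seq f2 = encode_seq(CHAR(STRING_ELT(seq2, i)));
      if (f2.empty()) continue;
      Seq r2 = revcomp_seq(f2);
      IntegerVector q2v = qual2[i];
      mapper.collect(f2, r2, INTEGER(q2v), h2);
      if (h2.empty()) continue;
      int L1 = (int)f1.size(), L2 = (int)f2.size();
      int minL = std::max(L1, L2);
      for (size_t a = 0; a < h1.size(); ++a) {
        for (size_t b = 0; b < h2.size(); ++b) {
          if (h1[a].ref != h2[b].ref) continue;
          if (h2[b].strand != -h1[a].strand) continue;  // FR orientation
          int ins = (h1[a].strand > 0)
            ? (h2[b].pos + L2) - h1[a].pos
            : (h1[a].pos + L1) - h2[b].pos;
          if (ins < min_ins || ins > max_ins || ins < minL) continue;
          Placement p;
          p.ref = h1[a].ref; p.s1 = h1[a].pos; p.st1 = h1[a].strand;
          p.s2 = h2[b].pos; p.st2 = h2[b].strand; p.mm = h1[a].mm + h2[b].mm;
          if (!have[p.ref]) {
            have[p.ref] = 1; best[p.ref] = p; touched.push_back(p.ref);
          } else if (p.better_than(best[p.ref])) best[p.ref] = p;
        }
      }
    } else {
      for (size_t a = 0; a < h1.size(); ++a) {
        Placement p;
        p.ref = h1[a].ref; p.s1 = h1[a].pos; p.st1 = h1[a].strand;
        p.s2 = NA_INTEGER; p.st2 = NA_INTEGER; p.mm = h1[a].mm;
        if (!have[p.ref]) {
          have[p.ref] = 1; best[p.ref] = p; touched.push_back(p.ref);
        } else if (p.better_than(best[p.ref])) best[p.ref] = p;
      }
    }
    if (touched.empty()) continue;

    // top stratum = minimal mismatch count over this read's references
    int mmin = INT_MAX;
    for (size_t t = 0; t < touched.size(); ++t)
      mmin = std::min(mmin, best[touched[t]].mm);
    top.clear();
    std::sort(touched.begin(), touched.end());
    for (size_t t = 0; t < touched.size(); ++t)
      if (best[touched[t]].mm == mmin) top.push_back(best[touched[t]]);

    if (best_single) {
      int k = (int)top.size();
      int pick = (k == 1) ? 0 : std::min(k - 1, (int)(unif_rand() * k));
      top[0] = top[pick];
      top.resize(1);
    }
    for (size_t t = 0; t < top.size(); ++t) {
      out_read.push_back((int)i + 1);
      out_ref.push_back(top[t].ref + 1);
      out_s1.push_back(top[t].s1);
      out_st1.push_back(top[t].st1);
      out_s2.push_back(top[t].s2);
      out_st2.push_back(top[t].st2);
      out_mm.push_back(top[t].mm);
    }
    for (size_t t = 0; t < touched.size(); ++t) have[touched[t]] = 0;
  }

  return List::create(
    _["read"] = wrap(out_read), _["ref"] = wrap(out_ref),
    _["start1"] = wrap(out_s1), _["strand1"] = wrap(out_st1),
    _["start2"] = wrap(out_s2), _["strand2"] = wrap(out_st2),
    _["mismatches"] = wrap(out_mm));
}

// ---------------------------------------------------------------------------
// E-step: per-placement log-likelihood and per-read posterior.
// Placements must be sorted by `read`.
// ---------------------------------------------------------------------------

static double mate_loglik(const Seq &aln, const double *ep, bool minus,
                          const NumericMatrix &P, int s) {
  int L = (int)aln.size();
  double ll = 0.0;
  for (int i = 0; i < L; ++i) {
    uint8_t b = aln[i];
    double p = ep[minus ? (L - 1 - i) : i];
    double e;
    if (b < 4) {
      double pn = P(s + i, b);
      e = (1.0 - p) * pn + (p / 3.0) * (1.0 - pn);
    } else {
      e = p / 3.0;                       // uninformative call
    }
    ll += std::log(e);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_estep(IntegerVector read, IntegerVector cand,
               IntegerVector s1, IntegerVector st1,
               IntegerVector s2, IntegerVector st2,
               CharacterVector seq1, List ep1,
               Nullable<CharacterVector> seq2_, Nullable<List> ep2_,
               List base_probs, NumericVector log_prior) {
  R_xlen_t n = read.size();
  NumericVector loglik(n), posterior(n);
  bool paired = seq2_.isNotNull();
  CharacterVector seq2;
  List ep2;
  if (paired) { seq2 = seq2_.get(); ep2 = ep2_.get(); }

  // cache encodings of reads actually referenced
  std::unordered_map<int, std::pair<Seq, Seq> > cache1, cache2;
  int n_fallback = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    int ri = read[i];
    std::pair<Seq, Seq> &c1 = cache1[ri];
    if (c1.first.empty()) {
      c1.first = encode_seq(CHAR(STRING_ELT(seq1, ri - 1)));
      c1.second = revcomp_seq(c1.first);
    }
    NumericMatrix P = base_probs[cand[i] - 1];
    NumericVector e1 = ep1[ri - 1];
    double ll = mate_loglik(st1[i] > 0 ? c1.first : c1.second,
                            REAL(e1), st1[i] < 0, P, s1[i]);
    if (paired && s2[i] != NA_INTEGER) {
      std::pair<Seq, Seq> &c2 = cache2[ri];
      if (c2.first.empty()) {
        c2.first = encode_seq(CHAR(STRING_ELT(seq2, ri - 1)));
        c2.second = revcomp_seq(c2.first);
      }
      NumericVector e2 = ep2[ri - 1];
      ll += mate_loglik(st2[i] > 0 ? c2.first : c2.second,
                        REAL(e2), st2[i] < 0, P, s2[i]);
    }
    loglik[i] = ll;
  }

  // grouped log-sum-exp over each read's placements
  NumericVector read_lognorm;
  std::vector<double> lognorms;
  std::vector<int> read_ids;
  R_xlen_t i = 0;
  while (i < n) {
    R_xlen_t j = i;
    double mx = R_NegInf;
    while (j < n && read[j] == read[i]) {
      double v = loglik[j] + log_prior[cand[j] - 1];
      if (v > mx) mx = v;
      ++j;
    }
    if (!R_FINITE(mx)) {             // total underflow: uniform fallback
      double u = 1.0 / (double)(j - i);
      for (R_xlen_t k = i; k < j; ++k) posterior[k] = u;
      lognorms.push_back(R_NegInf);
      ++n_fallback;
    } else {
      double sum = 0.0;
      for (R_xlen_t k = i; k < j; ++k)
        sum += std::exp(loglik[k] + log_prior[cand[k] - 1] - mx);
      double ln = mx + std::log(sum);
      for (R_xlen_t k = i; k < j; ++k)
        posterior[k] = std::exp(loglik[k] + log_prior[cand[k] - 1] - ln);
      lognorms.push_back(ln);
    }
    read_ids.push_back(read[i]);
    i = j;
  }

  return List::create(_["loglik"] = loglik, _["posterior"] = posterior,
                      _["read_id"] = wrap(read_ids),
                      _["read_lognorm"] = wrap(lognorms),
                      _["n_fallback"] = n_fallback);
}

// ---------------------------------------------------------------------------
// M-step consensus accumulator: weighted, quality-adjusted base evidence.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mstep_acc(IntegerVector read, IntegerVector cand,
                   IntegerVector s1, IntegerVector st1,
                   IntegerVector s2, IntegerVector st2,
                   NumericVector weight,
                   CharacterVector seq1, List ep1,
                   Nullable<CharacterVector> seq2_, Nullable<List> ep2_,
                   IntegerVector cand_len) {
  int ncand = cand_len.size();
  List acc(ncand), cov(ncand);
  std::vector<double *> accp(ncand);
  std::vector<int *> covp(ncand);
  std::vector<int> lens(ncand);
  for (int c = 0; c < ncand; ++c) {
    NumericMatrix m(cand_len[c], 4);
    IntegerVector v(cand_len[c]);
    acc[c] = m; cov[c] = v;
    accp[c] = REAL((SEXP)m); covp[c] = INTEGER((SEXP)v);
    lens[c] = cand_len[c];
  }
  bool paired = seq2_.isNotNull();
  CharacterVector seq2;
  List ep2;
  if (paired) { seq2 = seq2_.get(); ep2 = ep2_.get(); }

  R_xlen_t n = read.size();
  std::unordered_map<int, std::pair<Seq, Seq> > cache1, cache2;
  for (R_xlen_t i = 0; i < n; ++i) {
    int ri = read[i], ci = cand[i] - 1;
    double w = weight[i];
    double *A = accp[ci];
    int *C = covp[ci];
    int Lr = lens[ci];

    std::pair<Seq, Seq> &c1 = cache1[ri];
    if (c1.first.empty()) {
      c1.first = encode_seq(CHAR(STRING_ELT(seq1, ri - 1)));
      c1.second = revcomp_seq(c1.first);
    }
    {
      const Seq &aln = st1[i] > 0 ? c1.first : c1.second;
      NumericVector e1 = ep1[ri - 1];
      const double *ep = REAL(e1);
      int L = (int)aln.size();
      bool minus = st1[i] < 0;
      for (int k = 0; k < L; ++k) {
        int pos = s1[i] + k;
        uint8_t b = aln[k];
        double p = ep[minus ? (L - 1 - k) : k];
        double miss = w * p / 3.0;
        for (int nb = 0; nb < 4; ++nb) A[nb * Lr + pos] += miss;
        if (b < 4) A[b * Lr + pos] += w * (1.0 - p) - miss;
        C[pos] += 1;
      }
    }
    if (paired && s2[i] != NA_INTEGER) {
      std::pair<Seq, Seq> &c2 = cache2[ri];
      if (c2.first.empty()) {
        c2.first = encode_seq(CHAR(STRING_ELT(seq2, ri - 1)));
        c2.second = revcomp_seq(c2.first);
      }
      const Seq &aln = st2[i] > 0 ? c2.first : c2.second;
      NumericVector e2 = ep2[ri - 1];
      const double *ep = REAL(e2);
      int L = (int)aln.size();
      bool minus = st2[i] < 0;
      for (int k = 0; k < L; ++k) {
        int pos = s2[i] + k;
        uint8_t b = aln[k];
        double p = ep[minus ? (L - 1 - k) : k];
        double miss = w * p / 3.0;
        for (int nb = 0; nb < 4; ++nb) A[nb * Lr + pos] += miss;
        if (b < 4) A[b * Lr + pos] += w * (1.0 - p) - miss;
        C[pos] += 1;
      }
    }
  }
  return List::create(_["acc"] = acc, _["coverage"] = cov);
}

// shared-kmer prescreen used before expensive global alignments
// [[Rcpp::export]]
double cpp_shared_kmer_frac(std::string a, std::string b, int k) {
  if ((int)a.size() < k || (int)b.size() < k) return 0.0;
  Seq ea = encode_seq(a.c_str()), eb = encode_seq(b.c_str());
  std::unordered_set<uint32_t> ka;
  uint32_t code;
  for (int i = 0; i + k <= (int)ea.size(); ++i)
    if (piece_code(ea, i, k, code)) ka.insert(code);
  int tot = 0, shared = 0;
  for (int i = 0; i + k <= (int)eb.size(); ++i)
    if (piece_code(eb, i, k, code)) {
      ++tot;
      if (ka.count(code)) ++shared;
    }
  return tot == 0 ? 0.0 : (double)shared / (double)tot;
}
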