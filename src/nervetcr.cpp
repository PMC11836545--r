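#include <Rcpp.h>
using namespace Rcpp;

// ---- Hamming distance kernels -------------------------------------------
// Distances are defined only for equal-length strings; unequal-length pairs
// are "undefined" (NA in the full pair table, absent from edge lists).

static inline int hamming_eq(const char* a, const char* b, int n) {
  int d = 0;
  for (int k = 0; k < n; ++k) d += (a[k] != b[k]);
  return d;
}

// Full unordered pair table over one clone set (i < j, 1-based indices).
// [[Rcpp::export]]
DataFrame cpp_hamming_pairs(CharacterVector x, bool include_undefined) {
  int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  std::vector<int> ii, jj, dd;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s[i].size() == s[j].size()) {
        ii.push_back(i + 1); jj.push_back(j + 1);
        dd.push_back(hamming_eq(s[i].c_str(), s[j].c_str(), s[i].size()));
      } else if (include_undefined) {
        ii.push_back(i + 1); jj.push_back(j + 1);
        dd.push_back(NA_INTEGER);
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["distance"] = dd);
}

// Defined distances only (for density estimation; no pair bookkeeping).
// [[Rcpp::export]]
IntegerVector cpp_hamming_dists(CharacterVector x) {
  int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  std::vector<int> dd;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (s[i].size() == s[j].size())
        dd.push_back(hamming_eq(s[i].c_str(), s[j].c_str(), s[i].size()));
  return wrap(dd);
}

// Edges (defined distance <= max_d) within one set.
// [[Rcpp::export]]
DataFrame cpp_hamming_edges(CharacterVector x, int max_d) {
  int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  std::vector<int> ii, jj, dd;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s[i].size() != s[j].size()) continue;
      int d = hamming_eq(s[i].c_str(), s[j].c_str(), s[i].size());
      if (d <= max_d) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["distance"] = dd);
}

// Edges between two sets (1-based into each set).
// [[Rcpp::export]]
DataFrame cpp_cross_edges(CharacterVector a, CharacterVector b, int max_d) {
  int na = a.size(), nb = b.size();
  std::vector<std::string> sa(na), sb(nb);
  for (int i = 0; i < na; ++i) sa[i] = as<std::string>(a[i]);
  for (int j = 0; j < nb; ++j) sb[j] = as<std::string>(b[j]);
  std::vector<int> ii, jj, dd;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      if (sa[i].size() != sb[j].size()) continue;
      int d = hamming_eq(sa[i].c_str(), sb[j].c_str(), sa[i].size());
      if (d <= max_d) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["distance"] = dd);
}

// ---- Ungapped reference scan for V/J assignment --------------------------
// For each read, every reference is slid over every offset (reference start
// relative to read start, possibly negative); the aligned span is the
// intersection, scored +1 per match / -1 per mismatch. Only placements with
// span >= min_overlap and identity >= min_identity qualify. Ties resolve to
// the earlier reference (callers pass references sorted by gene name) and
// then the smaller offset, so results are a total order.
// [[Rcpp::export]]
DataFrame cpp_scan_reference(CharacterVector reads, CharacterVector refs,
                             double min_identity, int min_overlap) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> rs(nf);
  for (int f = 0; f < nf; ++f) rs[f] = as<std::string>(refs[f]);
  IntegerVector best_ref(nr, NA_INTEGER), best_off(nr, NA_INTEGER);
  NumericVector best_ident(nr, NA_REAL);
  IntegerVector best_overlap(nr, NA_INTEGER);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int nread = rd.size();
    int bscore = INT_MIN; double bident = -1.0;
    for (int f = 0; f < nf; ++f) {
      int nref = rs[f].size();
      for (int o = -(nref - min_overlap); o <= nread - min_overlap; ++o) {
        int lo = std::max(0, o), hi = std::min(nread, o + nref);
        int span = hi - lo;
        if (span < min_overlap) continue;
        int m = 0;
        const char* pr = rd.c_str();
        const char* pf = rs[f].c_str();
        for (int k = lo; k < hi; ++k) m += (pr[k] == pf[k - o]);
        double ident = (double)m / span;
        if (ident < min_identity) continue;
        int score = 2 * m - span;
        if (score > bscore || (score == bscore && ident > bident + 1e-12)) {
          bscore = score; bident = ident;
          best_ref[r] = f + 1; best_off[r] = o;
          best_ident[r] = ident; best_overlap[r] = span;
        }
      }
    }
  }
  return DataFrame::create(_["ref"] = best_ref, _["offset"] = best_off,
                           _["identity"] = best_ident, _["overlap"] = best_overlap);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t k = 0; k < r.size(); ++k) r[k] = comp_base(r[k]);
    out[i] = r;
  }
  return out;
}

// ---- Paired-end merging ---------------------------------------------------
// Candidate overlaps are suffix(read1) vs prefix(revcomp(read2)) of length
// min_overlap..min(n1, n2). The overlap maximising matches - mismatches,
// subject to mismatch_rate <= max_mismatch_rate, wins; ties go to the longer
// overlap. Consensus: agreeing bases keep the base at max quality;
// disagreements take the higher-quality base (read1 on a quality tie).
// Qualities are Phred+33 characters throughout.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_rate) {
  int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  IntegerVector ov_len(n, NA_INTEGER), ov_mm(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]);
    std::string q1 = as<std::string>(qual1[i]);
    std::string s2 = as<std::string>(seq2[i]);
    std::string q2 = as<std::string>(qual2[i]);
    std::string rc2(s2.rbegin(), s2.rend());
    for (size_t k = 0; k < rc2.size(); ++k) rc2[k] = comp_base(rc2[k]);
    std::string rq2(q2.rbegin(), q2.rend());
    int n1 = s1.size(), n2 = rc2.size();
    int best_score = INT_MIN, best_L = -1, best_mm = -1;
    int Lmax = std::min(n1, n2);
    for (int L = min_overlap; L <= Lmax; ++L) {
      int m = 0;
      for (int k = 0; k < L; ++k) m += (s1[n1 - L + k] == rc2[k]);
      int mm = L - m;
      if ((double)mm / L > max_mismatch_rate) continue;
      int score = m - mm;
      if (score > best_score || (score == best_score && L > best_L)) {
        best_score = score; best_L = L; best_mm = mm;
      }
    }
    if (best_L < 0) {
      merged[i] = false; mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      continue;
    }
    int L = best_L;
    std::string cs = s1.substr(0, n1 - L);
    std::string cq = q1.substr(0, n1 - L);
    for (int k = 0; k < L; ++k) {
      char b1 = s1[n1 - L + k], b2 = rc2[k];
      char c1 = q1[n1 - L + k], c2 = rq2[k];
      if (b1 == b2) { cs += b1; cq += std::max(c1, c2); }
      else if (c2 > c1) { cs += b2; cq += c2; }
      else { cs += b1; cq += c1; }
    }
    cs += rc2.substr(L); cq += rq2.substr(L);
    merged[i] = true; mseq[i] = cs; mqual[i] = cq;
    ov_len[i] = L; ov_mm[i] = best_mm;
  }
  return List::create(_["merged"] = merged, _["sequence"] = mseq,
                      _["quality"] = mqual, _["overlap_len"] = ov_len,
                      _["overlap_mismatches"] = ov_mm);
}

// Minimum Phred score over a substring span (1-based, inclusive) per read.
// [[Rcpp::export]]
IntegerVector cpp_min_phred(CharacterVector qual, IntegerVector start, IntegerVector end) {
  int n = qual.size();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (qual[i] == NA_STRING || start[i] == NA_INTEGER || end[i] == NA_INTEGER) continue;
    std::string q = as<std::string>(qual[i]);
    int lo = start[i] - 1, hi = end[i];
    if (lo < 0 || hi > (int)q.size() || lo >= hi) { out[i] = NA_INTEGER; continue; }
    int mn = 1000;
    for (int k = lo; k < hi; ++k) mn = std::min(mn, (int)q[k] - 33);
    out[i] = mn;
  }
  return out;
}
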