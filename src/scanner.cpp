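// Structural Helitron scanner core.
//
// A candidate 3' terminus is a CTRR-family motif (stringency set by the fuzzy
// level) preceded, spacer_min..spacer_max bases upstream, by a GC-rich
// palindromic hairpin: a left arm whose exact reverse complement recurs as the
// right arm after a loop of <= loop_max bases.  Coordinates here are 0-based
// half-open on the scanned strand; the R-facing wrappers receive 1-based
// inclusive forward-strand coordinates computed at the end of the scan.

#include <Rcpp.h>
#include <cctype>
#include <cmath>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 0;
  }
}
static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}
static inline bool is_s(char c) { return c == 'G' || c == 'C'; }

static void to_upper(std::string& s) {
  for (size_t i = 0; i < s.size(); ++i)
    s[i] = (char) std::toupper((unsigned char) s[i]);
}

// Strict reverse complement: any character outside {A,C,G,T,N} is an error.
// [[Rcpp::export]]
std::string revcomp_cpp(std::string seq) {
  to_upper(seq);
  const size_t n = seq.size();
  std::string out(n, ' ');
  for (size_t i = 0; i < n; ++i) {
    char c = comp_base(seq[i]);
    if (c == 0)
      stop("invalid nucleotide '%c' at position %d", seq[i], (int) (i + 1));
    out[n - 1 - i] = c;
  }
  return out;
}

// Lenient reverse complement used internally for the minus-strand pass:
// unknown IUPAC codes become N so they can never take part in a match.
static std::string revcomp_lenient(const std::string& s) {
  const size_t n = s.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = comp_base(s[i]);
    out[n - 1 - i] = (c == 0) ? 'N' : c;
  }
  return out;
}

struct ScanPar {
  int fuzzy, arm_min, arm_max, loop_max, spacer_min, spacer_max, upstream;
  double gc_min;
};

static inline int gc_needed(double gc_min, int L) {
  return (int) std::ceil(gc_min * L - 1e-9);
}

// Arm admissibility on the segment [start, start+L): all ACGT, first and last
// base strong (G/C), and at least ceil(gc_min * L) strong bases.
static bool arm_ok(const std::string& s, int start, int L, double gc_min) {
  if (!is_s(s[start]) || !is_s(s[start + L - 1])) return false;
  int gc = 0;
  for (int k = start; k < start + L; ++k) {
    char c = s[k];
    if (!is_acgt(c)) return false;
    if (is_s(c)) ++gc;
  }
  return gc >= gc_needed(gc_min, L);
}

// Greedy hairpin resolution anchored on the right-arm end (exclusive):
// longest admissible arm first, then shortest loop.  Returns true with the
// left-arm start, arm length and loop length of the first hit.
static bool hairpin_at_right_end(const std::string& s, int rend, const ScanPar& P,
                                 int& o_lstart, int& o_L, int& o_loop) {
  for (int L = P.arm_max; L >= P.arm_min; --L) {
    int rstart = rend - L;
    if (rstart < 0) continue;
    if (!arm_ok(s, rstart, L, P.gc_min)) continue;
    for (int loop = 0; loop <= P.loop_max; ++loop) {
      int lend = rstart - loop, lstart = lend - L;
      if (lstart < 0) break;
      bool ok = true;
      for (int k = lend; k < rstart; ++k)        // loop region may not hold N
        if (!is_acgt(s[k])) { ok = false; break; }
      if (!ok) continue;
      for (int k = 0; k < L && ok; ++k) {
        char c = s[lstart + k];
        if (!is_acgt(c) || c != comp_base(s[rend - 1 - k])) ok = false;
      }
      if (ok) { o_lstart = lstart; o_L = L; o_loop = loop; return true; }
    }
  }
  return false;
}

// 3' terminal motif whose 4-nt CTRR core starts at i.  At fuzzy level 0 the
// base following the core must additionally be the target-site T.
static inline bool motif_at(const std::string& s, int n, int i, int fuzzy) {
  if (i + 4 > n) return false;
  if (s[i] != 'C' || s[i + 1] != 'T') return false;
  const char a = s[i + 2], b = s[i + 3];
  switch (fuzzy) {
    case 0:
      if (!(a == 'A' && b == 'G')) return false;
      return i + 4 < n && s[i + 4] == 'T';
    case 1:  return a == 'A' && b == 'G';
    case 2:  return (a == 'A' || a == 'G') && (b == 'A' || b == 'G');
    default: return is_acgt(a) && is_acgt(b);
  }
}

struct StrandHits {
  std::vector<int> e3, lstart, lend, rstart, rend, loop;
  std::vector<std::string> motif, arm;
  std::vector<std::vector<int> > five;
  std::vector<int> ts;  // 1/0, NA_INTEGER when no 5' end
};

// One-strand scan.  Coordinates are 0-based on the scanned strand; e3 is the
// position of the last base of the CTRR core.
static void scan_strand(const std::string& s, const ScanPar& P, bool want_five,
                        StrandHits& H) {
  const int n = (int) s.size();
  for (int i = 0; i + 4 <= n; ++i) {
    if (!motif_at(s, n, i, P.fuzzy)) continue;
    int hit_lstart = -1, hit_L = 0, hit_loop = 0, hit_rend = -1;
    for (int sp = P.spacer_min; sp <= P.spacer_max; ++sp) {
      int rend = i - sp;
      if (rend < 2 * P.arm_min) break;
      bool ok = true;
      for (int k = rend; k < i; ++k)           // spacer region may not hold N
        if (!is_acgt(s[k])) { ok = false; break; }
      if (!ok) continue;
      int lstart, L, loop;
      if (hairpin_at_right_end(s, rend, P, lstart, L, loop)) {
        hit_lstart = lstart; hit_L = L; hit_loop = loop; hit_rend = rend;
        break;                                  // nearest hairpin wins
      }
    }
    if (hit_lstart < 0) continue;
    const int e3 = i + 3;
    H.e3.push_back(e3);
    H.lstart.push_back(hit_lstart);
    H.lend.push_back(hit_lstart + hit_L);
    H.rstart.push_back(hit_rend - hit_L);
    H.rend.push_back(hit_rend);
    H.loop.push_back(hit_loop);
    H.motif.push_back(s.substr(i, (P.fuzzy == 0) ? 5 : 4));
    H.arm.push_back(s.substr(hit_lstart, hit_L));
    std::vector<int> five;
    if (want_five) {
      int lo = e3 - P.upstream;
      if (lo < 0) lo = 0;
      for (int p = hit_lstart - 1; p >= lo; --p)  // nearest first
        if (s[p] == 'T' && s[p + 1] == 'C') five.push_back(p);
    }
    int ts = NA_INTEGER;
    if (!five.empty()) {
      bool after = (e3 + 1 < n && s[e3 + 1] == 'T');
      int p0 = five.front();
      bool before = (p0 > 0 && s[p0 - 1] == 'A');
      ts = (after && before) ? 1 : 0;
    }
    H.five.push_back(five);
    H.ts.push_back(ts);
  }
}

// Scan one sequence on both strands (or forward only).  All returned
// coordinates are 1-based inclusive on the forward strand of the input.
// [[Rcpp::export]]
List scan_sequence_cpp(std::string seq, int fuzzy, int arm_min, int arm_max,
                       int loop_max, int spacer_min, int spacer_max,
                       int upstream, double gc_min, bool want_five,
                       bool both_strands) {
  to_upper(seq);
  for (size_t i = 0; i < seq.size(); ++i)
    if (comp_base(seq[i]) == 0) seq[i] = 'N';
  ScanPar P = {fuzzy, arm_min, arm_max, loop_max, spacer_min, spacer_max,
               upstream, gc_min};
  const int n = (int) seq.size();

  StrandHits fw, rv;
  scan_strand(seq, P, want_five, fw);
  if (both_strands) {
    std::string rc = revcomp_lenient(seq);
    scan_strand(rc, P, want_five, rv);
  }

  const int m = (int) (fw.e3.size() + rv.e3.size());
  CharacterVector strand(m), motif(m), arm(m);
  IntegerVector end3(m), hls(m), hle(m), hrs(m), hre(m), loop(m), n5(m);
  LogicalVector ts(m);
  List five(m);

  int j = 0;
  for (size_t k = 0; k < fw.e3.size(); ++k, ++j) {
    strand[j] = "+";
    end3[j] = fw.e3[k] + 1;
    hls[j] = fw.lstart[k] + 1; hle[j] = fw.lend[k];
    hrs[j] = fw.rstart[k] + 1; hre[j] = fw.rend[k];
    loop[j] = fw.loop[k];
    motif[j] = fw.motif[k]; arm[j] = fw.arm[k];
    IntegerVector fv((int) fw.five[k].size());
    for (int q = 0; q < fv.size(); ++q) fv[q] = fw.five[k][q] + 1;
    five[j] = fv; n5[j] = fv.size();
    ts[j] = (fw.ts[k] == NA_INTEGER) ? NA_LOGICAL : (fw.ts[k] == 1);
  }
  for (size_t k = 0; k < rv.e3.size(); ++k, ++j) {
    strand[j] = "-";
    end3[j] = n - rv.e3[k];
    // scanned [a,b) maps to forward 1-based (n-b+1, n-a)
    hls[j] = n - rv.lend[k] + 1; hle[j] = n - rv.lstart[k];
    hrs[j] = n - rv.rend[k] + 1; hre[j] = n - rv.rstart[k];
    loop[j] = rv.loop[k];
    motif[j] = rv.motif[k]; arm[j] = rv.arm[k];
    IntegerVector fv((int) rv.five[k].size());
    for (int q = 0; q < fv.size(); ++q) fv[q] = n - rv.five[k][q];
    five[j] = fv; n5[j] = fv.size();
    ts[j] = (rv.ts[k] == NA_INTEGER) ? NA_LOGICAL : (rv.ts[k] == 1);
  }

  return List::create(_["strand"] = strand, _["end3_pos"] = end3,
                      _["end3_motif"] = motif, _["hp_left_start"] = hls,
                      _["hp_left_end"] = hle, _["hp_right_start"] = hrs,
                      _["hp_right_end"] = hre, _["loop_len"] = loop,
                      _["arm_seq"] = arm, _["n_five_prime"] = n5,
                      _["five_prime"] = five, _["target_site_ok"] = ts);
}

// Left-anchored hairpin search: for each admissible left-arm start report the
// longest arm, then the shortest loop.  Non-maximal matches -- those whose
// arms extend outward by one base into another admissible arm of the same
// stem (same loop) -- are suppressed, so a palindromic stem is reported once.
// 1-based inclusive coordinates.
// [[Rcpp::export]]
List find_hairpins_cpp(std::string seq, int arm_min, int arm_max, int loop_max,
                       double gc_min) {
  to_upper(seq);
  const int n = (int) seq.size();
  std::vector<int> ls, le, rs, re, lp;
  std::vector<std::string> arm;
  for (int i = 0; i < n; ++i) {
    for (int L = arm_max; L >= arm_min; --L) {
      if (i + L > n) continue;
      if (!arm_ok(seq, i, L, gc_min)) continue;
      bool found = false;
      for (int loop = 0; loop <= loop_max && !found; ++loop) {
        int rstart = i + L + loop;
        if (rstart + L > n) break;
        bool ok = true;
        for (int k = i + L; k < rstart; ++k)
          if (!is_acgt(seq[k])) { ok = false; break; }
        for (int k = 0; k < L && ok; ++k) {
          char c = seq[rstart + k];
          if (!is_acgt(c) || c != comp_base(seq[i + L - 1 - k])) ok = false;
        }
        if (ok) {
          bool ext = false;                    // outward-extended admissible arm?
          if (i >= 1 && rstart + L < n && L + 1 <= arm_max) {
            char lo = seq[i - 1], hi = seq[rstart + L];
            ext = is_acgt(lo) && lo == comp_base(hi) &&
                  arm_ok(seq, i - 1, L + 1, gc_min);
          }
          if (!ext) {
            ls.push_back(i + 1); le.push_back(i + L);
            rs.push_back(rstart + 1); re.push_back(rstart + L);
            lp.push_back(loop); arm.push_back(seq.substr(i, L));
          }
          found = true;
        }
      }
      if (found) break;
    }
  }
  return List::create(_["left_start"] = ls, _["left_end"] = le,
                      _["loop_len"] = lp, _["right_start"] = rs,
                      _["right_end"] = re, _["arm_seq"] = arm);
}

// i.i.d. nucleotide sequence from the categorical distribution over A,C,G,T
// (probs in that order), driven by R's RNG so set.seed() governs it.
// [[Rcpp::export]]
std::string random_dna_cpp(double n, NumericVector probs) {
  if (probs.size() != 4) stop("probs must have length 4 (A, C, G, T)");
  double c1 = probs[0], c2 = c1 + probs[1], c3 = c2 + probs[2];
  R_xlen_t len = (R_xlen_t) n;
  std::string out((size_t) len, 'A');
  for (R_xlen_t i = 0; i < len; ++i) {
    double u = unif_rand();
    out[(size_t) i] = (u < c1) ? 'A' : (u < c2) ? 'C' : (u < c3) ? 'G' : 'T';
  }
  return out;
}

// Base composition: counts of A, C, G, T, N and everything else.
// [[Rcpp::export]]
NumericVector base_counts_cpp(std::string seq) {
  to_upper(seq);
  double a = 0, c = 0, g = 0, t = 0, nn = 0, other = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': ++a; break;
      case 'C': ++c; break;
      case 'G': ++g; break;
      case 'T': ++t; break;
      case 'N': ++nn; break;
      default: ++other;
    }
  }
  NumericVector out = NumericVector::create(
    _["A"] = a, _["C"] = c, _["G"] = g, _["T"] = t, _["N"] = nn,
    _["other"] = other, _["length"] = (double) seq.size());
  return out;
}
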