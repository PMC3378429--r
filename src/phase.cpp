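// Long-range phasing kernels: surrogate-side classification from the
// pedigree, opposing-homozygote screening, within-core phasing votes,
// haplotype-library completion and genotype-consistent pair resolution.
//
// Conventions: individuals are pedigree rows (topological order, 1-based
// from R); genotype codes 0/1/2, 3 = missing; allele codes 0/1, 9 = missing.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int AMISS = 9;
static const int GMISS = 3;

class BitSets {
public:
  BitSets(int n) : n_(n), w_((n + 63) / 64), bits_((size_t)n * w_, 0) {}
  void set(int i, int j) { bits_[(size_t)i * w_ + j / 64] |= (uint64_t)1 << (j % 64); }
  bool get(int i, int j) const {
    return (bits_[(size_t)i * w_ + j / 64] >> (j % 64)) & 1;
  }
  void orInto(int dst, int src) {
    uint64_t *d = &bits_[(size_t)dst * w_];
    const uint64_t *s = &bits_[(size_t)src * w_];
    for (int k = 0; k < w_; ++k) d[k] |= s[k];
  }
  bool intersects(int i, int j) const {
    const uint64_t *a = &bits_[(size_t)i * w_], *b = &bits_[(size_t)j * w_];
    for (int k = 0; k < w_; ++k) if (a[k] & b[k]) return true;
    return false;
  }
private:
  int n_, w_;
  std::vector<uint64_t> bits_;
};

// Side classification of potential surrogates by exhaustive ancestor walk.
// anc(i) = {i} U ancestors(i).  For target i with known sire s and/or dam d:
//   paternal side:  anc(j) meets anc(s) but not anc(d), and j is not i or a
//                   descendant of i (those share a gamete of i itself);
//   maternal side:  symmetric.
// Returns an n x n integer matrix: 0 unassigned, 1 paternal, 2 maternal
// (row = target individual, column = candidate), computed only for rows and
// columns flagged in `hd`.
// [[Rcpp::export(name = ".surrogate_sides_cpp")]]
IntegerMatrix surrogate_sides_cpp(IntegerVector sire, IntegerVector dam,
                                  LogicalVector hd) {
  const int n = sire.size();
  BitSets anc(n);
  for (int i = 0; i < n; ++i) {
    anc.set(i, i);
    if (sire[i] > 0) anc.orInto(i, sire[i] - 1);
    if (dam[i] > 0) anc.orInto(i, dam[i] - 1);
  }
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    if (!hd[i]) continue;
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s < 0 && d < 0) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i || !hd[j]) continue;
      if (anc.get(j, i)) continue;              // j descends from i
      bool pat = s >= 0 && anc.intersects(j, s);
      bool mat = d >= 0 && anc.intersects(j, d);
      if (pat && !mat) out(i, j) = 1;
      else if (mat && !pat) out(i, j) = 2;
    }
  }
  return out;
}

static inline int opposing_hom(const IntegerMatrix &g, int i, int j,
                               int lo, int hi, int maxmm) {
  int mm = 0;
  for (int l = lo; l <= hi; ++l) {
    int a = g(i, l), b = g(j, l);
    if ((a == 0 && b == 2) || (a == 2 && b == 0)) {
      if (++mm > maxmm) return mm;
    }
  }
  return mm;
}

// Surrogate sets within a SNP region: candidates are side-classified HD
// animals with at most max_mismatch opposing homozygotes versus the target
// in the region; genotyped parents are always surrogates of their side.
// [[Rcpp::export(name = ".find_surrogates_cpp")]]
List find_surrogates_cpp(IntegerMatrix geno, IntegerMatrix sides,
                         IntegerVector sire, IntegerVector dam,
                         IntegerVector targets, int lo, int hi,
                         int max_mismatch) {
  const int n = geno.nrow();
  int m = targets.size();
  List pat(m), mat(m);
  // pre-collect candidate columns per row to avoid scanning all n twice
  for (int t = 0; t < m; ++t) {
    int i = targets[t] - 1;
    std::vector<int> ps, ms;
    for (int j = 0; j < n; ++j) {
      int side = sides(i, j);
      if (side == 0) continue;
      if (opposing_hom(geno, i, j, lo - 1, hi - 1, max_mismatch) > max_mismatch)
        continue;
      if (side == 1) ps.push_back(j + 1); else ms.push_back(j + 1);
    }
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= 0 && std::find(ps.begin(), ps.end(), s + 1) == ps.end()) {
      // genotyped parent: forced surrogate of its side
      bool has_geno = false;
      for (int l = lo - 1; l <= hi - 1; ++l) if (geno(s, l) != GMISS) { has_geno = true; break; }
      if (has_geno) ps.insert(ps.begin(), s + 1);
    }
    if (d >= 0 && std::find(ms.begin(), ms.end(), d + 1) == ms.end()) {
      bool has_geno = false;
      for (int l = lo - 1; l <= hi - 1; ++l) if (geno(d, l) != GMISS) { has_geno = true; break; }
      if (has_geno) ms.insert(ms.begin(), d + 1);
    }
    pat[t] = IntegerVector(ps.begin(), ps.end());
    mat[t] = IntegerVector(ms.begin(), ms.end());
  }
  return List::create(_["pat"] = pat, _["mat"] = mat);
}

// Phase a core by surrogate consensus.  Homozygous loci phase themselves.
// At a heterozygous locus the paternal allele is set when every informative
// paternal surrogate (homozygous there) agrees and at least min_agree are
// informative; the maternal allele is the complement.  Conflicting evidence
// (within a side, or between the two sides) leaves the locus unphased.
// [[Rcpp::export(name = ".phase_core_cpp")]]
List phase_core_cpp(IntegerMatrix geno, List pat_surr, List mat_surr,
                    IntegerVector targets, int lo, int hi, int min_agree) {
  const int n = geno.nrow();
  const int len = hi - lo + 1;
  const int m = targets.size();
  IntegerMatrix pat(n, len), mat(n, len);
  std::fill(pat.begin(), pat.end(), AMISS);
  std::fill(mat.begin(), mat.end(), AMISS);
  for (int t = 0; t < m; ++t) {
    int i = targets[t] - 1;
    IntegerVector ps = pat_surr[t], ms = mat_surr[t];
    for (int l = 0; l < len; ++l) {
      int g = geno(i, lo - 1 + l);
      if (g == 0) { pat(i, l) = 0; mat(i, l) = 0; }
      else if (g == 2) { pat(i, l) = 1; mat(i, l) = 1; }
      else if (g == 1) {
        int vote[2] = {-1, -1};   // consensus allele per side, -2 = conflict
        for (int side = 0; side < 2; ++side) {
          IntegerVector &sv = side == 0 ? ps : ms;
          int cnt = 0, allele = -1;
          bool conflict = false;
          for (int k = 0; k < sv.size(); ++k) {
            int gj = geno(sv[k] - 1, lo - 1 + l);
            int a = gj == 0 ? 0 : (gj == 2 ? 1 : -1);
            if (a < 0) continue;
            if (allele < 0) allele = a;
            else if (allele != a) { conflict = true; break; }
            ++cnt;
          }
          if (conflict) vote[side] = -2;
          else if (cnt >= min_agree && allele >= 0) vote[side] = allele;
        }
        if (vote[0] == -2 || vote[1] == -2) continue;
        if (vote[0] >= 0 && vote[1] >= 0 && vote[0] + vote[1] != 1) continue;
        if (vote[0] >= 0) { pat(i, l) = vote[0]; mat(i, l) = 1 - vote[0]; }
        else if (vote[1] >= 0) { mat(i, l) = vote[1]; pat(i, l) = 1 - vote[1]; }
      }
    }
  }
  return List::create(_["pat"] = pat, _["mat"] = mat);
}

// Complete partially resolved gametes against a library: a gamete with at
// least min_resolved resolved alleles is filled from the single library
// haplotype matching all its resolved positions; ambiguous or unmatched
// gametes are left unchanged.  Returns the completed matrix and the match
// count per row.
// [[Rcpp::export(name = ".complete_gametes_cpp")]]
List complete_gametes_cpp(IntegerMatrix gam, IntegerMatrix lib,
                          int min_resolved = 1) {
  const int m = gam.nrow(), len = gam.ncol(), H = lib.nrow();
  IntegerMatrix out(clone(gam));
  IntegerVector nmatch(m);
  for (int r = 0; r < m; ++r) {
    int resolved = 0, missing = 0;
    for (int l = 0; l < len; ++l) {
      if (gam(r, l) == AMISS) ++missing; else ++resolved;
    }
    if (resolved < min_resolved || missing == 0) { nmatch[r] = NA_INTEGER; continue; }
    int hit = -1, cnt = 0;
    for (int h = 0; h < H; ++h) {
      bool ok = true;
      for (int l = 0; l < len; ++l) {
        int a = gam(r, l);
        if (a != AMISS && lib(h, l) != a) { ok = false; break; }
      }
      if (ok) { ++cnt; hit = h; if (cnt > 1) break; }
    }
    nmatch[r] = cnt;
    if (cnt == 1) {
      for (int l = 0; l < len; ++l)
        if (out(r, l) == AMISS) out(r, l) = lib(hit, l);
    }
  }
  return List::create(_["gam"] = out, _["n_match"] = nmatch);
}

// Resolve an unordered haplotype pair per individual from the library:
// candidate pairs (h1, h2) must satisfy h1 + h2 = genotype at every observed
// locus.  Pairs are oriented by the first heterozygous locus (the haplotype
// carrying allele 0 there is slot A) and vote per locus; alleles with
// unanimous agreement across all candidate pairs are returned, others stay
// missing.  A unique candidate pair resolves the whole core.  Homozygous
// loci are implied by the genotype.  Individuals with more than `max_pairs`
// candidate pairs are left unresolved (evidence too diffuse).
// [[Rcpp::export(name = ".resolve_pairs_cpp")]]
List resolve_pairs_cpp(IntegerMatrix genoseg, IntegerMatrix lib,
                       int max_pairs = 64) {
  const int m = genoseg.nrow(), len = genoseg.ncol(), H = lib.nrow();
  IntegerMatrix A(m, len), B(m, len);
  std::fill(A.begin(), A.end(), AMISS);
  std::fill(B.begin(), B.end(), AMISS);
  IntegerVector npair(m);
  std::vector<std::pair<int,int>> pairs;
  for (int r = 0; r < m; ++r) {
    int first_het = -1;
    for (int l = 0; l < len; ++l)
      if (genoseg(r, l) == 1) { first_het = l; break; }
    pairs.clear();
    bool overflow = false;
    for (int h1 = 0; h1 < H && !overflow; ++h1) {
      bool ok1 = true;
      for (int l = 0; l < len; ++l) {
        int g = genoseg(r, l);
        if (g == GMISS) continue;
        int need = g - lib(h1, l);
        if (need < 0 || need > 1) { ok1 = false; break; }
      }
      if (!ok1) continue;
      for (int h2 = h1; h2 < H; ++h2) {
        bool ok = true;
        for (int l = 0; l < len; ++l) {
          int g = genoseg(r, l);
          if (g == GMISS) continue;
          if (lib(h1, l) + lib(h2, l) != g) { ok = false; break; }
        }
        if (ok) {
          if ((int)pairs.size() >= max_pairs) { overflow = true; break; }
          // orient: slot A carries allele 0 at the first het locus
          if (first_het >= 0 && lib(h1, first_het) == 1)
            pairs.push_back({h2, h1});
          else
            pairs.push_back({h1, h2});
        }
      }
    }
    npair[r] = overflow ? NA_INTEGER : (int)pairs.size();
    if (overflow) continue;
    if (!pairs.empty()) {
      for (int l = 0; l < len; ++l) {
        int va = lib(pairs[0].first, l), vb = lib(pairs[0].second, l);
        bool unan = true;
        for (size_t k = 1; k < pairs.size(); ++k) {
          if (lib(pairs[k].first, l) != va ||
              lib(pairs[k].second, l) != vb) { unan = false; break; }
        }
        if (unan) { A(r, l) = va; B(r, l) = vb; }
      }
      continue;
    }
    // no library pair: if exactly one library haplotype is genotype
    // compatible, its partner is the (novel) genotype complement
    int hit = -1, cnt = 0;
    for (int h = 0; h < H; ++h) {
      bool ok = true;
      for (int l = 0; l < len; ++l) {
        int g = genoseg(r, l);
        if (g == GMISS) continue;
        int need = g - lib(h, l);
        if (need < 0 || need > 1) { ok = false; break; }
      }
      if (ok) { ++cnt; hit = h; if (cnt > 1) break; }
    }
    if (cnt == 1) {
      bool swap = first_het >= 0 && lib(hit, first_het) == 1;
      for (int l = 0; l < len; ++l) {
        int g = genoseg(r, l);
        int va = lib(hit, l);
        int vb = g != GMISS ? g - va : AMISS;
        if (swap) { A(r, l) = vb; B(r, l) = va; }
        else { A(r, l) = va; B(r, l) = vb; }
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_pair"] = npair);
}

// Oriented pair completion for animals with known parental sides: candidate
// pairs (h1 -> paternal, h2 -> maternal) must match each gamete's resolved
// alleles and sum to the genotype at every observed locus.  Loci where all
// surviving pairs agree are filled.  Strictly stronger than per-gamete
// completion because heterozygous loci constrain the two gametes jointly.
// [[Rcpp::export(name = ".complete_pairs_cpp")]]
List complete_pairs_cpp(IntegerMatrix pat, IntegerMatrix mat,
                        IntegerMatrix genoseg, IntegerMatrix lib,
                        int max_pairs = 64) {
  const int m = pat.nrow(), len = pat.ncol(), H = lib.nrow();
  IntegerMatrix A(clone(pat)), B(clone(mat));
  IntegerVector npair(m);
  std::vector<std::pair<int,int>> pairs;
  for (int r = 0; r < m; ++r) {
    bool missing = false;
    for (int l = 0; l < len; ++l)
      if (pat(r, l) == AMISS || mat(r, l) == AMISS) { missing = true; break; }
    if (!missing) { npair[r] = NA_INTEGER; continue; }
    pairs.clear();
    bool overflow = false;
    for (int h1 = 0; h1 < H && !overflow; ++h1) {
      bool ok1 = true;
      for (int l = 0; l < len; ++l) {
        int a = pat(r, l), g = genoseg(r, l);
        if (a != AMISS && lib(h1, l) != a) { ok1 = false; break; }
        if (g != GMISS) {
          int need = g - lib(h1, l);
          if (need < 0 || need > 1) { ok1 = false; break; }
        }
      }
      if (!ok1) continue;
      for (int h2 = 0; h2 < H; ++h2) {
        bool ok = true;
        for (int l = 0; l < len; ++l) {
          int b = mat(r, l), g = genoseg(r, l);
          if (b != AMISS && lib(h2, l) != b) { ok = false; break; }
          if (g != GMISS && lib(h1, l) + lib(h2, l) != g) { ok = false; break; }
        }
        if (ok) {
          if ((int)pairs.size() >= max_pairs) { overflow = true; break; }
          pairs.push_back({h1, h2});
        }
      }
    }
    npair[r] = overflow ? NA_INTEGER : (int)pairs.size();
    if (overflow) continue;
    if (!pairs.empty()) {
      for (int l = 0; l < len; ++l) {
        int va = lib(pairs[0].first, l), vb = lib(pairs[0].second, l);
        bool una = true, unb = true;
        for (size_t k = 1; k < pairs.size() && (una || unb); ++k) {
          if (lib(pairs[k].first, l) != va) una = false;
          if (lib(pairs[k].second, l) != vb) unb = false;
        }
        if (una && A(r, l) == AMISS) A(r, l) = va;
        if (unb && B(r, l) == AMISS) B(r, l) = vb;
      }
      continue;
    }
    // no library pair: the partner haplotype is novel.  If exactly one
    // library haplotype fits one gamete (and the genotype), take it and
    // derive the partner as the genotype complement.
    for (int side = 0; side < 2; ++side) {
      IntegerMatrix &G = side == 0 ? A : B;
      IntegerMatrix &O = side == 0 ? B : A;
      int hit = -1, cnt = 0;
      for (int h = 0; h < H; ++h) {
        bool ok = true;
        for (int l = 0; l < len; ++l) {
          int a = G(r, l), o = O(r, l), g = genoseg(r, l);
          if (a != AMISS && lib(h, l) != a) { ok = false; break; }
          if (g != GMISS) {
            int need = g - lib(h, l);
            if (need < 0 || need > 1) { ok = false; break; }
            if (o != AMISS && need != o) { ok = false; break; }
          }
        }
        if (ok) { ++cnt; hit = h; if (cnt > 1) break; }
      }
      if (cnt == 1) {
        for (int l = 0; l < len; ++l) {
          if (G(r, l) == AMISS) G(r, l) = lib(hit, l);
          int g = genoseg(r, l);
          if (O(r, l) == AMISS && g != GMISS) O(r, l) = g - lib(hit, l);
        }
        break;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_pair"] = npair);
}
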