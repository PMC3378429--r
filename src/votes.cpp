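// Haplotype-matching vote machinery and the recombination scan used by the
// imputation engine, plus the four fast phase-propagation rules
// ("minor steps") that run between every major step.
//
// R matrices are column-major (individuals x SNP), so kernels either work
// on contiguous SNP columns or copy a row's core slice into a local buffer
// once before the haplotype loops.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int AMISS = 9;
static const int GMISS = 3;

// Candidate-haplotype library votes over one tiling of the chromosome.
// For each gamete row and each core, library haplotypes with more than
// `thresh` disagreements against the gamete's resolved alleles are rejected;
// at each unresolved locus where all survivors agree, the agreed allele's
// vote count is incremented.  votes0/votes1 accumulate in place across calls
// (cores of other rounds / other core lengths).
// [[Rcpp::export(name = ".library_votes_cpp")]]
void library_votes_cpp(IntegerMatrix gam, List libs, IntegerVector core_lo,
                       IntegerVector core_hi, int thresh,
                       IntegerMatrix votes0, IntegerMatrix votes1) {
  const int n = gam.nrow();
  const int ncore = core_lo.size();
  const int *G = INTEGER(gam);
  int *V0 = INTEGER(votes0), *V1 = INTEGER(votes1);
  std::vector<int> buf, cons, res_pos, res_val, miss_pos, surv;
  for (int c = 0; c < ncore; ++c) {
    IntegerMatrix lib = libs[c];
    const int H = lib.nrow();
    if (H == 0) continue;
    const int lo = core_lo[c] - 1, hi = core_hi[c] - 1, len = hi - lo + 1;
    const int *Lb = INTEGER(lib);
    // per-locus library consensus: unanimous value or -1
    cons.assign(len, -1);
    for (int l = 0; l < len; ++l) {
      int v = Lb[(size_t)l * H];
      bool un = true;
      for (int h = 1; h < H; ++h)
        if (Lb[(size_t)l * H + h] != v) { un = false; break; }
      if (un) cons[l] = v;
    }
    buf.resize(len);
    for (int i = 0; i < n; ++i) {
      res_pos.clear(); res_val.clear(); miss_pos.clear();
      for (int l = 0; l < len; ++l) {
        int a = G[(size_t)(lo + l) * n + i];
        buf[l] = a;
        if (a == AMISS) miss_pos.push_back(l);
        else res_pos.push_back(l), res_val.push_back(a);
      }
      if (miss_pos.empty()) continue;
      if (res_pos.empty()) {
        // nothing to filter on: every haplotype survives, consensus decides
        for (int l : miss_pos) {
          if (cons[l] == 0) ++V0[(size_t)(lo + l) * n + i];
          else if (cons[l] == 1) ++V1[(size_t)(lo + l) * n + i];
        }
        continue;
      }
      surv.clear();
      for (int h = 0; h < H; ++h) {
        int mm = 0;
        for (size_t k = 0; k < res_pos.size(); ++k) {
          if (Lb[(size_t)res_pos[k] * H + h] != res_val[k]) {
            if (++mm > thresh) break;
          }
        }
        if (mm <= thresh) surv.push_back(h);
      }
      if (surv.empty()) continue;
      for (int l : miss_pos) {
        int a0;
        if ((int)surv.size() == H) {
          a0 = cons[l];
          if (a0 < 0) continue;
        } else {
          a0 = Lb[(size_t)l * H + surv[0]];
          bool un = true;
          for (size_t k = 1; k < surv.size(); ++k)
            if (Lb[(size_t)l * H + surv[k]] != a0) { un = false; break; }
          if (!un) continue;
        }
        if (a0 == 0) ++V0[(size_t)(lo + l) * n + i];
        else ++V1[(size_t)(lo + l) * n + i];
      }
    }
  }
}

// Parent/own-pair candidate votes: per individual, the candidate set for a
// core is the two haplotypes candA/candB of the designated source row
// (a parent, or the individual itself).  Candidates with more than `thresh`
// disagreements at loci where both gamete and candidate are resolved are
// rejected; surviving candidates vote where they are resolved and unanimous.
// [[Rcpp::export(name = ".pair_votes_cpp")]]
void pair_votes_cpp(IntegerMatrix gam, IntegerMatrix candA, IntegerMatrix candB,
                    IntegerVector src_row, IntegerVector core_lo,
                    IntegerVector core_hi, int thresh,
                    IntegerMatrix votes0, IntegerMatrix votes1) {
  const int n = gam.nrow();
  const int ncore = core_lo.size();
  const int *G = INTEGER(gam), *CA = INTEGER(candA), *CB = INTEGER(candB);
  int *V0 = INTEGER(votes0), *V1 = INTEGER(votes1);
  for (int c = 0; c < ncore; ++c) {
    const int lo = core_lo[c] - 1, hi = core_hi[c] - 1, len = hi - lo + 1;
    for (int i = 0; i < n; ++i) {
      int s = src_row[i] - 1;
      if (s < 0) continue;
      bool any_missing = false;
      for (int l = 0; l < len; ++l)
        if (G[(size_t)(lo + l) * n + i] == AMISS) { any_missing = true; break; }
      if (!any_missing) continue;
      bool okA = true, okB = true;
      int mmA = 0, mmB = 0;
      for (int l = 0; l < len && (okA || okB); ++l) {
        int a = G[(size_t)(lo + l) * n + i];
        if (a == AMISS) continue;
        int ca = CA[(size_t)(lo + l) * n + s], cb = CB[(size_t)(lo + l) * n + s];
        if (okA && ca != AMISS && ca != a && ++mmA > thresh) okA = false;
        if (okB && cb != AMISS && cb != a && ++mmB > thresh) okB = false;
      }
      if (!okA && !okB) continue;
      for (int l = 0; l < len; ++l) {
        size_t q = (size_t)(lo + l) * n;
        if (G[q + i] != AMISS) continue;
        int ca = CA[q + s], cb = CB[q + s];
        int v = -1;
        if (okA && okB) {
          if (ca != AMISS && ca == cb) v = ca;
        } else if (okA) {
          if (ca != AMISS) v = ca;
        } else {
          if (cb != AMISS) v = cb;
        }
        if (v == 0) ++V0[q + i];
        else if (v == 1) ++V1[q + i];
      }
    }
  }
}

// Recombination scan: for each individual's gamete, determine at informative
// loci (individual and parent both heterozygous and phased) which parental
// gamete was transmitted; propagate the origin forward and backward assuming
// no double crossover between two same-origin determinations; impute alleles
// where the two directions agree (or only one direction reaches) and the
// parent is phased — subject to a ceiling on the crossover count and a
// minimum SNP span for any double-crossover interval.  Fills `gam` in place
// where missing (never contradicting an observed genotype); returns the
// number of alleles filled.
// [[Rcpp::export(name = ".recomb_scan_cpp")]]
int recomb_scan_cpp(IntegerMatrix gam, IntegerMatrix gam_other,
                    IntegerMatrix par_pat, IntegerMatrix par_mat,
                    IntegerVector par_row, IntegerMatrix geno,
                    int max_rec, int min_gap) {
  const int n = gam.nrow(), L = gam.ncol();
  int *Gm = INTEGER(gam);
  const int *Go = INTEGER(gam_other), *Pp = INTEGER(par_pat),
            *Pm = INTEGER(par_mat), *Gg = INTEGER(geno);
  int filled = 0;
  std::vector<int> info_pos, info_orig, fwd(L), bwd(L);
  for (int i = 0; i < n; ++i) {
    int p = par_row[i] - 1;
    if (p < 0) continue;
    info_pos.clear(); info_orig.clear();
    for (int l = 0; l < L; ++l) {
      size_t q = (size_t)l * n;
      int a = Gm[q + i], b = Go[q + i];
      if (a == AMISS || b == AMISS || a == b) continue;      // need het child
      int pp = Pp[q + p], pm = Pm[q + p];
      if (pp == AMISS || pm == AMISS || pp == pm) continue;  // need het parent
      info_pos.push_back(l);
      info_orig.push_back(a == pp ? 0 : 1);                  // 0 = grand-paternal
    }
    if (info_pos.empty()) continue;
    const int ni = (int)info_pos.size();
    int nrec = 0;
    bool violate = false;
    int run_start = 0;
    for (int k = 1; k < ni; ++k) {
      if (info_orig[k] != info_orig[k - 1]) {
        ++nrec;
        if (run_start > 0) {  // interior run bounded by switches on both sides
          int span = info_pos[k - 1] - info_pos[run_start - 1];
          if (span < min_gap) { violate = true; break; }
        }
        run_start = k;
      }
    }
    if (violate || nrec > max_rec) continue;
    {
      int cur = -1, k = 0;
      for (int l = 0; l < L; ++l) {
        while (k < ni && info_pos[k] <= l) cur = info_orig[k++];
        fwd[l] = cur;
      }
    }
    {
      int cur = -1, k = ni - 1;
      for (int l = L - 1; l >= 0; --l) {
        while (k >= 0 && info_pos[k] >= l) cur = info_orig[k--];
        bwd[l] = cur;
      }
    }
    for (int l = 0; l < L; ++l) {
      size_t q = (size_t)l * n;
      if (Gm[q + i] != AMISS) continue;
      int o;
      if (fwd[l] < 0) o = bwd[l];
      else if (bwd[l] < 0) o = fwd[l];
      else if (fwd[l] == bwd[l]) o = fwd[l];
      else continue;
      if (o < 0) continue;
      int a = o == 0 ? Pp[q + p] : Pm[q + p];
      if (a == AMISS) continue;
      int g = Gg[q + i], b = Go[q + i];
      if (g != GMISS) {   // never contradict an observed genotype
        if (b != AMISS) { if (b + a != g) continue; }
        else if (g - a < 0 || g - a > 1) continue;
      }
      Gm[q + i] = a; ++filled;
    }
  }
  return filled;
}

// The four minor phase-propagation rules, iterated in order until no rule
// fills anything.  All rules are per-locus, so each SNP column (contiguous
// in memory) is processed to its own fixed point.  Matrices are modified in
// place (they are owned by the working-state environment).
// Returns c(filled, conflicts).
// [[Rcpp::export(name = ".minor_steps_cpp")]]
IntegerVector minor_steps_cpp(IntegerMatrix pat, IntegerMatrix mat,
                              IntegerMatrix geno, IntegerVector sire,
                              IntegerVector dam) {
  const int n = pat.nrow(), L = pat.ncol();
  int *P = INTEGER(pat), *M = INTEGER(mat), *G = INTEGER(geno);
  const int *S = INTEGER(sire), *D = INTEGER(dam);
  long filled = 0, conflicts = 0;
  for (int l = 0; l < L; ++l) {
    int *p = P + (size_t)l * n, *m = M + (size_t)l * n, *g = G + (size_t)l * n;
    bool changed = true;
    while (changed) {
      changed = false;
      for (int i = 0; i < n; ++i) {
        // 1: parent homozygous fill-in
        int s = S[i] - 1, d = D[i] - 1;
        if (s >= 0 && p[i] == AMISS && p[s] != AMISS && p[s] == m[s]) {
          p[i] = p[s]; ++filled; changed = true;
        }
        if (d >= 0 && m[i] == AMISS && p[d] != AMISS && p[d] == m[d]) {
          m[i] = p[d]; ++filled; changed = true;
        }
        // 2: phase complement from the genotype
        if (g[i] != GMISS) {
          if (p[i] != AMISS && m[i] == AMISS) {
            int need = g[i] - p[i];
            if (need < 0 || need > 1) ++conflicts;
            else { m[i] = need; ++filled; changed = true; }
          } else if (m[i] != AMISS && p[i] == AMISS) {
            int need = g[i] - m[i];
            if (need < 0 || need > 1) ++conflicts;
            else { p[i] = need; ++filled; changed = true; }
          }
        }
        // 3: impute parents from progeny complement
        if (s >= 0 && p[i] != AMISS &&
            (p[s] == AMISS) != (m[s] == AMISS)) {
          int known = p[s] == AMISS ? m[s] : p[s];
          if (p[i] != known) {
            if (p[s] == AMISS) p[s] = p[i]; else m[s] = p[i];
            ++filled; changed = true;
          }
        }
        if (d >= 0 && m[i] != AMISS &&
            (p[d] == AMISS) != (m[d] == AMISS)) {
          int known = p[d] == AMISS ? m[d] : p[d];
          if (m[i] != known) {
            if (p[d] == AMISS) p[d] = m[i]; else m[d] = m[i];
            ++filled; changed = true;
          }
        }
        // 4: make genotype from both alleles
        if (g[i] == GMISS && p[i] != AMISS && m[i] != AMISS) {
          g[i] = p[i] + m[i]; ++filled; changed = true;
        }
      }
    }
  }
  return IntegerVector::create((int)filled, (int)conflicts);
}
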