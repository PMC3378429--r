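// Single-locus iterative peeling (segregation analysis) over a pedigree.
//
// Ordered genotype states per individual: index 2*a + b where a is the
// paternal allele and b the maternal allele, i.e. 0:(0,0) 1:(0,1) 2:(1,0)
// 3:(1,1).  Message passing runs anterior (down the pedigree) and posterior
// (up) sweeps to a fixed point; exact on loop-free pedigrees, approximate
// (damped) on looped ones.  All loci are peeled independently.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// P(transmit allele 1 | ordered genotype state)
static const double T1[4] = {0.0, 0.5, 0.5, 1.0};

struct Family {
  int sire;              // 0-based, -1 unknown
  int dam;
  std::vector<int> kids; // 0-based children
};

static inline void normalize4(double *v, bool &zero) {
  double s = v[0] + v[1] + v[2] + v[3];
  if (s <= 0.0 || !std::isfinite(s)) { zero = true; v[0]=v[1]=v[2]=v[3]=0.25; return; }
  for (int k = 0; k < 4; ++k) v[k] /= s;
}

// [[Rcpp::export(name = ".peel_all_cpp")]]
List peel_all_cpp(IntegerVector sire, IntegerVector dam, IntegerMatrix geno,
                  NumericVector freq, double tol, int maxit) {
  const int n = geno.nrow();
  const int L = geno.ncol();
  if (sire.size() != n || dam.size() != n || freq.size() != L)
    stop("dimension mismatch in peel inputs");

  // ---- pedigree structure (shared across loci) ----
  std::vector<Family> fams;
  std::vector<int> fam_of_child(n, -1);
  {
    // both-parent families grouped by (sire, dam); single-parent children get
    // their own family (the unknown parent is a fresh draw from the base
    // population for each such child)
    std::map<std::pair<int,int>, int> key2fam;
    for (int i = 0; i < n; ++i) {
      int s = sire[i] - 1, d = dam[i] - 1;
      if (s < 0 && d < 0) continue;
      if (s >= 0 && d >= 0) {
        auto key = std::make_pair(s, d);
        auto it = key2fam.find(key);
        int f;
        if (it == key2fam.end()) {
          f = (int)fams.size();
          fams.push_back({s, d, {}});
          key2fam[key] = f;
        } else f = it->second;
        fams[f].kids.push_back(i);
        fam_of_child[i] = f;
      } else {
        int f = (int)fams.size();
        fams.push_back({s, d, {i}});
        fam_of_child[i] = f;
      }
    }
  }
  const int nf = (int)fams.size();
  std::vector<std::vector<int>> fams_as_parent(n);
  for (int f = 0; f < nf; ++f) {
    if (fams[f].sire >= 0) fams_as_parent[fams[f].sire].push_back(f);
    if (fams[f].dam  >= 0) fams_as_parent[fams[f].dam ].push_back(f);
  }
  // posterior processing order: families with the youngest children first
  std::vector<int> famorder(nf);
  for (int f = 0; f < nf; ++f) famorder[f] = f;
  std::sort(famorder.begin(), famorder.end(), [&](int a, int b) {
    int ma = *std::max_element(fams[a].kids.begin(), fams[a].kids.end());
    int mb = *std::max_element(fams[b].kids.begin(), fams[b].kids.end());
    return ma > mb;
  });

  NumericVector post(n * L * 4);           // output: P(state) per ind x locus
  IntegerVector iters(L);
  int resets = 0;

  // ---- per-locus buffers ----
  std::vector<double> pen(n * 4), ant(n * 4), pprod(n * 4), full(n * 4),
      fullp(n * 4), msg(nf * 8);           // msg: [fam][side 0=to sire,1=to dam][4]

  // u = ant*pen*prod(messages from families as parent, excluding exc_f)
  auto side_dist = [&](int i, int exc_f, const double *hw, double *u) {
    if (i < 0) { for (int k = 0; k < 4; ++k) u[k] = hw[k]; return; }
    for (int k = 0; k < 4; ++k) u[k] = ant[i*4+k] * pen[i*4+k];
    for (int f : fams_as_parent[i]) {
      if (f == exc_f) continue;
      int side = (fams[f].sire == i) ? 0 : 1;
      const double *m = &msg[f*8 + side*4];
      for (int k = 0; k < 4; ++k) u[k] *= m[k];
    }
    bool z = false; normalize4(u, z);
  };

  // M_c[gs][gd] likelihood contribution of child c given parent states
  auto child_mat = [&](int c, double *M) {
    double w[4];
    for (int k = 0; k < 4; ++k) w[k] = pen[c*4+k] * pprod[c*4+k];
    double s = w[0]+w[1]+w[2]+w[3];
    if (s > 0) for (int k = 0; k < 4; ++k) w[k] /= s;
    else { w[0]=w[1]=w[2]=w[3]=0.25; }
    for (int gs = 0; gs < 4; ++gs) {
      double p1s = T1[gs], p0s = 1.0 - p1s;
      // inner term over b for a=0 and a=1
      for (int gd = 0; gd < 4; ++gd) {
        double p1d = T1[gd], p0d = 1.0 - p1d;
        double a0 = p0d * w[0] + p1d * w[1];   // a = 0: states (0,b)
        double a1 = p0d * w[2] + p1d * w[3];   // a = 1
        M[gs*4+gd] = p0s * a0 + p1s * a1;
      }
    }
  };

  for (int j = 0; j < L; ++j) {
    const double p = freq[j];
    const double hw[4] = {(1-p)*(1-p), p*(1-p), p*(1-p), p*p};

    for (int i = 0; i < n; ++i) {
      int g = geno(i, j);
      double *pe = &pen[i*4];
      switch (g) {
        case 0: pe[0]=1; pe[1]=0;   pe[2]=0;   pe[3]=0; break;
        case 1: pe[0]=0; pe[1]=0.5; pe[2]=0.5; pe[3]=0; break;
        case 2: pe[0]=0; pe[1]=0;   pe[2]=0;   pe[3]=1; break;
        default: pe[0]=pe[1]=pe[2]=pe[3]=1; break;
      }
      bool founder = (sire[i] == 0 && dam[i] == 0);
      for (int k = 0; k < 4; ++k) {
        ant[i*4+k] = founder ? hw[k] : 0.25;
        pprod[i*4+k] = 1.0;
        full[i*4+k] = 0.25;
      }
    }
    std::fill(msg.begin(), msg.end(), 1.0);

    double prev_delta = R_PosInf;
    bool damp = false;
    int it = 0;
    std::vector<double> Ms;  // per-family child matrices
    for (it = 1; it <= maxit; ++it) {
      // ---- anterior sweep (individuals are in topological order) ----
      int cached_f = -1;
      double us_c[4], ud_c[4];
      for (int i = 0; i < n; ++i) {
        int f = fam_of_child[i];
        if (f < 0) continue;  // founder: anterior stays at HW prior
        const Family &F = fams[f];
        int K = (int)F.kids.size();
        if (f != cached_f) {
          // sibling terms and parent side-distributions are stable within
          // the anterior sweep: compute once per family
          side_dist(F.sire, f, hw, us_c);
          side_dist(F.dam,  f, hw, ud_c);
          Ms.resize(16 * K);
          for (int c = 0; c < K; ++c) child_mat(F.kids[c], &Ms[16*c]);
          cached_f = f;
        }
        const double *us = us_c, *ud = ud_c;
        double J[16];
        for (int gs = 0; gs < 4; ++gs)
          for (int gd = 0; gd < 4; ++gd) {
            double v = us[gs] * ud[gd];
            for (int c = 0; c < K; ++c)
              if (F.kids[c] != i) v *= Ms[16*c + gs*4 + gd];
            J[gs*4+gd] = v;
          }
        double a_new[4] = {0, 0, 0, 0};
        for (int gs = 0; gs < 4; ++gs) {
          double v0 = 0, v1 = 0;
          for (int gd = 0; gd < 4; ++gd) {
            double p1d = T1[gd];
            v0 += J[gs*4+gd] * (1.0 - p1d);
            v1 += J[gs*4+gd] * p1d;
          }
          double p1s = T1[gs];
          a_new[0] += (1.0 - p1s) * v0;  // (a=0,b=0)
          a_new[1] += (1.0 - p1s) * v1;  // (0,1)
          a_new[2] += p1s * v0;          // (1,0)
          a_new[3] += p1s * v1;          // (1,1)
        }
        bool z = false; normalize4(a_new, z);
        for (int k = 0; k < 4; ++k) ant[i*4+k] = a_new[k];
      }

      // ---- posterior sweep (youngest families first) ----
      for (int fo = 0; fo < nf; ++fo) {
        int f = famorder[fo];
        const Family &F = fams[f];
        double us[4], ud[4];
        side_dist(F.sire, f, hw, us);
        side_dist(F.dam,  f, hw, ud);
        int K = (int)F.kids.size();
        Ms.resize(16 * K);
        for (int c = 0; c < K; ++c) child_mat(F.kids[c], &Ms[16*c]);
        double prodM[16];
        for (int q = 0; q < 16; ++q) {
          double v = 1.0;
          for (int c = 0; c < K; ++c) v *= Ms[16*c + q];
          prodM[q] = v;
        }
        if (F.sire >= 0) {
          double m[4];
          for (int gs = 0; gs < 4; ++gs) {
            double v = 0;
            for (int gd = 0; gd < 4; ++gd) v += ud[gd] * prodM[gs*4+gd];
            m[gs] = v;
          }
          bool z = false; normalize4(m, z);
          double *dst = &msg[f*8];
          for (int k = 0; k < 4; ++k)
            dst[k] = damp ? 0.5 * dst[k] + 0.5 * m[k] : m[k];
        }
        if (F.dam >= 0) {
          double m[4];
          for (int gd = 0; gd < 4; ++gd) {
            double v = 0;
            for (int gs = 0; gs < 4; ++gs) v += us[gs] * prodM[gs*4+gd];
            m[gd] = v;
          }
          bool z = false; normalize4(m, z);
          double *dst = &msg[f*8 + 4];
          for (int k = 0; k < 4; ++k)
            dst[k] = damp ? 0.5 * dst[k] + 0.5 * m[k] : m[k];
        }
        // refresh posterior products of both parents
        for (int pi : {F.sire, F.dam}) {
          if (pi < 0) continue;
          double v[4] = {1, 1, 1, 1};
          for (int f2 : fams_as_parent[pi]) {
            int side = (fams[f2].sire == pi) ? 0 : 1;
            for (int k = 0; k < 4; ++k) v[k] *= msg[f2*8 + side*4 + k];
          }
          bool z = false; normalize4(v, z);
          for (int k = 0; k < 4; ++k) pprod[pi*4+k] = v[k];
        }
      }

      // ---- full posterior + convergence ----
      double delta = 0;
      for (int i = 0; i < n; ++i) {
        double v[4];
        double s = 0;
        for (int k = 0; k < 4; ++k) {
          v[k] = ant[i*4+k] * pen[i*4+k] * pprod[i*4+k];
          s += v[k];
        }
        if (s <= 0 || !std::isfinite(s)) {
          // inconsistent observation survived cleaning: drop it and carry on
          ++resets;
          for (int k = 0; k < 4; ++k) pen[i*4+k] = 1.0;
          s = 0;
          for (int k = 0; k < 4; ++k) { v[k] = ant[i*4+k] * pprod[i*4+k]; s += v[k]; }
          if (s <= 0) { v[0]=v[1]=v[2]=v[3]=0.25; s = 1.0; }
        }
        for (int k = 0; k < 4; ++k) {
          v[k] /= s;
          double d = std::fabs(v[k] - full[i*4+k]);
          if (d > delta) delta = d;
          full[i*4+k] = v[k];
        }
      }
      if (delta < tol) break;
      if (it > 3 && delta > prev_delta) damp = true;
      prev_delta = delta;
    }
    iters[j] = std::min(it, maxit);

    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 4; ++k)
        post[(size_t)k * n * L + (size_t)j * n + i] = full[i*4+k];
  }

  post.attr("dim") = IntegerVector::create(n, L, 4);
  return List::create(_["post"] = post, _["iterations"] = iters,
                      _["resets"] = resets);
}
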