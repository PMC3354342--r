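#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> Hap; // sorted mutant positions, infinite-sites style

// One recombinant gamete from a pair of haplotypes.  Crossover count is
// Poisson(morgan) with uniform break positions (Haldane, no interference).
static Hap gamete_sparse(const Hap &a, const Hap &b, double morgan,
                         double lbp) {
  int nco = (int)R::rpois(morgan);
  int start = (unif_rand() < 0.5) ? 0 : 1; // 0: begin on a, 1: on b
  if (nco == 0) return start == 0 ? a : b;
  std::vector<double> br(nco);
  for (int k = 0; k < nco; ++k) br[k] = unif_rand() * lbp;
  std::sort(br.begin(), br.end());
  Hap pa, pb;
  pa.reserve(a.size());
  pb.reserve(b.size());
  for (int p : a) {
    int k = (int)(std::upper_bound(br.begin(), br.end(), (double)p) -
                  br.begin());
    if ((start + k) % 2 == 0) pa.push_back(p);
  }
  for (int p : b) {
    int k = (int)(std::upper_bound(br.begin(), br.end(), (double)p) -
                  br.begin());
    if ((start + k) % 2 == 1) pb.push_back(p);
  }
  Hap out;
  out.reserve(pa.size() + pb.size());
  std::merge(pa.begin(), pa.end(), pb.begin(), pb.end(),
             std::back_inserter(out));
  return out;
}

// Forward-in-time neutral simulation of 2*ne haplotypes to mutation-drift
// balance: random mating with replacement, Haldane recombination, Poisson
// mutation on an integer position grid (infinite sites in practice), fixed
// and lost sites pruned each generation.  Uses R's RNG throughout.
// [[Rcpp::export]]
List sim_pool_cpp(int ne, int ngen, double morgan, double mut_per_gamete,
                  double lbp) {
  int H = 2 * ne;
  std::vector<Hap> pop(H), nxt(H);
  std::vector<int> allpos;
  for (int gen = 0; gen < ngen; ++gen) {
    for (int k = 0; k < ne; ++k) {
      int sire = (int)(unif_rand() * ne);
      int dam = (int)(unif_rand() * ne);
      if (sire == ne) sire = ne - 1;
      if (dam == ne) dam = ne - 1;
      for (int side = 0; side < 2; ++side) {
        int par = side == 0 ? sire : dam;
        Hap g = gamete_sparse(pop[2 * par], pop[2 * par + 1], morgan, lbp);
        int nm = (int)R::rpois(mut_per_gamete);
        if (nm > 0) {
          std::vector<int> mu;
          mu.reserve(nm);
          for (int m = 0; m < nm; ++m) {
            int pos;
            int tries = 0;
            do {
              pos = 1 + (int)(unif_rand() * lbp);
              ++tries;
            } while ((std::binary_search(g.begin(), g.end(), pos) ||
                      std::find(mu.begin(), mu.end(), pos) != mu.end()) &&
                     tries < 100);
            mu.push_back(pos);
          }
          std::sort(mu.begin(), mu.end());
          Hap merged;
          merged.reserve(g.size() + mu.size());
          std::merge(g.begin(), g.end(), mu.begin(), mu.end(),
                     std::back_inserter(merged));
          g.swap(merged);
        }
        nxt[2 * k + side].swap(g);
      }
    }
    pop.swap(nxt);
    // prune fixed sites (lost ones disappear by themselves)
    allpos.clear();
    for (const Hap &h : pop) allpos.insert(allpos.end(), h.begin(), h.end());
    std::sort(allpos.begin(), allpos.end());
    std::vector<int> fixed;
    for (size_t i = 0; i < allpos.size();) {
      size_t j = i;
      while (j < allpos.size() && allpos[j] == allpos[i]) ++j;
      if ((int)(j - i) == H) fixed.push_back(allpos[i]);
      i = j;
    }
    if (!fixed.empty()) {
      for (Hap &h : pop) {
        Hap keep;
        keep.reserve(h.size());
        std::set_difference(h.begin(), h.end(), fixed.begin(), fixed.end(),
                            std::back_inserter(keep));
        h.swap(keep);
      }
    }
    if (gen % 64 == 0) Rcpp::checkUserInterrupt();
  }
  // segregating sites and derived-allele counts in the final generation
  allpos.clear();
  for (const Hap &h : pop) allpos.insert(allpos.end(), h.begin(), h.end());
  std::sort(allpos.begin(), allpos.end());
  std::vector<int> segpos, segcnt;
  for (size_t i = 0; i < allpos.size();) {
    size_t j = i;
    while (j < allpos.size() && allpos[j] == allpos[i]) ++j;
    segpos.push_back(allpos[i]);
    segcnt.push_back((int)(j - i));
    i = j;
  }
  List haps(H);
  for (int h = 0; h < H; ++h)
    haps[h] = IntegerVector(pop[h].begin(), pop[h].end());
  return List::create(_["haplotypes"] = haps,
                      _["positions"] = IntegerVector(segpos.begin(),
                                                     segpos.end()),
                      _["counts"] = IntegerVector(segcnt.begin(),
                                                  segcnt.end()));
}

typedef std::vector<unsigned char> LHap; // 0/1 alleles at the tracked loci

// Recombinant gamete on the projected locus grid.
static LHap gamete_loci(const LHap &a, const LHap &b,
                        const std::vector<double> &pos, double morgan,
                        double lbp) {
  int nco = (int)R::rpois(morgan);
  int start = (unif_rand() < 0.5) ? 0 : 1;
  if (nco == 0) return start == 0 ? a : b;
  std::vector<double> br(nco);
  for (int k = 0; k < nco; ++k) br[k] = unif_rand() * lbp;
  std::sort(br.begin(), br.end());
  size_t L = pos.size();
  LHap out(L);
  size_t k = 0;
  for (size_t l = 0; l < L; ++l) {
    while (k < br.size() && br[k] <= pos[l]) ++k;
    out[l] = ((start + (int)k) % 2 == 0) ? a[l] : b[l];
  }
  return out;
}

// Gene-drop founder haplotypes through a topologically sorted pedigree.
// pool: 2*Ne x L 0/1 matrix of final-generation haplotypes projected onto
// the tracked loci.  Founders draw pool haplotypes without replacement
// (falling back to with-replacement once exhausted); non-founders receive
// one recombinant gamete per parent; an unknown parent slot mid-pedigree is
// treated as a gamete from a freshly drawn founder pair.  No new mutation.
// [[Rcpp::export]]
List gene_drop_cpp(const IntegerMatrix &pool, const IntegerVector &sire,
                   const IntegerVector &dam, const NumericVector &loci_bp,
                   double morgan, double lbp,
                   const IntegerVector &marker_cols,
                   const IntegerVector &qtl_cols,
                   const IntegerVector &geno_rows,
                   bool return_haplotypes) {
  const int nind = sire.size();
  const int L = pool.ncol();
  const int npool = pool.nrow();
  std::vector<double> pos(loci_bp.begin(), loci_bp.end());

  // pre-shuffled draw order for without-replacement founder sampling
  std::vector<int> order(npool);
  for (int i = 0; i < npool; ++i) order[i] = i;
  for (int i = npool - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  int drawn = 0;
  bool exhausted = false;
  auto draw_pool = [&]() -> LHap {
    int row;
    if (drawn < npool) {
      row = order[drawn++];
    } else {
      exhausted = true;
      row = (int)(unif_rand() * npool);
      if (row == npool) row = npool - 1;
    }
    LHap h(L);
    for (int l = 0; l < L; ++l) h[l] = (unsigned char)pool(row, l);
    return h;
  };

  std::vector<LHap> haps(2 * nind);
  for (int i = 0; i < nind; ++i) {
    for (int side = 0; side < 2; ++side) {
      int par = side == 0 ? sire[i] : dam[i];
      if (par == 0) {
        if (sire[i] == 0 && dam[i] == 0) {
          haps[2 * i + side] = draw_pool(); // true founder: direct haplotype
        } else {
          LHap fa = draw_pool(), fb = draw_pool();
          haps[2 * i + side] = gamete_loci(fa, fb, pos, morgan, lbp);
        }
      } else {
        haps[2 * i + side] =
            gamete_loci(haps[2 * (par - 1)], haps[2 * (par - 1) + 1], pos,
                        morgan, lbp);
      }
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix mdose(geno_rows.size(), marker_cols.size());
  for (int r = 0; r < geno_rows.size(); ++r) {
    int i = geno_rows[r] - 1;
    for (int c = 0; c < marker_cols.size(); ++c) {
      int l = marker_cols[c] - 1;
      mdose(r, c) = haps[2 * i][l] + haps[2 * i + 1][l];
    }
  }
  IntegerMatrix qdose(nind, qtl_cols.size());
  for (int i = 0; i < nind; ++i)
    for (int c = 0; c < qtl_cols.size(); ++c) {
      int l = qtl_cols[c] - 1;
      qdose(i, c) = haps[2 * i][l] + haps[2 * i + 1][l];
    }

  List out = List::create(_["marker_dosage"] = mdose,
                          _["qtl_dosage"] = qdose,
                          _["pool_exhausted"] = exhausted);
  if (return_haplotypes) {
    IntegerMatrix hm(2 * nind, L);
    for (int i = 0; i < 2 * nind; ++i)
      for (int l = 0; l < L; ++l) hm(i, l) = haps[i][l];
    out["haplotypes"] = hm;
  }
  return out;
}
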