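#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured coalescent over a fixed universe of D demes with piecewise
// demography (epochs, backwards in time). Time is measured in generations;
// a specific pair of lineages in a deme of diploid size Ne coalesces at
// rate 1/(2*Ne) per generation.
//
// Epoch e spans [end_{e-1}, end_e); entering epoch e relabels demes via
// demeMap (lineage in deme d moves to demeMap(e, d)). Migration is either
// absent, island (per-lineage total emigration rate, uniform destination
// among the other active demes) or stepping-stone (per-neighbour rate along
// the chain of active demes in index order).
//
// Mutation models:
//   1 = single segregating site: one mutation placed uniformly on the
//       genealogy; per-deme derived-allele counts returned.
//   2 = infinite alleles: Poisson(mu * branch length) mutations per branch,
//       every mutation a novel allele; per-deme allele counts returned for
//       sampled demes.

namespace {

struct Tree {
  std::vector<int> parent;
  std::vector<int> child1, child2;
  std::vector<double> time;
  std::vector<int> leafDeme;
  int nLeaves;
  int nNodes;
};

inline int pickDeme(const std::vector<double> &rate, double target) {
  double acc = 0.0;
  int D = static_cast<int>(rate.size());
  for (int d = 0; d < D; ++d) {
    acc += rate[d];
    if (target <= acc) return d;
  }
  // numerical slop: return last deme with positive rate
  for (int d = D - 1; d >= 0; --d) if (rate[d] > 0) return d;
  return 0;
}

} // namespace

// [[Rcpp::export(name = ".simStructuredCoalescent")]]
List simStructuredCoalescent(IntegerVector sampleSizes,
                             NumericVector epochEnds,
                             NumericMatrix neMat,
                             IntegerVector migType,
                             NumericVector migRate,
                             IntegerMatrix demeMap,
                             int nReps,
                             int mutModel,
                             NumericVector mu) {
  const int D = sampleSizes.size();
  const int E = epochEnds.size();
  if (neMat.nrow() != E || neMat.ncol() != D)
    stop("neMat must be nEpochs x nDemes");
  if (demeMap.nrow() != E || demeMap.ncol() != D)
    stop("demeMap must be nEpochs x nDemes");
  int n = 0;
  for (int d = 0; d < D; ++d) {
    if (sampleSizes[d] < 0) stop("negative sample size");
    n += sampleSizes[d];
  }
  if (n < 2) stop("need at least 2 sampled gene copies");

  std::vector<int> sampledDemes;
  for (int d = 0; d < D; ++d)
    if (sampleSizes[d] > 0) sampledDemes.push_back(d);
  const int nSampled = static_cast<int>(sampledDemes.size());

  IntegerMatrix derivedOut;
  List iamOut;
  if (mutModel == 1) derivedOut = IntegerMatrix(nReps, D);
  else iamOut = List(nReps);

  const int nNodes = 2 * n - 1;
  Tree tr;
  tr.parent.assign(nNodes, -1);
  tr.child1.assign(nNodes, -1);
  tr.child2.assign(nNodes, -1);
  tr.time.assign(nNodes, 0.0);
  tr.leafDeme.assign(n, -1);
  tr.nLeaves = n;
  tr.nNodes = nNodes;

  std::vector<std::vector<int> > byDeme(D);
  std::vector<double> coalRate(D), migDemeRate(D), outLin(D);
  std::vector<int> kd(D);
  std::vector<int> active;        // active demes in current epoch
  std::vector<int> chainPos(D);   // position of deme in active chain, -1 if inactive

  for (int rep = 0; rep < nReps; ++rep) {
    if (rep % 64 == 0) Rcpp::checkUserInterrupt();
    // initialise leaves
    for (int d = 0; d < D; ++d) byDeme[d].clear();
    int leaf = 0;
    for (int d = 0; d < D; ++d) {
      for (int s = 0; s < sampleSizes[d]; ++s) {
        tr.leafDeme[leaf] = d;
        byDeme[d].push_back(leaf);
        ++leaf;
      }
    }
    std::fill(tr.parent.begin(), tr.parent.end(), -1);
    std::fill(tr.child1.begin(), tr.child1.end(), -1);
    std::fill(tr.child2.begin(), tr.child2.end(), -1);
    std::fill(tr.time.begin(), tr.time.end(), 0.0);

    int nLin = n;
    int nextNode = n;
    double t = 0.0;

    for (int e = 0; e < E && nLin > 1; ++e) {
      // relabel demes on epoch entry
      if (e > 0) {
        for (int d = 0; d < D; ++d) {
          int dest = demeMap(e, d) - 1;  // 1-based from R
          if (dest != d && !byDeme[d].empty()) {
            byDeme[dest].insert(byDeme[dest].end(), byDeme[d].begin(),
                                byDeme[d].end());
            byDeme[d].clear();
          }
        }
      }
      // epoch-specific rates
      active.clear();
      std::fill(chainPos.begin(), chainPos.end(), -1);
      for (int d = 0; d < D; ++d) {
        if (neMat(e, d) > 0) {
          chainPos[d] = static_cast<int>(active.size());
          active.push_back(d);
        }
      }
      const int nActive = static_cast<int>(active.size());
      const int mt = migType[e];
      const double m = migRate[e];
      for (int d = 0; d < D; ++d) {
        kd[d] = static_cast<int>(byDeme[d].size());
        double ne = neMat(e, d);
        coalRate[d] = (ne > 0 && kd[d] > 1)
          ? kd[d] * (kd[d] - 1.0) / (4.0 * ne) : 0.0;
        double out = 0.0;
        if (chainPos[d] >= 0 && nActive > 1) {
          if (mt == 1) out = m;
          else if (mt == 2) {
            int nb = 0;
            if (chainPos[d] > 0) ++nb;
            if (chainPos[d] < nActive - 1) ++nb;
            out = m * nb;
          }
        }
        outLin[d] = out;
        migDemeRate[d] = kd[d] * out;
      }
      const double epochEnd = epochEnds[e];

      long evt = 0;
      while (nLin > 1) {
        if ((++evt & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
        double totC = 0.0, totM = 0.0;
        for (int i = 0; i < nActive; ++i) {
          totC += coalRate[active[i]];
          totM += migDemeRate[active[i]];
        }
        const double tot = totC + totM;
        if (tot <= 0) { t = epochEnd; break; }  // wait for next epoch
        double dt = R::exp_rand() / tot;
        if (t + dt >= epochEnd) { t = epochEnd; break; }
        t += dt;
        double u = unif_rand() * tot;
        if (u <= totC) {
          int d = pickDeme(coalRate, u);
          // choose two distinct lineages
          int k = kd[d];
          int i = static_cast<int>(unif_rand() * k);
          int j = static_cast<int>(unif_rand() * (k - 1));
          if (i >= k) i = k - 1;
          if (j >= i) ++j;
          int a = byDeme[d][i], b = byDeme[d][j];
          int v = nextNode++;
          tr.parent[a] = v; tr.parent[b] = v;
          tr.child1[v] = a; tr.child2[v] = b;
          tr.time[v] = t;
          // remove a and b, add v (swap-pop, larger index first)
          int hi = (i > j) ? i : j, lo = (i > j) ? j : i;
          byDeme[d][hi] = byDeme[d].back(); byDeme[d].pop_back();
          byDeme[d][lo] = byDeme[d].back(); byDeme[d].pop_back();
          byDeme[d].push_back(v);
          kd[d] -= 1;
          --nLin;
          double ne = neMat(e, d);
          coalRate[d] = (ne > 0 && kd[d] > 1)
            ? kd[d] * (kd[d] - 1.0) / (4.0 * ne) : 0.0;
          migDemeRate[d] = kd[d] * outLin[d];
        } else {
          double target = u - totC;
          int d = pickDeme(migDemeRate, target);
          int k = kd[d];
          int i = static_cast<int>(unif_rand() * k);
          if (i >= k) i = k - 1;
          int lin = byDeme[d][i];
          int dest = d;
          if (mt == 1) {
            int j = static_cast<int>(unif_rand() * (nActive - 1));
            if (j >= nActive - 1) j = nActive - 2;
            if (j >= chainPos[d]) ++j;
            dest = active[j];
          } else {
            int pos = chainPos[d];
            bool hasL = pos > 0, hasR = pos < nActive - 1;
            if (hasL && hasR) dest = active[(unif_rand() < 0.5) ? pos - 1 : pos + 1];
            else if (hasL) dest = active[pos - 1];
            else dest = active[pos + 1];
          }
          byDeme[d][i] = byDeme[d].back(); byDeme[d].pop_back();
          byDeme[dest].push_back(lin);
          kd[d] -= 1; kd[dest] += 1;
          double neS = neMat(e, d), neD = neMat(e, dest);
          coalRate[d] = (neS > 0 && kd[d] > 1)
            ? kd[d] * (kd[d] - 1.0) / (4.0 * neS) : 0.0;
          coalRate[dest] = (neD > 0 && kd[dest] > 1)
            ? kd[dest] * (kd[dest] - 1.0) / (4.0 * neD) : 0.0;
          migDemeRate[d] = kd[d] * outLin[d];
          migDemeRate[dest] = kd[dest] * outLin[dest];
        }
      }
    }
    if (nLin > 1)
      stop("genealogy did not reach its MRCA; check that the final epoch allows coalescence");

    const int root = nNodes - 1;
    // branch lengths
    double L = 0.0;
    std::vector<double> len(nNodes, 0.0);
    for (int v = 0; v < nNodes - 1; ++v) {
      len[v] = tr.time[tr.parent[v]] - tr.time[v];
      L += len[v];
    }

    if (mutModel == 1) {
      // uniform placement on the genealogy => always segregating in sample
      double target = unif_rand() * L;
      int chosen = 0;
      double acc = 0.0;
      for (int v = 0; v < nNodes - 1; ++v) {
        acc += len[v];
        if (target <= acc) { chosen = v; break; }
        chosen = v;
      }
      // count leaves under `chosen` per deme
      std::vector<int> cnt(D, 0);
      std::vector<int> stack;
      stack.push_back(chosen);
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        if (v < n) cnt[tr.leafDeme[v]] += 1;
        else { stack.push_back(tr.child1[v]); stack.push_back(tr.child2[v]); }
      }
      for (int d = 0; d < D; ++d) derivedOut(rep, d) = cnt[d];
    } else {
      const double muRep = (mu.size() == 1) ? mu[0] : mu[rep];
      std::vector<int> allele(nNodes, 0);
      int nextAllele = 1;
      for (int v = nNodes - 2; v >= 0; --v) {
        int nm = static_cast<int>(R::rpois(muRep * len[v]));
        allele[v] = (nm > 0) ? nextAllele++ : allele[tr.parent[v]];
      }
      // compact allele ids among leaves
      std::vector<int> relab(nextAllele, -1);
      int nAll = 0;
      for (int l = 0; l < n; ++l)
        if (relab[allele[l]] < 0) relab[allele[l]] = nAll++;
      IntegerMatrix cnt(nSampled, nAll);
      for (int l = 0; l < n; ++l) {
        int d = tr.leafDeme[l];
        int row = -1;
        for (int s = 0; s < nSampled; ++s)
          if (sampledDemes[s] == d) { row = s; break; }
        cnt(row, relab[allele[l]]) += 1;
      }
      iamOut[rep] = cnt;
    }
  }

  if (mutModel == 1) {
    return List::create(_["derived"] = derivedOut,
                        _["sampleSizes"] = sampleSizes);
  }
  return List::create(_["counts"] = iamOut,
                      _["sampledDemes"] = wrap(sampledDemes),
                      _["sampleSizes"] = sampleSizes);
}
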