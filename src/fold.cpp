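// Core dynamic programmes for the additive reference energy model.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=U. Strand ids distinguish the
// molecules of a complex; pairs between different strands are exempt
// from the minimum hairpin-loop separation. All pairing is nested
// (pseudoknot-free) over the concatenation.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double EPS = 1e-9;

struct Model {
  double eGC, eAU, eGU;
  bool allowGU;       // GU wobble within a strand
  bool allowGUInter;  // GU wobble between strands
  int minHairpin;     // intramolecular pairs need j - i > minHairpin
};

Model makeModel(const List& par) {
  Model m;
  m.eGC = as<double>(par["eGC"]);
  m.eAU = as<double>(par["eAU"]);
  m.eGU = as<double>(par["eGU"]);
  m.allowGU = as<bool>(par["allowGU"]);
  m.allowGUInter = as<bool>(par["allowGUInter"]);
  m.minHairpin = as<int>(par["minHairpin"]);
  return m;
}

inline bool isGU(int a, int b) {
  return (a == 2 && b == 3) || (a == 3 && b == 2);
}

// Energy of pairing bases a, b; ok = false when the pair is disallowed.
inline double pairE(int a, int b, bool sameStrand, const Model& m, bool& ok) {
  ok = true;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return m.eGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return m.eAU;
  if (isGU(a, b) && (sameStrand ? m.allowGU : m.allowGUInter)) return m.eGU;
  ok = false;
  return 0.0;
}

// Pairability of positions i < j (original coordinates).
inline bool canPair(int i, int j, const IntegerVector& seq,
                    const IntegerVector& strand, const Model& m, double& e) {
  bool same = strand[i] == strand[j];
  if (same && j - i <= m.minHairpin) return false;
  bool ok;
  e = pairE(seq[i], seq[j], same, m, ok);
  return ok;
}

}  // namespace

// Minimum free energy fold. Returns 0-based partner vector (-1 =
// unpaired) and the energy. Tie-breaking in the traceback prefers the
// leftmost position unpaired; among equal-energy pairings the smallest
// partner index is taken.
// [[Rcpp::export]]
List cpp_fold(IntegerVector seq, IntegerVector strand, List par) {
  const Model m = makeModel(par);
  const int n = seq.size();
  IntegerVector pairs(n, -1);
  if (n == 0) return List::create(_["pairs"] = pairs, _["energy"] = 0.0);

  std::vector<double> E((size_t)n * n, 0.0);
  auto at = [&](int i, int j) -> double {
    return (i > j) ? 0.0 : E[(size_t)i * n + j];
  };

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = at(i + 1, j);  // i unpaired
      for (int k = i + 1; k <= j; ++k) {
        double e;
        if (!canPair(i, k, seq, strand, m, e)) continue;
        double v = e + at(i + 1, k - 1) + at(k + 1, j);
        if (v < best) best = v;
      }
      E[(size_t)i * n + j] = best;
    }
  }

  // traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double tgt = at(i, j);
    if (std::fabs(at(i + 1, j) - tgt) < EPS) {  // prefer i unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + 1; k <= j; ++k) {
      double e;
      if (!canPair(i, k, seq, strand, m, e)) continue;
      if (std::fabs(e + at(i + 1, k - 1) + at(k + 1, j) - tgt) < EPS) {
        pairs[i] = k;
        pairs[k] = i;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  return List::create(_["pairs"] = pairs, _["energy"] = at(0, n - 1));
}

// Reaction-coordinate profile: G(r) = minimum energy over all joint
// structures containing exactly r intermolecular pairs, r = 0..rmax.
// Infeasible r comes back as +Inf.
// [[Rcpp::export]]
NumericVector cpp_profile(IntegerVector seq, IntegerVector strand, List par,
                          int rmax) {
  const Model m = makeModel(par);
  const int n = seq.size();
  const int R = rmax + 1;
  if (n == 0) return NumericVector::create(0.0);

  // E[i][j][r]; empty interval: 0 at r = 0, INF otherwise.
  std::vector<double> E((size_t)n * n * R, INF);
  auto idx = [&](int i, int j, int r) -> size_t {
    return ((size_t)i * n + j) * R + r;
  };
  auto at = [&](int i, int j, int r) -> double {
    if (i > j) return (r == 0) ? 0.0 : INF;
    return E[idx(i, j, r)];
  };

  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      for (int r = 0; r < R; ++r) {
        double best = at(i + 1, j, r);
        for (int k = i + 1; k <= j; ++k) {
          double e;
          if (!canPair(i, k, seq, strand, m, e)) continue;
          int rp = (strand[i] != strand[k]) ? 1 : 0;
          if (rp > r) continue;
          for (int r1 = 0; r1 <= r - rp; ++r1) {
            double in = at(i + 1, k - 1, r1);
            if (in == INF) continue;
            double out = at(k + 1, j, r - rp - r1);
            if (out == INF) continue;
            double v = e + in + out;
            if (v < best) best = v;
          }
        }
        E[idx(i, j, r)] = best;
      }
    }
  }

  NumericVector G(R);
  for (int r = 0; r < R; ++r) G[r] = at(0, n - 1, r);
  return G;
}

namespace {

// Partition function over an ordered subset of positions (original
// coordinates used for pairability). Returns Q over the whole subset;
// optionally exposes the full table for reuse. A per-position energy
// shift mu (<= 0) rescales every structure's weight by
// exp(m * mu / RT); the factor is common to all structures over the
// same positions and cancels in probability ratios, keeping the sums
// inside double range at small RT.
double partitionSubset(const std::vector<int>& idxv, const IntegerVector& seq,
                       const IntegerVector& strand, const Model& m, double RT,
                       double mu = 0.0, std::vector<double>* table = NULL) {
  const int n = (int)idxv.size();
  if (n == 0) return 1.0;
  const double f = std::exp(mu / RT);  // unpaired-position factor
  std::vector<double> Q((size_t)n * n, 0.0);
  auto at = [&](int i, int j) -> double {
    return (i > j) ? 1.0 : Q[(size_t)i * n + j];
  };
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double s = f * at(i + 1, j);
      for (int k = i + 1; k <= j; ++k) {
        double e;
        if (!canPair(idxv[i], idxv[k], seq, strand, m, e)) continue;
        s += std::exp(-(e - 2.0 * mu) / RT) * at(i + 1, k - 1) * at(k + 1, j);
      }
      Q[(size_t)i * n + j] = s;
    }
  }
  double tot = at(0, n - 1);
  if (table) *table = Q;
  return tot;
}

// MFE energy only (no traceback), for the rescaling shift.
double mfeEnergy(const IntegerVector& seq, const IntegerVector& strand,
                 const Model& m) {
  const int n = seq.size();
  if (n == 0) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  auto at = [&](int i, int j) -> double {
    return (i > j) ? 0.0 : E[(size_t)i * n + j];
  };
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = at(i + 1, j);
      for (int k = i + 1; k <= j; ++k) {
        double e;
        if (!canPair(i, k, seq, strand, m, e)) continue;
        double v = e + at(i + 1, k - 1) + at(k + 1, j);
        if (v < best) best = v;
      }
      E[(size_t)i * n + j] = best;
    }
  }
  return at(0, n - 1);
}

}  // namespace

// Total partition function over all nested structures (Boltzmann sum,
// E = 0 reference for the fully unpaired state).
// [[Rcpp::export]]
double cpp_partition(IntegerVector seq, IntegerVector strand, List par,
                     double RT) {
  const Model m = makeModel(par);
  std::vector<int> idxv(seq.size());
  for (int i = 0; i < seq.size(); ++i) idxv[i] = i;
  return partitionSubset(idxv, seq, strand, m, RT);
}

// Base-pairing probability matrix P[i][j] = sum of Boltzmann weights of
// structures containing pair (i,j), divided by the total partition
// function. Exact for the additive model: the ensemble outside a forced
// pair is itself a nested partition function over the remaining
// positions.
// [[Rcpp::export]]
NumericMatrix cpp_pairprob(IntegerVector seq, IntegerVector strand, List par,
                           double RT) {
  const Model m = makeModel(par);
  const int n = seq.size();
  NumericMatrix P(n, n);
  if (n == 0) return P;

  const double mu = mfeEnergy(seq, strand, m) / n;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<double> Qfull;
  double Z = partitionSubset(all, seq, strand, m, RT, mu, &Qfull);
  auto Qin = [&](int i, int j) -> double {
    return (i > j) ? 1.0 : Qfull[(size_t)i * n + j];
  };

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double e;
      if (!canPair(i, j, seq, strand, m, e)) continue;
      std::vector<int> outside;
      outside.reserve(n - (j - i + 1));
      for (int k = 0; k < i; ++k) outside.push_back(k);
      for (int k = j + 1; k < n; ++k) outside.push_back(k);
      double qout = partitionSubset(outside, seq, strand, m, RT, mu);
      double p = std::exp(-(e - 2.0 * mu) / RT) * Qin(i + 1, j - 1) * qout / Z;
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  return P;
}

// Longest contiguous antiparallel complementary run between positions
// unpaired in both partners' individual MFE structures (the seed /
// nucleation site). Watson-Crick by default; GU optional. Runs may not
// cross strand boundaries. Returns c(startA, startB, len), 0-based with
// startB the smallest B index of the run; c(-1, -1, 0) when none.
// [[Rcpp::export]]
IntegerVector cpp_seed(IntegerVector seqA, IntegerVector unpairedA,
                       IntegerVector strandA, IntegerVector seqB,
                       IntegerVector unpairedB, IntegerVector strandB,
                       bool allowGU) {
  const int nA = seqA.size(), nB = seqB.size();
  auto comp = [&](int a, int b) -> bool {
    if (a + b == 3) return true;  // AU or GC
    return allowGU && isGU(a, b);
  };
  // M(i, j): length of the run starting at A[i] pairing B[j], B
  // descending. Computed by decreasing i, increasing j.
  std::vector<int> M((size_t)nA * nB, 0);
  auto at = [&](int i, int j) -> int { return M[(size_t)i * nB + j]; };
  for (int i = nA - 1; i >= 0; --i) {
    for (int j = 0; j < nB; ++j) {
      if (!unpairedA[i] || !unpairedB[j] || !comp(seqA[i], seqB[j])) continue;
      int ext = 0;
      if (i + 1 < nA && j - 1 >= 0 && strandA[i + 1] == strandA[i] &&
          strandB[j - 1] == strandB[j])
        ext = at(i + 1, j - 1);
      M[(size_t)i * nB + j] = 1 + ext;
    }
  }
  int bestL = 0, bestA = -1, bestB = -1;
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      int L = at(i, j);
      if (L == 0) continue;
      int sB = j - (L - 1);
      bool better = L > bestL || (L == bestL && (i < bestA || (i == bestA && sB < bestB)));
      if (bestA == -1) better = L > bestL;
      if (better) {
        bestL = L;
        bestA = i;
        bestB = sB;
      }
    }
  }
  return IntegerVector::create(bestA, bestB, bestL);
}
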