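// Rigid superposition and iterative pocket alignment core.
// Points are rows; a transform (R, t) maps x -> R x + t, i.e. X %*% t(R) + t
// on row-matrices. The moving set is always the second argument.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct KabschFit {
  arma::mat33 R;
  arma::vec3 t;
  double rmsd;
  bool ok;          // false when the point set is rank-deficient (collinear)
};

static KabschFit kabsch_fit(const arma::mat& A, const arma::mat& B,
                            bool require_rank = true) {
  KabschFit out;
  arma::rowvec ca = arma::mean(A, 0);
  arma::rowvec cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Bc.t() * Ac;   // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) { out.ok = false; return out; }
  // collinear inputs leave the rotation about the line undetermined
  if (require_rank && s(1) < 1e-9 * std::max(1.0, s(0))) {
    out.ok = false; return out;
  }
  double d = arma::det(V * U.t());
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  out.R = V * D * U.t();
  out.t = ca.t() - out.R * cb.t();
  arma::mat Bt = B * out.R.t();
  Bt.each_row() += out.t.t();
  out.rmsd = std::sqrt(arma::accu(arma::square(A - Bt)) / A.n_rows);
  out.ok = true;
  return out;
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat& A, const arma::mat& B) {
  KabschFit f = kabsch_fit(A, B);
  if (!f.ok) stop("degenerate input: fewer than 3 non-collinear point pairs");
  return List::create(_["rotation"] = arma::mat(f.R),
                      _["translation"] = NumericVector::create(f.t(0), f.t(1), f.t(2)),
                      _["rmsd"] = f.rmsd);
}

// Mutual-nearest-neighbour correspondence between Q and transformed T under a
// distance gate. Returns matched index pairs (0-based).
static void mutual_pairs(const arma::mat& Q, const arma::mat& Tt, double gate,
                         std::vector<int>& qi, std::vector<int>& ti) {
  const arma::uword nq = Q.n_rows, nt = Tt.n_rows;
  std::vector<int> bestForQ(nq, -1), bestForT(nt, -1);
  std::vector<double> dQ(nq, R_PosInf), dT(nt, R_PosInf);
  for (arma::uword i = 0; i < nq; ++i) {
    for (arma::uword j = 0; j < nt; ++j) {
      double dx = Q(i,0) - Tt(j,0), dy = Q(i,1) - Tt(j,1), dz = Q(i,2) - Tt(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < dQ[i]) { dQ[i] = d2; bestForQ[i] = (int) j; }
      if (d2 < dT[j]) { dT[j] = d2; bestForT[j] = (int) i; }
    }
  }
  qi.clear(); ti.clear();
  double g2 = gate * gate;
  for (arma::uword i = 0; i < nq; ++i) {
    int j = bestForQ[i];
    if (j >= 0 && bestForT[j] == (int) i && dQ[i] <= g2) {
      qi.push_back((int) i);
      ti.push_back(j);
    }
  }
}

// Iterative seed-superpose-extend alignment between two pocket coordinate
// sets. Each seed is a triple of 0-based row indices into Q and T; the seed
// superposition is refined by mutual-nearest reassignment under the gate
// until the correspondence reaches a fixed point. The best result by
// (score, aligned length, -rmsd) is returned.
// [[Rcpp::export(name = ".align_core_cpp")]]
List align_core_cpp(const arma::mat& Q, const arma::mat& T,
                    const arma::imat& seedQ, const arma::imat& seedT,
                    double d0, double gate, int maxIter, int lmin,
                    int seedKeep) {
  if (seedQ.n_rows != seedT.n_rows || seedQ.n_cols != 3 || seedT.n_cols != 3)
    stop("seed index matrices must be k x 3 and of equal length");
  double bestScore = -1.0, bestRmsd = R_PosInf;
  int bestLen = -1;
  std::vector<int> bestQi, bestTi;
  arma::mat33 bestR; arma::vec3 bestT0;
  bool haveBest = false;

  // phase 1: rank seeds by the mutual-pair count of their raw triple
  // superposition; only the most promising go through full refinement
  const arma::uword nSeeds = seedQ.n_rows;
  std::vector<KabschFit> seedFits(nSeeds);
  std::vector<std::pair<int,int>> rank;   // (-count, seed index)
  rank.reserve(nSeeds);
  {
    std::vector<int> qi, ti;
    for (arma::uword srow = 0; srow < nSeeds; ++srow) {
      arma::mat a(3, 3), b(3, 3);
      for (int k = 0; k < 3; ++k) {
        a.row(k) = Q.row(seedQ(srow, k));
        b.row(k) = T.row(seedT(srow, k));
      }
      seedFits[srow] = kabsch_fit(a, b);
      if (!seedFits[srow].ok) continue;
      arma::mat Tt = T * seedFits[srow].R.t();
      Tt.each_row() += seedFits[srow].t.t();
      mutual_pairs(Q, Tt, gate, qi, ti);
      rank.push_back(std::make_pair(-(int) qi.size(), (int) srow));
    }
  }
  std::sort(rank.begin(), rank.end());
  if ((int) rank.size() > seedKeep) rank.resize(seedKeep);

  for (auto& rk : rank) {
    arma::uword srow = (arma::uword) rk.second;
    KabschFit f = seedFits[srow];
    std::vector<int> qi, ti, prevQi, prevTi;
    arma::mat33 R = f.R; arma::vec3 t = f.t;
    for (int it = 0; it < maxIter; ++it) {
      arma::mat Tt = T * R.t();
      Tt.each_row() += t.t();
      mutual_pairs(Q, Tt, gate, qi, ti);
      if ((int) qi.size() < 3) { qi.clear(); break; }
      if (qi == prevQi && ti == prevTi) break;   // fixed point
      arma::mat Am(qi.size(), 3), Bm(qi.size(), 3);
      for (size_t k = 0; k < qi.size(); ++k) {
        Am.row(k) = Q.row(qi[k]);
        Bm.row(k) = T.row(ti[k]);
      }
      KabschFit g = kabsch_fit(Am, Bm, false);
      if (!g.ok) break;
      R = g.R; t = g.t;
      prevQi = qi; prevTi = ti;
    }
    if ((int) qi.size() < 3) continue;
    // final distances under the converged transform
    arma::mat Tt = T * R.t();
    Tt.each_row() += t.t();
    double score = 0.0, ss = 0.0;
    for (size_t k = 0; k < qi.size(); ++k) {
      double dx = Q(qi[k],0) - Tt(ti[k],0);
      double dy = Q(qi[k],1) - Tt(ti[k],1);
      double dz = Q(qi[k],2) - Tt(ti[k],2);
      double d2 = dx*dx + dy*dy + dz*dz;
      ss += d2;
      score += 1.0 / (1.0 + d2 / (d0 * d0));
    }
    score /= (double) lmin;
    double rmsd = std::sqrt(ss / qi.size());
    int len = (int) qi.size();
    bool better = false;
    if (score > bestScore + 1e-12) better = true;
    else if (std::abs(score - bestScore) <= 1e-12) {
      if (len > bestLen) better = true;
      else if (len == bestLen && rmsd < bestRmsd - 1e-12) better = true;
    }
    if (better) {
      bestScore = score; bestLen = len; bestRmsd = rmsd;
      bestQi = qi; bestTi = ti; bestR = R; bestT0 = t;
      haveBest = true;
    }
    if (bestScore >= 0.9999 && bestLen >= lmin) break;  // cannot improve
  }

  if (!haveBest)
    return List::create(_["ok"] = false);
  IntegerVector qout(bestQi.size()), tout(bestTi.size());
  for (size_t k = 0; k < bestQi.size(); ++k) {
    qout[k] = bestQi[k] + 1;    // back to 1-based for R
    tout[k] = bestTi[k] + 1;
  }
  return List::create(_["ok"] = true,
                      _["qidx"] = qout,
                      _["tidx"] = tout,
                      _["rotation"] = arma::mat(bestR),
                      _["translation"] = NumericVector::create(bestT0(0), bestT0(1), bestT0(2)),
                      _["rmsd"] = bestRmsd,
                      _["score"] = bestScore,
                      _["alignedLength"] = bestLen);
}

// All residue pairs between two atom sets whose minimum heavy-atom distance
// is at most the cutoff. Atom-to-residue assignment comes in as 1-based
// residue indices; returns the per-pair minimum distance.
// [[Rcpp::export(name = ".residue_contacts_cpp")]]
DataFrame residue_contacts_cpp(const arma::mat& xyzA, const IntegerVector& resA,
                               const arma::mat& xyzB, const IntegerVector& resB,
                               double cutoff, int nResA, int nResB) {
  std::map<std::pair<int,int>, double> best;
  double c2 = cutoff * cutoff;
  for (arma::uword i = 0; i < xyzA.n_rows; ++i) {
    for (arma::uword j = 0; j < xyzB.n_rows; ++j) {
      double dx = xyzA(i,0) - xyzB(j,0);
      if (std::abs(dx) > cutoff) continue;
      double dy = xyzA(i,1) - xyzB(j,1), dz = xyzA(i,2) - xyzB(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > c2) continue;
      std::pair<int,int> key(resA[i], resB[j]);
      auto it = best.find(key);
      if (it == best.end() || d2 < it->second) best[key] = d2;
    }
  }
  int n = (int) best.size();
  IntegerVector ra(n), rb(n);
  NumericVector dist(n);
  int k = 0;
  for (auto& kv : best) {
    ra[k] = kv.first.first;
    rb[k] = kv.first.second;
    dist[k] = std::sqrt(kv.second);
    ++k;
  }
  (void) nResA; (void) nResB;
  return DataFrame::create(_["ia"] = ra, _["ib"] = rb, _["dist"] = dist);
}
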