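// Pairwise-energy and surface-area kernels. The energy model is a simplified
// physics score (softened Lennard-Jones, distance-window hydrogen bond,
// screened Coulomb with distance-dependent dielectric, and a burial penalty
// for polar atoms). It is NOT any published force field; callers treat its
// values as ordinal.
#include <Rcpp.h>
using namespace Rcpp;

static const double PAIR_CUTOFF = 10.0;   // neighbour cutoff, Angstrom
static const double SOLV_RADIUS = 5.2;    // burial-count radius
static const double SOLV_THRESH = 22.0;   // neighbours before burial penalty
                                          // (surface atoms sit near 15-20)

// Softened LJ: 12-6 beyond 0.6*r0, linear continuation inside, capped.
static inline double lj_term(double d, double r0, double eps, double cap,
                             bool *clashed) {
  double d0 = 0.6 * r0;
  double e;
  if (d >= d0) {
    double x6 = std::pow(r0 / d, 6.0);
    e = eps * (x6 * x6 - 2.0 * x6);
  } else {
    double x6 = std::pow(r0 / d0, 6.0);
    double e0 = eps * (x6 * x6 - 2.0 * x6);
    double slope = eps * (-12.0 * std::pow(r0, 12.0) / std::pow(d0, 13.0)
                          + 12.0 * std::pow(r0, 6.0) / std::pow(d0, 7.0));
    e = e0 + slope * (d - d0);
  }
  if (e > cap) { e = cap; if (clashed) *clashed = true; }
  return e;
}

static inline double hb_term(double d, bool da, bool ad, double w) {
  if (!(da || ad)) return 0.0;
  if (d < 2.6 || d > 3.2) return 0.0;  // donor-acceptor heavy-atom range
  double u = (d - 2.9) / 0.3;
  double well = (1.0 - u * u);
  return -w * well * well;
}

static inline double coul_term(double d, double qi, double qj, double w) {
  if (qi == 0.0 || qj == 0.0) return 0.0;
  return w * 332.0 * qi * qj / (4.0 * d * d);
}

// Cross-set interaction energy (no exclusions): A atoms vs B atoms.
// Returns total and the per-A-atom share.
// [[Rcpp::export]]
List cpp_pair_energy(NumericMatrix xyzA, NumericVector radA,
                     NumericVector epsA, NumericVector qA,
                     LogicalVector donA, LogicalVector accA,
                     NumericMatrix xyzB, NumericVector radB,
                     NumericVector epsB, NumericVector qB,
                     LogicalVector donB, LogicalVector accB,
                     double w_lj, double w_hb, double w_coul,
                     double clash_cap) {
  int nA = xyzA.nrow(), nB = xyzB.nrow();
  NumericVector perA(nA);
  double total = 0.0;
  bool clashed = false;
  for (int i = 0; i < nA; ++i) {
    double ei = 0.0;
    for (int j = 0; j < nB; ++j) {
      double dx = xyzA(i, 0) - xyzB(j, 0);
      double dy = xyzA(i, 1) - xyzB(j, 1);
      double dz = xyzA(i, 2) - xyzB(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > PAIR_CUTOFF * PAIR_CUTOFF) continue;
      double d = std::sqrt(d2);
      if (d < 1e-6) d = 1e-6;
      double e = w_lj * lj_term(d, radA[i] + radB[j],
                                std::sqrt(epsA[i] * epsB[j]),
                                clash_cap, &clashed);
      e += hb_term(d, donA[i] && accB[j], accA[i] && donB[j], w_hb);
      e += coul_term(d, qA[i], qB[j], w_coul);
      ei += e;
    }
    perA[i] = ei;
    total += ei;
  }
  return List::create(_["total"] = total, _["per_atom"] = perA,
                      _["clashed"] = clashed);
}

// Full-system energy with bonded exclusions: pairs within the same residue
// are skipped, as are backbone-backbone pairs of chain-adjacent residues
// (the peptide-bond neighbourhood, which is fixed geometry here). Adds the
// burial penalty for polar atoms. Returns per-atom solvation for
// decomposition.
// [[Rcpp::export]]
List cpp_energy_full(NumericMatrix xyz, NumericVector rad, NumericVector eps,
                     NumericVector q, LogicalVector don, LogicalVector acc,
                     LogicalVector polar, IntegerVector residx,
                     IntegerVector chainidx, LogicalVector backbone,
                     double w_lj, double w_hb, double w_coul, double w_solv,
                     double clash_cap) {
  int n = xyz.nrow();
  double pair_total = 0.0;
  bool clashed = false;
  NumericVector ncount(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < SOLV_RADIUS * SOLV_RADIUS &&
          !(chainidx[i] == chainidx[j] && residx[i] == residx[j])) {
        ncount[i] += 1.0;
        ncount[j] += 1.0;
      }
      if (d2 > PAIR_CUTOFF * PAIR_CUTOFF) continue;
      bool same_chain = chainidx[i] == chainidx[j];
      if (same_chain && residx[i] == residx[j]) continue;
      if (same_chain && std::abs(residx[i] - residx[j]) == 1 &&
          backbone[i] && backbone[j]) continue;
      double d = std::sqrt(d2);
      if (d < 1e-6) d = 1e-6;
      double e = w_lj * lj_term(d, rad[i] + rad[j],
                                std::sqrt(eps[i] * eps[j]),
                                clash_cap, &clashed);
      e += hb_term(d, don[i] && acc[j], acc[i] && don[j], w_hb);
      e += coul_term(d, q[i], q[j], w_coul);
      pair_total += e;
    }
  }
  NumericVector solv(n);
  double solv_total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (polar[i] && ncount[i] > SOLV_THRESH) {
      solv[i] = w_solv * (ncount[i] - SOLV_THRESH);
      solv_total += solv[i];
    }
  }
  return List::create(_["total"] = pair_total + solv_total,
                      _["pair"] = pair_total, _["solv"] = solv_total,
                      _["solv_per_atom"] = solv, _["clashed"] = clashed);
}

// Shrake-Rupley accessible surface area. `points` is a fixed unit-sphere
// point set (n_points x 3), supplied by the caller so results are
// deterministic.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector rad, double probe,
                       NumericMatrix points) {
  int n = xyz.nrow(), np = points.nrow();
  NumericVector area(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, rad[i]);
  for (int i = 0; i < n; ++i) {
    double ri = rad[i] + probe;
    // neighbour prefilter
    std::vector<int> nb;
    double reach = ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz < reach * reach) nb.push_back(j);
    }
    int accessible = 0;
    for (int p = 0; p < np; ++p) {
      double px = xyz(i, 0) + ri * points(p, 0);
      double py = xyz(i, 1) + ri * points(p, 1);
      double pz = xyz(i, 2) + ri * points(p, 2);
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double rj = rad[j] + probe;
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * accessible / np;
  }
  return area;
}
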