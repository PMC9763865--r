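#include <Rcpp.h>
using namespace Rcpp;

static inline int draw_int(int n) {
  int k;
  do {
    k = (int)(unif_rand() * n);
  } while (k >= n);
  return k;
}

// Total lattice energy in units of J: E = -sum_<ij> s_i s_j over the
// right and down bonds of every site (periodic boundaries). Integer exact.
// [[Rcpp::export]]
int ising_energy_cpp(IntegerMatrix spins) {
  int L1 = spins.nrow(), L2 = spins.ncol();
  long long e = 0;
  for (int i = 0; i < L1; ++i) {
    int id = (i + 1) % L1;
    for (int j = 0; j < L2; ++j) {
      int jr = (j + 1) % L2;
      e -= (long long)spins(i, j) * (spins(id, j) + spins(i, jr));
    }
  }
  return (int)e;
}

// Kawasaki-Metropolis dynamics: each proposal picks a uniformly random
// site and a uniformly random nearest-neighbour direction. Proposals
// touching a frozen (inclusion) site, or an equal-spin pair, are no-ops;
// an opposite-spin mobile pair is exchanged with probability
// min(1, exp(-dE / T)), dE from the standard Ising Hamiltonian including
// bonds to frozen sites. Mobile composition is exactly conserved.
//
// Runs n_sweeps sweeps (one sweep = L^2 proposals). Energy is tracked
// incrementally and recorded once per sweep; spin snapshots are taken
// every snapshot_every sweeps (0 = none).
// [[Rcpp::export]]
List ising_run_cpp(IntegerMatrix spins_in, LogicalMatrix frozen,
                   double temp, int n_sweeps, int snapshot_every) {
  IntegerMatrix spins = clone(spins_in);
  int L1 = spins.nrow(), L2 = spins.ncol();
  int nsite = L1 * L2;
  long long E = ising_energy_cpp(spins);
  long long accepted = 0;

  int n_snap = (snapshot_every > 0) ? n_sweeps / snapshot_every : 0;
  IntegerVector snaps(n_snap > 0 ? (R_xlen_t)n_snap * nsite : 0);
  NumericVector energies(n_sweeps + 1);
  energies[0] = (double)E;

  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  int snap_k = 0;

  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int p = 0; p < nsite; ++p) {
      int idx = draw_int(nsite);
      int i = idx % L1, j = idx / L1;
      int d = draw_int(4);
      int i2 = (i + di[d] + L1) % L1;
      int j2 = (j + dj[d] + L2) % L2;
      if (frozen(i, j) || frozen(i2, j2)) continue;
      int sa = spins(i, j), sb = spins(i2, j2);
      if (sa == sb) continue;
      // neighbour sums excluding the partner site
      int ha = 0, hb = 0;
      for (int k = 0; k < 4; ++k) {
        int ni = (i + di[k] + L1) % L1, nj = (j + dj[k] + L2) % L2;
        if (!(ni == i2 && nj == j2)) ha += spins(ni, nj);
        ni = (i2 + di[k] + L1) % L1; nj = (j2 + dj[k] + L2) % L2;
        if (!(ni == i && nj == j)) hb += spins(ni, nj);
      }
      int dE = (sa - sb) * (ha - hb);  // energy change of the exchange
      bool acc;
      if (dE <= 0) acc = true;
      else if (!R_finite(temp)) acc = true;         // T -> infinity
      else if (temp <= 0.0) acc = false;            // T -> 0 quench
      else acc = (unif_rand() < std::exp(-dE / temp));
      if (acc) {
        spins(i, j) = sb;
        spins(i2, j2) = sa;
        E += dE;
        accepted++;
      }
    }
    energies[sw + 1] = (double)E;
    if (snapshot_every > 0 && (sw + 1) % snapshot_every == 0 && snap_k < n_snap) {
      std::copy(spins.begin(), spins.end(),
                snaps.begin() + (R_xlen_t)snap_k * nsite);
      snap_k++;
    }
  }

  List out = List::create(
    _["spins"] = spins,
    _["energy"] = (double)E,
    _["energies"] = energies,
    _["accepted"] = (double)accepted);
  if (n_snap > 0) {
    snaps.attr("dim") = IntegerVector::create(L1, L2, n_snap);
    out["snapshots"] = snaps;
  }
  return out;
}

// Raw proposal-level driver (n_props single Kawasaki proposals, no
// sweep bookkeeping). Used for the single-step operation and for exact
// energy/conservation checks.
// [[Rcpp::export]]
List ising_steps_cpp(IntegerMatrix spins_in, LogicalMatrix frozen,
                     double temp, double n_props) {
  IntegerMatrix spins = clone(spins_in);
  int L1 = spins.nrow(), L2 = spins.ncol();
  int nsite = L1 * L2;
  long long E = ising_energy_cpp(spins);
  long long accepted = 0;
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  for (double p = 0; p < n_props; p += 1.0) {
    int idx = draw_int(nsite);
    int i = idx % L1, j = idx / L1;
    int d = draw_int(4);
    int i2 = (i + di[d] + L1) % L1;
    int j2 = (j + dj[d] + L2) % L2;
    if (frozen(i, j) || frozen(i2, j2)) continue;
    int sa = spins(i, j), sb = spins(i2, j2);
    if (sa == sb) continue;
    int ha = 0, hb = 0;
    for (int k = 0; k < 4; ++k) {
      int ni = (i + di[k] + L1) % L1, nj = (j + dj[k] + L2) % L2;
      if (!(ni == i2 && nj == j2)) ha += spins(ni, nj);
      ni = (i2 + di[k] + L1) % L1; nj = (j2 + dj[k] + L2) % L2;
      if (!(ni == i && nj == j)) hb += spins(ni, nj);
    }
    int dE = (sa - sb) * (ha - hb);
    bool acc;
    if (dE <= 0) acc = true;
    else if (!R_finite(temp)) acc = true;
    else if (temp <= 0.0) acc = false;
    else acc = (unif_rand() < std::exp(-dE / temp));
    if (acc) {
      spins(i, j) = sb;
      spins(i2, j2) = sa;
      E += dE;
      accepted++;
    }
  }
  return List::create(_["spins"] = spins,
                      _["energy"] = (double)E,
                      _["accepted"] = (double)accepted);
}
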