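#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG stream (respects set.seed()).
static inline int draw_int(int n) {
  int k;
  do {
    k = (int)(unif_rand() * n);
  } while (k >= n);
  return k;
}

// slot index -> molecule type given current counts; molecules are
// exchangeable so slots [0, nI) are inactive, [nI, nI+nP) primed,
// [nI+nP, N) active, [N, M) empty.
static inline int slot_type(int idx, int nI, int nP, int N) {
  if (idx < nI) return 0;       // Lck_I
  if (idx < nI + nP) return 1;  // Lck_P
  if (idx < N) return 2;        // Lck_A
  return 3;                     // empty slot
}

// Advance the three-state trans-autophosphorylation chain by n_cycles
// pair-draw events. One cycle: two distinct arena slots drawn uniformly;
// if both are occupied the pair reacts:
//   any Lck_I in the pair -> Lck_P with prob p_prime (independently),
//   (P,P) -> (P,A) with prob p_PA,
//   (P,A) -> (A,A) with prob p_AA,
//   all other pairings (and draws hitting an empty slot) are no-ops.
// Total molecule number is conserved by construction. Returns
// (n_I, n_P, n_A, fired_PA, fired_AA) where the last two count realized
// firings of the P+P and P+A activation reactions.
// [[Rcpp::export]]
IntegerVector kinase_run_cpp(int nI, int nP, int nA, int M,
                             double p_prime, double p_PA, double p_AA,
                             int n_cycles) {
  int N = nI + nP + nA;
  int fPA = 0, fAA = 0;
  for (int c = 0; c < n_cycles; ++c) {
    int a = draw_int(M);
    int b = draw_int(M - 1);
    if (b >= a) b++;
    int ta = slot_type(a, nI, nP, N);
    int tb = slot_type(b, nI, nP, N);
    if (ta == 3 || tb == 3) continue;  // empty slot drawn
    if (ta == 0 || tb == 0) {
      if (ta == 0 && unif_rand() < p_prime) { nI--; nP++; }
      if (tb == 0 && unif_rand() < p_prime) { nI--; nP++; }
    } else if (ta == 1 && tb == 1) {
      if (unif_rand() < p_PA) { nP--; nA++; fPA++; }
    } else if (ta + tb == 3) {  // one P, one A
      if (unif_rand() < p_AA) { nP--; nA++; fAA++; }
    }
    // (A,A): no reaction
  }
  return IntegerVector::create(nI, nP, nA, fPA, fAA);
}

// Replicated terminal states from the all-inactive initial condition.
// Returns an n_reps x 5 matrix of (n_I, n_P, n_A, fired_PA, fired_AA).
//
// Uses an exact reformulation of the cycle loop: occupancy never changes,
// so the number of cycles in which both drawn slots are occupied is
// Binomial(n_cycles, N(N-1)/(M(M-1))); only those reactive cycles are
// simulated (two distinct molecules drawn uniformly). Runs stop early
// once the all-active absorbing state is reached.
// [[Rcpp::export]]
IntegerMatrix kinase_simulate_cpp(int N, int M,
                                  double p_prime, double p_PA, double p_AA,
                                  int n_cycles, int n_reps) {
  IntegerMatrix out(n_reps, 5);
  double q = (double)N * (N - 1) / ((double)M * (M - 1));
  for (int r = 0; r < n_reps; ++r) {
    int nI = N, nP = 0, nA = 0, fPA = 0, fAA = 0;
    int K = (N >= 2) ? (int)R::rbinom((double)n_cycles, q) : 0;
    for (int c = 0; c < K; ++c) {
      if (nA == N) break;  // absorbing: everything active
      if (nI == 0 && (nP == 0 || (p_PA == 0.0 && p_AA == 0.0))) break;
      if (nI == 0 && nA == 0 && p_PA == 0.0) break;  // P-only, PP blocked
      int a = draw_int(N);
      int b = draw_int(N - 1);
      if (b >= a) b++;
      int ta = slot_type(a, nI, nP, N);
      int tb = slot_type(b, nI, nP, N);
      if (ta == 0 || tb == 0) {
        if (ta == 0 && unif_rand() < p_prime) { nI--; nP++; }
        if (tb == 0 && unif_rand() < p_prime) { nI--; nP++; }
      } else if (ta == 1 && tb == 1) {
        if (unif_rand() < p_PA) { nP--; nA++; fPA++; }
      } else if (ta + tb == 3) {
        if (unif_rand() < p_AA) { nP--; nA++; fAA++; }
      }
    }
    out(r, 0) = nI; out(r, 1) = nP; out(r, 2) = nA;
    out(r, 3) = fPA; out(r, 4) = fAA;
  }
  return out;
}
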