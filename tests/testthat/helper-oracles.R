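# Independent oracles used by the test suite. These deliberately do not
# share code with the package implementation.

# --- kinase model: exact Markov-chain enumeration ------------------------
# State space: (n_I, n_P, n_A) with fixed total N in an arena of M slots.
# One cycle draws an unordered pair of distinct slots; transition
# probabilities follow from hypergeometric pair-type counts.
kinase_states <- function(N) {
  out <- list()
  for (i in 0:N) for (p in 0:(N - i)) out[[length(out) + 1]] <- c(i, p, N - i - p)
  do.call(rbind, out)
}

kinase_transition_matrix <- function(N, M, p_prime, p_PA, p_AA) {
  st <- kinase_states(N)
  ns <- nrow(st)
  key <- function(i, p) paste(i, p)
  idx <- stats::setNames(seq_len(ns), key(st[, 1], st[, 2]))
  Tm <- matrix(0, ns, ns)
  tot_pairs <- choose(M, 2)
  add <- function(Tm, from, i2, p2, pr) {
    to <- idx[[key(i2, p2)]]
    Tm[from, to] <- Tm[from, to] + pr
    Tm
  }
  for (s in seq_len(ns)) {
    i <- st[s, 1]; p <- st[s, 2]; a <- st[s, 3]
    stay <- 1
    # (I, I): each inactive partner converts independently
    q <- choose(i, 2) / tot_pairs
    if (q > 0) {
      Tm <- add(Tm, s, i - 2, p + 2, q * p_prime^2)
      Tm <- add(Tm, s, i - 1, p + 1, q * 2 * p_prime * (1 - p_prime))
      Tm <- add(Tm, s, i, p, q * (1 - p_prime)^2)
      stay <- stay - q
    }
    # (I, P) and (I, A): the inactive converts
    q <- (i * p + i * a) / tot_pairs
    if (q > 0) {
      Tm <- add(Tm, s, i - 1, p + 1, q * p_prime)
      Tm <- add(Tm, s, i, p, q * (1 - p_prime))
      stay <- stay - q
    }
    # (P, P)
    q <- choose(p, 2) / tot_pairs
    if (q > 0) {
      Tm <- add(Tm, s, i, p - 1, q * p_PA)
      Tm <- add(Tm, s, i, p, q * (1 - p_PA))
      stay <- stay - q
    }
    # (P, A)
    q <- (p * a) / tot_pairs
    if (q > 0) {
      Tm <- add(Tm, s, i, p - 1, q * p_AA)
      Tm <- add(Tm, s, i, p, q * (1 - p_AA))
      stay <- stay - q
    }
    # (A, A) and empty-slot draws: no-op
    Tm[s, s] <- Tm[s, s] + stay
  }
  list(states = st, matrix = Tm, index = idx)
}

# exact state distribution after n_cycles from a given start
kinase_enum_dist <- function(N, M, p_prime, p_PA, p_AA, n_cycles,
                             init = c(N, 0, 0)) {
  tm <- kinase_transition_matrix(N, M, p_prime, p_PA, p_AA)
  v <- numeric(nrow(tm$states))
  v[tm$index[[paste(init[1], init[2])]]] <- 1
  for (k in seq_len(n_cycles)) v <- as.numeric(v %*% tm$matrix)
  list(states = tm$states, prob = v)
}

# --- Ising 4x4: exhaustive fixed-composition enumeration -----------------
# All C(16, 8) = 12870 half-filled configurations of a 4x4 periodic
# lattice, their exact energies, and Boltzmann energy-level probabilities.
ising4_enumeration <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    L <- 4
    combs <- utils::combn(16, 8)
    ncfg <- ncol(combs)
    S <- matrix(-1L, 16, ncfg)
    S[cbind(as.vector(combs), rep(seq_len(ncfg), each = 8))] <- 1L
    # bond list (right and down neighbours, periodic), column-major (i, j)
    id <- function(i, j) (j - 1) * L + i
    b1 <- integer(0); b2 <- integer(0)
    for (j in 1:L) for (i in 1:L) {
      b1 <- c(b1, id(i, j), id(i, j))
      b2 <- c(b2, id(i %% L + 1, j), id(i, j %% L + 1))
    }
    E <- -colSums(S[b1, ] * S[b2, ])
    cache <<- list(energies = E)
    cache
  }
})

ising4_level_probs <- function(temp) {
  en <- ising4_enumeration()$energies
  w <- exp(-(en - min(en)) / temp)
  p <- tapply(w, en, sum)
  p <- p / sum(p)
  data.frame(E = as.numeric(names(p)), prob = as.numeric(p))
}

# --- Otsu: brute force over all candidate cuts ---------------------------
otsu_brute_force <- function(x) {
  x <- as.numeric(x)
  cand <- sort(unique(x))
  cand <- (head(cand, -1) + tail(cand, -1)) / 2
  best_t <- NA_real_; best_v <- -Inf
  for (t in cand) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# --- misc fixtures -------------------------------------------------------
# hand-built background-subtracted binned curve
fake_binned_curve <- function(x, y) {
  df <- data.frame(bin_id = seq_along(x), lckT_med = x, lckA_med = y,
                   n_events = 100L, lckT_bkg = 0, lckA_bkg = 0,
                   lckT_net = x, lckA_net = y, flag_negative = FALSE)
  class(df) <- c("binned_curve", "data.frame")
  df
}

# constant-channel event table
const_events <- function(n, lckT, lckA, violet = 100) {
  ev <- data.frame(cell_id = seq_len(n), lckT = lckT, lckA = lckA,
                   violet = violet)
  class(ev) <- c("event_table", "data.frame")
  ev
}
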