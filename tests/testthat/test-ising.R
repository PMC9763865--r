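test_that("critical temperature is the exact self-dual point", {
  tc <- critical_temperature()
  expect_equal(tc, 2 / log(1 + sqrt(2)), tolerance = 1e-14)
  expect_equal(sinh(2 / tc)^2, 1, tolerance = 1e-12)
  expect_lt(tc, 2.28)
})

test_that("configurations have exact composition and are seed-deterministic", {
  lat <- gen_ising_config(4, 0.5, seed = 1)
  expect_equal(sum(lat$spins == 1L), 8)
  expect_equal(sum(lat$spins == -1L), 8)
  expect_identical(gen_ising_config(16, 0.5, seed = 3)$spins,
                   gen_ising_config(16, 0.5, seed = 3)$spins)
  expect_true(all(gen_ising_config(6, 1, seed = 2)$spins == 1L))
  lat2 <- gen_ising_config(10, 0.37, seed = 4)
  expect_equal(sum(lat2$spins == 1L), round(0.37 * 100))
  expect_error(gen_ising_config(8, 0), "composition")
  expect_error(gen_ising_config(8, 1.2), "composition")
  expect_error(gen_ising_config(5, 0.5), "even")
})

test_that("Kawasaki dynamics conserve composition and track energy exactly", {
  lat <- gen_ising_config(24, 0.5, seed = 7)
  m0 <- sum(lat$spins)
  set.seed(8)
  out <- kawasaki_step(lat, 1e5)
  expect_identical(sum(out$spins), m0)                      # bitwise integer
  expect_identical(attr(out, "energy"), as.numeric(lattice_energy(out)))
  # off-critical composition conserved too
  lat2 <- gen_ising_config(20, 0.3, seed = 9)
  set.seed(10)
  out2 <- kawasaki_step(lat2, 5e4)
  expect_identical(sum(out2$spins), sum(lat2$spins))
})

test_that("sampled energies follow the exact fixed-composition Boltzmann law", {
  # 4x4 half-filled lattice: exhaustive enumeration of all 12870 states
  temp <- 2.28
  exact <- ising4_level_probs(temp)
  lat <- gen_ising_config(4, 0.5, temp = temp, seed = 21)
  set.seed(22)
  burn <- ising_run(lat, 500)
  run <- ising_run(burn$lattice, 40000)
  en <- run$energies[-1]
  # batch means give an autocorrelation-robust standard error
  n_batch <- 40
  bsize <- length(en) %/% n_batch
  for (lev in exact$E[exact$prob > 0.002]) {
    ind <- as.numeric(en == lev)
    phat <- mean(ind)
    bm <- vapply(seq_len(n_batch), function(b)
      mean(ind[((b - 1) * bsize + 1):(b * bsize)]), numeric(1))
    se <- sd(bm) / sqrt(n_batch)
    pex <- exact$prob[exact$E == lev]
    expect_lt(abs(phat - pex), 3 * se + 1e-4,
              label = sprintf("energy level %g", lev))
  }
})

test_that("zero-temperature quench is monotone towards phase separation", {
  lat <- gen_ising_config(16, 0.5, temp = 0, seed = 31)
  set.seed(32)
  run <- ising_run(lat, 300)
  expect_true(all(diff(run$energies) <= 0))
  expect_lt(run$energies[length(run$energies)], run$energies[1])
})

test_that("infinite temperature accepts every opposite-spin exchange", {
  lat <- gen_ising_config(12, 0.5, temp = Inf, seed = 33)
  set.seed(34)
  r <- ising_steps_cpp <- kawasaki_step(lat, 2000)
  # at T -> infinity roughly half of all proposals hit an opposite pair;
  # far more exchanges must be accepted than the near-critical run accepts
  expect_gt(attr(r, "accepted") / 2000, 0.3)
})

test_that("discs freeze the right sites and survive dynamics untouched", {
  lat <- gen_ising_config(64, 0.5, seed = 41)
  disc <- ising_disc(c(20, 30), 3, 1L)
  lat <- place_disc(lat, disc, seed = 42)
  # brute-force geometry oracle
  cnt <- 0
  for (i in 1:64) for (j in 1:64)
    if ((i - 20)^2 + (j - 30)^2 <= 9) cnt <- cnt + 1
  expect_equal(sum(lat$frozen), cnt)
  expect_true(all(lat$spins[lat$frozen] == 1L))
  # composition of mobile sites restored to the target
  expect_equal(sum(lat$spins[!lat$frozen] == 1L),
               round(0.5 * sum(!lat$frozen)))
  # immutability under dynamics
  set.seed(43)
  out <- ising_run(lat, 500)
  expect_true(all(out$lattice$spins[lat$frozen] == 1L))
  # sub-unit radius yields a single frozen site
  lat2 <- gen_ising_config(10, 0.5, seed = 44)
  lat2 <- place_disc(lat2, ising_disc(c(5, 5), 0.4), seed = 45)
  expect_equal(sum(lat2$frozen), 1)
  # overlapping discs rejected
  expect_error(place_disc(lat, ising_disc(c(21, 30), 2)), "overlaps")
})

test_that("dynamics are reversible (detailed balance) on a small lattice", {
  # under detailed balance the stationary flux i -> j equals j -> i;
  # compare forward and backward transition counts between energy levels
  lat <- gen_ising_config(4, 0.5, seed = 51)
  set.seed(52)
  run <- ising_run(lat, 20000)
  en <- run$energies
  from <- en[-length(en)]; to <- en[-1]
  moved <- from != to
  key_f <- paste(from[moved], to[moved])
  key_b <- paste(to[moved], from[moved])
  tab <- table(key_f)
  for (k in names(tab)) {
    nf <- tab[[k]]
    nb <- sum(key_f == strsplit(k, " ")[[1]] |> rev() |> paste(collapse = " "))
    if (nf + nb < 50) next
    expect_lt(abs(nf - nb), 4 * sqrt(nf + nb),
              label = sprintf("transition %s", k))
  }
})

test_that("a black-preferring disc gathers an annulus at T = 2.28 but not at T = Inf", {
  make_run <- function(temp, seed) {
    lat <- gen_ising_config(64, 0.5, temp = temp, seed = seed)
    disc <- ising_disc(c(32, 32), 4, 1L)
    lat <- place_disc(lat, disc, seed = seed + 1)
    set.seed(seed + 2)
    burn <- ising_run(lat, 1000)
    run <- ising_run(burn$lattice, 1000, snapshot_every = 10)
    radial_composition(run$snapshots, run$lattice, disc)
  }
  prof <- make_run(2.28, 61)
  bulk <- attr(prof, "bulk_mean")
  z <- (prof$mean_spin[1] - bulk) /
    sqrt(prof$se[1]^2 + attr(prof, "bulk_se")^2)
  expect_gt(z, qnorm(0.99))            # enrichment, alpha = 0.01
  # profile decays towards bulk: first shell strongest, within noise
  expect_gt(prof$mean_spin[1], prof$mean_spin[3] - 2 * prof$se[3])
  expect_gt(prof$mean_spin[2], prof$mean_spin[4] - 2 * prof$se[4])

  prof_inf <- make_run(Inf, 71)
  z_inf <- abs(prof_inf$mean_spin[1] - attr(prof_inf, "bulk_mean")) /
    sqrt(prof_inf$se[1]^2 + attr(prof_inf, "bulk_se")^2)
  expect_lt(z_inf, 3)                  # no enrichment in the athermal limit
})

test_that("annulus machinery shows no enrichment at a random bulk reference", {
  lat <- gen_ising_config(64, 0.5, temp = 2.28, seed = 81)
  set.seed(82)
  burn <- ising_run(lat, 500)
  run <- ising_run(burn$lattice, 1000, snapshot_every = 10)
  ref <- ising_disc(c(17, 44), 4, 1L)   # nothing is actually frozen here
  prof <- radial_composition(run$snapshots, run$lattice, ref)
  z <- abs(prof$mean_spin[1] - attr(prof, "bulk_mean")) /
    sqrt(prof$se[1]^2 + attr(prof, "bulk_se")^2)
  expect_lt(z, 3)
})

test_that("correlation functions behave across temperature", {
  runs <- function(temp, seed, sweeps = 2000) {
    lat <- gen_ising_config(64, 0.5, temp = temp, seed = seed)
    set.seed(seed + 1)
    burn <- ising_run(lat, 1000)
    ising_run(burn$lattice, sweeps, snapshot_every = 20)$snapshots
  }
  c5 <- correlation_length(runs(5, 91))
  # C(0) equals the (population) spin variance: exactly 1 at half filling
  expect_equal(c5$C[c5$r == 0], 1, tolerance = 1e-12)
  expect_lt(c5$xi, 2)                  # far above Tc: molecular-scale xi
  # single-run xi estimates near Tc are noisy (conserved dynamics relax
  # slowly); compare seed-averaged estimates
  xi_mean <- function(temp, seeds)
    mean(vapply(seeds, function(s) correlation_length(runs(temp, s))$xi,
                numeric(1)))
  x5 <- xi_mean(5, c(91, 121, 151, 181))
  x24 <- xi_mean(2.4, c(93, 123, 153, 183))
  x228 <- xi_mean(2.28, c(95, 125, 155, 185))
  expect_lt(x5, 2)
  expect_gt(x24, x5)
  expect_gt(x228, x24)                 # xi grows approaching Tc from above
})

test_that("frozen disc pairs sit at a fixed separation", {
  lat <- gen_ising_config(24, 0.5, temp = 2.28, seed = 101)
  lat <- place_disc(lat, ising_disc(c(12, 8), 2, 1L), seed = 102)
  lat <- place_disc(lat, ising_disc(c(12, 16), 2, 1L), seed = 103)
  set.seed(104)
  st <- pair_contact_stats(lat, n_sweeps = 50, burn_in = 10,
                           mobile_discs = FALSE)
  expect_equal(length(unique(st$separations)), 1)
  expect_equal(st$mean_separation, 4)
})

test_that("like discs stay in contact more than unlike discs near criticality", {
  run_pair <- function(phase_b, seed, temp) {
    lat <- gen_ising_config(24, 0.5, temp = temp, seed = seed)
    lat <- place_disc(lat, ising_disc(c(12, 10), 2, 1L), seed = seed + 100)
    lat <- place_disc(lat, ising_disc(c(12, 17), 2, phase_b),
                      seed = seed + 200)
    set.seed(seed + 300)
    pair_contact_stats(lat, n_sweeps = 500, burn_in = 100,
                       moves_per_sweep = 4)$contact_freq
  }
  seeds <- 1:20
  like <- vapply(seeds, function(s) run_pair(1L, s, 2.28), numeric(1))
  unlike <- vapply(seeds, function(s) run_pair(-1L, s, 2.28), numeric(1))
  expect_gt(mean(like), mean(unlike))
  expect_lt(t.test(like, unlike, alternative = "greater")$p.value, 0.05)
})

test_that("contact frequencies are indistinguishable in the athermal limit", {
  run_pair <- function(phase_b, seed) {
    lat <- gen_ising_config(24, 0.5, temp = Inf, seed = seed)
    lat <- place_disc(lat, ising_disc(c(12, 10), 2, 1L), seed = seed + 100)
    lat <- place_disc(lat, ising_disc(c(12, 17), 2, phase_b),
                      seed = seed + 200)
    set.seed(seed + 300)
    pair_contact_stats(lat, n_sweeps = 250, burn_in = 50,
                       moves_per_sweep = 4)$contact_freq
  }
  like <- vapply(1:8, function(s) run_pair(1L, s), numeric(1))
  unlike <- vapply(1:8, function(s) run_pair(-1L, s), numeric(1))
  expect_gt(t.test(like, unlike)$p.value, 0.01)
})
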