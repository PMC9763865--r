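#' Exact critical temperature of the 2-D square-lattice Ising model
#'
#' \code{2 / log(1 + sqrt(2))} in units of J/kB (about 2.269), from the
#' Kramers-Wannier self-duality condition \code{sinh(2J/Tc)^2 = 1}. The
#' membrane simulations run just above this, at T = 2.28, in the
#' weak-segregation (near-critical) regime.
#'
#' @return the critical temperature in J/kB units.
#' @export
critical_temperature <- function() 2 / log(1 + sqrt(2))

#' Random fixed-composition Ising configuration
#'
#' Spins are +1 ("black" phase, the protein-preferred lipid phase) or -1
#' ("white"), with exactly \code{round(composition * L^2)} black sites
#' placed uniformly at random: a canonical (conserved-composition) lipid
#' mixture. The critical composition is 0.5, both phases equally abundant.
#'
#' @param L lattice side length (periodic boundaries). Must be even when
#'   \code{composition} is exactly 0.5.
#' @param composition black-phase fraction in (0, 1].
#' @param temp temperature in J/kB units (default 2.28, just above
#'   [critical_temperature()]).
#' @param seed RNG seed.
#' @return an object of class \code{ising_lattice}: \code{L}, \code{spins}
#'   (L x L matrix of +/-1), \code{frozen} (logical matrix), \code{temp},
#'   \code{composition}, \code{discs}.
#' @export
gen_ising_config <- function(L, composition = 0.5, temp = 2.28, seed = NULL) {
  if (composition <= 0 || composition > 1)
    stopf("composition must lie in (0, 1]")
  if (composition == 0.5 && L %% 2 == 1)
    stopf("L must be even at the exact critical composition 0.5")
  n <- L * L
  n_black <- round(composition * n)
  spins <- with_seed(seed, {
    s <- rep(-1L, n)
    s[sample.int(n, n_black)] <- 1L
    matrix(s, L, L)
  })
  structure(list(L = as.integer(L), spins = spins,
                 frozen = matrix(FALSE, L, L),
                 temp = temp, composition = composition,
                 discs = list()),
            class = "ising_lattice")
}

#' Total lattice energy
#' @param lattice an \code{ising_lattice}.
#' @return integer energy in units of J (ferromagnetic Hamiltonian
#'   \code{-J sum s_i s_j} over nearest-neighbour bonds, periodic).
#' @export
lattice_energy <- function(lattice) ising_energy_cpp(lattice$spins)

#' Single Kawasaki-Metropolis proposals
#'
#' Each proposal draws a uniformly random nearest-neighbour site pair;
#' opposite-spin mobile pairs are exchanged with probability
#' \code{min(1, exp(-dE/T))}. Equal-spin pairs and pairs touching a frozen
#' inclusion site are no-ops, so the mobile composition is exactly
#' conserved.
#'
#' @param lattice an \code{ising_lattice}.
#' @param n_steps number of proposals (default 1).
#' @return the updated lattice; attributes \code{"energy"} (incrementally
#'   tracked, units of J) and \code{"accepted"}.
#' @export
kawasaki_step <- function(lattice, n_steps = 1) {
  stopifnot(inherits(lattice, "ising_lattice"))
  r <- ising_steps_cpp(lattice$spins, lattice$frozen, lattice$temp, n_steps)
  lattice$spins <- r$spins
  attr(lattice, "energy") <- r$energy
  attr(lattice, "accepted") <- r$accepted
  lattice
}

#' Run Kawasaki dynamics for a number of sweeps
#'
#' One sweep is \code{L^2} proposals. Energy is recorded after every sweep
#' and spin snapshots every \code{snapshot_every} sweeps.
#'
#' @param lattice an \code{ising_lattice}.
#' @param n_sweeps number of sweeps.
#' @param snapshot_every snapshot interval in sweeps (0 = no snapshots).
#' @return a list with the updated \code{lattice}, \code{energies} (length
#'   \code{n_sweeps + 1}, starting energy first), \code{snapshots} (L x L x
#'   n array or NULL) and \code{accepted}.
#' @export
ising_run <- function(lattice, n_sweeps, snapshot_every = 0) {
  stopifnot(inherits(lattice, "ising_lattice"), n_sweeps >= 0)
  if (n_sweeps == 0)
    return(list(lattice = lattice,
                energies = ising_energy_cpp(lattice$spins),
                snapshots = NULL, accepted = 0))
  r <- ising_run_cpp(lattice$spins, lattice$frozen, lattice$temp,
                     as.integer(n_sweeps), as.integer(snapshot_every))
  lattice$spins <- r$spins
  list(lattice = lattice, energies = r$energies,
       snapshots = r$snapshots %||% NULL, accepted = r$accepted)
}

#' Protein inclusion disc
#'
#' A rigid disc of lattice sites representing a membrane-protein anchor
#' whose boundary condition is "filled with" one lipid phase.
#'
#' @param center numeric (row, col) centre in lattice units.
#' @param radius disc radius (>= 1); a site belongs to the disc when its
#'   centre lies within \code{radius} of the disc centre (periodic
#'   minimum-image distance).
#' @param preferred_phase +1 (black) or -1 (white).
#' @return an object of class \code{ising_disc}.
#' @export
ising_disc <- function(center, radius, preferred_phase = 1L) {
  if (radius <= 0) stopf("disc radius must be positive")
  if (!preferred_phase %in% c(-1L, 1L)) stopf("preferred_phase must be +/-1")
  structure(list(center = as.numeric(center), radius = radius,
                 preferred_phase = as.integer(preferred_phase)),
            class = "ising_disc")
}

# minimum-image displacement on a ring of length L
min_image <- function(d, L) d - L * round(d / L)

disc_site_matrix <- function(disc, L) {
  i <- rep(seq_len(L), times = L)
  j <- rep(seq_len(L), each = L)
  di <- min_image(i - disc$center[1], L)
  dj <- min_image(j - disc$center[2], L)
  cbind(i, j)[di^2 + dj^2 <= disc$radius^2, , drop = FALSE]
}

#' Freeze a disc inclusion into a lattice
#'
#' Disc sites are set to the preferred phase and frozen (excluded from
#' exchange proposals but still contributing bonds to the Hamiltonian —
#' the stated boundary condition). The mobile composition is re-balanced
#' to the lattice's target concentration over the remaining sites.
#'
#' @param lattice an \code{ising_lattice}.
#' @param disc an [ising_disc()].
#' @param seed optional seed for the re-balancing flips.
#' @return the lattice with the disc frozen in.
#' @export
place_disc <- function(lattice, disc, seed = NULL) {
  stopifnot(inherits(lattice, "ising_lattice"), inherits(disc, "ising_disc"))
  sites <- disc_site_matrix(disc, lattice$L)
  if (nrow(sites) == 0) stopf("disc covers no lattice site")
  if (any(lattice$frozen[sites])) stopf("disc overlaps an existing inclusion")
  lattice$spins[sites] <- disc$preferred_phase
  lattice$frozen[sites] <- TRUE
  # restore the target composition on mobile sites
  mobile <- which(!lattice$frozen)
  n_target <- round(lattice$composition * length(mobile))
  n_black <- sum(lattice$spins[mobile] == 1L)
  delta <- n_target - n_black
  if (delta != 0) {
    from <- if (delta > 0) -1L else 1L
    cand <- mobile[lattice$spins[mobile] == from]
    flip <- with_seed(seed, sample(cand, abs(delta)))
    lattice$spins[flip] <- -from
  }
  lattice$discs <- c(lattice$discs, list(disc))
  lattice
}

#' Mean lipid composition versus distance from a disc edge
#'
#' For an ensemble of equilibrated snapshots, bins mobile sites by their
#' distance from the disc edge (centre distance minus radius) and averages
#' the spin per bin; the bulk reference is the mean spin of sites farther
#' than L/4 from the disc centre. Near criticality a black-preferring disc
#' gathers a black-enriched annulus whose extent is set by the correlation
#' length.
#'
#' @param snapshots L x L x n array of spin snapshots (from [ising_run()]).
#' @param lattice the \code{ising_lattice} (for the frozen mask).
#' @param disc the [ising_disc()] of interest.
#' @param bin_width annulus bin width in lattice units.
#' @return a data.frame of class \code{annulus_profile} with columns
#'   \code{dist} (bin midpoint from the disc edge), \code{mean_spin},
#'   \code{se}, \code{n}; attributes \code{"bulk_mean"} and
#'   \code{"bulk_se"}.
#' @export
radial_composition <- function(snapshots, lattice, disc, bin_width = 1) {
  stopifnot(length(dim(snapshots)) == 3)
  L <- lattice$L
  i <- rep(seq_len(L), times = L)
  j <- rep(seq_len(L), each = L)
  di <- min_image(i - disc$center[1], L)
  dj <- min_image(j - disc$center[2], L)
  dc <- sqrt(di^2 + dj^2)
  edge <- dc - disc$radius
  mobile <- !as.vector(lattice$frozen)
  ns <- dim(snapshots)[3]
  flat <- matrix(snapshots, nrow = L * L, ncol = ns)

  keep <- mobile & edge >= 0
  bins <- floor(edge[keep] / bin_width)
  site_mean <- rowMeans(flat[keep, , drop = FALSE])
  agg <- split(site_mean, bins)
  if (any(vapply(agg, length, integer(1)) == 0))
    stopf("no mobile sites in a distance bin")
  prof <- data.frame(
    dist = (as.numeric(names(agg)) + 0.5) * bin_width,
    mean_spin = vapply(agg, mean, numeric(1)),
    se = vapply(agg, function(v) sd(v) / sqrt(length(v)), numeric(1)),
    n = vapply(agg, length, numeric(1)))
  bulk_sites <- mobile & dc > L / 4
  bulk_vals <- flat[bulk_sites, , drop = FALSE]
  attr(prof, "bulk_mean") <- mean(bulk_vals)
  attr(prof, "bulk_se") <- sd(rowMeans(bulk_vals)) / sqrt(sum(bulk_sites))
  class(prof) <- c("annulus_profile", "data.frame")
  prof
}

#' Correlation length of a disc-free near-critical ensemble
#'
#' Radially averaged connected pair correlation computed by FFT
#' autocorrelation, averaged over snapshots, then fitted to the
#' Ornstein-Zernike-like form \code{C(r) = A r^(-1/4) exp(-r / xi)} (the 2-D
#' Ising critical exponent eta = 1/4) by log-linear regression over
#' separations 1..L/4.
#'
#' @param snapshots L x L x n array of disc-free spin snapshots.
#' @param r_max maximum separation used in the fit (default L/4).
#' @return a list of class \code{correlation_result}: \code{r}, \code{C}
#'   (the radial correlation function, \code{C[r = 0]} equals the mean
#'   population spin variance), \code{xi}, \code{fit_r_squared}.
#' @export
correlation_length <- function(snapshots, r_max = NULL) {
  stopifnot(length(dim(snapshots)) == 3)
  L <- dim(snapshots)[1]
  ns <- dim(snapshots)[3]
  acc <- matrix(0, L, L)
  for (k in seq_len(ns)) {
    s <- snapshots[, , k]
    m <- mean(s)
    f <- fft(s)
    a <- Re(fft(Mod(f)^2, inverse = TRUE)) / (L * L) / (L * L)
    acc <- acc + (a - m^2)
  }
  acc <- acc / ns
  # radial average over integer minimum-image separations
  dx <- min_image(rep(seq_len(L) - 1, times = L), L)
  dy <- min_image(rep(seq_len(L) - 1, each = L), L)
  rr <- round(sqrt(dx^2 + dy^2))
  cvals <- tapply(as.vector(acc), rr, mean)
  r <- as.numeric(names(cvals))
  r_max <- r_max %||% floor(L / 4)
  # discard separations where the correlation has decayed into the noise
  # floor (about 1% of the nearest-neighbour value): including them biases
  # the fitted decay length upwards
  floor_c <- max(cvals[r >= 1], 0) / 100
  sel <- r >= 1 & r <= r_max & cvals > max(floor_c, 0)
  if (sum(sel) < 3) stopf("correlation fit failure: too few usable points")
  yy <- log(cvals[sel]) + 0.25 * log(r[sel])
  fit <- lm(yy ~ r[sel])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0)
    stopf("correlation fit failure: non-decaying correlations")
  structure(list(r = r, C = as.numeric(cvals), xi = -1 / unname(slope),
                 fit_r_squared = summary(fit)$r.squared),
            class = "correlation_result")
}

# candidate lattice after rigid translation of disc `which_disc` by (di, dj);
# returns NULL if the move collides with another inclusion
translate_disc <- function(lattice, which_disc, di, dj) {
  disc <- lattice$discs[[which_disc]]
  L <- lattice$L
  new_disc <- disc
  new_disc$center <- ((disc$center + c(di, dj) - 1) %% L) + 1
  old_sites <- disc_site_matrix(disc, L)
  new_sites <- disc_site_matrix(new_disc, L)
  key <- function(s) (s[, 1] - 1) * L + s[, 2]
  enter <- new_sites[!(key(new_sites) %in% key(old_sites)), , drop = FALSE]
  leave <- old_sites[!(key(old_sites) %in% key(new_sites)), , drop = FALSE]
  # collision: entering a site frozen by another disc
  frozen_other <- lattice$frozen
  frozen_other[old_sites] <- FALSE
  if (any(frozen_other[enter])) return(NULL)
  cand <- lattice
  # lipids displaced by the advancing edge fill the vacated wake
  displaced <- cand$spins[enter]
  cand$frozen[leave] <- FALSE
  cand$spins[leave] <- displaced
  cand$frozen[enter] <- TRUE
  cand$spins[enter] <- disc$preferred_phase
  cand$discs[[which_disc]] <- new_disc
  cand
}

disc_separation <- function(lattice) {
  stopifnot(length(lattice$discs) == 2)
  a <- lattice$discs[[1]]; b <- lattice$discs[[2]]
  d <- sqrt(sum(min_image(a$center - b$center, lattice$L)^2))
  d - a$radius - b$radius
}

#' Lateral proximity statistics of two inclusion discs
#'
#' Operationalizes the boundary-lipid proximity mechanism: two discs with
#' like or unlike preferred phases diffuse (rigid-translation Metropolis
#' moves, same Hamiltonian) through a near-critical Kawasaki mixture;
#' edge-to-edge separations are sampled and the contact frequency (fraction
#' of snapshots at separation <= \code{contact_cutoff}) reported. Like
#' discs share one lipid annulus and stay in contact more often than unlike
#' discs, which pay an interfacial penalty.
#'
#' @param lattice an \code{ising_lattice} containing exactly two discs
#'   (see [place_disc()]).
#' @param n_sweeps sampled sweeps after burn-in.
#' @param burn_in equilibration sweeps.
#' @param contact_cutoff edge separation (lattice units) counting as
#'   contact.
#' @param mobile_discs if FALSE the discs stay put (the separation
#'   distribution is then a point mass).
#' @param moves_per_sweep translation proposals per disc per sweep.
#' @return a list of class \code{contact_stats}: \code{contact_freq},
#'   \code{separations}, \code{mean_separation}, \code{lattice}.
#' @export
pair_contact_stats <- function(lattice, n_sweeps = 400, burn_in = 100,
                               contact_cutoff = 1, mobile_discs = TRUE,
                               moves_per_sweep = 1) {
  stopifnot(inherits(lattice, "ising_lattice"))
  if (length(lattice$discs) != 2)
    stopf("lattice must carry exactly two discs")
  run_sweep <- function(lat) {
    r <- ising_run_cpp(lat$spins, lat$frozen, lat$temp, 1L, 0L)
    lat$spins <- r$spins
    if (mobile_discs) {
      e_cur <- r$energy
      for (m in seq_len(moves_per_sweep)) {
        for (wd in 1:2) {
          dir <- sample(4L, 1L)
          di <- c(1, -1, 0, 0)[dir]; dj <- c(0, 0, 1, -1)[dir]
          cand <- translate_disc(lat, wd, di, dj)
          if (is.null(cand)) next
          if (disc_separation(cand) < 0) next   # discs must not overlap
          e_cand <- ising_energy_cpp(cand$spins)
          dE <- e_cand - e_cur
          acc <- if (dE <= 0) TRUE
                 else if (!is.finite(lat$temp)) TRUE
                 else runif(1) < exp(-dE / lat$temp)
          if (acc) {
            lat <- cand
            e_cur <- e_cand
          }
        }
      }
    }
    lat
  }
  for (s in seq_len(burn_in)) lattice <- run_sweep(lattice)
  seps <- numeric(n_sweeps)
  for (s in seq_len(n_sweeps)) {
    lattice <- run_sweep(lattice)
    seps[s] <- disc_separation(lattice)
  }
  structure(list(contact_freq = mean(seps <= contact_cutoff),
                 separations = seps,
                 mean_separation = mean(seps),
                 lattice = lattice),
            class = "contact_stats")
}
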