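#' Specification for synthetic two-colour flow-cytometry data
#'
#' Describes barcoded cell populations whose total-Lck expression is
#' log-normal, with active-Lck values generated from a known mean dose curve
#' plus multiplicative log-normal noise and additive autofluorescence
#' background. The defaults emulate a dye-barcoded 1:1:1 mix of three
#' populations (carrier control plus two dye concentrations roughly a
#' log-decade apart) measured alongside an induced Lck titration.
#'
#' The mean curve mapping total to active Lck can be either
#' \itemize{
#'   \item \code{curve = crossover_curve(alpha, kappa)}: the smooth
#'     quadratic-to-linear form \eqn{y = \alpha x^2 / (x + \kappa)}, or
#'   \item \code{kinase_params = model_params(...)}: the stochastic
#'     activation model, interpolated on a molecule grid and scaled by
#'     \code{fluor_per_molecule}.
#' }
#'
#' @param n_cells_per_population events per barcoded population.
#' @param lckT_log_mean,lckT_log_sd meanlog/sdlog of the log-normal total-Lck
#'   signal (arbitrary linear fluorescence units). The default sdlog of 0.9
#'   spans over 1.5 orders of magnitude, the dynamic range of a
#'   doxycycline-induced titration.
#' @param curve a [crossover_curve()] mean-curve description (used when
#'   \code{kinase_params} is NULL).
#' @param kinase_params optional [model_params()]; when given the mean curve
#'   comes from the stochastic model.
#' @param fluor_per_molecule fluorescence units per molecule used with
#'   \code{kinase_params}.
#' @param noise_cv multiplicative coefficient of variation applied to both
#'   measured channels (default 0.1, typical median-fluorescence
#'   measurement noise; note that x-channel noise attenuates downstream
#'   curve fits through the usual errors-in-variables shrinkage).
#' @param background_T,background_A median additive autofluorescence of the
#'   total/active channels.
#' @param background_cv CV of the log-normal background.
#' @param barcode_levels ordered (strictly increasing) dye-intensity medians,
#'   one per population.
#' @param barcode_cv CV of the dye intensity around each level.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return an object of class \code{fcm_gen_spec}.
#' @export
fcm_gen_spec <- function(n_cells_per_population = 10000,
                         lckT_log_mean = log(300), lckT_log_sd = 0.9,
                         curve = crossover_curve(),
                         kinase_params = NULL,
                         fluor_per_molecule = 10,
                         noise_cv = 0.1,
                         background_T = 15, background_A = 8,
                         background_cv = 0.3,
                         barcode_levels = c(50, 1000, 20000),
                         barcode_cv = 0.25,
                         seed = 1L) {
  if (n_cells_per_population < 1) stopf("n_cells_per_population must be >= 1")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (length(barcode_levels) < 1 || any(diff(barcode_levels) <= 0))
    stopf("barcode_levels must be strictly increasing")
  structure(list(n_cells_per_population = as.integer(n_cells_per_population),
                 lckT_log_mean = lckT_log_mean, lckT_log_sd = lckT_log_sd,
                 curve = curve, kinase_params = kinase_params,
                 fluor_per_molecule = fluor_per_molecule,
                 noise_cv = noise_cv,
                 background_T = background_T, background_A = background_A,
                 background_cv = background_cv,
                 barcode_levels = barcode_levels, barcode_cv = barcode_cv,
                 seed = seed),
            class = "fcm_gen_spec")
}

#' Quadratic-to-linear crossover dose curve
#'
#' \eqn{y = \alpha x^2 / (x + \kappa)}: quadratic for \eqn{x \ll \kappa},
#' linear with slope \eqn{\alpha} for \eqn{x \gg \kappa}.
#'
#' @param alpha asymptotic linear slope (active per total fluorescence).
#' @param kappa crossover scale in total-Lck fluorescence units.
#' @return an object of class \code{crossover_curve}; callable via
#'   [eval_curve()].
#' @export
crossover_curve <- function(alpha = 0.5, kappa = 300) {
  if (alpha < 0 || kappa <= 0) stopf("need alpha >= 0 and kappa > 0")
  structure(list(alpha = alpha, kappa = kappa), class = "crossover_curve")
}

#' Evaluate a mean dose curve at total-Lck fluorescence values
#' @param curve a \code{crossover_curve}.
#' @param x total-Lck values.
#' @return expected active-Lck values.
#' @export
eval_curve <- function(curve, x) {
  stopifnot(inherits(curve, "crossover_curve"))
  curve$alpha * x^2 / (x + curve$kappa)
}

# Mean-curve closure for a generator spec: either the analytic crossover
# form or an interpolated simulation of the stochastic model.
fcm_mean_fun <- function(spec) {
  if (is.null(spec$kinase_params)) {
    curve <- spec$curve
    function(x) eval_curve(curve, x)
  } else {
    kp <- spec$kinase_params
    fpm <- spec$fluor_per_molecule
    Ns <- unique(pmax(1L, as.integer(round(seq(1, kp$arena_size, length.out = 25)))))
    dr <- dose_response(kp, Ns)
    function(x) {
      N <- pmin(x / fpm, kp$arena_size)
      approx(c(0, dr$lckT), c(0, dr$lckA_mean), xout = pmax(N, 0),
             rule = 2)$y * fpm
    }
  }
}

#' Generate a synthetic per-event flow-cytometry table
#'
#' One row per cell with linear-scale total-Lck, active-Lck and barcode-dye
#' fluorescence. Active Lck is the mean-curve prediction at the cell's true
#' total Lck, perturbed by multiplicative log-normal noise, plus additive
#' background; the measured total-Lck channel receives the same noise and
#' background treatment. Ground-truth population labels and noise-free
#' values are attached as the \code{"truth"} attribute (and written as a
#' sidecar by [write_events()]).
#'
#' @param spec an [fcm_gen_spec()].
#' @return a data.frame of class \code{event_table} with columns
#'   \code{cell_id}, \code{lckT}, \code{lckA}, \code{violet}.
#' @export
gen_fcm_events <- function(spec) {
  stopifnot(inherits(spec, "fcm_gen_spec"))
  mean_fun <- fcm_mean_fun(spec)
  k <- length(spec$barcode_levels)
  n <- spec$n_cells_per_population
  with_seed(spec$seed, {
    pops <- lapply(seq_len(k), function(i) {
      lckT_true <- rlnorm(n, spec$lckT_log_mean, spec$lckT_log_sd)
      lckA_true <- mean_fun(lckT_true)
      lckT <- lckT_true * rlnorm_cv(n, spec$noise_cv) +
        rlnorm_med(n, spec$background_T, spec$background_cv)
      lckA <- lckA_true * rlnorm_cv(n, spec$noise_cv) +
        rlnorm_med(n, spec$background_A, spec$background_cv)
      violet <- rlnorm_med(n, spec$barcode_levels[i], spec$barcode_cv)
      data.frame(lckT = lckT, lckA = lckA, violet = violet,
                 label = i, lckT_true = lckT_true, lckA_true = lckA_true)
    })
    all <- do.call(rbind, pops)
    all$cell_id <- seq_len(nrow(all))
    ev <- all[, c("cell_id", "lckT", "lckA", "violet")]
    class(ev) <- c("event_table", "data.frame")
    attr(ev, "truth") <- all[, c("cell_id", "label", "lckT_true", "lckA_true")]
    ev
  })
}

#' Generate a background-only (uninduced / inhibitor-treated) control table
#'
#' Events carrying only autofluorescence on both channels, for use as the
#' background control of [subtract_background()].
#'
#' @param spec an [fcm_gen_spec()]; only the background fields, population
#'   size and seed are used.
#' @param seed optional seed override (defaults to \code{spec$seed + 1} so
#'   control draws are independent of the induced sample).
#' @return an \code{event_table}.
#' @export
gen_fcm_background <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fcm_gen_spec"))
  n <- spec$n_cells_per_population
  with_seed(seed %||% (spec$seed + 1L), {
    ev <- data.frame(cell_id = seq_len(n),
                     lckT = rlnorm_med(n, spec$background_T, spec$background_cv),
                     lckA = rlnorm_med(n, spec$background_A, spec$background_cv),
                     violet = rlnorm_med(n, spec$barcode_levels[1],
                                         spec$barcode_cv))
    class(ev) <- c("event_table", "data.frame")
    ev
  })
}

#' Write an event table as CSV (with ground-truth sidecar)
#'
#' @param events an \code{event_table}.
#' @param path output CSV path; when the table carries a \code{"truth"}
#'   attribute a \code{<path>.truth.csv} sidecar is written as well.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  tr <- attr(events, "truth")
  if (!is.null(tr)) write.csv(tr, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}
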