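#' Read a per-event table from CSV or FCS
#'
#' CSV is the canonical interchange format (one row per event, linear
#' fluorescence). FCS 3.0/3.1 files are supported read-only through a
#' minimal built-in parser; log-amplified channels are converted to linear
#' values using the file's $PnE amplification metadata.
#'
#' @param path input file.
#' @param format \code{"csv"} or \code{"fcs"} (default guessed from the file
#'   extension).
#' @param channels named character vector mapping the canonical channel
#'   names \code{lckT}, \code{lckA}, \code{violet} to column/parameter names
#'   in the file. Defaults to identity for CSV.
#' @return an \code{event_table} data.frame with columns \code{cell_id},
#'   \code{lckT}, \code{lckA}, \code{violet}.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        channels = c(lckT = "lckT", lckA = "lckA",
                                     violet = "violet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  dat <- if (format == "csv") {
    if (file.size(path) == 0) stopf("empty input file: %s", path)
    read.csv(path, check.names = FALSE)
  } else {
    read_fcs(path)
  }
  if (nrow(dat) == 0) stopf("no events in %s", path)
  missing <- setdiff(channels, colnames(dat))
  if (length(missing))
    stopf("channel(s) not found in %s: %s", path,
          paste(missing, collapse = ", "))
  ev <- data.frame(cell_id = seq_len(nrow(dat)),
                   lckT = dat[[channels[["lckT"]]]],
                   lckA = dat[[channels[["lckA"]]]],
                   violet = dat[[channels[["violet"]]]])
  if (anyNA(ev)) stopf("missing channel values in %s", path)
  if (any(ev$lckT < 0 | ev$lckA < 0 | ev$violet < 0))
    stopf("negative fluorescence after linearization in %s", path)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Demultiplex dye-barcoded populations
#'
#' Assigns each event to one of k populations by a one-dimensional Gaussian
#' mixture model on log barcode-dye intensity (EM with deterministic
#' quantile initialization; k-means fallback on EM failure). Labels are
#' ordered by increasing component median so label 1 is always the dimmest
#' population.
#'
#' @param events an \code{event_table} with a \code{violet} column.
#' @param k number of populations (default 3, a 1:1:1 barcoded mix).
#' @param min_separation minimum separation, in pooled within-component
#'   standard deviations, between adjacent fitted component means; below
#'   this the populations are declared unresolvable and an error is raised
#'   with diagnostics rather than silently mislabeling.
#' @return the events with an added integer \code{label} column; the fitted
#'   mixture is attached as attribute \code{"mixture"}.
#' @export
demultiplex_barcodes <- function(events, k = 3, min_separation = 2) {
  stopifnot(is.data.frame(events), "violet" %in% names(events))
  if (k < 1) stopf("k must be >= 1")
  x <- log(pmax(events$violet, .Machine$double.eps))
  if (k == 1) {
    events$label <- 1L
    return(events)
  }
  fit <- tryCatch(gmm1d_em(x, k), error = function(e) NULL)
  if (is.null(fit)) {
    km <- suppressWarnings(stats::kmeans(x, centers = quantile(
      x, probs = (seq_len(k) - 0.5) / k), iter.max = 50))
    ord <- order(km$centers)
    fit <- list(mu = as.numeric(km$centers)[ord],
                sigma = rep(sd(x) / k, k),
                lambda = as.numeric(table(factor(km$cluster, levels = ord))) /
                  length(x),
                posterior = NULL, z = match(km$cluster, ord))
  }
  sep <- diff(fit$mu) /
    sqrt((head(fit$sigma, -1)^2 + tail(fit$sigma, -1)^2) / 2)
  if (any(!is.finite(sep)) || any(sep < min_separation))
    stopf(paste0("demultiplex failure: fitted dye components not separable ",
                 "(adjacent separations: %s sd)"),
          paste(sprintf("%.2f", sep), collapse = ", "))
  events$label <- as.integer(fit$z)
  attr(events, "mixture") <- fit[c("mu", "sigma", "lambda")]
  events
}

# Plain 1-D Gaussian mixture EM with quantile init; returns ordered
# components and hard assignments.
gmm1d_em <- function(x, k, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  mu <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
  sigma <- rep(sd(x) / k + 1e-6, k)
  lambda <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      lambda[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n))
    rs <- rowSums(dens)
    if (any(rs == 0 | !is.finite(rs))) stop("EM underflow")
    post <- dens / rs
    nk <- colSums(post)
    if (any(nk < 1e-8)) stop("EM component collapse")
    mu <- colSums(post * x) / nk
    sigma <- sqrt(colSums(post * (x - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, 1e-6)
    lambda <- nk / n
    ll <- sum(log(rs))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  ord <- order(mu)
  post <- post[, ord, drop = FALSE]
  list(mu = mu[ord], sigma = sigma[ord], lambda = lambda[ord],
       posterior = post, z = max.col(post))
}

#' Partition events into equal-count bins of total Lck
#'
#' Quantile (equal-count) binning on the linear total-Lck values: events are
#' ranked by \code{lckT} and split into \code{n_bins} contiguous groups of
#' near-equal size (exactly equal when the count divides evenly). Every
#' event lands in exactly one bin.
#'
#' @param events an \code{event_table}.
#' @param n_bins number of bins (default 73, a dense binning).
#' @return a list of event-table subsets, ordered by total Lck, with
#'   attribute \code{"degenerate"} set TRUE when the data cannot support the
#'   requested number of distinct bins (all-identical input collapses to a
#'   single effective bin).
#' @export
bin_lckT <- function(events, n_bins = 73) {
  stopifnot(is.data.frame(events), "lckT" %in% names(events))
  n <- nrow(events)
  if (n < n_bins) stopf("need at least %d events for %d bins", n_bins, n_bins)
  ord <- order(events$lckT)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  idx <- split(ord, rep(seq_len(n_bins), times = sizes))
  groups <- lapply(idx, function(i) events[i, , drop = FALSE])
  degenerate <- length(unique(events$lckT)) < n_bins
  if (degenerate)
    warning("fewer distinct lckT values than bins: binning is degenerate",
            call. = FALSE)
  attr(groups, "degenerate") <- degenerate
  groups
}

#' Geometric median of positive fluorescence values
#'
#' The per-channel location statistic of the binned curve: the median on the
#' log scale, back-transformed, i.e. \code{exp(median(log(x)))}. For
#' one-dimensional data this coincides with the geometric median proper;
#' zero or negative values are excluded and their count reported via the
#' \code{"n_excluded"} attribute.
#'
#' @param values numeric vector.
#' @param type \code{"median"} (default) or \code{"mean"} on the log scale
#'   (the latter gives the geometric mean, a documented alternative reading).
#' @return scalar geometric median (or mean).
#' @export
geometric_median <- function(values, type = c("median", "mean")) {
  type <- match.arg(type)
  keep <- values > 0
  if (!any(keep)) stopf("no positive values")
  out <- if (type == "median") exp(median(log(values[keep])))
         else exp(mean(log(values[keep])))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Binned dose curve of per-bin geometric medians
#'
#' Convenience constructor chaining [bin_lckT()] and [geometric_median()]:
#' per-bin geometric medians for both channels, plus event counts.
#'
#' @param events an \code{event_table}.
#' @param n_bins number of equal-count bins.
#' @param type statistic passed to [geometric_median()].
#' @return a data.frame of class \code{binned_curve} with columns
#'   \code{bin_id}, \code{lckT_med}, \code{lckA_med}, \code{n_events},
#'   ordered by \code{lckT_med}. Net (background-subtracted) columns are
#'   added by [subtract_background()].
#' @export
make_binned_curve <- function(events, n_bins = 73, type = "median") {
  groups <- bin_lckT(events, n_bins)
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(bin_id = i,
               lckT_med = as.numeric(geometric_median(g$lckT, type)),
               lckA_med = as.numeric(geometric_median(g$lckA, type)),
               n_events = nrow(g))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lckT_med), , drop = FALSE]
  out$bin_id <- seq_len(nrow(out))
  class(out) <- c("binned_curve", "data.frame")
  out
}

#' Subtract scalar control background from a binned curve
#'
#' The geometric median of each channel in the control sample (e.g. an
#' inhibitor-treated or uninduced culture) is subtracted from every bin
#' median. Negative net values are retained, not clamped, to avoid biasing
#' the low-expression quadratic regime; affected bins are flagged.
#'
#' @param curve a \code{binned_curve}.
#' @param control an \code{event_table} of control events (nonempty).
#' @param type statistic passed to [geometric_median()].
#' @return the curve with added columns \code{lckT_bkg}, \code{lckA_bkg},
#'   \code{lckT_net}, \code{lckA_net} and logical \code{flag_negative}.
#' @export
subtract_background <- function(curve, control, type = "median") {
  stopifnot(inherits(curve, "binned_curve"))
  if (!is.data.frame(control) || nrow(control) == 0)
    stopf("empty control sample")
  bkgT <- as.numeric(geometric_median(control$lckT, type))
  bkgA <- as.numeric(geometric_median(control$lckA, type))
  curve$lckT_bkg <- bkgT
  curve$lckA_bkg <- bkgA
  curve$lckT_net <- curve$lckT_med - bkgT
  curve$lckA_net <- curve$lckA_med - bkgA
  curve$flag_negative <- curve$lckT_net < 0 | curve$lckA_net < 0
  curve
}

#' Rectangular gate defining the physiological reference range
#'
#' @param lckT_min,lckT_max net total-Lck limits.
#' @param lckA_min,lckA_max optional net active-Lck limits.
#' @return an object of class \code{gate_box}.
#' @export
gate_box <- function(lckT_min, lckT_max, lckA_min = -Inf, lckA_max = Inf) {
  if (lckT_min >= lckT_max || lckA_min >= lckA_max)
    stopf("gate limits must satisfy min < max")
  structure(list(lckT_min = lckT_min, lckT_max = lckT_max,
                 lckA_min = lckA_min, lckA_max = lckA_max),
            class = "gate_box")
}

#' Restrict a binned curve to a reference expression range
#'
#' Keeps the bins whose net medians fall inside the gate (the range of the
#' physiological reference clone), preserving order.
#'
#' @param curve a background-subtracted \code{binned_curve}.
#' @param box a [gate_box()].
#' @return the filtered \code{binned_curve}; an error if no bin survives.
#' @export
restrict_range <- function(curve, box) {
  stopifnot(inherits(curve, "binned_curve"), inherits(box, "gate_box"))
  if (is.null(curve$lckT_net)) stopf("curve must be background-subtracted")
  keep <- curve$lckT_net >= box$lckT_min & curve$lckT_net <= box$lckT_max &
    curve$lckA_net >= box$lckA_min & curve$lckA_net <= box$lckA_max
  if (!any(keep)) stopf("no bins fall inside the gate")
  out <- curve[keep, , drop = FALSE]
  class(out) <- class(curve)
  out
}

#' Nonlinear regression of the active-versus-total Lck dose curve
#'
#' Default form is the quadratic-to-linear crossover
#' \eqn{y = \alpha x^2/(x+\kappa)} (see [crossover_curve()]); a pure
#' quadratic-plus-linear polynomial through the origin is selectable as an
#' alternative. Fit quality is summarized by R-squared and an F test
#' against a constant-mean model.
#'
#' @param curve a background-subtracted \code{binned_curve} (or any
#'   data.frame with \code{lckT_net}/\code{lckA_net}); at least 5 bins.
#' @param form \code{"crossover"} (default) or \code{"quadlin"}.
#' @return an object of class \code{regression_fit} with elements
#'   \code{form}, \code{coefficients}, \code{r_squared}, \code{f_test_p},
#'   \code{fitted} and \code{predict} (a function of x).
#' @export
fit_dose_response <- function(curve, form = c("crossover", "quadlin")) {
  form <- match.arg(form)
  x <- curve$lckT_net
  y <- curve$lckA_net
  if (is.null(x) || is.null(y)) stopf("curve must carry net medians")
  if (length(x) < 5) stopf("need at least 5 bins to fit")
  if (form == "crossover") {
    # initialize from the large-x linearization y ~ alpha * (x - kappa)
    top <- x >= median(x)
    lin <- lm(y[top] ~ x[top])
    a0 <- max(unname(coef(lin)[2]), 1e-8)
    k0 <- min(max(-unname(coef(lin)[1]) / a0, 1e-3), max(x))
    one_fit <- function(a0, k0) tryCatch(
      suppressWarnings(
        nls(y ~ alpha * x^2 / (x + kappa),
            start = list(alpha = a0, kappa = k0),
            algorithm = "port", lower = c(alpha = 0, kappa = 1e-12),
            control = list(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    fit <- one_fit(a0, k0)
    for (k_try in quantile(x, c(0.1, 0.25, 0.5))) {
      good <- !is.null(fit) &&
        (isTRUE(fit$convInfo$isConv) ||
           deviance(fit) <= 1e-8 * sum((y - mean(y))^2))
      if (good) break
      alt <- one_fit(a0, unname(k_try))
      if (!is.null(alt) && (is.null(fit) || deviance(alt) < deviance(fit)))
        fit <- alt
    }
    if (is.null(fit))
      stopf("crossover fit did not converge: no usable fit from any start")
    if (!isTRUE(fit$convInfo$isConv) &&
        deviance(fit) > 1e-8 * sum((y - mean(y))^2))
      stopf("crossover fit did not converge: %s", fit$convInfo$stopMessage)
    cf <- coef(fit)
    pred_fun <- function(xx) cf[["alpha"]] * xx^2 / (xx + cf[["kappa"]])
    n_par <- 2
  } else {
    fit <- lm(y ~ 0 + x + I(x^2))
    cf <- c(linear = unname(coef(fit)[1]), quadratic = unname(coef(fit)[2]))
    pred_fun <- function(xx) cf[["linear"]] * xx + cf[["quadratic"]] * xx^2
    n_par <- 2
  }
  fitted <- pred_fun(x)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  df2 <- length(x) - n_par
  fp <- if (sse > 0 && df2 > 0) {
    f <- ((sst - sse) / (n_par - 1)) / (sse / df2)
    pf(f, n_par - 1, df2, lower.tail = FALSE)
  } else 0
  structure(list(form = form, coefficients = cf, r_squared = r2,
                 f_test_p = fp, fitted = fitted, predict = pred_fun),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s; R^2 = %.4f, F-test p = %.3g\n", x$form,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$r_squared, x$f_test_p))
  invisible(x)
}

#' Normalize a binned curve to active fraction per total Lck
#'
#' Pointwise \code{lckA_net / lckT_net} versus \code{lckT_net}. Bins with
#' nonpositive net total Lck are dropped and their count reported. For a
#' crossover-form curve the normalized curve is the saturating function
#' \eqn{\alpha x / (x + \kappa)}: increasing, then plateauing.
#'
#' @param curve a background-subtracted \code{binned_curve}.
#' @return a data.frame with \code{lckT_net} and \code{ratio}; attribute
#'   \code{"n_dropped"} counts removed bins.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "binned_curve"))
  if (is.null(curve$lckT_net)) stopf("curve must be background-subtracted")
  keep <- curve$lckT_net > 0
  if (!any(keep)) stopf("all bins dropped: no positive net total Lck")
  out <- data.frame(lckT_net = curve$lckT_net[keep],
                    ratio = curve$lckA_net[keep] / curve$lckT_net[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Percent inhibition of a treated median relative to control
#'
#' \code{100 * (1 - treated/control)} on background-subtracted medians. A
#' treated value above control gives a negative percentage (an increase),
#' which is permitted and reported as such.
#'
#' @param treated_median,control_median background-subtracted medians;
#'   control must be positive.
#' @return percent inhibition.
#' @export
percent_inhibition <- function(treated_median, control_median) {
  if (any(control_median <= 0)) stopf("control median must be positive")
  100 * (1 - treated_median / control_median)
}

#' Percent change of a treated median relative to control
#'
#' \code{100 * (treated/control - 1)}: positive for an increase (e.g. the
#' active-pool rise upon phosphatase inhibition), negative for a decrease.
#'
#' @inheritParams percent_inhibition
#' @return percent change.
#' @export
fold_change <- function(treated_median, control_median) {
  if (any(control_median <= 0)) stopf("control median must be positive")
  100 * (treated_median / control_median - 1)
}
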