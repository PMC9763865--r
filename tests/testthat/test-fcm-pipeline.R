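test_that("CSV reading validates inputs and channels", {
  path <- tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_events(path), "empty input")
  write.csv(data.frame(a = 1:3, b = 1:3, c = 1:3), path, row.names = FALSE)
  expect_error(read_events(path), "channel")
  write.csv(data.frame(lckT = 1:3, lckA = 1:3, violet = 1:3), path,
            row.names = FALSE)
  ev <- read_events(path)
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 3)
  unlink(path)
  expect_error(read_events("no/such/file.csv"), "not found")
})

test_that("FCS round trip linearizes log-amplified channels", {
  set.seed(41)
  dat <- data.frame(lckT = rlnorm(200, log(300), 0.8),
                    lckA = rlnorm(200, log(80), 0.6),
                    violet = rlnorm(200, log(500), 0.4))
  path <- tempfile(fileext = ".fcs")
  write_fcs(dat, path, log_channels = c("lckT", "violet"))
  back <- read_fcs(path)
  expect_equal(back$lckT, dat$lckT, tolerance = 1e-4)
  expect_equal(back$violet, dat$violet, tolerance = 1e-4)
  expect_equal(back$lckA, dat$lckA, tolerance = 1e-6)
  ev <- read_events(path, format = "fcs")
  expect_equal(ev$lckT, dat$lckT, tolerance = 1e-4)
  unlink(path)
})

test_that("barcode demultiplexing recovers well-separated populations", {
  spec <- fcm_gen_spec(n_cells_per_population = 3000, seed = 9)
  ev <- gen_fcm_events(spec)
  lab <- demultiplex_barcodes(ev, k = 3)
  truth <- attr(ev, "truth")
  expect_gte(mean(lab$label == truth$label), 0.99)
  mix <- attr(lab, "mixture")
  expect_true(all(diff(mix$mu) > 0))
})

test_that("demultiplexing handles k = 1 and surfaces coincident populations", {
  ev <- const_events(200, 100, 10, violet = rlnorm(200, log(100), 0.25))
  expect_equal(unique(demultiplex_barcodes(ev, k = 1)$label), 1L)
  # two coincident populations cannot support k = 3
  set.seed(17)
  ev2 <- const_events(2000, 100, 10,
                      violet = rlnorm(2000, log(100), 0.25))
  expect_error(demultiplex_barcodes(ev2, k = 3), "demultiplex failure")
})

test_that("equal-count binning partitions events exactly", {
  set.seed(3)
  ev <- const_events(7300, runif(7300, 10, 1000), 5)
  groups <- bin_lckT(ev, 73)
  expect_length(groups, 73)
  expect_true(all(vapply(groups, nrow, integer(1)) == 100))
  ids <- unlist(lapply(groups, function(g) g$cell_id))
  expect_setequal(ids, ev$cell_id)
  expect_equal(length(ids), nrow(ev))  # partition: no duplicates
  # bins are ordered in lckT
  maxs <- vapply(groups, function(g) max(g$lckT), numeric(1))
  mins <- vapply(groups, function(g) min(g$lckT), numeric(1))
  expect_true(all(head(maxs, -1) <= tail(mins, -1)))
  expect_error(bin_lckT(const_events(50, 1:50, 1), 73), "at least")
  expect_warning(bin_lckT(const_events(200, 7, 1), 73), "degenerate")
})

test_that("geometric median matches hand computations and is scale-equivariant", {
  expect_equal(as.numeric(geometric_median(c(1, 10, 100))), 10)
  expect_equal(as.numeric(geometric_median(rep(4.2, 9))), 4.2)
  set.seed(5)
  x <- rlnorm(101, 2, 1)
  expect_equal(as.numeric(geometric_median(7 * x)),
               7 * as.numeric(geometric_median(x)))
  g <- geometric_median(c(-1, 0, 3, 27))
  expect_equal(attr(g, "n_excluded"), 2)
  expect_equal(as.numeric(g), 9)
  expect_error(geometric_median(c(-2, 0)), "no positive")
  # geometric-mean alternative
  expect_equal(as.numeric(geometric_median(c(1, 10, 1000), type = "mean")),
               10^(4 / 3))
})

test_that("background subtraction is scalar, retains and flags negatives", {
  curve <- fake_binned_curve(c(50, 100, 400), c(25, 100, 200))
  curve$lckT_net <- curve$lckA_net <- NULL
  ctrl <- const_events(50, 30, 30)
  out <- subtract_background(curve, ctrl)
  expect_equal(out$lckT_bkg, rep(30, 3))
  expect_equal(out$lckA_net, c(-5, 70, 170))
  expect_equal(out$flag_negative, c(TRUE, FALSE, FALSE))
  # zero-background control leaves the curve unchanged
  ctrl0 <- const_events(50, 1e-12, 1e-12)
  out0 <- subtract_background(curve, ctrl0)
  expect_equal(out0$lckA_net, curve$lckA_med, tolerance = 1e-9)
  expect_error(subtract_background(curve, ctrl[0, ]), "empty control")
})

test_that("range restriction matches a brute-force filter", {
  curve <- subtract_background(
    fake_binned_curve(seq(20, 400, by = 20), seq(5, 100, by = 5)),
    const_events(10, 1e-12, 1e-12))
  box <- gate_box(100, 300)
  out <- restrict_range(curve, box)
  keep <- curve$lckT_net >= 100 & curve$lckT_net <= 300
  expect_equal(out$lckT_med, curve$lckT_med[keep])
  # spanning box is the identity
  all_box <- gate_box(-Inf, Inf)
  expect_equal(nrow(restrict_range(curve, all_box)), nrow(curve))
  expect_error(restrict_range(curve, gate_box(1e6, 2e6)), "no bins")
  expect_error(gate_box(10, 10), "min < max")
})

test_that("crossover regression recovers exact data and its two regimes", {
  x <- seq(10, 2000, length.out = 40)
  alpha <- 0.62; kappa <- 240
  curve <- fake_binned_curve(x, alpha * x^2 / (x + kappa))
  fit <- fit_dose_response(curve)
  expect_equal(unname(fit$coefficients[["alpha"]]), alpha, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[["kappa"]]), kappa, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$f_test_p, 1e-6)
  # quadratic at small x, linear at large x (log-log slopes of the fit)
  llslope <- function(x0) {
    h <- x0 * 1e-3
    (log(fit$predict(x0 + h)) - log(fit$predict(x0 - h))) /
      (log(x0 + h) - log(x0 - h))
  }
  expect_equal(llslope(kappa * 1e-4), 2, tolerance = 1e-3)
  expect_equal(llslope(kappa * 1e4), 1, tolerance = 1e-3)
  expect_error(fit_dose_response(curve[1:3, ]), "at least 5")
})

test_that("quadratic-plus-linear alternative form is selectable", {
  x <- seq(5, 100, by = 5)
  curve <- fake_binned_curve(x, 0.3 * x + 0.01 * x^2)
  fit <- fit_dose_response(curve, form = "quadlin")
  expect_equal(unname(fit$coefficients[["linear"]]), 0.3, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[["quadratic"]]), 0.01,
               tolerance = 1e-8)
})

test_that("normalized curves have the expected algebraic shapes", {
  x <- seq(10, 500, by = 10)
  lin <- normalize_curve(fake_binned_curve(x, 0.4 * x))
  expect_equal(lin$ratio, rep(0.4, length(x)))
  quad <- normalize_curve(fake_binned_curve(x, 0.002 * x^2))
  expect_equal(quad$ratio, 0.002 * x, tolerance = 1e-12)
  cross <- normalize_curve(fake_binned_curve(x, 0.5 * x^2 / (x + 100)))
  expect_true(all(diff(cross$ratio) > 0))           # increasing
  expect_true(all(cross$ratio < 0.5))               # below the plateau
  expect_lt(diff(tail(cross$ratio, 2)), diff(head(cross$ratio, 2)))
  neg <- fake_binned_curve(c(-5, 10, 20), c(1, 2, 3))
  out <- normalize_curve(neg)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("percent inhibition and fold change follow their sign conventions", {
  expect_equal(percent_inhibition(100, 100), 0)
  expect_equal(percent_inhibition(10, 100), 90)
  expect_equal(percent_inhibition(150, 100), -50)
  expect_equal(fold_change(150, 100), 50)
  expect_equal(fold_change(100, 100), 0)
  expect_error(percent_inhibition(10, 0), "positive")
  expect_error(fold_change(10, -1), "positive")
})

test_that("phosphatase-block fold change is recovered from synthetic data", {
  # a pervanadate-like treatment converts the primed pool to active:
  # treated active median = (1 + pool) * control median
  spec <- fcm_gen_spec(n_cells_per_population = 8000, seed = 77,
                       background_A = 0, background_T = 0)
  ev_ctrl <- gen_fcm_events(spec)
  pool <- 0.5
  ev_pv <- ev_ctrl
  ev_pv$lckA <- ev_pv$lckA * (1 + pool)
  fc <- fold_change(as.numeric(geometric_median(ev_pv$lckA)),
                    as.numeric(geometric_median(ev_ctrl$lckA)))
  expect_equal(fc, 50, tolerance = 1e-9)
})

test_that("the pipeline is equivariant under a global fluorescence rescale", {
  spec <- fcm_gen_spec(n_cells_per_population = 4000, seed = 19,
                       barcode_levels = 100)
  ev <- gen_fcm_events(spec)
  ctrl <- gen_fcm_background(spec)
  scale_tab <- function(e, c) {
    e$lckT <- c * e$lckT; e$lckA <- c * e$lckA
    e
  }
  run <- function(e, c) {
    bc <- subtract_background(make_binned_curve(e, 30), scale_tab(ctrl, c))
    list(bc = bc, fit = fit_dose_response(bc))
  }
  r1 <- run(ev, 1)
  r2 <- run(scale_tab(ev, 13), 13)
  expect_equal(r2$bc$lckT_med, 13 * r1$bc$lckT_med, tolerance = 1e-9)
  expect_equal(r2$bc$lckA_net, 13 * r1$bc$lckA_net, tolerance = 1e-9)
  expect_equal(r2$fit$r_squared, r1$fit$r_squared, tolerance = 1e-6)
  expect_equal(percent_inhibition(r2$bc$lckA_med[3], r2$bc$lckA_med[5]),
               percent_inhibition(r1$bc$lckA_med[3], r1$bc$lckA_med[5]))
})

test_that("full pipeline recovers the generating curve parameters", {
  hits <- 0
  for (s in 1:20) {
    spec <- fcm_gen_spec(seed = s)
    ev <- gen_fcm_events(spec)
    ctrl <- gen_fcm_background(spec)
    bc <- subtract_background(make_binned_curve(ev, 73), ctrl)
    fit <- fit_dose_response(bc)
    a <- fit$coefficients[["alpha"]]
    k <- fit$coefficients[["kappa"]]
    ok <- abs(a - spec$curve$alpha) / spec$curve$alpha < 0.1 &&
      abs(k - spec$curve$kappa) / spec$curve$kappa < 0.1
    hits <- hits + ok
  }
  expect_gte(hits / 20, 0.9)
})
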