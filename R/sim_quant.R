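#' Modal-value background thresholding of a stack
#'
#' Per channel, the modal (most frequent, integer-rounded) intensity — the
#' centre of the noise distribution — is subtracted, negatives are clipped
#' to zero and the channel is linearly rescaled to the 16-bit range. The
#' operation is idempotent: after one application the mode is zero.
#'
#' @param stack an \code{image_stack}.
#' @param rescale rescale each channel to [0, 65535] (default TRUE).
#' @return the thresholded \code{image_stack}; the subtracted offsets are
#'   attached as attribute \code{"mode_offsets"}.
#' @export
mode_threshold <- function(stack, rescale = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  n_ch <- dim(stack$arr)[4]
  offsets <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- stack$arr[, , , ch]
    m <- modal_value(v)
    offsets[ch] <- m
    v <- pmax(v - m, 0)
    if (rescale && max(v) > 0) v <- v / max(v) * 65535
    stack$arr[, , , ch] <- v
  }
  attr(stack, "mode_offsets") <- offsets
  stack
}

modal_value <- function(v) {
  r <- as.integer(round(v))
  lo <- min(r)
  counts <- tabulate(r - lo + 1L)
  lo + which.max(counts) - 1L
}

#' Average projection of the central planes
#'
#' @param stack an \code{image_stack} (or a bare z, y, x, channel array).
#' @param n_planes number of central planes to average (default 4). For an
#'   even split the window is biased one plane towards the lower index.
#' @return a (y, x, channel) array; channel roles are carried in the
#'   \code{"channels"} attribute.
#' @export
project_central <- function(stack, n_planes = 4) {
  arr <- if (inherits(stack, "image_stack")) stack$arr else stack
  nz <- dim(arr)[1]
  zi <- central_planes(nz, as.integer(n_planes))
  proj <- apply(arr[zi, , , , drop = FALSE], c(2, 3, 4), mean)
  attr(proj, "channels") <- if (inherits(stack, "image_stack"))
    stack$channels else NULL
  proj
}

#' Segment plasma-membrane, nuclear and cytoplasmic ROIs
#'
#' From a projected multi-channel image: each segmentation channel is
#' Gaussian blurred, Otsu auto-thresholded and reduced to a binary mask;
#' holes are filled, a single 3x3 erosion is applied, and the largest
#' connected component is kept (one cell per field). The PM ROI is the
#' membrane-marker-positive ring, the nuclear ROI comes from the nuclear
#' dye, and the CP ROI is the filled PM contour minus the (uneroded) ring
#' and nucleus, so the three masks are pairwise disjoint.
#'
#' @param projected (y, x, channel) array from [project_central()], with
#'   channels ordered (nuclear_dye, pm_marker, target).
#' @param blur_sigma pre-segmentation Gaussian sigma in pixels.
#' @param erode_kernel structuring element passed to [erode()].
#' @return an object of class \code{roi_set}: list of logical masks
#'   \code{pm}, \code{nuclear}, \code{cp}.
#' @export
make_rois <- function(projected, blur_sigma = 3,
                      erode_kernel = "square") {
  stopifnot(length(dim(projected)) == 3, dim(projected)[3] >= 2)
  dapi <- blur(projected[, , 1], blur_sigma)
  cd45 <- blur(projected[, , 2], blur_sigma)
  if (max(dapi) <= min(dapi)) stopf("no foreground in the nuclear channel")
  if (max(cd45) <= min(cd45)) stopf("no foreground in the membrane channel")

  nfull <- largest_component(fill_holes(dapi > otsu_threshold(dapi)))
  if (!any(nfull)) stopf("no foreground in the nuclear channel")
  nuclear <- erode(nfull, kernel = erode_kernel)

  band <- largest_component(cd45 > otsu_threshold(cd45))
  if (!any(band)) stopf("no foreground in the membrane channel")
  pm <- erode(band, kernel = erode_kernel)
  filled <- fill_holes(band)
  cp <- erode(filled, kernel = erode_kernel) & !band & !nfull
  if (!any(cp)) stopf("segmentation failed: empty cytoplasmic ROI")
  structure(list(pm = pm, nuclear = nuclear, cp = cp), class = "roi_set")
}

#' Plasma-membrane to cytoplasm intensity ratio
#'
#' Mean target intensity over the PM and CP masks, their ratio, and the
#' implied percent of the target that is PM-resident (see
#' [ratio_to_fraction()]).
#'
#' @param target (y, x) numeric matrix of the target channel.
#' @param rois a \code{roi_set}.
#' @param eps floor below which the CP mean is considered zero (undefined
#'   ratio).
#' @return an object of class \code{pmcp_result}: \code{pm_mean},
#'   \code{cp_mean}, \code{ratio}, \code{pm_fraction_pct}.
#' @export
pm_cp_ratio <- function(target, rois, eps = 1e-9) {
  stopifnot(inherits(rois, "roi_set"), is.matrix(target))
  if (!any(rois$pm) || !any(rois$cp)) stopf("empty ROI")
  pm_mean <- mean(target[rois$pm])
  cp_mean <- mean(target[rois$cp])
  if (cp_mean <= eps) stopf("undefined ratio: CP mean at or below floor")
  r <- pm_mean / cp_mean
  structure(list(pm_mean = pm_mean, cp_mean = cp_mean, ratio = r,
                 pm_fraction_pct = ratio_to_fraction(r)),
            class = "pmcp_result")
}

#' @export
print.pmcp_result <- function(x, ...) {
  cat(sprintf("PM/CP = %.3f (PM mean %.2f, CP mean %.2f): %.1f%% PM-resident\n",
              x$ratio, x$pm_mean, x$cp_mean, x$pm_fraction_pct))
  invisible(x)
}

#' Convert a PM/CP mean-intensity ratio to percent PM-resident
#'
#' \code{100 * r / (1 + r)}, the strictly increasing map from the ratio of
#' compartment means to the percentage of signal residing at the membrane
#' (for comparable compartment sizes): r = 1 gives 50 percent, r = 2.5
#' gives 71 percent, r = 1.7 gives 63 percent.
#'
#' @param r positive ratio (vectorized).
#' @param digits optional rounding (e.g. 0 for whole percent).
#' @return percent PM-resident in (0, 100).
#' @export
ratio_to_fraction <- function(r, digits = NULL) {
  if (any(r <= 0)) stopf("ratio must be positive")
  out <- 100 * r / (1 + r)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Full image-quantification pipeline for one stack
#'
#' Chains [mode_threshold()], [project_central()], [make_rois()] (on the
#' blurred projection) and [pm_cp_ratio()]. The ratio itself is measured on
#' the unblurred projection of the target channel: smoothing is used only
#' to define ROIs, so thin-ring intensities are not diluted into the
#' cytoplasm at measurement time.
#'
#' @param stack an \code{image_stack}.
#' @param n_planes central planes to project.
#' @param blur_sigma ROI-definition blur in pixels.
#' @return a list with \code{result} (a \code{pmcp_result}), \code{rois}
#'   and \code{projected}.
#' @export
quantify_stack <- function(stack, n_planes = 4, blur_sigma = 3) {
  st <- mode_threshold(stack)
  proj <- project_central(st, n_planes)
  rois <- make_rois(proj, blur_sigma = blur_sigma)
  res <- pm_cp_ratio(proj[, , 3], rois)
  list(result = res, rois = rois, projected = proj)
}
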