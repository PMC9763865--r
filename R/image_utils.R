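# Small image-processing primitives used by the quantification pipeline.
# Images are plain numeric matrices (y, x) or arrays (y, x, channel);
# stacks are arrays (z, y, x, channel).

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# mirror (symmetric) boundary index
reflect_idx <- function(i, n) {
  i <- ((i - 1) %% (2 * n)) + 1
  ifelse(i > n, 2 * n + 1 - i, i)
}

index_along <- function(a, idx, dim) {
  nd <- length(dim(a))
  args <- rep(list(quote(expr = )), nd)
  args[[dim]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# separable 1-D Gaussian convolution along one array dimension,
# reflective boundary; kernel normalized so constants are preserved
blur_along <- function(a, sigma, dim) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1) / 2
  d <- dim(a)
  n <- d[dim]
  out <- array(0, d)
  for (j in seq_along(k)) {
    idx <- reflect_idx(seq_len(n) + (j - r - 1), n)
    out <- out + k[j] * index_along(a, idx, dim)
  }
  out
}

#' Gaussian blur of a projected image
#'
#' Separable Gaussian filter with reflective boundary handling, applied to
#' the spatial dimensions of a matrix (y, x) or multi-channel array
#' (y, x, channel). The kernel is normalized, so total intensity is
#' conserved away from the boundary.
#'
#' @param image numeric matrix or 3-d array.
#' @param sigma kernel standard deviation in pixels (default 3, the
#'   pre-segmentation smoothing of the quantification pipeline).
#' @return the blurred image, same shape.
#' @export
blur <- function(image, sigma = 3) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(image)
  was_mat <- is.matrix(image)
  if (was_mat) dim(image) <- c(dim(image), 1L)
  out <- blur_along(blur_along(image, sigma, 1L), sigma, 2L)
  if (was_mat) dim(out) <- dim(out)[1:2]
  out
}

#' Otsu threshold of an intensity image
#'
#' Exhaustive search over a binned histogram for the threshold maximizing
#' between-class variance. Foreground is \code{image > threshold}.
#'
#' @param image numeric matrix.
#' @param n_bins histogram resolution.
#' @return the threshold on the intensity scale of \code{image}.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stopf("blank image: no foreground to threshold")
  h <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1, 1),
                     n_bins), n_bins)
  w <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_tot <- mu[n_bins]
  sb <- (mu_tot * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  lo + k * (hi - lo) / n_bins
}

shift_mask <- function(m, di, dj, fill = FALSE) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  si <- seq_len(n1) - di; sj <- seq_len(n2) - dj
  oki <- si >= 1 & si <= n1; okj <- sj >= 1 & sj <= n2
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

#' Binary erosion
#'
#' Single-pass (or iterated) erosion with a 3x3 structuring element; pixels
#' outside the image count as background.
#'
#' @param mask logical matrix.
#' @param kernel \code{"square"} (8-neighbour, default) or \code{"cross"}
#'   (4-neighbour).
#' @param iterations number of erosion passes.
#' @return the eroded logical matrix.
#' @export
erode <- function(mask, kernel = c("square", "cross"), iterations = 1) {
  kernel <- match.arg(kernel)
  offs <- if (kernel == "square")
    expand.grid(di = -1:1, dj = -1:1)
  else
    data.frame(di = c(0, -1, 1, 0, 0), dj = c(0, 0, 0, -1, 1))
  for (it in seq_len(iterations)) {
    out <- mask
    for (r in seq_len(nrow(offs)))
      out <- out & shift_mask(mask, offs$di[r], offs$dj[r], fill = FALSE)
    mask <- out
  }
  mask
}

# breadth-first flood over TRUE cells of `open` starting from `seeds`
# (2-column matrix of (i, j)); 4- or 8-connectivity
flood_fill <- function(open, seeds, connectivity = 4) {
  n1 <- nrow(open); n2 <- ncol(open)
  visited <- matrix(FALSE, n1, n2)
  if (nrow(seeds) == 0) return(visited)
  ok <- open[seeds]
  frontier <- seeds[ok, , drop = FALSE]
  visited[frontier] <- TRUE
  offs <- if (connectivity == 4)
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  else
    as.matrix(expand.grid(di = -1:1, dj = -1:1))[-5, ]
  while (nrow(frontier) > 0) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
      cbind(frontier[, 1] + offs[r, 1], frontier[, 2] + offs[r, 2])))
    keep <- nxt[, 1] >= 1 & nxt[, 1] <= n1 & nxt[, 2] >= 1 & nxt[, 2] <= n2
    nxt <- nxt[keep, , drop = FALSE]
    keep <- open[nxt] & !visited[nxt]
    nxt <- unique(nxt[keep, , drop = FALSE])
    if (nrow(nxt) == 0) break
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  visited
}

#' Fill interior holes of a binary mask
#'
#' Background regions not reachable from the image border are considered
#' holes and set to foreground.
#'
#' @param mask logical matrix.
#' @return the filled logical matrix.
#' @export
fill_holes <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  border <- rbind(cbind(1, seq_len(n2)), cbind(n1, seq_len(n2)),
                  cbind(seq_len(n1), 1), cbind(seq_len(n1), n2))
  outside <- flood_fill(!mask, border, connectivity = 4)
  mask | (!mask & !outside)
}

#' Largest connected component of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix keeping only the largest component.
#' @export
largest_component <- function(mask, connectivity = 8) {
  remaining <- mask
  best <- NULL
  best_size <- 0
  while (any(remaining)) {
    seed <- which(remaining, arr.ind = TRUE)[1, , drop = FALSE]
    comp <- flood_fill(remaining, seed, connectivity)
    size <- sum(comp)
    if (size > best_size) {
      best <- comp
      best_size <- size
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) matrix(FALSE, nrow(mask), ncol(mask)) else best
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return \code{2|a & b| / (|a| + |b|)}; 1 for identical non-empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
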