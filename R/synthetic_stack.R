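#' Specification for a synthetic three-channel cell z-stack
#'
#' Describes a single roughly spherical suspension cell: a nuclear-dye
#' channel filling the nucleus, a membrane-marker channel confined to a
#' spherical plasma-membrane (PM) shell, and a target channel whose total
#' signal is split between the PM shell and the cytoplasm (CP, the space
#' between nucleus and shell) with a known fraction. Geometry is expressed
#' in voxels; \code{z_aspect} is the axial/lateral voxel-size ratio so the
#' cell is a sphere in physical units but spans fewer z-planes. The stack
#' is blurred by a Gaussian PSF and corrupted by Poisson noise on top of a
#' constant camera baseline.
#'
#' Defaults place an r = 48 px cell (about 3 um at SIM-like sampling) with
#' an 8 px membrane band in a 40 x 128 x 128 stack; the band is deliberately
#' wide relative to the pipeline's fixed 3 px analysis blur so that ring
#' segmentation is well posed.
#'
#' @param shape_zyx integer triple (z, y, x).
#' @param cell_radius,nuclear_radius,pm_thickness geometry in lateral
#'   voxels; must satisfy \code{nuclear_radius < cell_radius - pm_thickness}.
#' @param z_aspect axial/lateral voxel-size ratio.
#' @param pm_fraction_true fraction of total target signal residing in the
#'   PM shell (0 to 1).
#' @param channel_intensities named amplitudes (mean voxel intensity of the
#'   nuclear dye, PM marker, and target signal).
#' @param baseline constant background offset added to every voxel.
#' @param psf_sigma lateral PSF sigma in voxels (0 = no blur).
#' @param psf_sigma_z axial PSF sigma in planes.
#' @param poisson_scale photon-count scaling; \code{Inf} disables noise.
#' @param seed RNG seed.
#' @return an object of class \code{stack_gen_spec}.
#' @export
stack_gen_spec <- function(shape_zyx = c(40, 128, 128),
                           cell_radius = 48, nuclear_radius = 28,
                           pm_thickness = 8, z_aspect = 3,
                           pm_fraction_true = 0.7,
                           channel_intensities = c(nuclear = 400,
                                                   pm = 400, target = 200),
                           baseline = 10,
                           psf_sigma = 1.3, psf_sigma_z = 1,
                           poisson_scale = 1,
                           seed = 1L) {
  if (nuclear_radius >= cell_radius - pm_thickness)
    stopf("invalid geometry: need nuclear_radius < cell_radius - pm_thickness")
  if (pm_fraction_true < 0 || pm_fraction_true > 1)
    stopf("pm_fraction_true must lie in [0, 1]")
  if (2 * cell_radius / z_aspect + 4 > shape_zyx[1])
    stopf("stack too shallow for the cell along z")
  if (2 * cell_radius + 4 > min(shape_zyx[2:3]))
    stopf("stack too small for the cell laterally")
  structure(list(shape_zyx = as.integer(shape_zyx),
                 cell_radius = cell_radius, nuclear_radius = nuclear_radius,
                 pm_thickness = pm_thickness, z_aspect = z_aspect,
                 pm_fraction_true = pm_fraction_true,
                 channel_intensities = channel_intensities,
                 baseline = baseline,
                 psf_sigma = psf_sigma, psf_sigma_z = psf_sigma_z,
                 poisson_scale = poisson_scale, seed = seed),
            class = "stack_gen_spec")
}

#' Generate a synthetic cell stack with ground truth
#'
#' Builds the noise-free compartment intensities, records the ground-truth
#' masks and the pre-noise PM/CP mean-intensity ratio, then applies PSF blur
#' and Poisson noise. The 2-D ground-truth masks live on the frame of the
#' central-plane projection: a pixel belongs to a 2-D mask only if it
#' belongs to the corresponding 3-D compartment in all four central planes,
#' so compartment intensities project exactly onto them in the noiseless,
#' blur-free limit.
#'
#' @param spec a [stack_gen_spec()].
#' @return an object of class \code{image_stack}: a list with \code{arr}
#'   (array z, y, x, channel), \code{channels} (role names) and
#'   \code{truth} (2-D and 3-D masks, \code{true_ratio},
#'   \code{pm_fraction_true}, compartment intensities).
#' @export
gen_image_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_gen_spec"))
  d <- spec$shape_zyx
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  zc <- (nz + 1) / 2; yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
  zz <- ((seq_len(nz) - zc) * spec$z_aspect)^2
  yy <- (seq_len(ny) - yc)^2
  xx <- (seq_len(nx) - xc)^2
  d2 <- outer(outer(zz, yy, "+"), xx, "+")  # (z, y, x) squared distance
  dd <- sqrt(d2)

  R <- spec$cell_radius
  Rn <- spec$nuclear_radius
  t <- spec$pm_thickness
  pm3 <- dd <= R & dd > (R - t)
  nuc3 <- dd <= Rn
  cp3 <- dd <= (R - t) & dd > Rn

  amp <- spec$channel_intensities
  f <- spec$pm_fraction_true
  n_pm <- sum(pm3); n_cp <- sum(cp3)
  total <- amp[["target"]] * (n_pm + n_cp)
  i_pm <- if (n_pm > 0) f * total / n_pm else 0
  i_cp <- if (n_cp > 0) (1 - f) * total / n_cp else 0
  true_ratio <- if (i_cp > 0) i_pm / i_cp else Inf

  arr <- array(0, c(nz, ny, nx, 3))
  arr[, , , 1][nuc3] <- amp[["nuclear"]]
  arr[, , , 2][pm3] <- amp[["pm"]]
  arr[, , , 3][pm3] <- i_pm
  arr[, , , 3][cp3] <- arr[, , , 3][cp3] + i_cp
  pre_blur <- arr

  if (spec$psf_sigma > 0 || spec$psf_sigma_z > 0) {
    for (ch in 1:3) {
      v <- arr[, , , ch]
      v <- blur_along(v, spec$psf_sigma_z, 1L)
      v <- blur_along(v, spec$psf_sigma, 2L)
      v <- blur_along(v, spec$psf_sigma, 3L)
      arr[, , , ch] <- v
    }
  }
  arr <- arr + spec$baseline
  if (is.finite(spec$poisson_scale) && spec$poisson_scale > 0) {
    arr <- with_seed(spec$seed, {
      array(rpois(length(arr), pmax(arr, 0) * spec$poisson_scale) /
              spec$poisson_scale, dim(arr))
    })
  }

  # 2-D truth masks on the projection frame: member in all central planes
  zi <- central_planes(nz, 4L)
  all_planes <- function(m3) {
    out <- matrix(TRUE, ny, nx)
    for (z in zi) out <- out & m3[z, , ]
    out
  }
  truth <- list(
    masks = list(pm = all_planes(pm3), nuclear = all_planes(nuc3),
                 cp = all_planes(cp3)),
    masks_3d = list(pm = pm3, nuclear = nuc3, cp = cp3),
    true_ratio = true_ratio,
    pm_fraction_true = f,
    intensities = c(pm = i_pm, cp = i_cp),
    pre_blur = pre_blur
  )
  structure(list(arr = arr,
                 channels = c("nuclear_dye", "pm_marker", "target"),
                 truth = truth),
            class = "image_stack")
}

# 0-based-lower-biased central plane indices (1-based return)
central_planes <- function(nz, n_planes) {
  if (nz < n_planes) stopf("stack has %d planes, need %d", nz, n_planes)
  start <- floor((nz - n_planes) / 2)
  start + seq_len(n_planes)
}
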