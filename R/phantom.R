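#' Configuration for the periventricular diffusion phantom
#'
#' Describes a synthetic patch of periventricular white matter containing,
#' in each hemisphere, a slab of projection fibres (principal diffusion
#' axis craniocaudal, z) medially and a slab of association fibres
#' (principal axis anterior-posterior, y) laterally, embedded in an
#' isotropic background. A tunable right-left (x) diffusivity component,
#' `perivascular_boost`, is added to the x-diagonal of both fibre tensors
#' and emulates water movement along the perivascular spaces of the deep
#' medullary veins, which run perpendicular to both fibre populations.
#'
#' The closed-form ALPS index of such a phantom is
#' `(lambda_perp + perivascular_boost) / lambda_perp`, independent of
#' `lambda_parallel`, `s0` and of any global scaling of the diffusivities.
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z).
#' @param voxel_size voxel edge lengths in mm; default 2 mm isotropic,
#'   matching a 128 matrix over a 256 mm field of view with 2 mm sections.
#' @param lambda_parallel diffusivity along the fibre axis, mm^2/s.
#' @param lambda_perp diffusivity across the fibre axis, mm^2/s.
#' @param perivascular_boost additive right-left (x) diffusivity inside
#'   both fibre slabs, mm^2/s; 0 gives a ground-truth ALPS index of 1.
#' @param d_background isotropic background diffusivity, mm^2/s.
#' @param s0 unit-less baseline signal.
#' @param snr baseline signal-to-noise ratio of the additive Gaussian
#'   noise on a single acquisition; 0 disables noise.
#' @param n_averages number of signal averages (the acquisition's NSA);
#'   the stored volumes are the mean of this many independent noisy
#'   acquisitions, so their noise SD is `s0 / (snr * sqrt(n_averages))`.
#' @param seed integer seed for the noise generator.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 12),
                           voxel_size = c(2, 2, 2),
                           lambda_parallel = 1.4e-3,
                           lambda_perp = 0.8e-3,
                           perivascular_boost = 0.2e-3,
                           d_background = 0.8e-3,
                           s0 = 1, snr = 30, n_averages = 4L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop("'grid_shape' must be three integers >= 1")
  if (!(lambda_parallel >= lambda_perp) || !(lambda_perp > 0))
    stop("need lambda_parallel >= lambda_perp > 0")
  if (perivascular_boost < 0) stop("'perivascular_boost' must be >= 0")
  if (d_background <= 0) stop("'d_background' must be > 0")
  if (snr < 0) stop("'snr' must be >= 0")
  if (s0 <= 0) stop("'s0' must be > 0")
  if (n_averages < 1) stop("'n_averages' must be >= 1")
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 lambda_parallel = lambda_parallel, lambda_perp = lambda_perp,
                 perivascular_boost = perivascular_boost,
                 d_background = d_background, s0 = s0, snr = snr,
                 n_averages = as.integer(n_averages), seed = as.integer(seed)),
            class = "phantom_config")
}

# Axis-aligned fibre slab coordinates for a given grid. The x axis is
# right-left with the lower indices on the right; projection slabs sit
# medially (next to the "ventricle" at the midline), association slabs
# laterally, both spanning the full z extent.
phantom_regions <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  mid <- nx / 2
  w <- max(1L, round(nx / 8))             # slab thickness in voxels
  yr <- seq(max(1L, round(ny / 8)), min(ny, round(7 * ny / 8)))
  band <- function(lo, hi) seq(max(1L, lo), min(nx, hi))
  list(
    proj_right  = list(x = band(round(mid - 2 * w) + 1, round(mid - w)), y = yr),
    assoc_right = list(x = band(round(mid - 4 * w) + 1, round(mid - 3 * w)), y = yr),
    proj_left   = list(x = band(round(mid + w) + 1, round(mid + 2 * w)), y = yr),
    assoc_left  = list(x = band(round(mid + 3 * w) + 1, round(mid + 4 * w)), y = yr),
    z = seq_len(nz)
  )
}

#' Generate a synthetic periventricular diffusion phantom
#'
#' Builds the analytic tensor field described by a [phantom_config()],
#' synthesises diffusion-weighted signals under the monoexponential
#' tensor model for every voxel, optionally adds Gaussian noise at the
#' configured SNR, and labels single-slice regions of interest in the
#' projection and association fibre slabs of both hemispheres.
#'
#' Projection-fibre voxels carry `diag(lp + boost, lp, lpar)` and
#' association-fibre voxels `diag(lp + boost, lpar, lp)` (with
#' `lp = lambda_perp`, `lpar = lambda_parallel`), so the ground-truth
#' ALPS index is `(lambda_perp + perivascular_boost) / lambda_perp`.
#'
#' @param config a [phantom_config()].
#' @param scheme an [acquisition_scheme()]; defaults to
#'   [default_scheme()] (20 directions, b = 1000 s/mm^2, one b = 0).
#' @return A list of class `alps_phantom`: `dwi` (4-D array), `scheme`,
#'   `truth` (ground-truth [tensor_field()]), `labels` (3-D integer array,
#'   1 = right projection, 2 = right association, 3 = left projection,
#'   4 = left association), `rois` (single-slice [roi_mask()] objects for
#'   both hemispheres), `truth_alps` and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(snr = 0))
#' ph$truth_alps
#' @export
generate_phantom <- function(config = phantom_config(),
                             scheme = default_scheme()) {
  stopifnot(inherits(config, "phantom_config"))
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (!scheme_identifiable(scheme))
    stop("scheme has fewer than 6 non-collinear non-zero-b directions")

  gs <- config$grid_shape
  nvox <- prod(gs)
  lp <- config$lambda_perp; lpar <- config$lambda_parallel
  boost <- config$perivascular_boost

  D_proj  <- diag(c(lp + boost, lp, lpar))
  D_assoc <- diag(c(lp + boost, lpar, lp))
  D_bg    <- diag(rep(config$d_background, 3))

  reg <- phantom_regions(gs)
  labels <- array(0L, gs)
  labels[reg$proj_right$x,  reg$proj_right$y,  reg$z] <- 1L
  labels[reg$assoc_right$x, reg$assoc_right$y, reg$z] <- 2L
  labels[reg$proj_left$x,   reg$proj_left$y,   reg$z] <- 3L
  labels[reg$assoc_left$x,  reg$assoc_left$y,  reg$z] <- 4L

  to6 <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tensors <- matrix(rep(to6(D_bg), each = nvox), nvox, 6)
  lab <- as.integer(labels)
  tensors[lab %in% c(1L, 3L), ] <- rep(to6(D_proj),  each = sum(lab %in% c(1L, 3L)))
  tensors[lab %in% c(2L, 4L), ] <- rep(to6(D_assoc), each = sum(lab %in% c(2L, 4L)))
  truth <- tensor_field(tensors, rep(config$s0, nvox), gs, config$voxel_size)

  nvol <- length(scheme$bvals)
  sig <- rbind(bg    = synthesize_signal(D_bg,    config$s0, scheme),
               proj  = synthesize_signal(D_proj,  config$s0, scheme),
               assoc = synthesize_signal(D_assoc, config$s0, scheme))
  kind <- ifelse(lab == 0L, 1L, ifelse(lab %in% c(1L, 3L), 2L, 3L))
  dwi <- array(sig[kind, ], c(gs, nvol))

  if (config$snr > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    sd_eff <- config$s0 / (config$snr * sqrt(config$n_averages))
    dwi <- dwi + array(stats::rnorm(length(dwi), sd = sd_eff), dim(dwi))
  }

  # measurement ROIs: the full slab cross-section on the mid slice
  mid_z <- max(1L, gs[3] %/% 2L)
  roi_from <- function(r, fiber, hemi) {
    roi_mask(as.matrix(expand.grid(i = r$x, j = r$y, k = mid_z)),
             fiber = fiber, hemisphere = hemi, voxel_size = config$voxel_size)
  }
  rois <- list(
    right = list(projection  = roi_from(reg$proj_right,  "projection",  "right"),
                 association = roi_from(reg$assoc_right, "association", "right")),
    left  = list(projection  = roi_from(reg$proj_left,   "projection",  "left"),
                 association = roi_from(reg$assoc_left,  "association", "left")))

  structure(list(dwi = dwi, scheme = scheme, truth = truth, labels = labels,
                 rois = rois, truth_alps = (lp + boost) / lp, config = config),
            class = "alps_phantom")
}

#' @export
print.alps_phantom <- function(x, ...) {
  cat(sprintf("alps_phantom: %s grid, %d volumes, SNR %g, ground-truth ALPS %.4f\n",
              paste(x$config$grid_shape, collapse = "x"),
              length(x$scheme$bvals), x$config$snr, x$truth_alps))
  invisible(x)
}

#' Write a phantom to NIfTI + gradient-table files
#'
#' Writes `<prefix>_dwi.nii.gz`, `<prefix>.bval`, `<prefix>.bvec` and the
#' fibre-ROI label volume `<prefix>_roi.nii.gz`.
#'
#' @param phantom an `alps_phantom` from [generate_phantom()].
#' @param prefix output path prefix.
#' @return Invisibly, the four paths written.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "alps_phantom"))
  pd <- phantom$config$voxel_size
  roi_lab <- array(0L, phantom$config$grid_shape)
  k <- 0L
  for (h in c("right", "left")) for (f in c("projection", "association")) {
    k <- k + 1L
    roi_lab[phantom$rois[[h]][[f]]$voxels] <- k
  }
  paths <- c(dwi = paste0(prefix, "_dwi.nii.gz"),
             bval = paste0(prefix, ".bval"),
             bvec = paste0(prefix, ".bvec"),
             roi = paste0(prefix, "_roi.nii.gz"))
  write_nifti_vol(phantom$dwi, pd, paths["dwi"])
  write_scheme(phantom$scheme, paths["bval"], paths["bvec"])
  write_nifti_vol(roi_lab, pd, paths["roi"])
  invisible(paths)
}
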