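#' Single-slice fibre region of interest
#'
#' An ROI is a set of voxels on one axial slice (all voxels share the
#' same z index), labelled with the fibre population it samples and the
#' hemisphere it belongs to, mirroring manual placement on a
#' directionally encoded colour map at the level of the lateral
#' ventricle body.
#'
#' @param voxels integer `n x 3` matrix of 1-based voxel indices (i, j, k).
#' @param fiber `"projection"` or `"association"`.
#' @param hemisphere `"right"` or `"left"`.
#' @param voxel_size voxel edge lengths in mm, used for the in-plane area.
#' @return An object of class `roi_mask` with an `area_mm2` field.
#' @export
roi_mask <- function(voxels, fiber = c("projection", "association"),
                     hemisphere = c("right", "left"),
                     voxel_size = c(1, 1, 1)) {
  fiber <- match.arg(fiber)
  hemisphere <- match.arg(hemisphere)
  voxels <- as.matrix(voxels)
  storage.mode(voxels) <- "integer"
  if (ncol(voxels) != 3 || nrow(voxels) < 1)
    stop("'voxels' must be a non-empty n x 3 index matrix")
  if (length(unique(voxels[, 3])) != 1)
    stop("an ROI must lie on a single axial slice")
  if (anyDuplicated(voxels)) stop("duplicate voxels in ROI")
  structure(list(voxels = voxels, fiber = fiber, hemisphere = hemisphere,
                 area_mm2 = nrow(voxels) * voxel_size[1] * voxel_size[2]),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %s %s fibre, %d voxels (%.1f mm^2), slice z = %d\n",
              x$hemisphere, x$fiber, nrow(x$voxels), x$area_mm2,
              x$voxels[1, 3]))
  invisible(x)
}

#' Build ROI masks from a label volume
#'
#' @param labels 3-D integer array (or NIfTI path) with one label value
#'   per ROI.
#' @param value the label value to extract.
#' @inheritParams roi_mask
#' @return A [roi_mask()].
#' @export
roi_from_labels <- function(labels, value, fiber, hemisphere,
                            voxel_size = c(1, 1, 1)) {
  if (is.character(labels)) {
    img <- RNifti::readNifti(labels)
    voxel_size <- RNifti::pixdim(img)[1:3]
    labels <- array(as.integer(round(as.numeric(img))), dim(img))
  }
  idx <- which(labels == value, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no voxels carry label ", value)
  roi_mask(idx, fiber = fiber, hemisphere = hemisphere,
           voxel_size = voxel_size)
}

#' Axis diffusivities of the ALPS geometry
#'
#' Mean tensor diagonal elements over the projection- and
#' association-fibre ROIs: the right-left (x) diffusivity in each fibre,
#' plus the diffusivity perpendicular to both the x axis and the fibre
#' axis (y in the projection fibre, z in the association fibre).
#'
#' @param d_xproj,d_yproj mean Dxx and Dyy over the projection-fibre ROI.
#' @param d_xassoc,d_zassoc mean Dxx and Dzz over the association-fibre ROI.
#' @return An object of class `axis_diffusivities`.
#' @export
axis_diffusivities <- function(d_xproj, d_yproj, d_xassoc, d_zassoc) {
  v <- c(d_xproj = d_xproj, d_yproj = d_yproj,
         d_xassoc = d_xassoc, d_zassoc = d_zassoc)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("axis diffusivities must be finite and > 0")
  structure(as.list(v), class = "axis_diffusivities")
}

#' Extract axis diffusivities from a tensor field
#'
#' @param field a [tensor_field()].
#' @param proj_roi projection-fibre [roi_mask()].
#' @param assoc_roi association-fibre [roi_mask()].
#' @return An [axis_diffusivities()] object. A warning is recorded if any
#'   ROI voxel had clipped eigenvalues during fitting.
#' @export
extract_axis_diffusivities <- function(field, proj_roi, assoc_roi) {
  stopifnot(inherits(field, "tensor_field"),
            inherits(proj_roi, "roi_mask"), inherits(assoc_roi, "roi_mask"))
  if (proj_roi$fiber != "projection" || assoc_roi$fiber != "association")
    stop("ROI fibre labels do not match the argument slots")
  ip <- voxel_index(field$dim, proj_roi$voxels)
  ia <- voxel_index(field$dim, assoc_roi$voxels)
  if (any(field$clipped[c(ip, ia)]))
    warning("ROI contains voxels with clipped tensor eigenvalues")
  axis_diffusivities(
    d_xproj  = mean(field$tensors[ip, "xx"]),
    d_yproj  = mean(field$tensors[ip, "yy"]),
    d_xassoc = mean(field$tensors[ia, "xx"]),
    d_zassoc = mean(field$tensors[ia, "zz"]))
}

#' The ALPS index
#'
#' Ratio of the mean right-left diffusivity in the two fibre ROIs to the
#' mean diffusivity perpendicular to both the vessels and the fibres:
#' `mean(d_xproj, d_xassoc) / mean(d_yproj, d_zassoc)`. Values near 1
#' indicate no preferential diffusion along the perivascular (x)
#' direction; larger values indicate more.
#'
#' @param d an [axis_diffusivities()] object, or a numeric vector with
#'   names `d_xproj, d_yproj, d_xassoc, d_zassoc`.
#' @return The unit-less index.
#' @examples
#' compute_alps(axis_diffusivities(1.2e-3, 0.7e-3, 1.0e-3, 0.9e-3))
#' @export
compute_alps <- function(d) {
  if (!inherits(d, "axis_diffusivities")) {
    d <- as.list(d)
    d <- axis_diffusivities(d$d_xproj, d$d_yproj, d$d_xassoc, d$d_zassoc)
  }
  mean(c(d$d_xproj, d$d_xassoc)) / mean(c(d$d_yproj, d$d_zassoc))
}

#' Single-observer ALPS measurement
#'
#' Convenience wrapper: extract axis diffusivities and compute the index
#' for one hemisphere and one observer.
#'
#' @inheritParams extract_axis_diffusivities
#' @param subject_id subject identifier carried into the result.
#' @param observer observer label (e.g. 1 or 2).
#' @return An object of class `alps_result` with fields `subject_id`,
#'   `hemisphere`, `observers` (per-observer diffusivities and index) and
#'   `index` (the final index, mean over observers).
#' @export
measure_alps <- function(field, proj_roi, assoc_roi, subject_id = NA_character_,
                         observer = 1L) {
  if (proj_roi$hemisphere != assoc_roi$hemisphere)
    stop("projection and association ROIs belong to different hemispheres")
  d <- extract_axis_diffusivities(field, proj_roi, assoc_roi)
  idx <- compute_alps(d)
  obs <- list(list(observer = observer, diffusivities = d, index = idx))
  structure(list(subject_id = subject_id,
                 hemisphere = proj_roi$hemisphere,
                 observers = obs, index = idx),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("alps_result: subject %s, %s hemisphere, %d observer(s), index %.4f\n",
              x$subject_id, x$hemisphere, length(x$observers), x$index))
  invisible(x)
}

#' Average two observers' ALPS measurements
#'
#' The final index for a subject and hemisphere is the arithmetic mean of
#' the two observers' independently measured indices.
#'
#' @param a,b `alps_result` objects for the same subject and hemisphere.
#' @return An `alps_result` carrying both observers and the averaged index.
#' @export
average_observers <- function(a, b) {
  stopifnot(inherits(a, "alps_result"), inherits(b, "alps_result"))
  if (a$hemisphere != b$hemisphere)
    stop("cannot average results from different hemispheres")
  if (!identical(a$subject_id, b$subject_id))
    stop("cannot average results from different subjects")
  obs <- c(a$observers, b$observers)
  idx <- mean(c(a$index, b$index))
  structure(list(subject_id = a$subject_id, hemisphere = a$hemisphere,
                 observers = obs, index = idx),
            class = "alps_result")
}

#' Tabulate ALPS results
#'
#' Flattens `alps_result` objects into the per-subject CSV layout
#' (subject, side, observer, four diffusivities, index; observer "final"
#' rows carry the averaged index).
#'
#' @param results list of `alps_result` objects.
#' @return A data.frame.
#' @export
alps_table <- function(results) {
  if (inherits(results, "alps_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    per_obs <- do.call(rbind, lapply(r$observers, function(o) {
      d <- o$diffusivities
      data.frame(subject_id = r$subject_id, side = r$hemisphere,
                 observer = as.character(o$observer),
                 d_xproj = d$d_xproj, d_yproj = d$d_yproj,
                 d_xassoc = d$d_xassoc, d_zassoc = d$d_zassoc,
                 index = o$index)
    }))
    rbind(per_obs,
          data.frame(subject_id = r$subject_id, side = r$hemisphere,
                     observer = "final", d_xproj = NA, d_yproj = NA,
                     d_xassoc = NA, d_zassoc = NA, index = r$index))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
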