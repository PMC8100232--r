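#' Planar polygonal ROI
#'
#' One manually drawn polygon on one transverse slice, in in-plane mm
#' coordinates. Polygons must be simple (non-self-intersecting) with at
#' least three vertices.
#'
#' @param vertices numeric `n x 2` matrix of (x, y) vertices in mm,
#'   ordered along the boundary; the polygon is implicitly closed.
#' @param slice integer slice index the polygon was drawn on.
#' @param lesion lesion identifier; polygons sharing an id belong to one
#'   lesion.
#' @return An object of class `planar_polygon`.
#' @export
planar_polygon <- function(vertices, slice = 1L, lesion = 1L) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("a polygon needs at least 3 (x, y) vertices")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  if (anyDuplicated(vertices)) stop("repeated vertices")
  if (self_intersects(vertices)) stop("polygon is self-intersecting")
  structure(list(vertices = vertices, slice = as.integer(slice),
                 lesion = lesion),
            class = "planar_polygon")
}

# segment-intersection test over all non-adjacent edge pairs
self_intersects <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  on_seg <- function(px, py, qx, qy, rx, ry)
    rx <= pmax(px, qx) + 1e-12 & rx >= pmin(px, qx) - 1e-12 &
    ry <= pmax(py, qy) + 1e-12 & ry >= pmin(py, qy) - 1e-12
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]      # skip edges sharing a vertex
    for (j in js) {
      d1 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d2 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      d3 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d4 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
      if (d1 == 0 && on_seg(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])) return(TRUE)
      if (d2 == 0 && on_seg(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])) return(TRUE)
      if (d3 == 0 && on_seg(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])) return(TRUE)
      if (d4 == 0 && on_seg(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area by the shoelace formula
#'
#' Absolute value of the signed shoelace area, so the result does not
#' depend on vertex orientation.
#'
#' @param p a [planar_polygon()] or an `n x 2` vertex matrix.
#' @return Area in mm^2.
#' @examples
#' polygon_area(planar_polygon(rbind(c(0, 0), c(4, 0), c(0, 3))))
#' @export
polygon_area <- function(p) {
  v <- if (inherits(p, "planar_polygon")) p$vertices else
    planar_polygon(p)$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Stack of planar ROIs for one structure
#'
#' Groups the polygons outlining one structure (a tumor or its
#' peritumoral edema) across slices and lesions, together with the slice
#' thickness. Two polygons of the same lesion on the same slice are
#' rejected; distinct lesions may share a slice.
#'
#' @param polygons list of [planar_polygon()] objects.
#' @param slice_thickness slice thickness in mm.
#' @param kind `"tumor"` or `"ptbe"`.
#' @return An object of class `roi_stack`.
#' @export
roi_stack <- function(polygons, slice_thickness, kind = c("tumor", "ptbe")) {
  kind <- match.arg(kind)
  if (slice_thickness <= 0) stop("'slice_thickness' must be > 0")
  if (length(polygons)) {
    stopifnot(all(vapply(polygons, inherits, TRUE, "planar_polygon")))
    key <- vapply(polygons, function(p) paste(p$lesion, p$slice), "")
    if (anyDuplicated(key))
      stop("duplicate polygon for one lesion on one slice")
  }
  structure(list(polygons = polygons, slice_thickness = slice_thickness,
                 kind = kind),
            class = "roi_stack")
}

#' Volume of an ROI stack
#'
#' Sums polygon area times slice thickness over all slices and lesions
#' (multiple lesions are measured separately and their volumes summed),
#' with no inter-slice interpolation, and converts mm^3 to cm^3.
#'
#' @param s an [roi_stack()].
#' @return Volume in cm^3. An empty stack returns 0 with a warning.
#' @export
stack_volume <- function(s) {
  stopifnot(inherits(s, "roi_stack"))
  if (!length(s$polygons)) {
    warning("empty ROI stack; volume 0")
    return(0)
  }
  areas <- vapply(s$polygons, polygon_area, 0)
  sum(areas) * s$slice_thickness / 1000
}

#' Volume of a binary mask
#'
#' Voxel-counting alternative used when the structure is supplied as a
#' binary mask volume instead of polygon outlines.
#'
#' @param mask 3-D array (non-zero = inside) or path to a NIfTI mask.
#' @param voxel_size voxel edge lengths in mm (read from the header when
#'   `mask` is a path).
#' @return Volume in cm^3.
#' @export
mask_volume <- function(mask, voxel_size = c(1, 1, 1)) {
  if (is.character(mask)) {
    img <- RNifti::readNifti(mask)
    voxel_size <- RNifti::pixdim(img)[1:3]
    mask <- as.numeric(img) != 0
  }
  sum(mask != 0) * prod(voxel_size) / 1000
}

#' Read an ROI stack from JSON
#'
#' The JSON layout is a list of polygons, each with `slice`, `lesion`
#' and an `n x 2` `vertices` array in mm, plus top-level
#' `slice_thickness` and `kind`.
#'
#' @param path JSON file path.
#' @return An [roi_stack()].
#' @export
read_roi_stack <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- lapply(j$polygons, function(p) {
    v <- p$vertices
    vm <- if (is.list(v)) do.call(rbind, lapply(v, function(r)
      as.numeric(unlist(r)))) else matrix(as.numeric(v), ncol = 2)
    planar_polygon(vm, slice = p$slice, lesion = p$lesion)
  })
  roi_stack(polys, j$slice_thickness, j$kind)
}
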