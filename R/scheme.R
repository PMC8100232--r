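#' Diffusion acquisition scheme
#'
#' Bundles b-values and gradient directions for a diffusion-weighted
#' acquisition. Directions are stored one per row in image coordinates
#' (x = right-left, y = anterior-posterior, z = craniocaudal). Gradient
#' tables are assumed to already be in image coordinates; set `flip` to
#' reverse the sign of individual axes if a table uses the opposite
#' convention.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs numeric matrix of gradient directions, `length(bvals)` rows
#'   by 3 columns. Rows with `b > 0` must have unit norm (tolerance 1e-6);
#'   rows with `b = 0` are ignored and may be zero.
#' @param flip length-3 vector of +1/-1 sign flips applied to the x, y, z
#'   components of `bvecs`.
#' @return An object of class `acquisition_scheme` with elements `bvals`
#'   and `bvecs`.
#' @examples
#' sch <- default_scheme()
#' sum(sch$bvals == 0)
#' @export
acquisition_scheme <- function(bvals, bvecs, flip = c(1, 1, 1)) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3 || nrow(bvecs) != length(bvals))
    stop("'bvecs' must be a length(bvals) x 3 matrix")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  stopifnot(length(flip) == 3, all(flip %in% c(-1, 1)))
  bvecs <- sweep(bvecs, 2, flip, `*`)
  nz <- bvals > 0
  if (!any(!nz)) stop("scheme must contain at least one b = 0 volume")
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("non-zero-b gradient directions must have unit norm (within 1e-6)")
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("acquisition_scheme: %d volumes (%d b=0), b in [%g, %g] s/mm^2\n",
              length(x$bvals), sum(x$bvals == 0), min(x$bvals), max(x$bvals)))
  invisible(x)
}

#' Default single-shell scheme
#'
#' A deterministic 20-direction, b = 1000 s/mm^2 scheme with one b = 0
#' volume, mirroring a typical clinical single-shot EPI DTI protocol.
#' Directions are placed on a Fibonacci hemisphere, which keeps them
#' well-spread and non-collinear.
#'
#' @param n_dir number of diffusion-encoding directions.
#' @param b b-value of the diffusion-weighted volumes, s/mm^2.
#' @param n_b0 number of unweighted volumes.
#' @return An [acquisition_scheme()].
#' @export
default_scheme <- function(n_dir = 20, b = 1000, n_b0 = 1) {
  stopifnot(n_dir >= 6, b > 0, n_b0 >= 1)
  i <- seq_len(n_dir) - 0.5
  z <- i / n_dir                      # hemisphere only: antipodal dirs are redundant
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  acquisition_scheme(c(rep(0, n_b0), rep(b, n_dir)),
                     rbind(matrix(0, n_b0, 3), dirs))
}

#' Read and write FSL-style gradient tables
#'
#' `read_scheme()` reads whitespace-delimited `bval` (one row) and `bvec`
#' (three rows, x/y/z) text files; `write_scheme()` writes them.
#'
#' @param bval_path,bvec_path paths to the text files.
#' @param scheme an [acquisition_scheme()].
#' @inheritParams acquisition_scheme
#' @return `read_scheme()` returns an [acquisition_scheme()];
#'   `write_scheme()` returns the scheme invisibly.
#' @export
read_scheme <- function(bval_path, bvec_path, flip = c(1, 1, 1)) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  acquisition_scheme(bvals, bvecs, flip = flip)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  utils::write.table(t(scheme$bvecs), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(scheme)
}

# Design matrix of the log-linear tensor model: columns are
# log(S0), Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
tensor_design <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

# A scheme identifies the 6 tensor elements iff the diffusion-weighted part
# of the design has full column rank, which requires >= 6 non-collinear
# directions.
scheme_identifiable <- function(scheme) {
  nz <- scheme$bvals > 0
  if (sum(nz) < 6) return(FALSE)
  X <- tensor_design(scheme)[nz, -1, drop = FALSE]
  qr(X)$rank == 6
}
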