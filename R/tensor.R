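#' Diffusion tensor forward model
#'
#' Predicts the diffusion-weighted signal of a single voxel under the
#' standard monoexponential tensor model: for each volume,
#' `S = s0 * exp(-b * t(g) %*% D %*% g)`.
#'
#' @param D symmetric 3x3 diffusion tensor, mm^2/s.
#' @param s0 baseline (b = 0) signal, arbitrary units.
#' @param scheme an [acquisition_scheme()].
#' @return Numeric vector of signals, one per volume.
#' @examples
#' sch <- default_scheme()
#' synthesize_signal(diag(3) * 1e-3, 1, sch)
#' @export
synthesize_signal <- function(D, s0, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    stop("'D' must be a symmetric 3x3 matrix")
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values < -1e-15))
    stop("'D' must be positive semi-definite")
  if (s0 < 0) stop("'s0' must be non-negative")
  g <- scheme$bvecs
  quad <- rowSums((g %*% D) * g)
  as.numeric(s0 * exp(-scheme$bvals * quad))
}

#' Per-voxel tensor field
#'
#' Container for fitted (or analytically constructed) diffusion tensors.
#' Tensors are stored as an `n_voxel x 6` matrix of unique elements in the
#' order `xx, yy, zz, xy, xz, yz` (mm^2/s), alongside the per-voxel
#' baseline signal and quality flags.
#'
#' @param tensors `n x 6` matrix of tensor elements (`xx, yy, zz, xy, xz, yz`).
#' @param s0 per-voxel baseline signal.
#' @param dim length-3 integer grid shape.
#' @param voxel_size length-3 voxel edge lengths, mm.
#' @param clipped logical per voxel: eigenvalues were clipped to the
#'   positivity floor during fitting.
#' @param floored logical per voxel: at least one non-positive signal was
#'   floored before the log transform.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensors, s0, dim, voxel_size = c(1, 1, 1),
                         clipped = rep(FALSE, nrow(tensors)),
                         floored = rep(FALSE, nrow(tensors))) {
  tensors <- as.matrix(tensors)
  stopifnot(ncol(tensors) == 6, length(dim) == 3,
            nrow(tensors) == prod(dim), length(s0) == nrow(tensors),
            length(voxel_size) == 3, all(voxel_size > 0))
  colnames(tensors) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  structure(list(tensors = tensors, s0 = as.numeric(s0),
                 dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 clipped = as.logical(clipped), floored = as.logical(floored)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %d x %d x %d voxels (%g x %g x %g mm), %d clipped\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              sum(x$clipped)))
  invisible(x)
}

# linear index into the voxel-major storage
voxel_index <- function(dim, vox) {
  vox <- matrix(as.integer(vox), ncol = 3)
  if (any(vox < 1) || any(vox[, 1] > dim[1]) || any(vox[, 2] > dim[2]) ||
      any(vox[, 3] > dim[3]))
    stop("voxel indices outside the grid")
  vox[, 1] + (vox[, 2] - 1L) * dim[1] + (vox[, 3] - 1L) * dim[1] * dim[2]
}

# expand a 6-element row to the full symmetric matrix
tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Fit diffusion tensors by weighted log-linear least squares
#'
#' Estimates a symmetric tensor and baseline signal per voxel from the
#' log-transformed signals. The fit is ordinary least squares on
#' `log(S)` followed by one signal-squared-weighted refinement pass
#' (weights `S^2`), the standard correction for the log transform's
#' heteroscedasticity. Multiple b = 0 volumes are averaged into one
#' before fitting. Non-positive signals are floored at `min_signal` and
#' flagged; negative eigenvalues are clipped to `eig_floor` and flagged.
#'
#' @param dwi 4-D numeric array (`x, y, z, volume`) of signals, or an
#'   `n_voxel x n_volume` matrix (then `dim` must be given).
#' @param scheme an [acquisition_scheme()] with at least 6 non-collinear
#'   non-zero-b directions.
#' @param voxel_size length-3 voxel edge lengths, mm.
#' @param dim grid shape when `dwi` is a matrix.
#' @param weighted logical; apply the weighted refinement pass.
#' @param min_signal positive floor applied to non-positive signals.
#' @param eig_floor positivity floor for eigenvalues, mm^2/s.
#' @return A [tensor_field()].
#' @examples
#' sch <- default_scheme()
#' D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
#' s <- synthesize_signal(D, 100, sch)
#' f <- fit_tensor(array(s, c(1, 1, 1, length(s))), sch)
#' round(f$tensors, 6)
#' @export
fit_tensor <- function(dwi, scheme, voxel_size = c(1, 1, 1), dim = NULL,
                       weighted = TRUE, min_signal = 1e-8, eig_floor = 1e-6) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (!scheme_identifiable(scheme))
    stop("scheme has fewer than 6 non-collinear non-zero-b directions; ",
         "the tensor is not identifiable")
  if (is.array(dwi) && length(base::dim(dwi)) == 4) {
    dim <- base::dim(dwi)[1:3]
    S <- matrix(dwi, prod(dim), base::dim(dwi)[4])
  } else {
    if (is.null(dim)) stop("'dim' is required when 'dwi' is a matrix")
    S <- as.matrix(dwi)
  }
  if (ncol(S) != length(scheme$bvals))
    stop("number of volumes does not match the scheme")

  # average b=0 volumes into a single column
  b0 <- scheme$bvals == 0
  if (sum(b0) > 1) {
    S <- cbind(rowMeans(S[, b0, drop = FALSE]), S[, !b0, drop = FALSE])
    scheme <- acquisition_scheme(c(0, scheme$bvals[!b0]),
                                 rbind(c(0, 0, 0),
                                       scheme$bvecs[!b0, , drop = FALSE]))
  }

  nvox <- nrow(S)
  dead <- rowSums(abs(S)) == 0
  floored <- rowSums(S <= 0) > 0 & !dead
  S[S <= min_signal] <- min_signal

  X <- tensor_design(scheme)
  logS <- log(S)
  # OLS for every voxel at once: coef is nvox x 7
  coef <- logS %*% t(chol2inv(chol(crossprod(X))) %*% t(X))
  if (weighted) {
    # batched WLS normal equations: for voxel v,
    # (X' W_v X) b = X' W_v y with W_v = diag(S[v, ]^2).
    # All 28 unique entries of X'W_vX are linear in the weights, so they
    # come from one matrix product; the 7x7 solves remain per voxel.
    W <- S^2
    p <- ncol(X)
    pair_i <- rep(seq_len(p), times = p:1)
    pair_j <- unlist(lapply(seq_len(p), function(a) a:p))
    P <- X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE]
    A <- W %*% P                        # nvox x 28
    Bv <- (W * logS) %*% X              # nvox x 7
    M <- matrix(0, p, p)
    low <- cbind(pair_i, pair_j)
    for (v in which(!dead)) {
      M[low] <- A[v, ]; M[low[, 2:1]] <- A[v, ]
      cf <- tryCatch(solve(M, Bv[v, ]), error = function(e) NULL)
      if (!is.null(cf)) coef[v, ] <- cf
    }
  }

  tensors <- coef[, 2:7, drop = FALSE]
  s0 <- exp(coef[, 1])
  tensors[dead, ] <- 0
  s0[dead] <- 0

  # Sylvester check for positive definiteness (with the eigenvalue floor
  # folded in); only failing voxels need an eigendecomposition.
  shift <- tensors[, 1:3, drop = FALSE] - eig_floor
  m1 <- shift[, 1]
  m2 <- shift[, 1] * shift[, 2] - tensors[, 4]^2
  m3 <- shift[, 1] * (shift[, 2] * shift[, 3] - tensors[, 6]^2) -
    tensors[, 4] * (tensors[, 4] * shift[, 3] - tensors[, 6] * tensors[, 5]) +
    tensors[, 5] * (tensors[, 4] * tensors[, 6] - shift[, 2] * tensors[, 5])
  suspect <- which(!(m1 > 0 & m2 > 0 & m3 > 0) & !dead)
  clipped <- logical(nvox)
  for (v in suspect) {
    e <- eigen(tensor6_to_mat(tensors[v, ]), symmetric = TRUE)
    if (any(e$values < eig_floor)) {
      clipped[v] <- TRUE
      lam <- pmax(e$values, eig_floor)
      Dm <- e$vectors %*% diag(lam) %*% t(e$vectors)
      tensors[v, ] <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3],
                        Dm[1, 2], Dm[1, 3], Dm[2, 3])
    }
  }
  clipped[dead] <- TRUE

  tensor_field(tensors, s0, dim, voxel_size,
               clipped = clipped, floored = floored | dead)
}

#' Scalar and directional maps from a tensor field
#'
#' Computes fractional anisotropy, the principal diffusion direction
#' (unit eigenvector of the largest eigenvalue), and the directionally
#' encoded colour map whose three channels are `|x|, |y|, |z|` of the
#' principal direction scaled by FA, as used to visualise projection
#' (blue, z) and association (green, y) fibres.
#'
#' @param field a [tensor_field()].
#' @return A list with `fa` (3-D array in `[0, 1]`), `v1`
#'   (4-D array, last dimension the x/y/z components) and `color`
#'   (4-D array, channels `|x|,|y|,|z|` times FA). Degenerate voxels get
#'   FA 0 and an arbitrary direction.
#' @export
scalar_maps <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  n <- nrow(field$tensors)
  fa <- numeric(n)
  v1 <- matrix(0, n, 3)
  for (v in seq_len(n)) {
    e <- eigen(tensor6_to_mat(field$tensors[v, ]), symmetric = TRUE)
    lam <- e$values
    md <- mean(lam)
    den <- sum(lam^2)
    fa[v] <- if (den <= 0) 0 else sqrt(1.5 * sum((lam - md)^2) / den)
    v1[v, ] <- e$vectors[, 1]
  }
  fa <- pmin(pmax(fa, 0), 1)
  col <- abs(v1) * fa
  list(fa = array(fa, field$dim),
       v1 = array(v1, c(field$dim, 3)),
       color = array(col, c(field$dim, 3)))
}

#' Read a 4-D DWI NIfTI with its gradient table
#'
#' @param dwi_path path to a 4-D NIfTI file.
#' @param bval_path,bvec_path FSL-style gradient table text files.
#' @inheritParams acquisition_scheme
#' @return A list with `dwi` (4-D array), `scheme` and `voxel_size` (mm).
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path, flip = c(1, 1, 1)) {
  img <- RNifti::readNifti(dwi_path)
  scheme <- read_scheme(bval_path, bvec_path, flip = flip)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4-D DWI volume")
  if (d[4] != length(scheme$bvals))
    stop("volume count does not match the bval file")
  list(dwi = array(as.numeric(img), d), scheme = scheme,
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write tensor-derived maps as NIfTI volumes
#'
#' Writes FA, the directionally encoded colour map and the six tensor
#' element volumes under `prefix` (`<prefix>_fa.nii.gz`, `_dec.nii.gz`,
#' `_tensor.nii.gz`).
#'
#' @param field a [tensor_field()].
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_tensor_maps <- function(field, prefix) {
  maps <- scalar_maps(field)
  pd <- field$voxel_size
  paths <- c(fa = paste0(prefix, "_fa.nii.gz"),
             dec = paste0(prefix, "_dec.nii.gz"),
             tensor = paste0(prefix, "_tensor.nii.gz"))
  write_nifti_vol(maps$fa, pd, paths["fa"])
  write_nifti_vol(maps$color, pd, paths["dec"])
  write_nifti_vol(array(field$tensors, c(field$dim, 6)), pd, paths["tensor"])
  invisible(paths)
}

# write an array as NIfTI with the spatial pixdim set
write_nifti_vol <- function(arr, voxel_size, path) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_size, rep(1, max(0, nd - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
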