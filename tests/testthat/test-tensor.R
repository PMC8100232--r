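test_that("forward model matches the closed form in simple geometries", {
  sch <- default_scheme()
  # b = 0 volumes return s0 regardless of the tensor
  s <- synthesize_signal(diag(3) * 1e-3, 5, sch)
  expect_equal(s[sch$bvals == 0], rep(5, sum(sch$bvals == 0)))
  # isotropic tensor at b = 1000: attenuation exp(-1) for any direction
  expect_equal(s[sch$bvals > 0], rep(5 * exp(-1), 20))
  # diagonal tensor probed along x sees only Dxx
  sch_x <- acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  D <- diag(c(1.2e-3, 0.4e-3, 0.9e-3))
  expect_equal(synthesize_signal(D, 2, sch_x)[2], 2 * exp(-1000 * 1.2e-3))
})

test_that("forward model rejects invalid tensors", {
  sch <- default_scheme()
  M <- matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1) * 1e-3, 3, 3)
  expect_error(synthesize_signal(M, 1, sch), "symmetric")
  expect_error(synthesize_signal(diag(c(-1, 1, 1)) * 1e-3, 1, sch),
               "semi-definite")
})

test_that("noiseless fit inverts the forward model to near machine precision", {
  sch <- default_scheme()
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  s <- synthesize_signal(D, 100, sch)
  f <- fit_tensor(array(s, c(1, 1, 1, length(s))), sch)
  expect_lt(max(abs(f$tensors[1, ] -
                      c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0))), 1e-12)
  expect_equal(f$s0[1], 100, tolerance = 1e-10)
  expect_false(any(f$clipped))
})

test_that("round trip holds for random positive-definite tensors", {
  set.seed(41)
  sch <- default_scheme()
  for (i in 1:20) {
    D <- random_spd_tensor()
    s0 <- stats::runif(1, 10, 500)
    s <- synthesize_signal(D, s0, sch)
    f <- fit_tensor(array(s, c(1, 1, 1, length(s))), sch)
    d6 <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    expect_lt(max(abs(f$tensors[1, ] - d6)) / max(abs(d6)), 1e-9)
  }
})

test_that("fitted eigenvalues are rotation-equivariant", {
  set.seed(5)
  sch <- default_scheme()
  D <- random_spd_tensor()
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  sch_rot <- acquisition_scheme(sch$bvals, sch$bvecs %*% t(R))
  Drot <- R %*% D %*% t(R)
  f1 <- fit_tensor(array(synthesize_signal(D, 1, sch), c(1, 1, 1, 21)), sch)
  f2 <- fit_tensor(array(synthesize_signal(Drot, 1, sch_rot), c(1, 1, 1, 21)),
                   sch_rot)
  ev <- function(f) eigen(matrix(c(f$tensors[1, c(1, 4, 5)],
                                   f$tensors[1, c(4, 2, 6)],
                                   f$tensors[1, c(5, 6, 3)]), 3),
                          symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev(f1), ev(f2), tolerance = 1e-9)
})

test_that("unidentifiable or degenerate schemes are rejected", {
  expect_error(acquisition_scheme(c(1000, 1000), rbind(c(1, 0, 0), c(0, 1, 0))),
               "b = 0")
  only_b0 <- acquisition_scheme(c(0, 0), matrix(0, 2, 3))
  expect_error(fit_tensor(array(1, c(1, 1, 1, 2)), only_b0), "6 non-collinear")
  # 6 directions but collinear (all +/- x): rank-deficient
  coll <- acquisition_scheme(c(0, rep(1000, 6)),
                             rbind(c(0, 0, 0),
                                   matrix(rep(c(1, 0, 0), 6), 6, 3,
                                          byrow = TRUE) *
                                     c(1, -1, 1, -1, 1, -1)))
  expect_error(fit_tensor(array(1, c(1, 1, 1, 7)), coll), "6 non-collinear")
})

test_that("all-zero voxels are flagged and zeroed, non-positive signals floored", {
  sch <- default_scheme()
  s <- synthesize_signal(diag(3) * 1e-3, 10, sch)
  dwi <- rbind(s, rep(0, length(s)))          # voxel 2 is empty
  f <- fit_tensor(dwi, sch, dim = c(2, 1, 1))
  expect_true(f$floored[2])
  expect_equal(unname(f$tensors[2, ]), rep(0, 6))
  expect_false(f$floored[1])
})

test_that("scalar maps give FA, principal directions and colour channels", {
  sch <- default_scheme()
  iso <- synthesize_signal(diag(3) * 1e-3, 1, sch)
  ani <- synthesize_signal(diag(c(1.7, 0.3, 0.3)) * 1e-3, 1, sch)
  f <- fit_tensor(matrix(c(iso, ani), 2, byrow = TRUE), sch, dim = c(2, 1, 1))
  m <- scalar_maps(f)
  expect_lt(abs(m$fa[1]), 1e-9)                         # isotropic: FA 0
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa_true <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(m$fa[2], fa_true, tolerance = 1e-9)
  expect_equal(abs(m$v1[2, 1, 1, ]), c(1, 0, 0), tolerance = 1e-9)
  # dominant colour channel of projection-fibre voxels is z
  ph <- generate_phantom(small_phantom_config(snr = 0))
  mm <- scalar_maps(ph$truth)
  vox <- ph$rois$right$projection$voxels[1, ]
  ch <- mm$color[vox[1], vox[2], vox[3], ]
  expect_identical(which.max(ch), 3L)
  vox_a <- ph$rois$right$association$voxels[1, ]
  expect_identical(which.max(mm$color[vox_a[1], vox_a[2], vox_a[3], ]), 2L)
})

test_that("tensor error shrinks with more signal averages at fixed SNR", {
  errs <- sapply(c(1, 4, 16), function(na) {
    ph <- generate_phantom(small_phantom_config(snr = 20, n_averages = na,
                                                seed = 9))
    f <- fit_tensor(ph$dwi, ph$scheme)
    stats::median(abs(f$tensors - ph$truth$tensors))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("gradient tables round-trip through FSL-style files", {
  sch <- default_scheme()
  bv <- tempfile(fileext = ".bval"); gv <- tempfile(fileext = ".bvec")
  write_scheme(sch, bv, gv)
  sch2 <- read_scheme(bv, gv)
  expect_equal(sch2$bvals, sch$bvals)
  expect_equal(sch2$bvecs, sch$bvecs, tolerance = 1e-12,
               ignore_attr = TRUE)
  # sign-flip flag mirrors the x axis
  sch3 <- read_scheme(bv, gv, flip = c(-1, 1, 1))
  expect_equal(sch3$bvecs[, 1], -sch$bvecs[, 1], ignore_attr = TRUE)
})
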