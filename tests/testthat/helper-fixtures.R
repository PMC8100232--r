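# Small shared fixtures; everything is generated in code.

# fast phantom settings for unit tests (the default 64x64x12 grid is
# used only where the test needs its noise-averaging properties)
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(16, 16, 6), ...)
}

# random symmetric positive-definite tensor with eigenvalues in
# [0.2, 1.8] x 1e-3 mm^2/s
random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  lam <- stats::runif(3, 0.2e-3, 1.8e-3)
  Q %*% diag(lam) %*% t(Q)
}

# uniform tensor field: every voxel carries the same 6-vector
uniform_field <- function(d6, dim = c(4, 4, 2), s0 = 1) {
  tensor_field(matrix(rep(d6, each = prod(dim)), prod(dim), 6),
               rep(s0, prod(dim)), dim)
}

# ICC(A,1) oracle: mean squares from an explicit two-way ANOVA via aov(),
# then the absolute-agreement single-rater formula
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(score = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(score ~ subj + rater, data = long))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# rasterization oracle for convex polygon areas: count 0.05 mm pixel
# centres inside (all edge cross-products share a sign)
raster_area_convex <- function(v, res = 0.05) {
  n <- nrow(v)
  xs <- seq(min(v[, 1]) - res, max(v[, 1]) + res, by = res)
  ys <- seq(min(v[, 2]) - res, max(v[, 2]) + res, by = res)
  g <- expand.grid(x = xs, y = ys)
  inside <- rep(TRUE, nrow(g))
  orient <- sum((v[c(2:n, 1), 1] - v[, 1]) * (v[c(2:n, 1), 2] + v[, 2]))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (v[j, 1] - v[i, 1]) * (g$y - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (g$x - v[i, 1])
    inside <- inside & (if (orient < 0) cr >= 0 else cr <= 0)
  }
  sum(inside) * res^2
}

# random convex polygon: convex hull of random points
random_convex_polygon <- function(n_pts = 12, scale = 10) {
  p <- matrix(stats::runif(2 * n_pts, 0, scale), ncol = 2)
  h <- grDevices::chull(p)
  p[h, , drop = FALSE]
}
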