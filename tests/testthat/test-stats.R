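test_that("the normality screen accepts normal and rejects uniform samples", {
  set.seed(19)
  expect_true(ks_normality(stats::rnorm(1e4))$is_normal)
  expect_false(ks_normality(stats::runif(1e4))$is_normal)
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("ICC(A,1) equals the ANOVA mean-squares oracle on integer matrices", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(5:6, 1)
    m <- matrix(sample(0:5, 2 * n, replace = TRUE), n, 2)
    if (stats::var(rowMeans(m)) == 0) next
    expect_equal(icc_absolute_agreement(m)$icc, icc_oracle(m),
                 tolerance = 1e-12)
  }
})

test_that("ICC(A,1) and its F-based CI match an independent implementation", {
  # frozen from pingouin.intraclass_corr (ICC(A,1) rows)
  m1 <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  r1 <- icc_absolute_agreement(m1)
  expect_equal(r1$icc, 0.125654, tolerance = 1e-4)
  expect_equal(r1$p_value, 0.027249, tolerance = 1e-4)
  expect_lt(abs(r1$ci_low - (-0.02)), 0.005)
  expect_lt(abs(r1$ci_high - 0.60), 0.005)
  m2 <- cbind(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  r2 <- icc_absolute_agreement(m2)
  expect_equal(r2$icc, 0.833333, tolerance = 1e-5)
  expect_equal(r2$p_value, 0.028, tolerance = 1e-3)
})

test_that("absolute agreement penalises a fixed rater bias", {
  x <- c(1, 2, 3, 4, 5)
  biased <- icc_absolute_agreement(cbind(x, x + 10))
  expect_lt(biased$icc, 0.1)
  # the consistency form from the same mean squares would be 1
  ms <- biased$ms
  expect_equal((ms$msr - ms$mse) / (ms$msr + ms$mse), 1)
  expect_equal(icc_absolute_agreement(cbind(x, x))$icc, 1)
  expect_true(icc_absolute_agreement(matrix(2, 5, 2) +
                                       0 * diag(5)[, c(1, 1)])$undefined)
  expect_error(icc_absolute_agreement(cbind(c(1, 2, NA, 4, 5), x)),
               "missing")
})

test_that("ANCOVA contrasts reproduce estimated-marginal-means results", {
  co <- generate_cohort(cohort_config(seed = 42))
  a <- ancova_pairwise(co, "alps_right", "group")
  fit <- stats::lm(alps_right ~ group + age + sex, data = co)
  em <- emmeans::emmeans(fit, "group")
  prs <- summary(emmeans::contrast(em, "pairwise"), adjust = "bonferroni")
  ci <- stats::confint(emmeans::contrast(em, "pairwise"),
                       adjust = "bonferroni")
  # emmeans orders pairs the same way (level order)
  expect_equal(a$contrasts$difference, prs$estimate, tolerance = 1e-10)
  expect_equal(a$contrasts$p_adj, prs$p.value, tolerance = 1e-10)
  expect_equal(a$contrasts$ci_low, ci$lower.CL, tolerance = 1e-10)
  expect_equal(a$contrasts$ci_high, ci$upper.CL, tolerance = 1e-10)
  expect_equal(a$contrasts$p_adj, pmin(1, 3 * a$contrasts$p_raw))
})

test_that("ANCOVA validates its design", {
  co <- generate_cohort(cohort_config(seed = 1))
  co$const <- 1
  expect_error(ancova_pairwise(co, "alps_right", "group",
                               covariates = "const"), "constant")
  co$dup <- as.numeric(factor(co$group))
  expect_error(ancova_pairwise(co, "alps_right", "group",
                               covariates = c("age", "dup")), "singular")
  tiny <- co[c(1:2, 14:16, 45:50), ]
  expect_error(ancova_pairwise(tiny, "alps_right", "group"), "at least 3")
})

test_that("ANCOVA stays calibrated under null covariates and tracks ANOVA", {
  set.seed(61)
  raw_sig <- 0; p_anc <- p_anv <- numeric(200)
  for (i in 1:200) {
    n <- 60
    d <- data.frame(y = stats::rnorm(n),
                    g = factor(rep(c("a", "b", "c"), each = 20)),
                    age = stats::rnorm(n), sex = stats::rbinom(n, 1, 0.5))
    a <- ancova_pairwise(d, "y", "g")
    raw_sig <- raw_sig + (a$contrasts$p_raw[1] < 0.05)
    p_anc[i] <- a$contrasts$p_raw[1]
    p_anv[i] <- summary(stats::lm(y ~ g, d))$coefficients["gb", 4]
  }
  expect_lt(abs(raw_sig / 200 - 0.05), 0.04)   # type-I calibration
  # covariates with zero true effect leave the contrast essentially the
  # ANOVA one up to finite-sample covariate noise
  expect_lt(stats::median(abs(p_anc - p_anv)), 0.06)
  expect_gt(stats::cor(p_anc, p_anv), 0.9)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x + 1)$r, 1.0)
  set.seed(2)
  y <- stats::rnorm(20)
  y_orth <- stats::residuals(stats::lm(y ~ x))   # orthogonal by construction
  expect_lt(abs(pearson(x, y_orth)$r), 1e-12)
  expect_error(pearson(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson(rep(1, 10), stats::rnorm(10)), "constant")
})

test_that("VIFs equal 1/(1-R^2) from independent per-column regressions", {
  set.seed(33)
  n <- 20
  X <- data.frame(a = stats::rnorm(n))
  X$b <- 0.8 * X$a + stats::rnorm(n, sd = 0.4)
  X$c <- -0.5 * X$b + stats::rnorm(n, sd = 0.7)
  v <- vif(X)
  for (j in 1:3) {
    r2 <- summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared
    expect_equal(v$vif[j], 1 / (1 - r2), tolerance = 1e-10)
  }
  # agreement with the standard regression diagnostic
  y <- stats::rnorm(n)
  expect_equal(v$vif, unname(car::vif(stats::lm(y ~ a + b + c, data = X))),
               tolerance = 1e-10)
  # orthogonal (and centred) candidates -> all VIF exactly 1
  Q <- as.data.frame(unclass(stats::poly(seq_len(n), 3)))
  names(Q) <- c("p1", "p2", "p3")
  expect_equal(vif(Q)$vif, rep(1, 3), tolerance = 1e-10)
  # duplicated candidate -> infinite and flagged
  X$d <- X$a
  vd <- suppressWarnings(vif(X))
  expect_true(all(vd$collinear[vd$candidate %in% c("a", "d")]))
  expect_true(all(is.infinite(vd$vif[vd$candidate %in% c("a", "d")])))
})

test_that("stepwise recovers an exact linear dependence", {
  set.seed(4)
  d <- data.frame(x1 = stats::rnorm(40), x2 = stats::rnorm(40),
                  x3 = stats::rnorm(40))
  d$y <- 3 * d$x1
  r <- suppressWarnings(stepwise_regression(d, "y", c("x1", "x2", "x3")))
  expect_identical(r$selected, "x1")
  expect_equal(r$coefficients$beta, 1.0, tolerance = 1e-9)
  expect_equal(r$r_squared, 1.0, tolerance = 1e-12)
  d$y2 <- -2 * d$x2
  r2 <- suppressWarnings(stepwise_regression(d, "y2", c("x1", "x2", "x3")))
  expect_equal(r2$coefficients$beta, -1.0, tolerance = 1e-9)
})

test_that("stepwise entry and sole-selection rates match partial-F theory", {
  # with one strong predictor (std effect 0.6, n = 56) and 6 null
  # candidates at entry p <= 0.05, the chance that no null candidate ever
  # enters is about 0.95^6 = 0.735; the true predictor enters essentially
  # always
  set.seed(87)
  n_rep <- 150
  incl <- 0; sole <- 0
  for (i in seq_len(n_rep)) {
    n <- 56
    X <- matrix(stats::rnorm(n * 7), n, 7,
                dimnames = list(NULL, paste0("x", 1:7)))
    d <- as.data.frame(X)
    d$y <- 0.6 * d$x1 + sqrt(1 - 0.36) * stats::rnorm(n)
    r <- stepwise_regression(d, "y", paste0("x", 1:7))
    incl <- incl + ("x1" %in% r$selected)
    sole <- sole + identical(r$selected, "x1")
  }
  expect_gt(incl / n_rep, 0.99)
  expect_lt(abs(sole / n_rep - 0.95^6), 0.12)
})

test_that("stepwise returns the intercept-only model when nothing qualifies", {
  set.seed(55)
  d <- data.frame(y = stats::rnorm(30), x1 = stats::rnorm(30),
                  x2 = stats::rnorm(30))
  # force a null fit by using an absurdly strict entry threshold
  r <- stepwise_regression(d, "y", c("x1", "x2"), entry_p = 1e-12,
                           removal_p = 1e-11)
  expect_length(r$selected, 0)
  expect_equal(nrow(r$coefficients), 0)
  expect_error(stepwise_regression(d[1:4, ], "y", c("x1", "x2")), "n >")
})

test_that("stepwise records its trace and removal works", {
  set.seed(71)
  n <- 80
  d <- data.frame(x1 = stats::rnorm(n))
  d$x2 <- d$x1 + stats::rnorm(n, sd = 0.3)   # proxy of x1
  d$x3 <- stats::rnorm(n)
  d$y <- d$x1 + 0.9 * d$x3 + stats::rnorm(n, sd = 0.5)
  r <- stepwise_regression(d, "y", c("x2", "x1", "x3"))
  expect_true(all(c("x1", "x3") %in% r$selected))
  expect_true(all(r$trace$action %in% c("enter", "remove")))
  expect_true(all(r$selected %in% c("x1", "x2", "x3")))
  # every selected variable is significant below the removal threshold
  expect_true(all(r$coefficients$p < r$removal_p))
})
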