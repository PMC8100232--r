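test_that("group marginals converge to the configured moments", {
  big <- study_group_params("right")
  big$n <- c(10000L, 10000L, 10000L)
  co <- generate_cohort(cohort_config(groups = big, seed = 101))
  g <- co[co$group == "meningioma_ptbe", ]
  # 3-standard-error bands at n = 1e4
  expect_lt(abs(mean(g$alps_right) - 1.260), 3 * 0.112 / sqrt(1e4))
  expect_lt(abs(sd(g$alps_right) - 0.112), 0.01)
  expect_lt(abs(mean(co$alps_right[co$group == "control"]) - 1.215),
            3 * 0.093 / sqrt(1e4))
  expect_lt(abs(mean(g$alps_right) - 1.260), 0.01)
  # sex proportion
  expect_lt(abs(mean(co$sex == "woman") - 43 / 80),
            3 * sqrt(0.5^2 / nrow(co)))
})

test_that("the copula induces (or suppresses) the ALPS-edema correlation", {
  big <- study_group_params("right")
  big$n <- c(2L, 10000L, 2L)
  co0 <- generate_cohort(cohort_config(groups = big, rho = 0, seed = 5))
  g0 <- co0[co0$group == "meningioma_ptbe", ]
  expect_lt(abs(cor(g0$alps_right, g0$ptbe_volume)), 0.05)

  # rho = -0.9 at n = 56: mean sample r over replicates stays within 0.02
  grp <- study_group_params("right")
  grp$n <- c(2L, 56L, 2L)
  rs <- vapply(1:300, function(i) {
    co <- generate_cohort(cohort_config(groups = grp, rho = -0.9, seed = i))
    g <- co[co$group == "meningioma_ptbe", ]
    cor(g$alps_right, g$ptbe_volume)
  }, 0)
  expect_lt(abs(mean(rs) - (-0.9)), 0.02)
})

test_that("cohorts satisfy their structural invariants and are seed-stable", {
  cc <- cohort_config(seed = 31)
  co <- generate_cohort(cc)
  expect_identical(co, generate_cohort(cc))
  expect_false(identical(co, generate_cohort(cohort_config(seed = 32))))
  expect_true(all(co$ptbe_volume >= 0))
  expect_true(all((co$ptbe_volume > 0) == (co$group == "meningioma_ptbe")))
  expect_true(all(co$alps_right > 0 & co$alps_left > 0))
  expect_true(all(co$age >= 18 & co$age <= 95))
  expect_true(all(co$tumor_side[co$group == "control"] == "none"))
  expect_true(all(co$tumor_volume[co$group != "control"] > 0))
})

test_that("invalid cohort configurations are rejected", {
  bad <- study_group_params("right"); bad$n[1] <- 1L
  expect_error(cohort_config(groups = bad), "n >= 2")
  bad2 <- study_group_params("right"); bad2$alps_right_sd[2] <- 0
  expect_error(cohort_config(groups = bad2), "SDs")
  expect_error(cohort_config(rho = -1.5), "rho")
  bad3 <- study_group_params("right"); bad3$group[1] <- "unknown_group"
  expect_error(cohort_config(groups = bad3), "unknown group")
})

test_that("two-observer simulation reproduces noise-free and biased designs", {
  truth <- c(1.2, 1.4, 1.1, 1.5, 1.3)
  o <- simulate_two_observers(truth, noise_sd = 0, bias = 0, seed = 3)
  expect_equal(o$observer1, truth)
  expect_equal(o$observer2, truth)
  expect_equal(icc_absolute_agreement(cbind(o$observer1, o$observer2))$icc, 1)
  ob <- simulate_two_observers(truth, noise_sd = 0, bias = 0.1, seed = 3)
  expect_equal(ob$observer2 - ob$observer1, rep(0.1, 5))
  expect_error(simulate_two_observers(truth, noise_sd = -1), "noise_sd")
})

test_that("small measurement noise yields high two-way random ICC", {
  set.seed(14)
  truth <- stats::rnorm(60, 1.3, 0.15)      # between-subject SD 0.15
  o <- simulate_two_observers(truth, noise_sd = 0.02, seed = 9)
  r <- icc_absolute_agreement(cbind(o$observer1, o$observer2))
  expect_gt(r$icc, 0.9)
  expect_lt(r$p_value, 0.001)
})

test_that("cohort CSVs round-trip and are validated on load", {
  co <- generate_cohort(cohort_config(seed = 2))
  p <- tempfile(fileext = ".csv")
  write_cohort(co, p)
  co2 <- read_cohort(p)
  expect_equal(co2$alps_right, co$alps_right)
  expect_equal(nrow(co2), nrow(co))
  bad <- co; bad$ptbe_volume[bad$group == "control"][1] <- 5
  write_cohort(bad, p)
  expect_error(read_cohort(p), "edema group")
  bad2 <- co; bad2$alps_left[1] <- -0.2
  write_cohort(bad2, p)
  expect_error(read_cohort(p), "positive")
  write_cohort(co[, -2], p)
  expect_error(read_cohort(p), "missing columns")
})

test_that("the deterministic descriptive fixture matches its marginal counts", {
  tab <- reference_cohort()
  s <- cohort_summary(tab)
  expect_equal(s$n_patients, 80L)
  expect_equal(unname(s$sex[c("man", "woman")]), c(37L, 43L),
               ignore_attr = TRUE)
  expect_equal(sum(tab$location == "skull_base"), 15L)
  expect_equal(unname(s$grade[c("I", "II", "III")]), c(61L, 15L, 4L),
               ignore_attr = TRUE)
  expect_equal(as.integer(s$tumor_volume_bins), c(7L, 15L, 28L, 22L, 8L))
  expect_equal(as.integer(s$edema_volume_bins), c(24L, 15L, 15L, 17L, 9L))
  expect_equal(table(tab$tumor_side)[["right"]], 44L)
  expect_equal(mean(tab$age), 58.8, tolerance = 1e-9)
})
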