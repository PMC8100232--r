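#' Group-level parameters printed in the group-comparison table
#'
#' Per-hemisphere ALPS means and SDs, and group sizes, for the three
#' analysis groups (meningioma without peritumoral edema, meningioma with
#' peritumoral edema, normal subjects), separately for cohorts of
#' right-side and left-side tumors.
#'
#' @param side `"right"` or `"left"`: the tumor side of the cohort.
#' @return A data.frame with one row per group (columns `group`, `n`,
#'   `tumor_side`, `alps_right_mean`, `alps_right_sd`, `alps_left_mean`,
#'   `alps_left_sd`).
#' @export
study_group_params <- function(side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "right") {
    data.frame(
      group = c("meningioma_no_ptbe", "meningioma_ptbe", "control"),
      n = c(13L, 31L, 44L),
      tumor_side = c("right", "right", "none"),
      alps_right_mean = c(1.502, 1.260, 1.215),
      alps_right_sd   = c(0.089, 0.112, 0.093),
      alps_left_mean  = c(1.353, 1.263, 1.273),
      alps_left_sd    = c(0.213, 0.173, 0.105))
  } else {
    data.frame(
      group = c("meningioma_no_ptbe", "meningioma_ptbe", "control"),
      n = c(11L, 25L, 44L),
      tumor_side = c("left", "left", "none"),
      alps_right_mean = c(1.272, 1.198, 1.215),
      alps_right_sd   = c(0.167, 0.204, 0.093),
      alps_left_mean  = c(1.513, 1.304, 1.273),
      alps_left_sd    = c(0.198, 0.178, 0.105))
  }
}

#' Configuration for the cohort simulator
#'
#' Defines the sampling distributions of a simulated case-control cohort:
#' per-group sample sizes and bilateral ALPS normals, a truncated-normal
#' (at 0) marginal for the peritumoral edema volume, a Gaussian-copula
#' correlation `rho` between the edema volume and the ALPS index
#' ipsilateral to the tumor, and demographic/histologic marginals.
#'
#' @param groups data.frame as returned by [study_group_params()]; group
#'   names must be among `meningioma_no_ptbe`, `meningioma_ptbe`,
#'   `control`, each with `n >= 2`.
#' @param ptbe_mean,ptbe_sd mean and SD (cm^3) of the edema-volume
#'   marginal before truncation at 0.
#' @param rho Pearson correlation (in `[-1, 1]`) induced between
#'   ipsilateral ALPS and edema volume in the edema group.
#' @param age_mean,age_sd patient age distribution (years), truncated to
#'   `[18, 95]`.
#' @param control_age_mean,control_age_sd age distribution of controls.
#' @param p_woman probability of female sex.
#' @param p_grade2_3 probability of WHO grade II/III (patients).
#' @param p_skull_base probability of a skull-base location (patients).
#' @param ki67_mean,ki67_sd proliferation index (%), truncated at 0.
#' @param tumor_mean,tumor_sd tumor volume (cm^3), truncated at 0.5.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = study_group_params("right"),
                          ptbe_mean = 67.1, ptbe_sd = 46.8,
                          rho = -0.68,
                          age_mean = 58.8, age_sd = 13.5,
                          control_age_mean = 53.3, control_age_sd = 10.0,
                          p_woman = 43 / 80,
                          p_grade2_3 = 19 / 80,
                          p_skull_base = 15 / 80,
                          ki67_mean = 4.8, ki67_sd = 3.1,
                          tumor_mean = 58.6, tumor_sd = 45.3,
                          seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "tumor_side", "alps_right_mean",
                  "alps_right_sd", "alps_left_mean", "alps_left_sd")
                %in% names(groups)))
  if (any(!groups$group %in% c("meningioma_no_ptbe", "meningioma_ptbe",
                               "control")))
    stop("unknown group name")
  if (anyDuplicated(groups$group)) stop("duplicated group")
  if (any(groups$n < 2))
    stop("each group used in a contrast needs n >= 2")
  sds <- unlist(groups[, c("alps_right_sd", "alps_left_sd")])
  if (any(sds <= 0) || ptbe_sd <= 0 || age_sd <= 0 || ki67_sd <= 0)
    stop("SDs must be > 0")
  if (rho < -1 || rho > 1) stop("'rho' must lie in [-1, 1]")
  stopifnot(p_woman >= 0, p_woman <= 1)
  structure(list(groups = groups, ptbe_mean = ptbe_mean, ptbe_sd = ptbe_sd,
                 rho = rho, age_mean = age_mean, age_sd = age_sd,
                 control_age_mean = control_age_mean,
                 control_age_sd = control_age_sd,
                 p_woman = p_woman, p_grade2_3 = p_grade2_3,
                 p_skull_base = p_skull_base,
                 ki67_mean = ki67_mean, ki67_sd = ki67_sd,
                 tumor_mean = tumor_mean, tumor_sd = tumor_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# quantile of a normal truncated below at `lo`
qtnorm_lower <- function(u, mean, sd, lo = 0) {
  a <- stats::pnorm((lo - mean) / sd)
  mean + sd * stats::qnorm(a + u * (1 - a))
}

rtnorm_range <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(a + stats::runif(n) * (b - a))
}

#' Simulate a case-control cohort
#'
#' Draws one subject table from a [cohort_config()]. Within each group
#' the bilateral ALPS indices are normal with the configured moments. In
#' the edema group the ALPS index ipsilateral to the tumor and the edema
#' volume are coupled through a Gaussian copula with correlation `rho`;
#' the edema volume then receives its truncated-normal marginal, so
#' volumes stay non-negative while the Pearson correlation is preserved
#' up to the (small) distortion of the marginal transform. Edema volume
#' is exactly 0 outside the edema group.
#'
#' @param config a [cohort_config()].
#' @return A data.frame with one row per subject: `subject_id`, `age`,
#'   `sex` (`"man"`/`"woman"`), `group`, `tumor_side`, `tumor_grade`
#'   (`"I"`, `"II_III"`, `"none"`), `ki67`, `location` (`"skull_base"`,
#'   `"non_skull_base"`, `"none"`), `tumor_volume`, `ptbe_volume` (cm^3),
#'   `alps_right`, `alps_left`.
#' @examples
#' head(generate_cohort(cohort_config(seed = 7)))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  rows <- lapply(seq_len(nrow(config$groups)), function(gi) {
    g <- config$groups[gi, ]
    n <- g$n
    is_control <- g$group == "control"
    is_ptbe <- g$group == "meningioma_ptbe"
    side <- g$tumor_side

    z_r <- stats::rnorm(n)
    z_l <- stats::rnorm(n)
    ptbe <- rep(0, n)
    if (is_ptbe) {
      # copula: couple the ipsilateral ALPS z-score with the edema volume
      z_v <- config$rho * (if (side == "right") z_r else z_l) +
        sqrt(1 - config$rho^2) * stats::rnorm(n)
      ptbe <- qtnorm_lower(stats::pnorm(z_v), config$ptbe_mean,
                           config$ptbe_sd, lo = 0)
    }
    alps_r <- g$alps_right_mean + g$alps_right_sd * z_r
    alps_l <- g$alps_left_mean + g$alps_left_sd * z_l

    age <- if (is_control)
      rtnorm_range(n, config$control_age_mean, config$control_age_sd, 18, 95)
    else rtnorm_range(n, config$age_mean, config$age_sd, 18, 95)

    data.frame(
      subject_id = sprintf("%s_%03d", g$group, seq_len(n)),
      age = age,
      sex = ifelse(stats::runif(n) < config$p_woman, "woman", "man"),
      group = g$group,
      tumor_side = if (is_control) "none" else side,
      tumor_grade = if (is_control) "none" else
        ifelse(stats::runif(n) < config$p_grade2_3, "II_III", "I"),
      ki67 = if (is_control) 0 else
        qtnorm_lower(stats::runif(n), config$ki67_mean, config$ki67_sd),
      location = if (is_control) "none" else
        ifelse(stats::runif(n) < config$p_skull_base,
               "skull_base", "non_skull_base"),
      tumor_volume = if (is_control) 0 else
        qtnorm_lower(stats::runif(n), config$tumor_mean, config$tumor_sd,
                     lo = 0.5),
      ptbe_volume = ptbe,
      alps_right = alps_r,
      alps_left = alps_l)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate two observers' measurements
#'
#' Produces two independent noisy copies of a vector of true values,
#' with an optional systematic bias added to the second observer only.
#'
#' @param truth numeric vector of per-subject true measurements.
#' @param noise_sd SD of the independent Gaussian measurement error
#'   (>= 0).
#' @param bias additive systematic offset of observer 2.
#' @param seed integer seed.
#' @return A list with numeric vectors `observer1` and `observer2`.
#' @export
simulate_two_observers <- function(truth, noise_sd, bias = 0, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(truth)
  list(observer1 = truth + stats::rnorm(n, sd = noise_sd),
       observer2 = truth + bias + stats::rnorm(n, sd = noise_sd))
}

#' Read and write cohort tables
#'
#' CSV round trip for the subject-record schema produced by
#' [generate_cohort()]. `read_cohort()` validates the header and the
#' basic invariants (non-negative volumes, positive ALPS indices, edema
#' volume 0 exactly outside the edema group).
#'
#' @param path CSV file path.
#' @param cohort a cohort data.frame.
#' @return `read_cohort()` returns the validated data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "group", "tumor_side", "tumor_grade",
            "ki67", "location", "tumor_volume", "ptbe_volume",
            "alps_right", "alps_left")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$tumor_volume < 0) || any(x$ptbe_volume < 0))
    stop("volumes must be non-negative")
  if (any(x$alps_right <= 0) || any(x$alps_left <= 0))
    stop("ALPS indices must be positive")
  bad <- (x$group == "meningioma_ptbe") != (x$ptbe_volume > 0)
  if (any(bad))
    stop("ptbe_volume must be 0 exactly for subjects outside the edema group")
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
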