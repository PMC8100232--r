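#' Deterministic reference cohort matching the published marginal counts
#'
#' Reconstructs an 80-patient meningioma cohort whose every printed
#' marginal matches the study's descriptive table exactly: 37 men and 43
#' women; detailed locations sphenoid ridge 12, parasellar 1, frontal
#' base 2, convexity 39, parasagittal 23, intraventricular 2, tentorium 1
#' (hence 15 skull-base); grades I/II/III = 61/15/4; tumor-volume bins
#' 1-8, 8-27, 27-64, 64-125, >125 cm^3 with counts 7/15/28/22/8;
#' edema-volume bins 0, 1-27, 27-64, 64-125, >125 cm^3 with counts
#' 24/15/15/17/9 (so 56 patients with edema); 44 right-side and 36
#' left-side tumors; mean age 58.8 years within the 24-90 range.
#'
#' Only the marginals are published; the joint assignment of attributes
#' to rows is an arbitrary deterministic construction (no randomness),
#' useful as a loading/descriptive-statistics fixture, and is synthetic
#' in every respect beyond the marginal counts. ALPS columns carry the
#' group means of the comparison table with small deterministic spread.
#'
#' @return A cohort data.frame in the [generate_cohort()] schema plus
#'   `location_detail` and `grade_detail` columns.
#' @examples
#' tab <- reference_cohort()
#' nrow(tab); table(tab$sex); sum(tab$ptbe_volume > 0)
#' @export
reference_cohort <- function() {
  n <- 80L
  side <- rep(c("right", "left"), c(44L, 36L))
  # PTBE status per side: 13/31 on the right, 11/25 on the left
  ptbe_pos <- c(rep(c(FALSE, TRUE), c(13L, 31L)),
                rep(c(FALSE, TRUE), c(11L, 25L)))
  group <- ifelse(ptbe_pos, "meningioma_ptbe", "meningioma_no_ptbe")

  # edema volumes: 56 positive values filling the printed bins, spread
  # deterministically inside each bin over the printed 4.1-171.3 range
  bin_fill <- function(lo, hi, k) seq(lo, hi, length.out = k)
  edema_vals <- c(bin_fill(4.1, 26.5, 15), bin_fill(27.5, 63.5, 15),
                  bin_fill(64.5, 124.5, 17), bin_fill(126, 171.3, 9))
  ptbe_volume <- numeric(n)
  ptbe_volume[ptbe_pos] <- edema_vals

  tumor_volume <- c(bin_fill(3.1, 7.9, 7), bin_fill(8.2, 26.5, 15),
                    bin_fill(27.5, 63.5, 28), bin_fill(64.5, 124.5, 22),
                    bin_fill(126, 202.9, 8))
  sex <- rep(rep(c("man", "woman"), 40L), length.out = n)
  sex[seq_len(6L) * 13L] <- "woman"        # 37 men / 43 women
  location_detail <- rep(c("sphenoid_ridge", "parasellar", "frontal_base",
                           "convexity", "parasagittal", "intraventricular",
                           "tentorium"),
                         c(12L, 1L, 2L, 39L, 23L, 2L, 1L))
  location <- ifelse(location_detail %in%
                       c("sphenoid_ridge", "parasellar", "frontal_base"),
                     "skull_base", "non_skull_base")
  grade_detail <- rep(c("I", "II", "III"), c(61L, 15L, 4L))
  tumor_grade <- ifelse(grade_detail == "I", "I", "II_III")
  age <- seq(27.6, 90, length.out = n)     # mean 58.8, inside 24-90
  ki67 <- rep(c(1, 2, 3, 4, 5, 6, 7, 8, 10, 12), 8L)  # range 1-12

  pr <- study_group_params("right"); pl <- study_group_params("left")
  spread <- function(k) if (k == 1) 0 else seq(-1, 1, length.out = k)
  alps_right <- alps_left <- numeric(n)
  for (s in c("right", "left")) for (g in unique(group)) {
    i <- which(side == s & group == g)
    p <- if (s == "right") pr else pl
    row <- p[p$group == g, ]
    alps_right[i] <- row$alps_right_mean + row$alps_right_sd * spread(length(i))
    alps_left[i]  <- row$alps_left_mean + row$alps_left_sd * spread(length(i))
  }

  data.frame(subject_id = sprintf("pt_%03d", seq_len(n)),
             age = age, sex = sex, group = group, tumor_side = side,
             tumor_grade = tumor_grade, ki67 = ki67, location = location,
             tumor_volume = tumor_volume, ptbe_volume = ptbe_volume,
             alps_right = alps_right, alps_left = alps_left,
             location_detail = location_detail, grade_detail = grade_detail)
}

#' Descriptive volume bins
#'
#' Bins a volume vector into the descriptive-table categories. Bins are
#' half-open `[low, high)` with the printed labels; for edema volumes, 0
#' forms its own bin and the first positive bin covers `(0, 27)`.
#'
#' @param v numeric vector of volumes, cm^3.
#' @param kind `"tumor"` (bins 1-8, 8-27, 27-64, 64-125, >125) or
#'   `"edema"` (bins 0, 1-27, 27-64, 64-125, >125).
#' @return A factor with the printed bin labels.
#' @export
volume_bins <- function(v, kind = c("tumor", "edema")) {
  kind <- match.arg(kind)
  if (kind == "tumor") {
    cut(v, c(-Inf, 8, 27, 64, 125, Inf), right = FALSE,
        labels = c("1-8", "8-27", "27-64", "64-125", ">125"))
  } else {
    labs <- c("0", "1-27", "27-64", "64-125", ">125")
    factor(ifelse(v == 0, "0",
                  as.character(cut(v, c(0, 27, 64, 125, Inf), right = FALSE,
                                   labels = labs[-1]))),
           levels = labs)
  }
}

#' Descriptive summary of a cohort
#'
#' Counts mirroring the layout of the study's characteristics table:
#' sample size, age, sex, location, grade and the tumor/edema volume
#' bins of [volume_bins()].
#'
#' @param cohort a cohort data.frame (patients and/or controls).
#' @return A list of count tables and summary scalars.
#' @export
cohort_summary <- function(cohort) {
  pat <- cohort[cohort$group != "control", , drop = FALSE]
  list(n_patients = nrow(pat),
       age_mean = mean(pat$age), age_sd = stats::sd(pat$age),
       sex = table(pat$sex),
       location = table(if ("location_detail" %in% names(pat))
         pat$location_detail else pat$location),
       grade = table(if ("grade_detail" %in% names(pat))
         pat$grade_detail else pat$tumor_grade),
       tumor_volume_bins = table(volume_bins(pat$tumor_volume, "tumor")),
       edema_volume_bins = table(volume_bins(pat$ptbe_volume, "edema")),
       n_with_ptbe = sum(pat$ptbe_volume > 0),
       prop_without_ptbe = mean(pat$ptbe_volume == 0))
}
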