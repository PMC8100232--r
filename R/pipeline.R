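#' Read a study configuration
#'
#' YAML configuration for the command-line pipeline. Unknown keys are
#' kept; missing keys fall back to defaults (`alpha = 0.05`, stepwise
#' entry/removal 0.05/0.10, both tumor sides, both response columns,
#' seed 1).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list of class `study_config`.
#' @export
read_study_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(alpha = 0.05, entry_p = 0.05, removal_p = 0.10,
                   sides = c("right", "left"),
                   responses = c("alps_right", "alps_left"),
                   covariates = c("age", "sex"), seed = 1L,
                   log_level = "info")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  structure(cfg, class = "study_config")
}

pipeline_log <- function(..., file = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
}

#' ALPS indices of a phantom
#'
#' Runs the full tensor-fitting + ROI-extraction chain on a synthetic
#' phantom and returns per-hemisphere results.
#'
#' @param phantom an `alps_phantom` from [generate_phantom()].
#' @param use_truth logical; measure on the analytic ground-truth field
#'   instead of refitting from the signals.
#' @param subject_id identifier carried into the results.
#' @return A list with `alps_result` elements `right` and `left`.
#' @export
alps_from_phantom <- function(phantom, use_truth = FALSE,
                              subject_id = "phantom") {
  stopifnot(inherits(phantom, "alps_phantom"))
  field <- if (use_truth) phantom$truth else
    fit_tensor(phantom$dwi, phantom$scheme,
               voxel_size = phantom$config$voxel_size)
  lapply(phantom$rois, function(r)
    measure_alps(field, r$projection, r$association,
                 subject_id = subject_id))
}

#' Run the ALPS pipeline over a subject manifest
#'
#' For each subject: read the 4-D DWI and gradient table, fit tensors,
#' build the four fibre ROIs from a label volume (1 = right projection,
#' 2 = right association, 3 = left projection, 4 = left association),
#' compute the per-hemisphere index for each observer's ROI set, and
#' average observers when two sets are given. Per-subject failures are
#' logged and skipped; the run fails only if no subject succeeds.
#'
#' @param manifest data.frame with columns `subject_id`, `dwi`, `bval`,
#'   `bvec`, `roi` (observer 1 label NIfTI) and optionally `roi2`
#'   (observer 2).
#' @param out_csv optional path; when given, the per-subject table is
#'   written there.
#' @param log_file optional path appended to by the stage log.
#' @return The per-subject data.frame from [alps_table()], invisibly
#'   written to `out_csv` when requested.
#' @export
run_alps_pipeline <- function(manifest, out_csv = NULL, log_file = NULL) {
  stopifnot(all(c("subject_id", "dwi", "bval", "bvec", "roi")
                %in% names(manifest)))
  roi_set <- function(path) {
    spec <- list(c(1L, "projection", "right"), c(2L, "association", "right"),
                 c(3L, "projection", "left"), c(4L, "association", "left"))
    rois <- lapply(spec, function(s)
      roi_from_labels(path, as.integer(s[1]), fiber = s[2], hemisphere = s[3]))
    list(right = list(projection = rois[[1]], association = rois[[2]]),
         left = list(projection = rois[[3]], association = rois[[4]]))
  }
  results <- list()
  n_fail <- 0L
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      inp <- read_dwi(row$dwi, row$bval, row$bvec)
      field <- fit_tensor(inp$dwi, inp$scheme, voxel_size = inp$voxel_size)
      obs1 <- roi_set(row$roi)
      two <- "roi2" %in% names(row) && !is.na(row$roi2) && nzchar(row$roi2)
      per_side <- lapply(c(right = "right", left = "left"), function(h) {
        r1 <- measure_alps(field, obs1[[h]]$projection, obs1[[h]]$association,
                           subject_id = row$subject_id, observer = 1L)
        if (two) {
          obs2 <- roi_set(row$roi2)
          r2 <- measure_alps(field, obs2[[h]]$projection,
                             obs2[[h]]$association,
                             subject_id = row$subject_id, observer = 2L)
          average_observers(r1, r2)
        } else r1
      })
      pipeline_log("subject ", row$subject_id, ": ok (right ",
                   sprintf("%.4f", per_side$right$index), ", left ",
                   sprintf("%.4f", per_side$left$index), ")",
                   file = log_file)
      per_side
    }, error = function(e) {
      pipeline_log("subject ", row$subject_id, ": FAILED (",
                   conditionMessage(e), ")", file = log_file)
      NULL
    })
    if (is.null(res)) n_fail <- n_fail + 1L else
      results <- c(results, unname(res))
  }
  if (!length(results))
    stop("no subject processed successfully (", n_fail, " failures)")
  tab <- alps_table(results)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}

# ipsilateral ALPS: index on the tumor side; NA for controls
ipsilateral_alps <- function(cohort) {
  ifelse(cohort$tumor_side == "right", cohort$alps_right,
         ifelse(cohort$tumor_side == "left", cohort$alps_left, NA_real_))
}

#' Covariate-adjusted group comparison grid
#'
#' For each requested tumor side, compares the three groups (meningioma
#' without edema, meningioma with edema, controls on that side's cohort)
#' on each response column with an age/sex-adjusted ANCOVA and
#' Bonferroni pairwise contrasts — the per-side, per-hemisphere grid of
#' adjusted p-values and joint CIs. A side whose cohort lacks one of the
#' three groups is skipped with a warning.
#'
#' @param cohort a cohort data.frame (patients of both sides plus
#'   controls).
#' @param sides tumor sides to analyse.
#' @param responses response columns.
#' @param covariates adjustment covariates.
#' @param conf_level joint confidence level of the contrast CIs.
#' @return A data.frame grid with one row per side x response x pair,
#'   carrying `difference`, `p_adj`, `ci_low`, `ci_high` and the omnibus
#'   p of the side/response model.
#' @export
run_group_comparison <- function(cohort, sides = c("right", "left"),
                                 responses = c("alps_right", "alps_left"),
                                 covariates = c("age", "sex"),
                                 conf_level = 0.95) {
  out <- list()
  for (s in sides) {
    sub <- cohort[cohort$group == "control" | cohort$tumor_side == s, ,
                  drop = FALSE]
    if (length(setdiff(c("meningioma_no_ptbe", "meningioma_ptbe", "control"),
                       unique(sub$group)))) {
      warning("side '", s, "' skipped: missing group")
      next
    }
    for (resp in responses) {
      a <- ancova_pairwise(sub, resp, "group", covariates, conf_level)
      g <- a$contrasts
      out[[length(out) + 1]] <- data.frame(
        tumor_side = s, response = resp, g[, c("pair", "difference")],
        p_adj = g$p_adj, ci_low = g$ci_low, ci_high = g$ci_high,
        omnibus_p = a$omnibus_p)
    }
  }
  if (!length(out)) stop("no side could be analysed")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlates of edema volume in the edema group
#'
#' Within the subjects that have peritumoral edema: Pearson correlations
#' of edema volume with age, sex, tumor grade, Ki-67, location, tumor
#' volume and the ALPS index ipsilateral to the tumor (binary variables
#' on their 0/1 coding), a variance-inflation screen of the same seven
#' candidates, and stepwise multivariable linear regression of edema
#' volume on all of them.
#'
#' @param cohort a cohort data.frame.
#' @param entry_p,removal_p stepwise thresholds.
#' @param min_n minimum size of the edema subset.
#' @return A list of class `correlation_analysis`: `correlations`
#'   (data.frame with `variable`, `r`, `p`, `n`), `vif`, `stepwise`
#'   (a `stepwise_result`) and `n`.
#' @export
run_correlation_analysis <- function(cohort, entry_p = 0.05,
                                     removal_p = 0.10, min_n = 10) {
  sub <- cohort[cohort$group == "meningioma_ptbe", , drop = FALSE]
  if (nrow(sub) < min_n)
    stop("edema subset too small (", nrow(sub), " < ", min_n, ")")
  d <- data.frame(
    ptbe_volume = sub$ptbe_volume,
    age = sub$age,
    sex = as.numeric(sub$sex == "woman"),
    tumor_grade = as.numeric(sub$tumor_grade == "II_III"),
    ki67 = sub$ki67,
    location = as.numeric(sub$location == "skull_base"),
    tumor_volume = sub$tumor_volume,
    alps_ipsilateral = ipsilateral_alps(sub))
  candidates <- c("age", "sex", "tumor_grade", "ki67", "location",
                  "tumor_volume", "alps_ipsilateral")
  cors <- do.call(rbind, lapply(candidates, function(v) {
    ct <- pearson(d[[v]], d$ptbe_volume)
    data.frame(variable = v, r = ct$r, p = ct$p, n = ct$n)
  }))
  structure(list(correlations = cors,
                 vif = vif(d[, candidates, drop = FALSE]),
                 stepwise = stepwise_regression(d, "ptbe_volume", candidates,
                                                entry_p, removal_p),
                 n = nrow(d)),
            class = "correlation_analysis")
}

#' @export
print.correlation_analysis <- function(x, ...) {
  cat(sprintf("correlation analysis in the edema group (n = %d)\n", x$n))
  print(transform(x$correlations, r = round(r, 3), p = signif(p, 3)))
  print(x$stepwise)
  invisible(x)
}

#' Full study report
#'
#' Runs the descriptive summary, the group-comparison grid and the
#' correlation/stepwise analysis on a cohort and writes a JSON report
#' plus CSV tables under `out_dir`.
#'
#' @param cohort a cohort data.frame.
#' @param out_dir output directory, created if needed.
#' @param config a `study_config` (thresholds and switches).
#' @return Invisibly, the report list.
#' @export
study_report <- function(cohort, out_dir, config = read_study_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  desc <- cohort_summary(cohort)
  grid <- run_group_comparison(cohort, sides = config$sides,
                               responses = config$responses,
                               covariates = config$covariates)
  corr <- tryCatch(run_correlation_analysis(cohort, config$entry_p,
                                            config$removal_p),
                   error = function(e) {
                     pipeline_log("correlation analysis skipped: ",
                                  conditionMessage(e))
                     NULL
                   })
  report <- list(
    descriptives = list(
      n_patients = desc$n_patients, age_mean = desc$age_mean,
      sex = as.list(desc$sex), location = as.list(desc$location),
      grade = as.list(desc$grade),
      tumor_volume_bins = as.list(desc$tumor_volume_bins),
      edema_volume_bins = as.list(desc$edema_volume_bins),
      n_with_ptbe = desc$n_with_ptbe,
      prop_without_ptbe = desc$prop_without_ptbe),
    comparisons = grid,
    correlations = if (is.null(corr)) NULL else corr$correlations,
    vif = if (is.null(corr)) NULL else corr$vif,
    stepwise = if (is.null(corr)) NULL else list(
      selected = corr$stepwise$selected,
      coefficients = corr$stepwise$coefficients,
      r_squared = corr$stepwise$r_squared,
      trace = corr$stepwise$trace))
  utils::write.csv(grid, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  if (!is.null(corr)) {
    utils::write.csv(corr$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(corr$stepwise$trace,
                     file.path(out_dir, "stepwise_trace.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Diagnostic plots
#'
#' Base-graphics versions of the usual study figures: per-group boxplots
#' of an ALPS column, and the edema-volume versus ipsilateral-ALPS
#' scatterplot with its least-squares line.
#'
#' @param cohort a cohort data.frame.
#' @param response ALPS column for the boxplot.
#' @param file optional PNG path; when given the plot is written there.
#' @return Invisibly `NULL`.
#' @export
plot_group_boxplot <- function(cohort, response = "alps_right",
                               file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(stats::reformulate("group", response), data = cohort,
                    ylab = response, col = "grey85")
  invisible(NULL)
}

#' @rdname plot_group_boxplot
#' @export
plot_alps_ptbe <- function(cohort, file = NULL) {
  sub <- cohort[cohort$group == "meningioma_ptbe", , drop = FALSE]
  x <- ipsilateral_alps(sub)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x, sub$ptbe_volume, xlab = "ipsilateral ALPS index",
                 ylab = "PTBE volume (cm^3)", pch = 19)
  graphics::abline(stats::lm(sub$ptbe_volume ~ x), col = "red3")
  invisible(NULL)
}
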