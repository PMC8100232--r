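#' Lilliefors-corrected Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test against a normal distribution with estimated mean
#' and SD, using the Lilliefors correction for the estimated moments.
#' The flag is used to choose between parametric and nonparametric
#' reporting downstream.
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @param alpha significance level for the normality flag.
#' @return A list with `statistic`, `p`, `is_normal` and `n`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 finite values")
  if (stats::sd(values) == 0) stop("constant input: normality undefined")
  t <- nortest::lillie.test(values)
  list(statistic = unname(t$statistic), p = t$p.value,
       is_normal = t$p.value >= alpha, n = length(values))
}

# two-way (subjects x raters) ANOVA mean squares
icc_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Absolute-agreement two-way random-effects ICC
#'
#' Single-rater intraclass correlation ICC(A,1) under the two-way
#' random-effects model (both subjects and raters random), which
#' penalises systematic rater bias, with the F-distribution 95% CI and
#' p-value. This is the form used to report inter-observer agreement of
#' repeated image measurements.
#'
#' @param m numeric matrix, subjects in rows and raters in columns
#'   (exactly 2 raters for the two-observer design; more are accepted),
#'   no missing cells.
#' @param conf_level confidence level of the CI.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `n_subjects`, `n_raters`, the mean squares, and
#'   `undefined` (TRUE when the between-subject variance is zero, in
#'   which case `icc` is NA).
#' @examples
#' m <- cbind(c(1, 2, 3, 4, 5, 6), c(1, 3, 3, 5, 5, 7))
#' icc_absolute_agreement(m)$icc
#' @export
icc_absolute_agreement <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not supported")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 raters")
  ms <- icc_mean_squares(m)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse

  if (msr <= .Machine$double.eps * mean(m)^2) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          n_subjects = n, n_raters = k, ms = ms,
                          undefined = TRUE), class = "icc_result"))
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse == 0 && msc == mse) {           # perfect agreement: degenerate CI
    lo <- hi <- 1; p <- 0
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    f0 <- msr / mse
    p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, p_value = p,
                 n_subjects = n, n_raters = k, ms = ms, undefined = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined) cat("ICC(A,1): undefined (no between-subject variance)\n")
  else cat(sprintf("ICC(A,1) = %.3f, 95%% CI %.3f-%.3f, P = %.3g (n = %d, k = %d)\n",
                   x$icc, x$ci_low, x$ci_high, x$p_value,
                   x$n_subjects, x$n_raters))
  invisible(x)
}

#' Covariate-adjusted pairwise group contrasts (ANCOVA)
#'
#' Fits the additive linear model `response ~ group + covariates` and
#' reports all pairwise differences of covariate-adjusted group means
#' (estimated-marginal-means contrasts, which under an additive model
#' equal the differences of the group coefficients), each with a
#' Bonferroni-adjusted p-value (raw p times the number of pairs, capped
#' at 1) and a correspondingly widened joint confidence interval, plus
#' the omnibus partial-F p-value for the group factor.
#'
#' @param data data.frame holding the response, group and covariates.
#' @param response name of the response column.
#' @param group name of the grouping column (coerced to factor).
#' @param covariates character vector of covariate column names;
#'   character/factor covariates are allowed (sex enters as an indicator).
#' @param conf_level nominal joint confidence level.
#' @return A list of class `ancova_result`: `contrasts` (data.frame with
#'   `pair`, `difference`, `se`, `df`, `p_raw`, `p_adj`, `ci_low`,
#'   `ci_high`), `omnibus_p`, `covariates`, `group_sizes`, `model`.
#' @export
ancova_pairwise <- function(data, response, group,
                            covariates = c("age", "sex"),
                            conf_level = 0.95) {
  stopifnot(response %in% names(data), group %in% names(data),
            all(covariates %in% names(data)))
  d <- data[, c(response, group, covariates), drop = FALSE]
  d[[group]] <- factor(d[[group]])
  lev <- levels(d[[group]])
  sizes <- table(d[[group]])
  if (any(sizes < 3)) stop("need at least 3 observations per group")
  for (cv in covariates) {
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
    if (length(unique(d[[cv]])) < 2)
      stop("covariate '", cv, "' is constant")
  }

  fml <- stats::reformulate(c(group, covariates), response)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: aliased coefficients in ", deparse(fml))

  # omnibus partial F for the group factor
  fit0 <- stats::lm(stats::reformulate(covariates, response), data = d)
  omnibus_p <- stats::anova(fit0, fit)[2, "Pr(>F)"]

  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  df <- fit$df.residual
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- length(pairs)
  alpha <- 1 - conf_level
  tcrit <- stats::qt(1 - (alpha / m) / 2, df)

  rows <- lapply(pairs, function(pr) {
    cvec <- stats::setNames(numeric(length(cf)), names(cf))
    for (s in c(1, -1)) {
      g <- pr[if (s == 1) 1 else 2]
      nm <- paste0(group, g)
      if (nm %in% names(cvec)) cvec[nm] <- s     # baseline level contributes 0
    }
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    p_raw <- 2 * stats::pt(-abs(tval), df)
    data.frame(pair = paste(pr, collapse = " vs "),
               difference = est, se = se, df = df,
               p_raw = p_raw, p_adj = min(1, m * p_raw),
               ci_low = est - tcrit * se, ci_high = est + tcrit * se)
  })
  structure(list(contrasts = do.call(rbind, rows), omnibus_p = omnibus_p,
                 covariates = covariates, group_sizes = sizes, model = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA (covariates: %s), omnibus P = %.4g\n",
              paste(x$covariates, collapse = ", "), x$omnibus_p))
  print(cbind(x$contrasts[, c("pair", "difference")],
              p_adj = signif(x$contrasts$p_adj, 3),
              ci = sprintf("(%.3f, %.3f)", x$contrasts$ci_low,
                           x$contrasts$ci_high)))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' Binary factors (sex, grade, location) may be passed as 0/1 codings,
#' giving the point-biserial correlation as a special case.
#'
#' @param x,y numeric vectors of equal length (n >= 3), both
#'   non-constant.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Variance inflation factors
#'
#' VIF of each candidate predictor: `1 / (1 - R^2)` from regressing that
#' candidate on all others. Exactly collinear candidates are reported as
#' `Inf` and flagged.
#'
#' @param x numeric matrix or data.frame of candidate predictors
#'   (>= 2 columns, more rows than columns).
#' @return A data.frame with `candidate`, `vif` and `collinear`.
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  x[] <- lapply(x, function(cl) if (is.character(cl) || is.factor(cl))
    as.numeric(factor(cl)) - 1 else as.numeric(cl))
  p <- ncol(x)
  if (p < 2) stop("need at least 2 candidates")
  if (nrow(x) <= p) stop("need more rows than candidates")
  out <- lapply(seq_len(p), function(j) {
    fit <- stats::lm(stats::reformulate(names(x)[-j], names(x)[j]), data = x)
    r2 <- summary(fit)$r.squared
    coll <- r2 > 1 - 1e-10
    data.frame(candidate = names(x)[j],
               vif = if (coll) Inf else 1 / (1 - r2),
               collinear = coll)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Stepwise multivariable linear regression
#'
#' Classic p-value-driven stepwise selection: forward entry of the
#' candidate with the smallest partial-F p-value when it is at or below
#' `entry_p`, followed after every entry by backward removal of any
#' included predictor whose p-value is at or above `removal_p`, until no
#' change. Ties break on the smaller entry p, then on the fixed candidate
#' order. If no candidate meets the entry criterion the intercept-only
#' model is returned. Standardized coefficients (beta) are reported for
#' the final model.
#'
#' @param data data.frame holding the response and candidates.
#' @param response response column name.
#' @param candidates character vector of candidate column names;
#'   character/factor candidates are converted to 0/1 indicators.
#' @param entry_p forward-entry threshold.
#' @param removal_p backward-removal threshold (> `entry_p`).
#' @return A list of class `stepwise_result`: `selected`, `coefficients`
#'   (data.frame with unstandardized `b`, standardized `beta`, `p`),
#'   `r_squared`, `trace` (data.frame of entry/removal steps), `vif`
#'   (VIFs of all candidates), `entry_p`, `removal_p`, `model`.
#' @export
stepwise_regression <- function(data, response, candidates,
                                entry_p = 0.05, removal_p = 0.10) {
  stopifnot(response %in% names(data), all(candidates %in% names(data)),
            entry_p < removal_p)
  d <- data.frame(.y = as.numeric(data[[response]]))
  for (cv in candidates) {
    v <- data[[cv]]
    d[[cv]] <- if (is.character(v) || is.factor(v))
      as.numeric(factor(v)) - 1 else as.numeric(v)
  }
  n <- nrow(d)
  if (n <= length(candidates) + 2)
    stop("need n > number of candidates + 2")
  vifs <- vif(d[, candidates, drop = FALSE])

  coef_p <- function(sel) {
    fit <- stats::lm(stats::reformulate(sel, ".y"), data = d)
    summary(fit)$coefficients
  }
  sel <- character(0)
  trace <- list()
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, sel)
    if (length(remaining)) {
      ps <- vapply(remaining, function(v) coef_p(c(sel, v))[v, 4], 0)
      if (min(ps) <= entry_p) {
        add <- remaining[which.min(ps)]      # which.min: first on ties
        sel <- c(sel, add)
        trace[[length(trace) + 1]] <- data.frame(
          step = length(trace) + 1L, action = "enter", variable = add,
          p = min(ps))
        changed <- TRUE
      }
    }
    repeat {
      if (!length(sel)) break
      ps <- coef_p(sel)[sel, 4]
      if (max(ps) >= removal_p) {
        drop <- sel[which.max(ps)]
        sel <- setdiff(sel, drop)
        trace[[length(trace) + 1]] <- data.frame(
          step = length(trace) + 1L, action = "remove", variable = drop,
          p = max(ps))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  fit <- stats::lm(stats::reformulate(if (length(sel)) sel else "1", ".y"),
                   data = d)
  sm <- summary(fit)
  coefs <- if (length(sel)) {
    cf <- sm$coefficients[sel, , drop = FALSE]
    data.frame(variable = sel, b = cf[, 1],
               beta = cf[, 1] * vapply(sel, function(v) stats::sd(d[[v]]), 0) /
                 stats::sd(d$.y),
               p = cf[, 4], row.names = NULL)
  } else data.frame(variable = character(0), b = numeric(0),
                    beta = numeric(0), p = numeric(0))
  structure(list(selected = sel, coefficients = coefs,
                 r_squared = sm$r.squared,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(step = integer(0), action = character(0),
                              variable = character(0), p = numeric(0)),
                 vif = vifs, entry_p = entry_p, removal_p = removal_p,
                 model = fit),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (!length(x$selected)) {
    cat("stepwise: intercept-only model (no candidate met entry p <=",
        x$entry_p, ")\n")
  } else {
    cat(sprintf("stepwise: selected %s (R^2 = %.3f)\n",
                paste(x$selected, collapse = ", "), x$r_squared))
    print(transform(x$coefficients, beta = signif(beta, 3),
                    p = signif(p, 3)))
  }
  invisible(x)
}
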