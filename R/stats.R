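# Cohort statistics: descriptives, a Shapiro-Wilk normality gate, the
# two-sided paired t-test, and Cohen's d on the paired differences
# (mean(d) / sd(d)); with that convention t = d * sqrt(n) exactly.

#' Descriptive statistics of a sample
#'
#' Sample mean, standard deviation (n - 1 denominator), and
#' linear-interpolation percentiles (the convention of mainstream numeric
#' stacks).
#'
#' @param values Numeric vector (>= 1 value).
#' @return A one-row tibble: `n`, `mean`, `std`, `min`, `q25`, `median`,
#'   `q75`, `max`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(n = length(values), mean = mean(values),
         std = if (length(values) > 1) sd(values) else 0,
         min = min(values), q25 = q[1], median = q[2], q75 = q[3],
         max = max(values))
}

#' Shapiro-Wilk normality gate
#'
#' Returns the Shapiro-Wilk p-value; when `p <= alpha` a warning is raised
#' (the pipeline warns but does not abort, recording the value alongside
#' the parametric test).
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @param alpha Warning threshold (default 0.05).
#' @return The Shapiro-Wilk p-value.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (sd(values) == 0) {
    warn("constant sample: normality undefined, returning p = 0")
    return(0)
  }
  p <- shapiro.test(values)$p.value
  if (p <= alpha) {
    warn(sprintf(
      "Shapiro-Wilk p = %.4g <= %.2f: normality assumption questionable",
      p, alpha))
  }
  p
}

#' Two-sided paired t-test with Cohen's d
#'
#' Tests the mean of the paired differences `d = x - y` against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom,
#' two-sided p, and effect size `cohen_d = mean(d) / sd(d)` (the
#' paired-differences convention, so `t = cohen_d * sqrt(n)`). The
#' Shapiro-Wilk p-value of the differences is recorded when `n >= 3`.
#'
#' If all differences are exactly zero the exact null is returned
#' (`t = 0, p = 1, cohen_d = 0`); zero-variance differences with a nonzero
#' mean are a degenerate sample and raise an error.
#'
#' @param x,y Paired numeric vectors (same subject order, `n >= 2`).
#' @param bundle Optional label carried into the output row.
#' @return A one-row tibble: `bundle` (if given), `n`, `t_statistic`,
#'   `dof`, `p_value`, `cohen_d`, `shapiro_p`.
#' @export
paired_t_test <- function(x, y, bundle = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2) abort("paired test requires n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite")
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      t_stat <- 0
      p <- 1
      cd <- 0
    } else {
      abort("degenerate sample: zero-variance differences with nonzero mean")
    }
  } else {
    tt <- t.test(x, y, paired = TRUE, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    cd <- mean(d) / sdd
  }
  shapiro_p <- if (n >= 3 && sdd > 0) {
    suppressWarnings(normality_gate(d))
  } else {
    NA_real_
  }
  out <- tibble(n = n, t_statistic = t_stat, dof = n - 1L, p_value = p,
                cohen_d = cd, shapiro_p = shapiro_p)
  if (!is.null(bundle)) out <- dplyr::bind_cols(tibble(bundle = bundle), out)
  out
}

#' Compare segmentation approaches across a cohort
#'
#' Takes per-subject, per-bundle, per-method shape measures and produces
#' the cohort comparison: descriptive statistics of the irregularity per
#' bundle and method, and a two-sided paired t-test (with Cohen's d on the
#' paired differences and a Shapiro-Wilk record) per bundle, pairing the
#' two methods within subject.
#'
#' @param measures A data frame with columns `subject_id`, `bundle`,
#'   `method`, and the compared `metric` column (default `irregularity`).
#'   Every subject x bundle cell must be present for both methods.
#' @param methods Length-2 character: the method pair, differenced as
#'   `methods[1] - methods[2]` (default `c("roi", "streamline")`).
#' @param metric Name of the measure column to compare.
#' @param alpha Significance level (default 0.05; no multiple-testing
#'   correction is applied across bundles).
#' @return An object of class `bundle_comparison` with components
#'   `descriptives` (one row per bundle x method), `tests` (one row per
#'   bundle), and `data` (the per-subject values in wide form). Use
#'   [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()].
#' @export
compare_cohort <- function(measures, methods = c("roi", "streamline"),
                           metric = "irregularity", alpha = 0.05) {
  req <- c("subject_id", "bundle", "method", metric)
  missing_cols <- setdiff(req, names(measures))
  if (length(missing_cols)) {
    abort(sprintf("`measures` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(methods) != 2) abort("`methods` must name exactly two methods")
  measures <- dplyr::filter(measures, .data$method %in% methods)
  # every subject x bundle x method cell must be present exactly once
  cells <- dplyr::count(measures, .data$subject_id, .data$bundle, .data$method)
  if (any(cells$n > 1)) abort("duplicate subject x bundle x method cells")
  grid_full <- tidyr::expand_grid(
    subject_id = unique(measures$subject_id),
    bundle = unique(measures$bundle),
    method = methods)
  gap <- dplyr::anti_join(grid_full, cells,
                          by = c("subject_id", "bundle", "method"))
  if (nrow(gap)) {
    abort(sprintf(
      "missing measures for: %s",
      paste(utils::head(sprintf("subject %s / %s / %s", gap$subject_id,
                                gap$bundle, gap$method), 5),
            collapse = "; ")))
  }
  descriptives <- measures |>
    dplyr::group_by(.data$bundle, .data$method) |>
    dplyr::summarise(descriptive_stats(.data[[metric]]), .groups = "drop")
  wide <- measures |>
    dplyr::select(dplyr::all_of(c("subject_id", "bundle", "method", metric))) |>
    tidyr::pivot_wider(names_from = "method", values_from = dplyr::all_of(metric)) |>
    dplyr::arrange(.data$bundle, .data$subject_id)
  tests <- wide |>
    dplyr::group_by(.data$bundle) |>
    dplyr::summarise(paired_t_test(.data[[methods[1]]], .data[[methods[2]]]),
                     .groups = "drop") |>
    dplyr::mutate(significant = .data$p_value < alpha)
  structure(list(descriptives = descriptives, tests = tests, data = wide,
                 methods = methods, metric = metric, alpha = alpha),
            class = "bundle_comparison")
}

#' @export
print.bundle_comparison <- function(x, ...) {
  cat("<bundle_comparison> ", x$metric, ": ", x$methods[1], " vs ",
      x$methods[2], " over ", length(unique(x$data$subject_id)),
      " subjects\n\n", sep = "")
  print(x$tests)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-bundle test table of a comparison
#'
#' @param x A [compare_cohort()] result.
#' @param ... Unused.
#' @return The per-bundle test tibble (`bundle`, `n`, `t_statistic`, `dof`,
#'   `p_value`, `cohen_d`, `shapiro_p`, `significant`).
#' @export
tidy.bundle_comparison <- function(x, ...) x$tests

#' One-row summary of a comparison
#'
#' @param x A [compare_cohort()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_bundles`, `n_subjects`, `max_p`, `min_d`,
#'   `all_significant`.
#' @export
glance.bundle_comparison <- function(x, ...) {
  tibble(n_bundles = nrow(x$tests),
         n_subjects = length(unique(x$data$subject_id)),
         max_p = max(x$tests$p_value),
         min_d = min(abs(x$tests$cohen_d)),
         all_significant = all(x$tests$significant))
}
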