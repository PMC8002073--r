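#' Build a patients x time points trajectory matrix
#'
#' Reshapes a per-sample summary table into a complete matrix of one metric.
#' Patients missing any time point are excluded listwise (in the default
#' study design the patient with the failed 3-month culture, leaving n = 14).
#'
#' @param summary_table Tibble with `patient_id`, `timepoint` and the metric
#'   column.
#' @param metric Name of the metric column (e.g. `"mtl"`, `"n_short"`,
#'   `"n_long"`, or an aberration frequency).
#' @return Numeric matrix, rownames = patient IDs, columns = the four time
#'   points in study order.
#' @export
trajectory_matrix <- function(summary_table, metric) {
  wide <- summary_table %>%
    select("patient_id", "timepoint", all_of(metric)) %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = all_of(metric))
  missing_tp <- setdiff(TIMEPOINTS, names(wide))
  for (tp in missing_tp) wide[[tp]] <- NA_real_
  mat <- as.matrix(wide[, TIMEPOINTS])
  rownames(mat) <- as.character(wide$patient_id)
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    mat <- mat[complete, , drop = FALSE]
  }
  mat
}

#' Repeated-measures ANOVA with post hoc Tukey HSD
#'
#' One-within-factor repeated-measures ANOVA on a complete patients x time
#' points matrix, with two-tailed Tukey HSD comparisons between every pair
#' of time points. The error term is the subject x time interaction of the
#' balanced design, computed in closed form; it is identical to the residual
#' of `aov(y ~ timepoint + patient)`. Counts of short and long telomeres are
#' square-root transformed before analysis when `sqrt_transform` is set,
#' stabilising the variance of count data.
#'
#' @param mat Complete numeric matrix (patients x time points, >= 3 rows,
#'   >= 2 columns); incomplete matrices signal an error — exclude patients
#'   first via [trajectory_matrix()].
#' @param sqrt_transform Apply `sqrt()` to the matrix before analysis.
#' @return List: `f_statistic`, `df`, `p_value`, and `tukey`, a tibble with
#'   one row per time-point pair (`pair`, `estimate`, `p_adj`).
#' @export
repeated_measures_anova <- function(mat, sqrt_transform = FALSE) {
  if (anyNA(mat)) abort("incomplete matrix: exclude patients with missing time points first")
  n <- nrow(mat)
  t <- ncol(mat)
  if (n < 3 || t < 2) abort("degenerate input: need >= 3 patients and >= 2 time points")
  if (sqrt_transform) {
    if (any(mat < 0)) abort("sqrt transform requires non-negative values")
    mat <- sqrt(mat)
  }
  grand <- mean(mat)
  col_means <- colMeans(mat)
  row_means <- rowMeans(mat)
  ss_time <- n * sum((col_means - grand)^2)
  ss_subj <- t * sum((row_means - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_time - ss_subj
  df_time <- t - 1
  df_err <- (t - 1) * (n - 1)
  ms_time <- ss_time / df_time
  ms_err <- ss_err / df_err
  f <- if (ms_err > 0) ms_time / ms_err else 0
  p <- pf(f, df_time, df_err, lower.tail = FALSE)

  cn <- colnames(mat)
  if (is.null(cn)) cn <- paste0("t", seq_len(t))
  pairs <- utils::combn(t, 2)
  tukey <- tibble(
    pair = apply(pairs, 2, function(ij) paste(cn[ij[2]], cn[ij[1]], sep = " - ")),
    estimate = apply(pairs, 2, function(ij) col_means[ij[2]] - col_means[ij[1]]),
    p_adj = apply(pairs, 2, function(ij) {
      q <- abs(col_means[ij[2]] - col_means[ij[1]]) / sqrt(ms_err / n)
      ptukey(q, nmeans = t, df = df_err, lower.tail = FALSE)
    })
  )
  list(f_statistic = unname(f), df = c(df_time, df_err), p_value = unname(p), tukey = tukey)
}

#' Hierarchically cluster patients by longitudinal trajectories
#'
#' Rows are z-score normalised (so clustering sees trajectory shape, not
#' level), pairwise distance is `1 - Pearson correlation` between rows, and
#' the single-linkage tree is cut into `k` groups.
#'
#' @param mat Complete patients x time points matrix.
#' @param k Number of groups to cut (default 2, the study's replication
#'   setting).
#' @return List of class `cluster_result`: `labels` (named integer vector),
#'   `linkage` (`hclust` object), `k`.
#' @export
cluster_patients <- function(mat, k = 2) {
  if (anyNA(mat)) abort("incomplete matrix: exclude patients with missing time points first")
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("degenerate row: zero variance trajectory for patient(s) ",
                 paste(rownames(mat)[sds == 0], collapse = ", ")))
  }
  z <- t(scale(t(mat)))
  d <- stats::as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "single")
  labels <- cutree(hc, k = k)
  structure(list(labels = labels, linkage = hc, k = k), class = "cluster_result")
}

#' Ordinary least squares baseline prediction
#'
#' Fits the study's linear-regression baselines: the 3-month outcome
#' regressed on the pre-therapy non-irradiated metric alone, or on both
#' pre-therapy metrics (non-irradiated and 4 Gy in vitro). The coefficient
#' of determination is reported in-sample, matching how these baselines are
#' usually quoted.
#'
#' @param baseline_metric Numeric vector, one value per patient.
#' @param irradiated_metric Optional numeric vector (4 Gy sample metric), or
#'   `NULL` for the baseline-only model.
#' @param target_metric Numeric vector of 3-month outcomes.
#' @return List: `coefficients`, `r_squared`, `predictor_set`
#'   (`"baseline-only"` or `"baseline+4gy"`), `fitted`.
#' @export
baseline_linear_prediction <- function(baseline_metric, irradiated_metric = NULL,
                                       target_metric) {
  n <- length(target_metric)
  if (n < 3) abort("degenerate input: need >= 3 patients")
  df <- data.frame(y = target_metric, x1 = baseline_metric)
  form <- y ~ x1
  if (!is.null(irradiated_metric)) {
    df$x2 <- irradiated_metric
    form <- y ~ x1 + x2
  }
  fit <- lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) abort("collinearity error: rank-deficient design")
  list(
    coefficients = stats::coef(fit),
    r_squared = summary(fit)$r.squared,
    predictor_set = if (is.null(irradiated_metric)) "baseline-only" else "baseline+4gy",
    fitted = unname(stats::fitted(fit))
  )
}

#' Longitudinal Pearson correlation between two metrics
#'
#' Pools paired per-patient per-time-point observations and returns the
#' signed Pearson correlation. Reported alongside its square rather than as
#' a signed value labelled r-squared.
#'
#' @param series_a,series_b Numeric vectors of equal length (>= 3 pairs),
#'   aligned by patient x time point.
#' @return List: `r` (signed), `r_squared`, `n`.
#' @export
longitudinal_correlation <- function(series_a, series_b) {
  keep <- stats::complete.cases(series_a, series_b)
  a <- series_a[keep]
  b <- series_b[keep]
  if (length(a) < 3) abort("degenerate input: need >= 3 paired observations")
  if (sd(a) == 0 || sd(b) == 0) abort("undefined correlation: zero variance series")
  r <- cor(a, b)
  list(r = r, r_squared = r^2, n = length(a))
}
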