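# A "sample" throughout this file is a long tibble for one patient x time
# point with columns patient_id, timepoint, telomere_rfi and (after
# imputation) a logical `imputed` provenance flag.

#' Control-based standardization ratio
#'
#' Each patient's batch carries a pair of control slides (a normal and an
#' immortalized fibroblast line) imaged alongside the patient's samples. The
#' ratio of cohort reference means to the batch's control means standardizes
#' the patient's telomere values across batches. The convention is the mean
#' of the two per-line ratios `reference / batch`; equal batch and reference
#' means give ratio 1, and a batch measuring uniformly twice as bright as the
#' reference gives ratio 0.5.
#'
#' @param pair One-row data frame (or list) with `batch_mean_normal`,
#'   `batch_mean_immortal`, `reference_mean_normal`,
#'   `reference_mean_immortal`, all > 0.
#' @return Positive scalar ratio.
#' @export
compute_control_ratio <- function(pair) {
  m <- c(pair$batch_mean_normal, pair$batch_mean_immortal,
         pair$reference_mean_normal, pair$reference_mean_immortal)
  if (length(m) != 4 || any(!is.finite(m)) || any(m <= 0)) {
    abort("domain error: control means must be positive")
  }
  mean(c(pair$reference_mean_normal / pair$batch_mean_normal,
         pair$reference_mean_immortal / pair$batch_mean_immortal))
}

#' Standardize a telomere sample by its batch control ratio
#'
#' Multiplies every telomere value by the batch's control ratio, preserving
#' row order and any provenance flags.
#'
#' @param sample Long sample tibble with a `telomere_rfi` column.
#' @param ratio Positive scalar from [compute_control_ratio()].
#' @return The sample with `telomere_rfi` scaled.
#' @export
standardize_sample <- function(sample, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) || ratio <= 0) {
    abort("domain error: ratio must be a positive scalar")
  }
  sample$telomere_rfi <- sample$telomere_rfi * ratio
  sample
}

#' Remove 3-SD outliers from a telomere sample
#'
#' Single-pass filter: the mean and sample SD are computed once from the
#' input, and every value with `|x - mean| > 3 * SD` is dropped. The filter
#' is deliberately not iterated; on clean unimodal samples it removes well
#' under 1 percent of measurements.
#'
#' @param sample Long sample tibble with >= 2 values.
#' @return The sample restricted to values within 3 SD of the mean.
#' @export
remove_outliers <- function(sample) {
  x <- sample$telomere_rfi
  if (length(x) < 2) abort("degenerate input: need at least 2 values to estimate spread")
  m <- mean(x)
  s <- sd(x)
  sample[abs(x - m) <= 3 * s, , drop = FALSE]
}

#' Impute a telomere sample up to its theoretical size
#'
#' Samples with fewer measurements than the theoretical number (cells imaged
#' x telomeres per cell) are topped up by resampling, with replacement, from
#' the observed values; imputed rows are flagged. A sample already at the
#' theoretical size is returned unchanged apart from gaining the provenance
#' flag.
#'
#' @param sample Long sample tibble with 1..`theoretical_n` observed values.
#' @param theoretical_n Target number of measurements (e.g. 50 x 92 = 4600).
#' @param seed Integer seed for the resampling draws.
#' @return The sample with exactly `theoretical_n` rows and a logical
#'   `imputed` column (`FALSE` for observed rows).
#' @export
impute_to_theoretical <- function(sample, theoretical_n, seed = 1L) {
  n <- nrow(sample)
  if (n == 0) abort("degenerate input: cannot impute from an empty sample")
  if (n > theoretical_n) {
    abort("contract violation: sample has more values than the theoretical number")
  }
  sample$imputed <- FALSE
  if (n == theoretical_n) return(sample)
  set.seed(seed)
  idx <- sample.int(n, theoretical_n - n, replace = TRUE)
  extra <- sample[idx, , drop = FALSE]
  extra$imputed <- TRUE
  out <- dplyr::bind_rows(sample, extra)
  out
}

#' Summary statistics of a telomere sample
#'
#' @param sample Long sample tibble with >= 1 value.
#' @return One-row tibble: `mtl` (mean telomere length, the arithmetic mean
#'   of the RFI values), `sd` (sample SD, n-1 denominator), `n_values`.
#' @export
summarize_sample <- function(sample) {
  x <- sample$telomere_rfi
  if (length(x) == 0) abort("degenerate input: empty sample")
  tibble(mtl = mean(x), sd = if (length(x) > 1) sd(x) else 0, n_values = length(x))
}

#' Process all telomere samples of a cohort
#'
#' Applies the fixed pipeline standardize -> remove 3-SD outliers -> impute
#' to the theoretical count, per patient x time point. Standardization comes
#' first so the 3-SD rule operates on batch-comparable values; imputation
#' seeds are derived per sample from `seed` so the result is reproducible
#' and independent of processing order.
#'
#' @param telo Long tibble of raw telomere values (`patient_id`, `timepoint`,
#'   `telomere_rfi`, optionally `cell_id`).
#' @param controls Control table with one row per patient
#'   (see [compute_control_ratio()]).
#' @param theoretical_n Measurements per complete sample (default 4600).
#' @param seed Integer base seed for imputation.
#' @return Long tibble of processed samples with an `imputed` flag.
#' @export
process_telo_cohort <- function(telo, controls, theoretical_n = 4600L, seed = 1L) {
  ratios <- vapply(seq_len(nrow(controls)), function(i) {
    compute_control_ratio(controls[i, ])
  }, numeric(1))
  names(ratios) <- as.character(controls$patient_id)
  telo %>%
    group_by(.data$patient_id, .data$timepoint) %>%
    group_modify(function(df, key) {
      df$patient_id <- key$patient_id
      df$timepoint <- key$timepoint
      ratio <- ratios[[as.character(key$patient_id)]]
      tp_idx <- match(key$timepoint, TIMEPOINTS)
      out <- df %>%
        standardize_sample(ratio) %>%
        remove_outliers() %>%
        impute_to_theoretical(theoretical_n,
                              seed = seed_stream(seed, key$patient_id, tp_idx, 6L))
      out$patient_id <- NULL
      out$timepoint <- NULL
      out
    }) %>%
    ungroup()
}

#' Per-sample summary table for a processed cohort
#'
#' @param processed Long tibble from [process_telo_cohort()].
#' @return Tibble with one row per patient x time point: `mtl`, `sd`,
#'   `n_values`.
#' @export
summarize_telo_cohort <- function(processed) {
  processed %>%
    group_by(.data$patient_id, .data$timepoint) %>%
    summarise(
      mtl = mean(.data$telomere_rfi),
      sd = sd(.data$telomere_rfi),
      n_values = dplyr::n(),
      .groups = "drop"
    )
}
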