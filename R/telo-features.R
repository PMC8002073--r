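#' Baseline-anchored quartile cut-offs
#'
#' Computes the 25th and 75th percentiles of a patient's pre-therapy
#' non-irradiated telomere distribution. These cut-offs are fixed once per
#' patient and reapplied to every later time point to count relatively
#' short, mid-length and long telomeres.
#'
#' @param baseline Long sample tibble (or numeric vector) of the baseline
#'   non-irradiated sample; needs >= 4 values.
#' @param type Percentile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return List with `q25` and `q75`.
#' @export
baseline_cutoffs <- function(baseline, type = 7) {
  x <- if (is.numeric(baseline)) baseline else baseline$telomere_rfi
  if (length(x) < 4) abort("degenerate input: need at least 4 values for quartile cut-offs")
  q <- quantile(x, c(0.25, 0.75), type = type, names = FALSE)
  list(q25 = q[1], q75 = q[2])
}

#' Count short, mid-length and long telomeres
#'
#' Partitions a sample against fixed cut-offs: short if strictly below
#' `q25`, long if strictly above `q75`, otherwise mid-length (boundary ties
#' fall in the middle class). The partition is exhaustive and exclusive, so
#' the three counts always sum to the sample size.
#'
#' @param sample Long sample tibble (or numeric vector).
#' @param cutoffs List from [baseline_cutoffs()].
#' @return One-row tibble: `n_short`, `n_mid`, `n_long`.
#' @export
count_length_classes <- function(sample, cutoffs) {
  x <- if (is.numeric(sample)) sample else sample$telomere_rfi
  if (length(x) == 0) abort("degenerate input: empty sample")
  n_short <- sum(x < cutoffs$q25)
  n_long <- sum(x > cutoffs$q75)
  tibble(n_short = n_short, n_mid = length(x) - n_short - n_long, n_long = n_long)
}

#' Length-class feature table for a processed cohort
#'
#' For each patient, quartile cut-offs are computed once from the baseline
#' non-irradiated sample and applied to all of that patient's time points.
#'
#' @param processed Long tibble from [process_telo_cohort()].
#' @param type Percentile convention (see [baseline_cutoffs()]).
#' @return Tibble with one row per patient x time point: `n_short`, `n_mid`,
#'   `n_long`, `q25`, `q75`.
#' @export
length_class_table <- function(processed, type = 7) {
  patients <- unique(processed$patient_id)
  rows <- lapply(patients, function(p) {
    base <- processed %>%
      filter(.data$patient_id == p, .data$timepoint == "baseline_nonirr")
    if (nrow(base) == 0) {
      warn(paste0("patient ", p, " has no baseline non-irradiated sample; skipped"))
      return(NULL)
    }
    cuts <- baseline_cutoffs(base, type = type)
    pd <- processed %>% filter(.data$patient_id == p)
    pd %>%
      group_by(.data$timepoint) %>%
      group_modify(~ count_length_classes(.x, cuts)) %>%
      ungroup() %>%
      mutate(patient_id = p, q25 = cuts$q25, q75 = cuts$q75) %>%
      select("patient_id", "timepoint", "n_short", "n_mid", "n_long", "q25", "q75")
  })
  dplyr::bind_rows(rows)
}
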