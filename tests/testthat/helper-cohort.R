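# Shared fixtures, all generated in code.

# Miniature cohort: 6 patients (2 shortening / 3 lengthening / 1 with the
# missing final sample), 5 cells x 20 telomeres, 10 CA cells per sample.
small_config <- function(seed = 1L, ...) {
  cohort_config(
    n_patients = 6L, n_cells_telo = 5L, telomeres_per_cell = 20L,
    n_cells_ca = 10L, n_shortening = 2L, n_lengthening = 3L,
    missing_final_patient = 5L, seed = seed, ...
  )
}

# A single-sample tibble of positive RFI values.
make_sample <- function(values, patient = 1L, timepoint = "baseline_nonirr") {
  tibble::tibble(patient_id = patient, timepoint = timepoint,
                 telomere_rfi = values)
}

# Label agreement between a 2-group clustering and binary truth, up to label
# permutation.
cluster_agreement <- function(labels, truth) {
  tab <- table(labels, truth)
  max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
}

# Small hand-buildable long dataset: n patients x 2 origins x m telomeres.
toy_rows <- function(n_patients = 4, m = 30, seed = 1) {
  set.seed(seed)
  loc <- seq(80, 140, length.out = n_patients)
  rows <- lapply(seq_len(n_patients), function(p) {
    tibble::tibble(
      patient_id = p,
      telomere_rfi = c(rnorm(m, loc[p], 2), rnorm(m, loc[p] * 1.1, 2)),
      origin_label = rep(0:1, each = m),
      target = 1.3 * loc[p]
    )
  })
  dplyr::bind_rows(rows)
}
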