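#' Configuration of the synthetic radiotherapy cohort
#'
#' Builds the full parameterization of the synthetic cohort generator. The
#' defaults emulate the study design the analysis assumes: 15 prostate-cancer
#' patients sampled at four points (pre-therapy non-irradiated, pre-therapy
#' 4 Gy in vitro, immediately post-IMRT, 3 months post-IMRT), 50 metaphase
#' cells x 92 telomeres = 4600 individual telomere measurements per sample,
#' one patient (ID 13) whose final sample fails to culture, two planted
#' response groups (3 patients whose mean telomere length falls after
#' therapy, 11 whose rises), 30 metaphase cells scored for chromosome
#' aberrations per sample with inversions the most frequent radiation-induced
#' type, and batch-paired control samples for standardization.
#'
#' Telomere intensities are drawn from a right-skewed gamma distribution
#' (arbitrary relative-fluorescence-intensity units). A patient's location at
#' a time point is `base_location * group_baseline_shift * patient_effect *
#' group_timepoint_multiplier * sample_jitter`; the per-patient effect and
#' per-sample jitter are lognormal. The distribution family parameters are
#' configuration, not a claim about real Q-FISH data.
#'
#' @param n_patients Number of patients (default 15).
#' @param n_cells_telo Metaphase cells imaged per telomere sample (default 50).
#' @param telomeres_per_cell Telomere signals quantified per cell (default 92,
#'   i.e. 46 chromosomes x 2 termini with sister-chromatid signals merged;
#'   50 x 92 = 4600 measurements per sample).
#' @param n_cells_ca Metaphase cells scored for aberrations per sample
#'   (default 30).
#' @param n_shortening,n_lengthening Planted response-group sizes (defaults
#'   3 and 11). Together with the patient carrying the missing final sample
#'   they must account for all patients.
#' @param missing_final_patient Patient ID whose 3-month sample is absent
#'   (default 13); `NA` for a complete cohort.
#' @param telo_dist_params Named list: `base_location` (RFI), `shape` (gamma
#'   shape; coefficient of variation is `1/sqrt(shape)`), `patient_effect_sd`
#'   and `sample_jitter_sd` (lognormal sdlog), `group_baseline_shift` and
#'   `group_timepoint_multipliers` per response group.
#' @param missing_rate Fraction of telomere measurements dropped before
#'   imputation (default 0.02).
#' @param outlier_rate Fraction of measurements replaced by injected extreme
#'   values > 3 SD above the bulk (default 0.002; with the gamma tail this
#'   keeps the overall 3-SD outlier fraction below 1 percent).
#' @param ca_rates Matrix-like named list of mean aberrations per cell, one
#'   numeric vector of length 4 (time points in order) per aberration type
#'   (`inversions`, `translocations`, `dicentrics`, `fragments`, `sce`).
#'   Inversions must have the highest rate among radiation-induced types at
#'   irradiated time points.
#' @param ca_patient_effect_sd Lognormal sdlog of the per-patient multiplier
#'   on aberration rates (default 0.2; weak patient-level signal).
#' @param clonal_fraction Probability that a scored aberration duplicates an
#'   earlier cell's aberration signature within the same patient x time point
#'   (default 0.1).
#' @param cbc_params Named list of complete-blood-count baselines and the
#'   coupling coefficient linking lymphocyte counts to relative MTL change.
#' @param control_params Named list: cohort reference means for the normal
#'   (BJ1-like) and immortalized (hTERT-like) control lines and the lognormal
#'   sdlog of the per-patient batch effect that standardization removes.
#' @param seed Integer global seed; expanded into independent per-stream
#'   sub-seeds.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [ml_recovery_config()]
#' @export
cohort_config <- function(n_patients = 15L,
                          n_cells_telo = 50L,
                          telomeres_per_cell = 92L,
                          n_cells_ca = 30L,
                          n_shortening = 3L,
                          n_lengthening = 11L,
                          missing_final_patient = 13L,
                          telo_dist_params = list(),
                          missing_rate = 0.02,
                          outlier_rate = 0.002,
                          ca_rates = NULL,
                          ca_patient_effect_sd = 0.2,
                          clonal_fraction = 0.1,
                          cbc_params = list(),
                          control_params = list(),
                          seed = 1L) {
  telo_defaults <- list(
    base_location = 100,
    shape = 8,
    patient_effect_sd = 0.08,
    sample_jitter_sd = 0.03,
    group_baseline_shift = c(shortening = 1.30, lengthening = 0.90),
    group_timepoint_multipliers = list(
      # shortening patients: modest rise at 4 Gy, persistent drop after IMRT
      shortening  = c(1.00, 1.05, 0.80, 0.70),
      # lengthening patients: sustained rise post-IMRT
      lengthening = c(1.00, 1.10, 1.25, 1.30)
    )
  )
  cbc_defaults <- list(
    wbc_base = 6.0, lymph_base = 2.0, baso_base = 0.04,
    nk_base = 10, cd4_base = 45, cd8_base = 25, cd19_base = 12,
    lymph_mtl_coupling = -0.8, noise_sd = 0.05
  )
  control_defaults <- list(
    reference_mean_normal = 80, reference_mean_immortal = 160,
    batch_effect_sd = 0.05
  )
  if (is.null(ca_rates)) {
    ca_rates <- list(
      inversions     = c(0.08, 0.35, 0.30, 0.30),
      translocations = c(0.03, 0.25, 0.18, 0.12),
      dicentrics     = c(0.02, 0.22, 0.15, 0.08),
      fragments      = c(0.03, 0.20, 0.15, 0.10),
      sce            = c(0.10, 0.10, 0.10, 0.10)
    )
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_cells_telo = as.integer(n_cells_telo),
    telomeres_per_cell = as.integer(telomeres_per_cell),
    n_cells_ca = as.integer(n_cells_ca),
    timepoints = TIMEPOINTS,
    n_shortening = as.integer(n_shortening),
    n_lengthening = as.integer(n_lengthening),
    missing_final_patient = if (is.na(missing_final_patient)) NA_integer_ else as.integer(missing_final_patient),
    telo_dist_params = modifyList(telo_defaults, telo_dist_params),
    missing_rate = missing_rate,
    outlier_rate = outlier_rate,
    ca_rates = ca_rates,
    ca_patient_effect_sd = ca_patient_effect_sd,
    clonal_fraction = clonal_fraction,
    cbc_params = modifyList(cbc_defaults, cbc_params),
    control_params = modifyList(control_defaults, control_params),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_patients, cfg$n_cells_telo, cfg$telomeres_per_cell, cfg$n_cells_ca)
  if (any(counts < 1L)) abort("configuration error: counts must be >= 1")
  fr <- c(cfg$missing_rate, cfg$outlier_rate, cfg$clonal_fraction)
  if (any(fr < 0 | fr > 1)) abort("configuration error: rates/fractions must lie in [0, 1]")
  if (cfg$missing_rate >= 1) abort("configuration error: missing_rate must be < 1")
  td <- cfg$telo_dist_params
  if (td$base_location <= 0 || td$shape <= 0) {
    abort("configuration error: distribution location and shape must be > 0")
  }
  if (td$patient_effect_sd < 0 || td$sample_jitter_sd < 0) {
    abort("configuration error: distribution scales must be >= 0")
  }
  n_excluded <- if (is.na(cfg$missing_final_patient)) 0L else 1L
  if (cfg$n_shortening + cfg$n_lengthening + n_excluded != cfg$n_patients) {
    abort("configuration error: n_shortening + n_lengthening + excluded patients must equal n_patients")
  }
  rates <- cfg$ca_rates
  if (any(unlist(rates) < 0)) abort("configuration error: aberration rates must be >= 0")
  if (any(lengths(rates) != 4L)) abort("configuration error: each ca_rate needs one value per time point")
  induced <- setdiff(names(rates), c("inversions", "sce"))
  irr <- 2:4  # irradiated time points (4 Gy in vitro and the two post-IMRT samples)
  for (ty in induced) {
    if (any(rates$inversions[irr] < rates[[ty]][irr])) {
      abort("configuration error: inversions must have the highest radiation-induced rate at irradiated time points")
    }
  }
  invisible(cfg)
}

#' Low-noise cohort configuration for parameter-recovery studies
#'
#' A cohort configuration in which the 3-month telomeric outcome is a
#' near-deterministic smooth function of each patient's baseline distribution
#' location and 4 Gy shift: narrow within-patient spread (gamma shape 1000,
#' coefficient of variation ~3 percent), minimal per-sample jitter, and no
#' missingness or injected outliers. Under these conditions a boosted
#' regressor can recover the value-to-outcome mapping and generalize to
#' held-out patients, which is what the recovery test suites probe. The
#' default [cohort_config()] keeps a realistic wide Q-FISH-like spread and is
#' not expected to support near-perfect prediction.
#'
#' @param seed Integer global seed.
#' @param ... Further overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
ml_recovery_config <- function(seed = 1L, ...) {
  cohort_config(
    telo_dist_params = list(shape = 1000, sample_jitter_sd = 0.005),
    missing_rate = 0,
    outlier_rate = 0,
    seed = seed,
    ...
  )
}
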