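# Stream codes for sub-seed derivation (see seed_stream in teloRT-package.R)
STREAM_PATIENT <- 1L
STREAM_TELO    <- 2L
STREAM_CA      <- 3L
STREAM_CBC     <- 4L
STREAM_CONTROL <- 5L

#' Generate one synthetic telomere sample
#'
#' Draws individual telomere relative-fluorescence intensities for one
#' patient x time point from a right-skewed gamma distribution, drops a
#' fraction of measurements (emulating unquantifiable signals) and replaces a
#' fraction with injected extreme values lying more than 3 SD above the bulk
#' mean (emulating acquisition artefacts).
#'
#' @param patient Patient identifier.
#' @param timepoint Canonical time-point label.
#' @param location Gamma mean in RFI units (> 0).
#' @param shape Gamma shape parameter (> 0); values are
#'   `rgamma(n, shape, rate = shape / location)` so the mean is `location`.
#' @param missing_rate Fraction of measurements dropped, in `[0, 1)`.
#' @param outlier_rate Fraction of retained measurements replaced by extreme
#'   values.
#' @param n_cells,telomeres_per_cell Sample geometry; the complete sample has
#'   `n_cells * telomeres_per_cell` measurements.
#' @param seed Integer seed for this sample's draws.
#' @return Tibble with columns `patient_id`, `timepoint`, `cell_id`,
#'   `telomere_rfi`.
#' @export
generate_telo_sample <- function(patient, timepoint, location, shape,
                                 missing_rate = 0, outlier_rate = 0,
                                 n_cells = 50L, telomeres_per_cell = 92L,
                                 seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) abort("configuration error: missing_rate must lie in [0, 1)")
  if (location <= 0 || shape <= 0) abort("configuration error: location and shape must be > 0")
  set.seed(seed)
  n <- n_cells * telomeres_per_cell
  values <- rgamma(n, shape = shape, rate = shape / location)
  cell_id <- rep(seq_len(n_cells), each = telomeres_per_cell)
  keep <- runif(n) >= missing_rate
  values <- values[keep]
  cell_id <- cell_id[keep]
  if (outlier_rate > 0 && length(values) > 1) {
    bulk_mean <- mean(values)
    bulk_sd <- sd(values)
    is_out <- runif(length(values)) < outlier_rate
    n_out <- sum(is_out)
    if (n_out > 0) {
      values[is_out] <- bulk_mean + (4 + 3 * runif(n_out)) * bulk_sd
    }
  }
  tibble(
    patient_id = patient,
    timepoint = timepoint,
    cell_id = cell_id,
    telomere_rfi = values
  )
}

#' Generate synthetic per-cell chromosome aberration scores
#'
#' Per-cell aberration counts are independent Poisson draws per type. A
#' `clonal_fraction` of scored aberrations duplicate the signature of an
#' aberration already scored in an earlier cell of the same patient x time
#' point, emulating clonal expansion; [clonality_correct()] removes such
#' duplicates. Clonal copying redirects an aberration's identity, not its
#' count, so raw per-type means remain Poisson with the configured rates.
#'
#' @param patient Patient identifier.
#' @param timepoint Canonical time-point label.
#' @param rates Named numeric vector of mean aberrations per cell for
#'   `inversions`, `translocations`, `dicentrics`, `fragments`, `sce`.
#' @param clonal_fraction Probability an aberration is a clone of an earlier
#'   one (same type, same patient x time point).
#' @param n_cells Number of metaphase cells scored.
#' @param seed Integer seed.
#' @return Tibble with one row per cell: `patient_id`, `timepoint`,
#'   `cell_id`, one count column per type, and `signatures`
#'   (semicolon-delimited `type:label` entries, one per scored aberration).
#' @export
generate_aberration_cells <- function(patient, timepoint, rates,
                                      clonal_fraction = 0, n_cells = 30L,
                                      seed = 1L) {
  if (any(rates < 0)) abort("configuration error: aberration rates must be >= 0")
  if (n_cells < 1) abort("configuration error: n_cells must be >= 1")
  types <- names(rates)
  set.seed(seed)
  counts <- lapply(types, function(ty) rpois(n_cells, rates[[ty]]))
  names(counts) <- types
  seen <- setNames(vector("list", length(types)), types)  # signature pool per type
  sig_col <- character(n_cells)
  counter <- setNames(integer(length(types)), types)
  for (i in seq_len(n_cells)) {
    sigs <- character(0)
    for (ty in types) {
      k <- counts[[ty]][i]
      if (k == 0) next
      for (j in seq_len(k)) {
        pool <- seen[[ty]]
        if (length(pool) > 0 && runif(1) < clonal_fraction) {
          lab <- pool[sample.int(length(pool), 1)]
        } else {
          counter[[ty]] <- counter[[ty]] + 1L
          lab <- paste0(patient, "_", timepoint, "_", ty, "_", counter[[ty]])
          seen[[ty]] <- c(seen[[ty]], lab)
        }
        sigs <- c(sigs, paste0(ty, ":", lab))
      }
    }
    sig_col[i] <- paste(sigs, collapse = ";")
  }
  out <- tibble(patient_id = patient, timepoint = timepoint, cell_id = seq_len(n_cells))
  for (ty in types) out[[ty]] <- as.integer(counts[[ty]])
  out$signatures <- sig_col
  out
}

# Resolve per-patient generative structure: random effects, batch effects,
# group labels (the n_shortening included patients with the largest effects
# shorten, matching the observation that the shortening group started with
# relatively longer telomeres) and the location matrix patients x timepoints.
cohort_truth <- function(cfg) {
  td <- cfg$telo_dist_params
  patients <- seq_len(cfg$n_patients)
  patient_effect <- vapply(patients, function(p) {
    set.seed(seed_stream(cfg$seed, p, 0, STREAM_PATIENT))
    rlnorm(1, 0, td$patient_effect_sd)
  }, numeric(1))
  batch_effect <- vapply(patients, function(p) {
    set.seed(seed_stream(cfg$seed, p, 0, STREAM_CONTROL))
    rlnorm(1, 0, cfg$control_params$batch_effect_sd)
  }, numeric(1))
  included <- patients[!patients %in% cfg$missing_final_patient]
  shortening <- included[order(patient_effect[included], decreasing = TRUE)][seq_len(cfg$n_shortening)]
  group <- ifelse(patients %in% cfg$missing_final_patient, "excluded",
                  ifelse(patients %in% shortening, "shortening", "lengthening"))
  # generative multipliers: excluded patients follow the majority (lengthening) pattern
  gen_group <- ifelse(group == "shortening", "shortening", "lengthening")
  loc <- matrix(NA_real_, cfg$n_patients, 4,
                dimnames = list(patients, TIMEPOINTS))
  for (p in patients) {
    g <- gen_group[p]
    shift <- td$group_baseline_shift[[g]]
    mult <- td$group_timepoint_multipliers[[g]]
    for (t in 1:4) {
      set.seed(seed_stream(cfg$seed, p, t, STREAM_PATIENT))
      jitter <- rlnorm(1, 0, td$sample_jitter_sd)
      loc[p, t] <- td$base_location * shift * patient_effect[p] * mult[t] * jitter
    }
  }
  list(
    table = tibble(
      patient_id = patients,
      group = group,
      patient_effect = patient_effect,
      batch_effect = batch_effect,
      target_mtl_generative = loc[, "three_month_post"]
    ),
    locations = loc
  )
}

#' Generate a full synthetic cohort
#'
#' Produces every table the analysis pipeline consumes: raw (batch-affected)
#' individual telomere measurements for each patient x time point, paired
#' control summaries for standardization, per-cell chromosome aberration
#' scores, complete blood counts, and a ground-truth table recording each
#' patient's planted response group and generative parameters. The patient
#' named by `missing_final_patient` has no 3-month telomere or aberration
#' sample, emulating a culture failure. Regeneration with an identical
#' configuration (including seed) yields identical tables.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `telo`
#'   (long tibble of raw telomere RFIs), `controls`, `ca_cells`, `cbc`,
#'   `truth`, and the `config` used.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("configuration error: expected a cohort_config")
  validate_cohort_config(config)
  cfg <- config
  truth <- cohort_truth(cfg)
  td <- cfg$telo_dist_params
  patients <- seq_len(cfg$n_patients)

  samples <- list()
  ca <- list()
  for (p in patients) {
    be <- truth$table$batch_effect[p]
    ca_effect <- {
      set.seed(seed_stream(cfg$seed, p, 0, STREAM_CA))
      rlnorm(1, 0, cfg$ca_patient_effect_sd)
    }
    for (t in 1:4) {
      tp <- TIMEPOINTS[t]
      if (tp == "three_month_post" && p %in% cfg$missing_final_patient) next
      s <- generate_telo_sample(
        patient = p, timepoint = tp,
        location = truth$locations[p, t] * be, shape = td$shape,
        missing_rate = cfg$missing_rate, outlier_rate = cfg$outlier_rate,
        n_cells = cfg$n_cells_telo, telomeres_per_cell = cfg$telomeres_per_cell,
        seed = seed_stream(cfg$seed, p, t, STREAM_TELO)
      )
      samples[[length(samples) + 1L]] <- s
      rates <- vapply(cfg$ca_rates, function(r) r[t], numeric(1)) * ca_effect
      ca[[length(ca) + 1L]] <- generate_aberration_cells(
        patient = p, timepoint = tp, rates = rates,
        clonal_fraction = cfg$clonal_fraction, n_cells = cfg$n_cells_ca,
        seed = seed_stream(cfg$seed, p, t, STREAM_CA)
      )
    }
  }

  controls <- tibble(
    patient_id = patients,
    batch_mean_normal = cfg$control_params$reference_mean_normal * truth$table$batch_effect,
    batch_mean_immortal = cfg$control_params$reference_mean_immortal * truth$table$batch_effect,
    reference_mean_normal = cfg$control_params$reference_mean_normal,
    reference_mean_immortal = cfg$control_params$reference_mean_immortal
  )

  cbc <- generate_cbc_table(cfg, truth)

  structure(
    list(
      telo = dplyr::bind_rows(samples),
      controls = controls,
      ca_cells = dplyr::bind_rows(ca),
      cbc = cbc,
      truth = truth$table,
      config = cfg
    ),
    class = "synthetic_cohort"
  )
}

# Complete blood counts: lymphocytes are negatively coupled to each patient's
# relative MTL change (cell killing raises apparent MTL while depressing
# counts); lymphocyte sub-populations shift mildly with the same signal.
generate_cbc_table <- function(cfg, truth) {
  cb <- cfg$cbc_params
  rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    base_loc <- truth$locations[p, 1]
    for (t in 1:4) {
      set.seed(seed_stream(cfg$seed, p, t, STREAM_CBC))
      rel_change <- truth$locations[p, t] / base_loc - 1
      noise <- function() exp(rnorm(1, 0, cb$noise_sd))
      lymph <- cb$lymph_base * (1 + cb$lymph_mtl_coupling * rel_change) * noise()
      lymph <- max(lymph, 0.1)
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = p,
        timepoint = TIMEPOINTS[t],
        wbc = lymph + 4.0 * noise(),
        lymphocytes = lymph,
        basophils = cb$baso_base * noise(),
        nk_pct = cb$nk_base * (1 + 0.5 * rel_change) * noise(),
        cd4_pct = cb$cd4_base * (1 + 0.3 * rel_change) * noise(),
        cd8_pct = cb$cd8_base * (1 - 0.3 * rel_change) * noise(),
        cd19_pct = cb$cd19_base * (1 - 0.3 * rel_change) * noise()
      )
    }
  }
  dplyr::bind_rows(rows)
}
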