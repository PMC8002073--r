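ABERRATION_TYPES <- c("inversions", "translocations", "dicentrics", "fragments", "sce")

#' Parse a per-cell chromosome-aberration score sheet
#'
#' Reads (or validates) a per-cell score sheet with one row per metaphase
#' cell and integer counts per aberration type. Sister chromatid exchanges
#' (`sce`) are carried through; they are excluded later from the aberration
#' index and from ML features. An optional `signatures` column holds
#' semicolon-delimited `type:label` entries enabling clonality correction.
#'
#' @param table Path to a CSV file, or a data frame already in memory.
#' @return Tibble of aberration cells; malformed rows raise row-numbered
#'   errors.
#' @export
parse_score_sheet <- function(table) {
  df <- if (is.character(table)) {
    readr::read_csv(table, show_col_types = FALSE)
  } else {
    as_tibble(table)
  }
  required <- c("patient_id", "timepoint", "cell_id", ABERRATION_TYPES)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing column(s) ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    df$signatures <- character(0)
    return(df[, c(required, "signatures")])
  }
  df$timepoint <- timepoint_levels(df$timepoint)
  for (ty in ABERRATION_TYPES) {
    v <- df[[ty]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort(paste0("value error: non-negative integer expected for ", ty,
                   " at row(s) ", paste(head(bad, 5), collapse = ", ")))
    }
    df[[ty]] <- as.integer(v)
  }
  if (!"signatures" %in% names(df)) {
    df$signatures <- NA_character_
  } else {
    # CSV round-trips read empty signature lists back as NA
    df$signatures[is.na(df$signatures)] <- ""
  }
  df[, c(required, "signatures")]
}

split_signatures <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Clonality correction of aberration counts
#'
#' An identical aberration signature observed in several cells of one
#' patient x time point reflects clonal expansion of a single event, not
#' independent induction, and is scored only once: the first cell (by
#' `cell_id`) keeps the aberration, later duplicates are removed and their
#' counts decremented. Cells without signatures pass through unchanged with
#' a warning. The correction never increases a count and is idempotent.
#'
#' @param cells Tibble from [parse_score_sheet()] (any mix of patients and
#'   time points; correction is applied within each patient x time point).
#' @return The corrected tibble.
#' @export
clonality_correct <- function(cells) {
  if (nrow(cells) == 0) return(cells)
  if (!"signatures" %in% names(cells) || all(is.na(cells$signatures))) {
    warn("no aberration signatures available; clonality correction skipped")
    return(cells)
  }
  cells %>%
    group_by(.data$patient_id, .data$timepoint) %>%
    group_modify(function(df, key) {
      df <- df[order(df$cell_id), , drop = FALSE]
      seen <- character(0)
      for (i in seq_len(nrow(df))) {
        sigs <- split_signatures(df$signatures[i])
        dup <- sigs %in% seen
        if (any(dup)) {
          for (sg in sigs[dup]) {
            ty <- sub(":.*$", "", sg)
            if (ty %in% ABERRATION_TYPES) df[[ty]][i] <- df[[ty]][i] - 1L
          }
        }
        seen <- c(seen, sigs[!dup])
        df$signatures[i] <- paste(sigs[!dup], collapse = ";")
      }
      df
    }) %>%
    ungroup()
}

#' Per-type aberration frequencies for one patient x time point
#'
#' Mean aberrations per cell (events/cell): clonality-corrected per-type
#' totals divided by the number of cells scored.
#'
#' @param cells Tibble of cells for one patient x time point (>= 1 cell),
#'   already clonality-corrected.
#' @return One-row tibble with a frequency per type and `n_cells`.
#' @export
aberration_frequencies <- function(cells) {
  if (nrow(cells) == 0) abort("degenerate input: zero cells")
  out <- as_tibble(lapply(cells[ABERRATION_TYPES], function(v) sum(v) / nrow(cells)))
  out$n_cells <- nrow(cells)
  out
}

#' Aberration-frequency table for a cohort
#'
#' Applies [clonality_correct()] then [aberration_frequencies()] per
#' patient x time point.
#'
#' @param cells Tibble from [parse_score_sheet()].
#' @param correct_clonality Apply clonality correction first (default TRUE).
#' @return Tibble with one row per patient x time point.
#' @export
aberration_frequency_table <- function(cells, correct_clonality = TRUE) {
  if (correct_clonality) cells <- clonality_correct(cells)
  cells %>%
    group_by(.data$patient_id, .data$timepoint) %>%
    group_modify(~ aberration_frequencies(.x)) %>%
    ungroup()
}

#' Per-cell aberration index
#'
#' Sum of all scored aberration types per cell excluding sister chromatid
#' exchanges: inversions + translocations + dicentrics + fragments.
#'
#' @param cells Tibble of aberration cells.
#' @return Integer vector, one index per cell.
#' @export
aberration_index <- function(cells) {
  as.integer(cells$inversions + cells$translocations + cells$dicentrics + cells$fragments)
}

#' Build the per-cell chromosome-aberration ML dataset
#'
#' One row per pre-therapy cell: the cell's count for the modelled
#' aberration type (or all four non-SCE counts with `joint_features`), the
#' sample-of-origin label (0 = non-irradiated, 1 = 4 Gy in vitro), and the
#' patient's 3-month mean frequency of that type as target. With 14
#' patients x 2 pre-therapy samples x 30 cells this yields 840 rows,
#' splitting 672/168 under the stratified 80/20 machinery shared with the
#' telomere models.
#'
#' @param cells Clonality-corrected cell table (all time points; the two
#'   pre-therapy time points are selected here).
#' @param targets Tibble `patient_id`, `target` (3-month mean frequency of
#'   the modelled type).
#' @param type Modelled aberration type, one of `"inversions"`,
#'   `"translocations"`, `"dicentrics"`, `"fragments"`, `"sce"`, or
#'   `"aberration_index"`.
#' @param joint_features Use all four non-SCE counts as features instead of
#'   the single modelled type's count.
#' @return Tibble of ML rows with attribute `"feature_cols"` naming the
#'   feature columns for [fit_boosted_regressor()].
#' @export
build_cell_dataset <- function(cells, targets, type = "inversions",
                               joint_features = FALSE) {
  if (!type %in% c(ABERRATION_TYPES, "aberration_index")) {
    abort("unknown aberration type")
  }
  pre <- cells %>%
    filter(.data$timepoint %in% c("baseline_nonirr", "baseline_4gy"))
  have_both <- pre %>%
    distinct(.data$patient_id, .data$timepoint) %>%
    dplyr::count(.data$patient_id) %>%
    filter(.data$n == 2) %>%
    pull(.data$patient_id)
  eligible <- intersect(have_both, targets$patient_id[!is.na(targets$target)])
  dropped <- setdiff(unique(pre$patient_id), eligible)
  if (length(dropped) > 0) {
    warn(paste0("excluding patient(s) without both pre-therapy CA samples and a target: ",
                paste(dropped, collapse = ", ")))
  }
  pre <- pre %>% filter(.data$patient_id %in% eligible)
  if (type == "aberration_index") pre$aberration_index <- aberration_index(pre)
  rows <- pre %>%
    mutate(origin_label = as.integer(.data$timepoint == "baseline_4gy")) %>%
    left_join(targets, by = "patient_id")
  feature_cols <- if (joint_features) {
    c(setdiff(ABERRATION_TYPES, "sce"), "origin_label")
  } else {
    c(type, "origin_label")
  }
  rows <- rows[, unique(c("patient_id", feature_cols, "target"))]
  attr(rows, "feature_cols") <- feature_cols
  rows
}
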