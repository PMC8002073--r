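make_cells <- function() {
  tibble::tibble(
    patient_id = 1L,
    timepoint = "baseline_nonirr",
    cell_id = 1:3,
    inversions = c(1L, 0L, 1L),
    translocations = c(1L, 1L, 0L),
    dicentrics = c(0L, 1L, 0L),
    fragments = c(0L, 0L, 2L),
    sce = c(3L, 0L, 1L),
    signatures = c(
      "inversions:inv-a;translocations:t(1;3)a;sce:s1;sce:s2;sce:s3",
      "translocations:t(1;3)a;dicentrics:dic-a",
      "inversions:inv-b;fragments:fr-a;fragments:fr-b;sce:s4"
    )
  )
}

test_that("score sheets round-trip through CSV and reject malformed input", {
  cells <- make_cells()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cells, path)
  back <- parse_score_sheet(path)
  expect_equal(as.data.frame(back), as.data.frame(cells))

  # 30 rows for one patient x time point -> 30 cells
  coh <- generate_cohort(cohort_config(seed = 3))
  one <- dplyr::filter(coh$ca_cells, patient_id == 1, timepoint == "baseline_4gy")
  expect_equal(nrow(parse_score_sheet(one)), 30)

  expect_equal(nrow(parse_score_sheet(cells[0, ])), 0)
  expect_error(parse_score_sheet(dplyr::select(cells, -inversions)), "schema error")
  bad <- cells
  bad$dicentrics[2] <- -1L
  expect_error(parse_score_sheet(bad), "value error.*row\\(s\\) 2")
  # score-sheet time-point aliases normalise to canonical codes
  alias <- cells
  alias$timepoint <- "1 non irrad"
  expect_equal(parse_score_sheet(alias)$timepoint, rep("baseline_nonirr", 3))
})

test_that("clonality correction scores identical aberrations once", {
  cells <- make_cells()
  corrected <- clonality_correct(cells)
  # the shared translocation signature is kept only in the first cell
  expect_equal(corrected$translocations, c(1L, 0L, 0L))
  # everything else untouched
  expect_equal(corrected$inversions, cells$inversions)
  expect_equal(corrected$fragments, cells$fragments)
  expect_equal(corrected$sce, cells$sce)

  # monotone non-increasing, idempotent, identity without duplicates
  types <- c("inversions", "translocations", "dicentrics", "fragments", "sce")
  expect_true(all(as.matrix(corrected[types]) <= as.matrix(cells[types])))
  expect_equal(clonality_correct(corrected), corrected)
  nodup <- cells[3, ]
  expect_equal(clonality_correct(nodup), nodup)

  expect_warning(out <- clonality_correct(dplyr::mutate(cells, signatures = NA_character_)),
                 "skipped")
  expect_equal(out$translocations, cells$translocations)

  # duplicates are only collapsed within a patient x time point
  two_tp <- dplyr::bind_rows(cells, dplyr::mutate(cells, timepoint = "baseline_4gy"))
  ct <- clonality_correct(two_tp)
  expect_equal(sum(ct$translocations), 2L)
})

test_that("aberration frequencies are corrected totals per cell", {
  cells <- make_cells()
  freq <- aberration_frequencies(cells)
  expect_equal(freq$inversions, 2 / 3)
  expect_equal(freq$n_cells, 3)
  zero <- dplyr::mutate(cells, dplyr::across(inversions:sce, ~ 0L))
  expect_true(all(aberration_frequencies(zero)[1:5] == 0))
  expect_error(aberration_frequencies(cells[0, ]), "zero cells")

  # 30 cells holding 6 inversions in total -> 0.2 inversions per cell
  thirty <- tibble::tibble(
    patient_id = 1L, timepoint = "post_imrt", cell_id = 1:30,
    inversions = c(rep(2L, 3), rep(0L, 27)), translocations = 0L,
    dicentrics = 0L, fragments = 0L, sce = 0L, signatures = NA_character_
  )
  expect_equal(aberration_frequencies(thirty)$inversions, 0.2)

  # frequencies on Poisson-simulated cells recover the generative rates
  rates <- c(inversions = 0.3, translocations = 0.15, dicentrics = 0.1,
             fragments = 0.12, sce = 0.1)
  sim <- generate_aberration_cells(1, "baseline_4gy", rates,
                                   clonal_fraction = 0, n_cells = 200, seed = 8)
  f <- aberration_frequencies(sim)
  for (ty in names(rates)) {
    expect_lt(abs(f[[ty]] - rates[[ty]]), 3 * sqrt(rates[[ty]] / 200))
  }
})

test_that("the aberration index sums the four non-SCE types", {
  only_sce <- tibble::tibble(inversions = 0L, translocations = 0L,
                             dicentrics = 0L, fragments = 0L, sce = 3L)
  expect_equal(aberration_index(only_sce), 0L)
  one_each <- tibble::tibble(inversions = 1L, translocations = 1L,
                             dicentrics = 1L, fragments = 1L, sce = 5L)
  expect_equal(aberration_index(one_each), 4L)
  expect_equal(aberration_index(dplyr::mutate(one_each, dplyr::across(dplyr::everything(), ~ 0L))), 0L)
  # additivity: the index of merged counts is the sum of indices
  a <- make_cells()[1, ]
  b <- make_cells()[3, ]
  merged <- a
  for (ty in c("inversions", "translocations", "dicentrics", "fragments", "sce")) {
    merged[[ty]] <- a[[ty]] + b[[ty]]
  }
  expect_equal(aberration_index(merged), aberration_index(a) + aberration_index(b))
})

test_that("the per-cell ML dataset mirrors the telomere reshaping", {
  coh <- generate_cohort(small_config(seed = 6))
  cells <- clonality_correct(coh$ca_cells)
  freq <- aberration_frequency_table(coh$ca_cells)
  targets <- dplyr::transmute(
    dplyr::filter(freq, timepoint == "three_month_post"),
    patient_id, target = inversions)
  expect_warning(rows <- build_cell_dataset(cells, targets, "inversions"),
                 "excluding patient")
  expect_equal(nrow(rows), 5 * 2 * 10)  # 5 complete patients x 2 samples x 10 cells
  expect_equal(sort(unique(rows$origin_label)), 0:1)
  expect_equal(attr(rows, "feature_cols"), c("inversions", "origin_label"))

  joint <- suppressWarnings(build_cell_dataset(cells, targets, "inversions",
                                               joint_features = TRUE))
  expect_equal(attr(joint, "feature_cols"),
               c("inversions", "translocations", "dicentrics", "fragments", "origin_label"))
  expect_false("sce" %in% attr(joint, "feature_cols"))

  idx <- suppressWarnings(build_cell_dataset(cells, targets, "aberration_index"))
  expect_true("aberration_index" %in% names(idx))
  expect_error(build_cell_dataset(cells, targets, "nonsense"), "unknown")
})
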