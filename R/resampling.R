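#' Default decade age bins for balanced resampling
#'
#' Bin edges 18, 30, 40, ..., 90, 100; intervals are left-closed.
#' @return Numeric vector of bin edges.
#' @export
age_decade_bins <- function() c(18, 30, 40, 50, 60, 70, 80, 90, 100)

#' Demographically balanced test set by resampling with replacement
#'
#' Constructs an evaluation set in which racial imbalance, age differences
#' and subgroup-dependent disease prevalence cannot drive subgroup metric
#' differences: rows are drawn with replacement, `n_per_cell` from every
#' (group x label-status x age-bin) stratum, so by construction every group
#' has equal frequency, 0.5 prevalence of the audited label, and the same
#' age-bin profile.
#'
#' @param cohort A cohort table (typically its test split).
#' @param label Name of the binary label column being audited.
#' @param age_bins Bin edges for age stratification (default decade bins
#'   [age_decade_bins()]).
#' @param n_per_cell Draws per stratum; `NULL` picks the value that makes the
#'   balanced set roughly the size of `cohort`.
#' @param seed Integer seed.
#' @return An object of class `balanced_index`: a tibble with columns `row`
#'   (index into `cohort`, repetition allowed), `group`, `label_status`,
#'   `age_bin`; attributes record `label`, `n_per_cell` and `seed`.
#' @examples
#' cfg <- synthetic_config(n_patients = 4000, group_proportions = rep(1/3, 3),
#'                         prevalence = rep(0.3, 4), seed = 5)
#' cohort <- generate_cohort(cfg)
#' bal <- balance_test_set(cohort, "cardiomegaly",
#'                         age_bins = c(18, 50, 65, 80, 100), n_per_cell = 50)
#' table(bal$group, bal$label_status)
#' @export
balance_test_set <- function(cohort, label, age_bins = age_decade_bins(),
                             n_per_cell = NULL, seed = 1L) {
  validate_cohort(cohort, label)
  if (length(age_bins) < 2 || is.unsorted(age_bins, strictly = TRUE)) {
    abort("`age_bins` must be strictly increasing edges.")
  }
  if (any(cohort$age < age_bins[1] | cohort$age > age_bins[length(age_bins)])) {
    abort("ages fall outside the bin edges.")
  }
  bin <- cut(cohort$age, breaks = age_bins, right = FALSE, include.lowest = TRUE)
  strata <- tibble::tibble(
    row = seq_len(nrow(cohort)),
    group = cohort$group,
    label_status = cohort[[label]],
    age_bin = as.character(bin)
  )
  cells <- tidyr::expand_grid(
    group = sort(unique(strata$group)),
    label_status = c(0L, 1L),
    age_bin = levels(bin)
  )
  by_cell <- dplyr::left_join(
    cells,
    dplyr::group_by(strata, .data$group, .data$label_status, .data$age_bin) |>
      dplyr::summarise(rows = list(.data$row), .groups = "drop"),
    by = c("group", "label_status", "age_bin")
  )
  empty <- purrr::map_lgl(by_cell$rows, is.null)
  if (any(empty)) {
    bad <- by_cell[empty, ]
    abort(paste0(
      "empty strata; cannot balance. Missing (group, ", label, ", age bin): ",
      paste(sprintf("(%s, %d, %s)", bad$group, bad$label_status, bad$age_bin),
            collapse = "; ")
    ))
  }
  if (is.null(n_per_cell)) {
    n_per_cell <- max(1L, round(nrow(cohort) / nrow(by_cell)))
  }
  out <- local_seed(seed, 505L, {
    drawn <- purrr::pmap(by_cell, function(group, label_status, age_bin, rows) {
      tibble::tibble(
        row = sample(rows, n_per_cell, replace = TRUE),
        group = group, label_status = label_status, age_bin = age_bin
      )
    })
    dplyr::bind_rows(drawn)
  })
  attr(out, "label") <- label
  attr(out, "n_per_cell") <- as.integer(n_per_cell)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("balanced_index", class(out))
  out
}

#' One scan per patient
#'
#' Sensitivity-analysis subsample removing within-patient clustering: selects
#' exactly one row per distinct patient, uniformly at random, deterministic
#' given the seed.
#'
#' @param cohort A cohort table.
#' @param seed Integer seed.
#' @return A tibble with columns `row` and `patient_id`, one row per patient,
#'   ordered by first appearance.
#' @export
one_scan_per_patient <- function(cohort, seed = 1L) {
  validate_cohort(cohort)
  local_seed(seed, 606L, {
    picks <- tapply(seq_len(nrow(cohort)), cohort$patient_id, function(rows) {
      if (length(rows) == 1) rows else sample(rows, 1)
    })
    rows <- sort(unname(unlist(picks)))
    tibble::tibble(row = rows, patient_id = cohort$patient_id[rows])
  })
}
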