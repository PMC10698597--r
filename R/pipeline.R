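# End-to-end orchestration: simulate -> inspect -> performance audit, with
# file outputs and a provenance manifest. These functions are the package's
# "subcommands"; each is deterministic given its config and reproduces its
# outputs byte-identically on re-run.

config_hash <- function(config) rlang::hash(config)

write_output_csv <- function(df, path, hash, seed) {
  # provenance header as a comment line; read back with comment = "#"
  readr::write_lines(sprintf("# config_hash: %s seed: %d", hash, seed), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir, entries) {
  path <- file.path(out_dir, "manifest.json")
  existing <- if (file.exists(path)) jsonlite::read_json(path) else list()
  jsonlite::write_json(utils::modifyList(existing, entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a synthetic audit input set to disk
#'
#' Generates a cohort table and embedding matrix from a [synthetic_config()]
#' and writes them, together with the full generating configuration (the
#' ground-truth manifest), into `out_dir`. Re-running with the same config
#' reproduces the files byte-identically.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
audit_simulate <- function(config, out_dir) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created by synthetic_config().")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  emb <- generate_embeddings(cohort, config)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    embeddings = file.path(out_dir, "embeddings.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_cohort(cohort, paths$cohort)
  write_embeddings(emb, paths$embeddings)
  write_synthetic_config(config, paths$ground_truth)
  write_manifest(out_dir, list(simulate = list(
    config_hash = config_hash(config), seed = config$seed,
    n_patients = config$n_patients, n_scans = nrow(cohort),
    files = unlist(lapply(paths, basename), use.names = FALSE)
  )))
  invisible(paths)
}

#' Run the shift inspection and write its report
#'
#' Reads (or is given) a cohort and embeddings, restricts to the test split,
#' runs [run_shift_audit()], and writes the per-test report
#' (`shift_tests.csv`: comparison, mode, KS D, raw and adjusted p-values,
#' significance), the per-characteristic significance tally
#' (`shift_summary.csv`) and the per-mode explained-variance ratios
#' (`explained_variance.csv`).
#'
#' @param cohort A cohort table, or path to a cohort CSV.
#' @param embeddings An embedding matrix, or path to an embeddings CSV.
#' @param out_dir Output directory (created if missing).
#' @param config An [audit_config()].
#' @param comparisons Comparisons tibble; `NULL` for the default set.
#' @param split Which split to inspect (default `"test"`; `NULL` for all rows).
#' @return The `shift_audit` object, invisibly.
#' @export
audit_inspect <- function(cohort, embeddings, out_dir, config = audit_config(),
                          comparisons = NULL, split = "test") {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(embeddings)) embeddings <- read_embeddings(embeddings)
  check_alignment(embeddings, cohort)
  if (!is.null(split)) {
    sel <- cohort$split == split
    cohort <- cohort[sel, ]
    embeddings <- embeddings[sel, , drop = FALSE]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  audit <- run_shift_audit(embeddings, cohort, comparisons, config)
  hash <- config_hash(list(config = config, comparisons = comparisons, split = split))
  write_output_csv(tidy(audit), file.path(out_dir, "shift_tests.csv"),
                   hash, config$seed)
  write_output_csv(audit$tally, file.path(out_dir, "shift_summary.csv"),
                   hash, config$seed)
  write_output_csv(
    tibble::tibble(mode = seq_along(audit$ev_ratio_all),
                   ev_ratio = audit$ev_ratio_all,
                   cumulative = cumsum(audit$ev_ratio_all)),
    file.path(out_dir, "explained_variance.csv"), hash, config$seed
  )
  write_manifest(out_dir, list(inspect = list(
    config_hash = hash, seed = config$seed,
    n_tests = nrow(audit$results), n_significant = sum(audit$results$significant),
    adjustment = audit$adjustment,
    files = c("shift_tests.csv", "shift_summary.csv", "explained_variance.csv")
  )))
  invisible(audit)
}

#' Run the subgroup performance audit and write its reports
#'
#' The full downstream pipeline: train classification heads of the requested
#' capacities on the frozen embeddings of the training split (validation split
#' for model selection); for each head and each label, build a
#' demographically balanced test set by stratified resampling with
#' replacement, calibrate the decision threshold to the target pooled FPR,
#' compute per-subgroup TPR/FPR/Youden-J/AUC with patient-level bootstrap
#' CIs, and the relative change of Youden J against the subgroup mean,
#' separately for the sex and race panels. One performance CSV is written per
#' (head, label), plus one disparity CSV per (head, label, characteristic).
#'
#' @param cohort A cohort table, or path to a cohort CSV.
#' @param embeddings An embedding matrix, or path to an embeddings CSV.
#' @param out_dir Output directory.
#' @param labels Label columns to audit (default: all of them).
#' @param heads Head names to train (default all three capacities).
#' @param hidden_width Hidden width for the MLP heads (default 64 here; the
#'   audit is about disparities, not capacity maximization).
#' @param target_fpr Pooled FPR target (default 0.20).
#' @param age_bins Age stratification edges for balancing.
#' @param n_per_cell Draws per balancing stratum (`NULL`: auto).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param epochs Training epochs per head (default 200).
#' @param seed Integer seed for the whole subcommand.
#' @return Invisibly, a list with elements `performance` (tibble over all
#'   heads/labels/characteristics) and `disparity` (tibble of relative
#'   changes).
#' @export
audit_performance <- function(cohort, embeddings, out_dir,
                              labels = NULL,
                              heads = c("linear", "mlp3", "mlp5"),
                              hidden_width = 64L,
                              target_fpr = 0.20,
                              age_bins = age_decade_bins(),
                              n_per_cell = NULL,
                              n_boot = 2000L,
                              epochs = 200L,
                              seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(embeddings)) embeddings <- read_embeddings(embeddings)
  check_alignment(embeddings, cohort)
  labels <- labels %||% cohort_labels(cohort)
  validate_cohort(cohort, labels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(list(labels = labels, heads = heads, hidden_width = hidden_width,
                           target_fpr = target_fpr, age_bins = age_bins,
                           n_per_cell = n_per_cell, n_boot = n_boot,
                           epochs = epochs, seed = seed))

  tr <- cohort$split == "train"
  va <- cohort$split == "validation"
  te <- cohort$split == "test"
  if (!any(tr) || !any(va) || !any(te)) {
    abort("cohort must contain train, validation and test rows.")
  }
  y_tr <- as.matrix(cohort[tr, labels])
  y_va <- as.matrix(cohort[va, labels])
  test_cohort <- cohort[te, ]
  test_emb <- embeddings[te, , drop = FALSE]

  perf_all <- list()
  disp_all <- list()
  for (head_name in heads) {
    spec <- head_spec(head_name, n_labels = length(labels),
                      hidden_width = hidden_width)
    fit <- train_head(embeddings[tr, , drop = FALSE], y_tr,
                      embeddings[va, , drop = FALSE], y_va,
                      spec, seed = seed, epochs = epochs)
    probs <- predict(fit, test_emb)
    for (label in labels) {
      bal <- balance_test_set(test_cohort, label, age_bins = age_bins,
                              n_per_cell = n_per_cell, seed = seed)
      rows <- bal$row
      sc <- probs[rows, label]
      yy <- test_cohort[[label]][rows]
      pid <- test_cohort$patient_id[rows]
      op <- calibrate_threshold(sc[yy == 0], target_fpr = target_fpr, label = label)
      for (characteristic in c("sex", "race")) {
        grp <- if (characteristic == "sex") test_cohort$sex[rows] else test_cohort$group[rows]
        perf <- subgroup_metrics_ci(sc, yy, grp, op, patient_id = pid,
                                    n_boot = n_boot, seed = seed)
        perf <- dplyr::mutate(perf, head = head_name, label = label,
                              characteristic = characteristic,
                              threshold = op$threshold,
                              achieved_fpr = op$achieved_fpr,
                              .before = 1)
        perf_all[[length(perf_all) + 1L]] <- perf
        disp <- relative_change(perf)
        disp_all[[length(disp_all) + 1L]] <- dplyr::mutate(
          disp, head = head_name, label = label,
          characteristic = characteristic, .before = 1)
      }
      one_head_label <- dplyr::bind_rows(utils::tail(perf_all, 2))
      write_output_csv(one_head_label,
                       file.path(out_dir, sprintf("performance_%s_%s.csv", head_name, label)),
                       hash, seed)
    }
  }
  performance <- dplyr::bind_rows(perf_all)
  disparity <- dplyr::bind_rows(disp_all)
  write_output_csv(disparity, file.path(out_dir, "disparity.csv"), hash, seed)
  write_manifest(out_dir, list(performance = list(
    config_hash = hash, seed = seed, heads = heads, labels = labels,
    target_fpr = target_fpr, n_boot = n_boot,
    files = c(sprintf("performance_%s_%s.csv",
                      rep(heads, each = length(labels)), labels), "disparity.csv")
  )))
  invisible(list(performance = performance, disparity = disparity))
}
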