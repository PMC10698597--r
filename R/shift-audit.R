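#' Balanced patient-level subsample of a cohort
#'
#' Draws the same number of patients from every group (the paper-style
#' "1000 per racial group" subsample) and selects one scan per drawn patient,
#' so the downstream shift tests are not driven by group imbalance or
#' within-patient clustering. Sampling is without replacement when a group has
#' enough patients, otherwise with replacement (flagged per group in the
#' `with_replacement` attribute).
#'
#' @param cohort A cohort table.
#' @param per_group_n Number of patients to draw from each group.
#' @param seed Integer seed.
#' @param group_col Column defining the groups (default `"group"`).
#' @return A tibble with columns `row` (row index into `cohort`),
#'   `patient_id` and `group`; attribute `with_replacement` is a named logical
#'   per group.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 300, seed = 1))
#' idx <- balanced_subsample(cohort, per_group_n = 20, seed = 1)
#' table(idx$group)
#' @export
balanced_subsample <- function(cohort, per_group_n, seed = 1L, group_col = "group") {
  validate_cohort(cohort)
  if (per_group_n < 0) abort("`per_group_n` must be non-negative.")
  groups <- sort(unique(cohort[[group_col]]))
  if (length(groups) == 0 || any(is.na(groups))) abort("no groups found in cohort.")
  local_seed(seed, 303L, {
    flagged <- stats::setNames(logical(length(groups)), groups)
    picked <- purrr::map(groups, function(g) {
      rows_g <- which(cohort[[group_col]] == g)
      if (length(rows_g) == 0) abort(sprintf("group `%s` is empty.", g))
      patients <- unique(cohort$patient_id[rows_g])
      replace <- length(patients) < per_group_n
      flagged[[g]] <<- replace
      if (per_group_n == 0) return(integer(0))
      chosen <- sample(patients, per_group_n, replace = replace)
      # one scan per drawn patient, uniformly at random
      vapply(chosen, function(p) {
        scans <- rows_g[cohort$patient_id[rows_g] == p]
        if (length(scans) == 1) scans else sample(scans, 1)
      }, integer(1), USE.NAMES = FALSE)
    })
    rows <- unlist(picked)
    out <- tibble::tibble(
      row = rows,
      patient_id = cohort$patient_id[rows],
      group = cohort[[group_col]][rows]
    )
    attr(out, "with_replacement") <- flagged
    out
  })
}

#' Default pairwise subgroup comparisons for a shift audit
#'
#' Builds the audit's comparison list: presence-of-disease contrasts (the
#' reference label, normally "no finding", against each other condition
#' label), the biologic-sex pair, and all pairwise racial-group contrasts.
#'
#' @param cohort A cohort table.
#' @param characteristics Which characteristics to include.
#' @param disease_reference Reference label for disease contrasts.
#' @return A tibble with columns `characteristic`, `a`, `b`.
#' @export
shift_comparisons <- function(cohort,
                              characteristics = c("disease", "sex", "race"),
                              disease_reference = "no_finding") {
  validate_cohort(cohort)
  out <- list()
  if ("disease" %in% characteristics) {
    labels <- cohort_labels(cohort)
    others <- setdiff(labels, disease_reference)
    if (disease_reference %in% labels && length(others) > 0) {
      out$disease <- tibble::tibble(characteristic = "disease",
                                    a = disease_reference, b = others)
    }
  }
  if ("sex" %in% characteristics) {
    sexes <- sort(unique(cohort$sex))
    if (length(sexes) == 2) {
      out$sex <- tibble::tibble(characteristic = "sex", a = sexes[1], b = sexes[2])
    }
  }
  if ("race" %in% characteristics) {
    groups <- sort(unique(cohort$group))
    if (length(groups) >= 2) {
      pairs <- utils::combn(groups, 2)
      out$race <- tibble::tibble(characteristic = "race",
                                 a = pairs[1, ], b = pairs[2, ])
    }
  }
  dplyr::bind_rows(out)
}

#' Audit configuration for feature-space shift detection
#'
#' @param n_modes Number of leading PCA modes tested (default 4).
#' @param alpha Significance level after adjustment (default 0.05).
#' @param per_group_subsample Patients drawn per group before testing
#'   (default 1000).
#' @param tsne_variance Cumulative explained-variance fraction the t-SNE input
#'   must retain (default 0.99).
#' @param seed Integer seed.
#' @return An object of class `audit_config`.
#' @export
audit_config <- function(n_modes = 4L, alpha = 0.05, per_group_subsample = 1000L,
                         tsne_variance = 0.99, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (tsne_variance <= 0 || tsne_variance > 1) {
    abort("`tsne_variance` must lie in (0, 1].")
  }
  if (n_modes < 1) abort("`n_modes` must be >= 1.")
  structure(list(
    n_modes = as.integer(n_modes), alpha = alpha,
    per_group_subsample = as.integer(per_group_subsample),
    tsne_variance = tsne_variance, seed = as.integer(seed)
  ), class = "audit_config")
}

# Row indices of the two sides of one subgroup comparison, within `rows`.
# Disease contrasts compare scans positive for exactly one of the two labels.
comparison_sides <- function(cohort, rows, characteristic, a, b) {
  sub <- cohort[rows, ]
  if (characteristic == "sex") {
    if (!all(c(a, b) %in% sub$sex)) abort(sprintf("unknown sex level in `%s` vs `%s`.", a, b))
    list(a = which(sub$sex == a), b = which(sub$sex == b))
  } else if (characteristic %in% c("race", "group")) {
    if (!all(c(a, b) %in% sub$group)) abort(sprintf("unknown group in `%s` vs `%s`.", a, b))
    list(a = which(sub$group == a), b = which(sub$group == b))
  } else if (characteristic == "disease") {
    if (!all(c(a, b) %in% names(sub))) {
      abort(sprintf("unknown label column in `%s` vs `%s`.", a, b))
    }
    list(a = which(sub[[a]] == 1 & sub[[b]] == 0),
         b = which(sub[[b]] == 1 & sub[[a]] == 0))
  } else {
    abort(sprintf("unknown characteristic `%s`.", characteristic))
  }
}

#' Run the feature-space subgroup shift audit
#'
#' The full inspection pipeline: draw a balanced patient subsample (equal
#' patients per racial group, one scan each), project its embeddings onto the
#' leading PCA modes, and for every requested subgroup comparison and every
#' tested mode run a two-sample Kolmogorov-Smirnov test on the marginal
#' projections. All p-values of the report form one family and are jointly
#' adjusted by the Benjamini-Yekutieli procedure (the most conservative
#' reading of a single multiple-testing family); a comparison is significant
#' when its adjusted p-value falls below `alpha`. The report also carries the
#' per-mode explained-variance ratios and a per-characteristic tally of
#' significant tests.
#'
#' @param embeddings Numeric matrix, rows aligned to `cohort`.
#' @param cohort A cohort table.
#' @param comparisons Tibble of comparisons (`characteristic`, `a`, `b`) as
#'   built by [shift_comparisons()]; `NULL` for the default set.
#' @param config An [audit_config()].
#' @return An object of class `shift_audit` carrying the per-test results
#'   (see [tidy.shift_audit()]), the explained-variance ratios, the
#'   significance tally, and the subsample used.
#' @examples
#' cfg <- synthetic_config(n_patients = 400, seed = 3)
#' cohort <- generate_cohort(cfg)
#' emb <- generate_embeddings(cohort, cfg)
#' audit <- run_shift_audit(emb, cohort,
#'   config = audit_config(per_group_subsample = 25, seed = 3))
#' tidy(audit)
#' @export
run_shift_audit <- function(embeddings, cohort, comparisons = NULL,
                            config = audit_config()) {
  check_alignment(embeddings, cohort)
  validate_cohort(cohort)
  if (is.null(comparisons)) comparisons <- shift_comparisons(cohort)
  if (nrow(comparisons) > 0) {
    # fail early on unknown subgroup labels (full cohort, pre-subsample)
    purrr::pwalk(comparisons, function(characteristic, a, b) {
      comparison_sides(cohort, seq_len(nrow(cohort)), characteristic, a, b)
    })
  }

  sub <- balanced_subsample(cohort, config$per_group_subsample, seed = config$seed)
  pca <- fit_pca(embeddings[sub$row, , drop = FALSE], n_modes = config$n_modes)

  results <- if (nrow(comparisons) == 0) {
    tibble::tibble(characteristic = character(), comparison = character(),
                   a = character(), b = character(), mode = integer(),
                   ks_statistic = numeric(), p_raw = numeric(),
                   p_adjusted = numeric(), significant = logical())
  } else {
    rows <- purrr::pmap(comparisons, function(characteristic, a, b) {
      sides <- comparison_sides(cohort, sub$row, characteristic, a, b)
      if (length(sides$a) == 0 || length(sides$b) == 0) {
        abort(sprintf("comparison `%s` vs `%s`: a side is empty in the subsample.", a, b))
      }
      purrr::map_dfr(seq_len(config$n_modes), function(m) {
        ks <- ks_two_sample(pca$coordinates[sides$a, m], pca$coordinates[sides$b, m])
        tibble::tibble(characteristic = characteristic,
                       comparison = paste(a, "vs", b), a = a, b = b,
                       mode = m, ks_statistic = ks$statistic, p_raw = ks$p_value)
      })
    })
    res <- dplyr::bind_rows(rows)
    res$p_adjusted <- adjust_benjamini_yekutieli(res$p_raw)
    res$significant <- res$p_adjusted < config$alpha
    res
  }

  tally <- results |>
    dplyr::group_by(.data$characteristic) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     n_significant = sum(.data$significant), .groups = "drop")

  structure(list(
    results = results,
    ev_ratio = pca$ev_ratio,
    ev_ratio_all = pca$ev_ratio_all,
    tally = tally,
    config = config,
    subsample = sub,
    adjustment = "benjamini-yekutieli, single family over all comparisons x modes",
    pca = pca
  ), class = "shift_audit")
}

#' @export
print.shift_audit <- function(x, ...) {
  cat(sprintf("<shift_audit> %d tests (%d comparisons x %d modes), alpha = %g\n",
              nrow(x$results), nrow(x$results) / max(1, x$config$n_modes),
              x$config$n_modes, x$config$alpha))
  cat(sprintf("  significant after BY adjustment: %d of %d\n",
              sum(x$results$significant), nrow(x$results)))
  cat(sprintf("  first %d modes explain %.1f%% of variance\n",
              x$config$n_modes, 100 * sum(x$ev_ratio)))
  invisible(x)
}

#' Tidiers for shift-audit reports
#'
#' `tidy()` returns one row per (comparison, mode) test with the KS statistic
#' and raw/adjusted p-values; `glance()` a one-row summary including the
#' significance tally and the cumulative explained variance of the tested
#' modes.
#'
#' @param x A `shift_audit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy shift_audit
#' @export
tidy.shift_audit <- function(x, ...) {
  dplyr::select(x$results, "characteristic", "comparison", "mode",
                "ks_statistic", "p_raw", "p_adjusted", "significant")
}

#' @rdname tidy.shift_audit
#' @method glance shift_audit
#' @export
glance.shift_audit <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$results),
    n_significant = sum(x$results$significant),
    alpha = x$config$alpha,
    n_modes = x$config$n_modes,
    var_explained_tested = sum(x$ev_ratio),
    adjustment = x$adjustment
  )
}

#' @describeIn tidy.shift_audit Tile plot of KS statistics by comparison and
#'   mode, significance outlined.
#' @param object A `shift_audit` object.
#' @method autoplot shift_audit
#' @export
autoplot.shift_audit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$mode), y = .data$comparison)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$ks_statistic), colour = "white") +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        shape = 8, size = 2, colour = "black") +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$characteristic),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "PCA mode", y = NULL, fill = "KS D",
                  title = "Subgroup shift audit (* = significant after BY)") +
    ggplot2::theme_minimal()
}

#' Normalized marginal densities by subgroup
#'
#' Kernel density estimates of a projected coordinate for each subgroup,
#' evaluated on a common grid and renormalized independently so each curve
#' integrates to 1 — removing differences in subgroup base rates, as in the
#' audit's marginal-distribution panels.
#'
#' @param data Data frame with the value and subgroup columns.
#' @param value,subgroup Column names (strings).
#' @param n_grid Grid resolution (default 512).
#' @return A tibble with columns `subgroup`, `x`, `density`; each subgroup's
#'   density integrates to 1 over the grid (trapezoid rule) within 1e-3.
#' @examples
#' df <- data.frame(v = rnorm(500), g = rep(c("a", "b"), 250))
#' m <- normalized_marginals(df, "v", "g")
#' @export
normalized_marginals <- function(data, value = "value", subgroup = "subgroup",
                                 n_grid = 512) {
  v <- data[[value]]
  g <- data[[subgroup]]
  if (is.null(v) || is.null(g)) abort("value/subgroup columns not found.")
  counts <- table(g)
  if (any(counts < 2)) {
    abort(sprintf("subgroup(s) with fewer than 2 values: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  pad <- 0.1 * diff(range(v))
  grid <- seq(min(v) - pad, max(v) + pad, length.out = n_grid)
  purrr::map_dfr(sort(unique(g)), function(gg) {
    d <- density(v[g == gg], from = grid[1], to = grid[n_grid], n = n_grid)
    dens <- d$y
    # renormalize on the common grid (trapezoid)
    area <- sum((dens[-1] + dens[-n_grid]) / 2 * diff(grid))
    tibble::tibble(subgroup = gg, x = grid, density = dens / area)
  })
}

#' Plot normalized marginal densities
#'
#' @param marginals Output of [normalized_marginals()].
#' @return A ggplot.
#' @export
plot_marginals <- function(marginals) {
  ggplot2::ggplot(marginals,
                  ggplot2::aes(x = .data$x, y = .data$density,
                               colour = .data$subgroup, fill = .data$subgroup)) +
    ggplot2::geom_area(alpha = 0.25, position = "identity") +
    ggplot2::labs(x = "Projected coordinate", y = "Normalized density") +
    ggplot2::theme_minimal()
}
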