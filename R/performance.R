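#' Calibrate a decision threshold to a pooled false-positive rate
#'
#' Picks the decision threshold on the whole evaluation sample (never per
#' subgroup) so that the pooled false-positive rate meets a target, 0.20 by
#' default. Predictions are positive when `score > threshold`; the threshold
#' is the smallest value whose FPR does not exceed the target, so
#' `achieved_fpr <= target_fpr` always, and for continuous scores
#' `|achieved - target| <= 1/n_neg`.
#'
#' @param negative_scores Scores of the label-negative rows of the pooled
#'   sample.
#' @param target_fpr Target pooled false-positive rate (default 0.20).
#' @param label Optional label name carried into the result.
#' @return An object of class `operating_point` with fields `label`,
#'   `threshold`, `target_fpr`, `achieved_fpr`, `n_neg`.
#' @examples
#' op <- calibrate_threshold(seq(0.1, 1, by = 0.1), target_fpr = 0.2)
#' op$achieved_fpr
#' @export
calibrate_threshold <- function(negative_scores, target_fpr = 0.20, label = NULL) {
  if (length(negative_scores) == 0) abort("no negative scores: threshold undefined.")
  if (any(!is.finite(negative_scores))) abort("scores must be finite.")
  if (target_fpr < 0 || target_fpr > 1) abort("`target_fpr` must lie in [0, 1].")
  n <- length(negative_scores)
  s <- sort(negative_scores, decreasing = TRUE)
  k <- floor(target_fpr * n)
  tau <- if (k >= n) s[n] - 1 else s[k + 1]
  achieved <- mean(negative_scores > tau)
  structure(list(
    label = label,
    threshold = tau,
    target_fpr = target_fpr,
    achieved_fpr = achieved,
    n_neg = n
  ), class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point>%s threshold %.4g, target FPR %.3f, achieved %.3f (n_neg %d)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$threshold, x$target_fpr, x$achieved_fpr, x$n_neg))
  invisible(x)
}

#' Per-subgroup classification metrics at a fixed operating point
#'
#' Computes, for each subgroup, the true-positive rate and false-positive
#' rate at the pooled-sample threshold (never recalibrated per subgroup), the
#' Youden J statistic `J = TPR - FPR`, and the threshold-free AUC
#' (rank-based, ties counted one half). A subgroup missing a class gets its
#' affected metrics flagged `NA` with `defined = FALSE`, never silently
#' dropped.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector, aligned to `scores`.
#' @param subgroups Subgroup assignment vector, aligned to `scores`.
#' @param op An `operating_point` from [calibrate_threshold()].
#' @return A tibble of class `subgroup_performance`: one row per subgroup with
#'   `subgroup`, `label`, `n_pos`, `n_neg`, `tpr`, `fpr`, `youden_j`, `auc`,
#'   `defined`.
#' @export
subgroup_metrics <- function(scores, labels, subgroups, op) {
  if (!inherits(op, "operating_point")) abort("`op` must be an operating_point.")
  if (length(scores) != length(labels) || length(scores) != length(subgroups)) {
    abort("scores, labels and subgroups must have equal length.")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1.")
  tau <- op$threshold
  out <- purrr::map_dfr(sort(unique(subgroups)), function(g) {
    sel <- subgroups == g
    y <- labels[sel]
    s <- scores[sel]
    n_pos <- sum(y == 1)
    n_neg <- sum(y == 0)
    tpr <- if (n_pos > 0) mean(s[y == 1] > tau) else NA_real_
    fpr <- if (n_neg > 0) mean(s[y == 0] > tau) else NA_real_
    tibble::tibble(
      subgroup = g,
      label = op$label %||% NA_character_,
      n_pos = n_pos, n_neg = n_neg,
      tpr = tpr, fpr = fpr,
      youden_j = tpr - fpr,
      auc = auc_rank(s, y),
      defined = n_pos > 0 && n_neg > 0
    )
  })
  class(out) <- c("subgroup_performance", class(out))
  out
}

#' Percentile bootstrap confidence interval for an evaluation metric
#'
#' Resamples the evaluation rows with replacement (the operating point stays
#' fixed — its own uncertainty is not propagated), recomputes the metric on
#' each replicate, and returns the percentile interval. When a `unit` column
#' is given (typically `patient_id`), whole units are resampled so that all
#' of a patient's rows move together, respecting within-patient clustering.
#' Replicates on which the metric is undefined (`NA`) are redrawn and
#' counted.
#'
#' @param data Data frame of evaluation rows.
#' @param metric_fn Function taking a resampled data frame, returning one
#'   number.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the interval is deterministic given it.
#' @param unit Optional column name defining the resampling unit.
#' @return One-row tibble: `lower`, `upper`, `n_boot`, `n_redrawn`.
#' @examples
#' d <- data.frame(hit = rbinom(100, 1, 0.8))
#' bootstrap_ci(d, function(x) mean(x$hit), n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(data, metric_fn, n_boot = 2000L, level = 0.95,
                         seed = 1L, unit = NULL) {
  if (n_boot < 2) abort("`n_boot` must be >= 2.")
  if (nrow(data) == 0) abort("no evaluation rows.")
  unit_rows <- if (!is.null(unit)) {
    split(seq_len(nrow(data)), data[[unit]])
  } else {
    as.list(seq_len(nrow(data)))
  }
  n_units <- length(unit_rows)
  local_seed(seed, 808L, {
    stats_out <- numeric(n_boot)
    n_redrawn <- 0L
    for (i in seq_len(n_boot)) {
      val <- NA_real_
      for (attempt in seq_len(100L)) {
        draw <- sample.int(n_units, n_units, replace = TRUE)
        rows <- unlist(unit_rows[draw], use.names = FALSE)
        val <- metric_fn(data[rows, , drop = FALSE])
        if (!is.na(val)) break
        n_redrawn <- n_redrawn + 1L
      }
      if (is.na(val)) abort("metric undefined on 100 consecutive bootstrap redraws.")
      stats_out[i] <- val
    }
    alpha <- 1 - level
    q <- quantile(stats_out, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    tibble::tibble(lower = q[1], upper = q[2], n_boot = as.integer(n_boot),
                   n_redrawn = n_redrawn)
  })
}

#' Subgroup metrics with bootstrap confidence intervals
#'
#' Convenience wrapper: computes [subgroup_metrics()] and adds percentile
#' bootstrap 95% CIs for TPR, FPR, Youden J and AUC, resampling each
#' subgroup's evaluation rows (patient-level when `patient_id` is supplied)
#' with the operating point held fixed. All four metrics are computed on the
#' same replicates.
#'
#' @inheritParams subgroup_metrics
#' @param patient_id Optional patient identifier vector for cluster
#'   resampling.
#' @param n_boot,level,seed Bootstrap parameters (defaults 2000, 0.95, 1).
#' @return A `subgroup_performance` tibble with `*_lower`/`*_upper` columns
#'   per metric.
#' @export
subgroup_metrics_ci <- function(scores, labels, subgroups, op,
                                patient_id = NULL, n_boot = 2000L,
                                level = 0.95, seed = 1L) {
  point <- subgroup_metrics(scores, labels, subgroups, op)
  tau <- op$threshold
  cis <- purrr::map_dfr(point$subgroup, function(g) {
    sel <- subgroups == g
    d <- tibble::tibble(score = scores[sel], y = labels[sel])
    if (!is.null(patient_id)) d$pid <- patient_id[sel]
    unit_rows <- if (!is.null(patient_id)) {
      split(seq_len(nrow(d)), d$pid)
    } else {
      as.list(seq_len(nrow(d)))
    }
    n_units <- length(unit_rows)
    local_seed(seed, 909L, {
      reps <- matrix(NA_real_, n_boot, 4)
      for (i in seq_len(n_boot)) {
        for (attempt in seq_len(100L)) {
          rows <- unlist(unit_rows[sample.int(n_units, n_units, replace = TRUE)],
                         use.names = FALSE)
          y <- d$y[rows]; s <- d$score[rows]
          if (any(y == 1) && any(y == 0)) break
        }
        tpr <- mean(s[y == 1] > tau)
        fpr <- mean(s[y == 0] > tau)
        reps[i, ] <- c(tpr, fpr, tpr - fpr, auc_rank(s, y))
      }
      alpha <- 1 - level
      q <- apply(reps, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                 names = FALSE, na.rm = TRUE)
      tibble::tibble(
        subgroup = g,
        tpr_lower = q[1, 1], tpr_upper = q[2, 1],
        fpr_lower = q[1, 2], fpr_upper = q[2, 2],
        youden_j_lower = q[1, 3], youden_j_upper = q[2, 3],
        auc_lower = q[1, 4], auc_upper = q[2, 4]
      )
    })
  })
  out <- dplyr::left_join(point, cis, by = "subgroup")
  class(out) <- c("subgroup_performance", class(out))
  out
}

#' Relative subgroup performance change
#'
#' The audit's disparity measure: each subgroup's metric compared with the
#' unweighted mean over the audited subgroups of one characteristic,
#' `relative_change = (m_g - mean) / mean`. Subgroups of different
#' characteristics (sex, race) form separate panels and should be passed
#' separately. The relative changes sum to zero across subgroups by
#' construction.
#'
#' @param data Data frame with one row per subgroup.
#' @param metric Name of the metric column (default `"youden_j"`).
#' @param subgroup Name of the subgroup column (default `"subgroup"`).
#' @return A tibble of class `disparity_report`: `subgroup`, `value`,
#'   `mean_value`, `relative_change`.
#' @examples
#' relative_change(data.frame(subgroup = c("f", "m"), youden_j = c(0.4, 0.6)))
#' @export
relative_change <- function(data, metric = "youden_j", subgroup = "subgroup") {
  m <- data[[metric]]
  g <- data[[subgroup]]
  if (is.null(m) || is.null(g)) abort("metric/subgroup columns not found.")
  if (length(m) < 2) abort("need at least two subgroups.")
  if (any(is.na(m))) abort("metric is undefined (NA) for some subgroup.")
  mbar <- mean(m)
  if (abs(mbar) < 1e-12) abort("mean metric is zero: relative change undefined.")
  out <- tibble::tibble(
    subgroup = g,
    value = m,
    mean_value = mbar,
    relative_change = (m - mbar) / mbar
  )
  class(out) <- c("disparity_report", class(out))
  out
}

#' @describeIn subgroup_metrics Bar chart of per-subgroup Youden J with CI
#'   bars when present.
#' @param object A `subgroup_performance` tibble.
#' @param ... Unused.
#' @method autoplot subgroup_performance
#' @export
autoplot.subgroup_performance <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$subgroup, y = .data$youden_j)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Youden J (TPR - FPR)") +
    ggplot2::theme_minimal()
  if ("youden_j_lower" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$youden_j_lower, ymax = .data$youden_j_upper),
      width = 0.2
    )
  }
  p
}

#' @describeIn relative_change Diverging bar chart of relative changes.
#' @param object A `disparity_report` tibble.
#' @param ... Unused.
#' @method autoplot disparity_report
#' @export
autoplot.disparity_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$subgroup, y = 100 * .data$relative_change,
                               fill = .data$relative_change > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen", `FALSE` = "indianred")) +
    ggplot2::labs(x = NULL, y = "Relative change vs subgroup mean (%)") +
    ggplot2::theme_minimal()
}
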