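# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded from `seed + offset`.
# Each exported operation uses its own fixed offset so that results are
# reproducible per operation without coupling RNG state across operations.
local_seed <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer((seed + offset) %% .Machine$integer.max), expr)
}

assert_probabilities <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", what))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", what, sum(p)))
  }
  invisible(p)
}

assert_unit_vectors <- function(m, what, tol = 1e-9) {
  norms <- sqrt(colSums(m^2))
  if (any(abs(norms - 1) > tol)) {
    abort(sprintf("columns of `%s` must have unit norm.", what))
  }
  invisible(m)
}

# Rank-based AUC (Mann-Whitney with ties counted 1/2). Returns NA if a class
# is missing.
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Columns a cohort table must carry beyond its label columns.
cohort_base_cols <- c("patient_id", "scan_id", "sex", "group", "age", "split")

validate_cohort <- function(cohort, labels = NULL) {
  missing <- setdiff(cohort_base_cols, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(cohort$scan_id) > 0) abort("scan_id values must be unique.")
  if (!is.null(labels)) {
    absent <- setdiff(labels, names(cohort))
    if (length(absent) > 0) {
      abort(paste0("cohort has no label column(s): ", paste(absent, collapse = ", ")))
    }
    for (l in labels) {
      if (!all(cohort[[l]] %in% c(0L, 1L))) {
        abort(sprintf("label column `%s` must be binary 0/1.", l))
      }
    }
  }
  invisible(cohort)
}

# Label columns = everything beyond the base metadata columns.
cohort_labels <- function(cohort) setdiff(names(cohort), cohort_base_cols)

check_alignment <- function(embeddings, cohort) {
  if (!is.matrix(embeddings) || !is.numeric(embeddings)) {
    abort("`embeddings` must be a numeric matrix.")
  }
  if (nrow(embeddings) != nrow(cohort)) {
    abort(sprintf(
      "embeddings (%d rows) and cohort (%d rows) are misaligned.",
      nrow(embeddings), nrow(cohort)
    ))
  }
  if (any(!is.finite(embeddings))) abort("embeddings contain non-finite values.")
  invisible(TRUE)
}
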