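#' Generate a synthetic per-scan cohort table
#'
#' Draws a patient population from a [synthetic_config()] — group, sex, age
#' (truncated normal on 18-100 years), a patient-level train/validation/test
#' split and a number of scans per patient — then expands it to one row per
#' scan with per-(group, label) Bernoulli condition labels. No patient
#' straddles splits, and group/sex frequencies and per-group prevalences
#' converge to the configured values as `n_patients` grows.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `patient_id`, `scan_id`, `sex`, `group`,
#'   `age`, `split` and one binary column per configured label, one row per
#'   scan. Deterministic given `config$seed`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 100, seed = 1))
#' table(cohort$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created by synthetic_config().")
  }
  local_seed(config$seed, 101L, {
    n <- config$n_patients
    group <- sample(config$group_names, n, replace = TRUE, prob = config$group_proportions)
    sex <- sample(names(config$sex_proportions), n, replace = TRUE,
                  prob = config$sex_proportions)
    mu <- config$age_mean_sd[group, "mean"]
    sigma <- config$age_mean_sd[group, "sd"]
    # inverse-CDF truncated normal on [18, 100]
    lo <- pnorm((18 - mu) / sigma)
    hi <- pnorm((100 - mu) / sigma)
    age <- mu + sigma * qnorm(lo + runif(n) * (hi - lo))
    split <- sample(names(config$split_fractions), n, replace = TRUE,
                    prob = config$split_fractions)
    n_scans <- if (length(config$scans_per_patient) == 1) {
      rep(config$scans_per_patient, n)
    } else {
      sample(config$scans_per_patient, n, replace = TRUE)
    }
    width <- max(6, nchar(as.character(n)))
    patient_id <- sprintf(paste0("P%0", width, "d"), seq_len(n))

    idx <- rep(seq_len(n), n_scans)
    scan_no <- sequence(n_scans)
    pid_scan <- patient_id[idx]
    cohort <- tibble::tibble(
      patient_id = pid_scan,
      scan_id = sprintf("%s_S%d", pid_scan, scan_no),
      sex = sex[idx],
      group = group[idx],
      age = age[idx],
      split = split[idx]
    )
    for (l in config$label_names) {
      p <- config$prevalence[cohort$group, l]
      cohort[[l]] <- rbinom(nrow(cohort), 1L, p)
    }
    cohort
  })
}

#' Generate synthetic embeddings for a cohort
#'
#' Simulates a frozen backbone's feature vectors under the additive
#' linear-Gaussian model described in [synthetic_config()]: each scan's
#' embedding is isotropic Gaussian noise plus a patient-level random effect
#' shared across that patient's scans, displaced along mutually orthogonalized
#' unit directions by its disease labels (with per-group effect sizes), its
#' sex and its group. With all shifts and effect sizes zero the rows are
#' i.i.d. isotropic Gaussian.
#'
#' @param cohort A cohort table from [generate_cohort()] (or with the same
#'   columns).
#' @param config The [synthetic_config()] the cohort was generated from.
#' @return A numeric matrix (`n_scans` x `embed_dim`), rows aligned to and
#'   named by `cohort$scan_id`. Deterministic given `config$seed`.
#' @examples
#' cfg <- synthetic_config(n_patients = 50, seed = 2)
#' emb <- generate_embeddings(generate_cohort(cfg), cfg)
#' @export
generate_embeddings <- function(cohort, config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created by synthetic_config().")
  }
  validate_cohort(cohort, config$label_names)
  if (!all(cohort$group %in% config$group_names)) {
    abort("cohort contains groups unknown to the config.")
  }
  d <- config$embed_dim
  dirs <- orthogonalize_directions(config)

  local_seed(config$seed, 202L, {
    n <- nrow(cohort)
    x <- matrix(rnorm(n * d, sd = config$noise_sd), n, d)
    # patient random effect, shared across a patient's scans
    if (config$patient_effect_sd > 0) {
      pid <- match(cohort$patient_id, unique(cohort$patient_id))
      u <- matrix(rnorm(max(pid) * d, sd = config$patient_effect_sd), max(pid), d)
      x <- x + u[pid, , drop = FALSE]
    }
    sigma <- config$noise_sd
    for (l in config$label_names) {
      beta <- config$disease_effect_size[cohort$group, l] * cohort[[l]]
      x <- x + (sigma * beta) %o% dirs$disease[, l]
    }
    s <- as.numeric(cohort$sex == names(config$sex_proportions)[1])
    x <- x + (sigma * config$sex_shift * s) %o% dirs$sex
    gshift <- config$group_shifts[cohort$group]
    for (g in config$group_names) {
      sel <- cohort$group == g
      if (any(sel) && config$group_shifts[[g]] > 0) {
        x[sel, ] <- x[sel, ] + rep(1, sum(sel)) %o%
          (sigma * config$group_shifts[[g]] * dirs$group[, g])
      }
    }
    rownames(x) <- cohort$scan_id
    x
  })
}

# Gram-Schmidt orthonormalization of the configured direction vectors, in the
# order disease labels, sex, groups. Keeps injected shifts separable.
orthogonalize_directions <- function(config) {
  m <- cbind(config$disease_directions, sex = config$sex_direction,
             config$group_directions)
  q <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (j > 1) v <- v - q[, seq_len(j - 1), drop = FALSE] %*%
        crossprod(q[, seq_len(j - 1), drop = FALSE], m[, j])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) {
      abort("direction vectors are linearly dependent and cannot be orthogonalized.")
    }
    q[, j] <- v / nv
  }
  n_labels <- length(config$label_names)
  n_groups <- length(config$group_names)
  list(
    disease = matrix(q[, seq_len(n_labels)], ncol = n_labels,
                     dimnames = list(NULL, config$label_names)),
    sex = q[, n_labels + 1L],
    group = matrix(q[, n_labels + 1L + seq_len(n_groups)], ncol = n_groups,
                   dimnames = list(NULL, config$group_names))
  )
}

#' Read and write audit inputs
#'
#' Plain-text serialization of the audit's inputs: the per-scan cohort table
#' as CSV, the embedding matrix as CSV with a leading `scan_id` column, and a
#' generating configuration as JSON (the ground-truth manifest for synthetic
#' runs).
#'
#' @param cohort,embeddings,config Objects to write.
#' @param path File path.
#' @return The path (writers, invisibly); a tibble, matrix or list (readers).
#' @name audit_io
NULL

#' @rdname audit_io
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname audit_io
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(cohort)
  cohort
}

#' @rdname audit_io
#' @export
write_embeddings <- function(embeddings, path) {
  df <- tibble::as_tibble(embeddings, .name_repair = "minimal")
  names(df) <- sprintf("e%03d", seq_len(ncol(df)))
  df <- dplyr::bind_cols(tibble::tibble(scan_id = rownames(embeddings)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname audit_io
#' @export
read_embeddings <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[setdiff(names(df), "scan_id")])
  rownames(m) <- df$scan_id
  m
}

#' @rdname audit_io
#' @export
write_synthetic_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
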