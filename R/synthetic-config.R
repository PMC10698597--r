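#' Configuration for the synthetic cohort and embedding generator
#'
#' Describes a multi-site-style study population (imbalanced racial groups,
#' sex split, age structure, repeated scans per patient, subgroup-dependent
#' disease prevalence) together with a linear-Gaussian model of how disease
#' status, biologic sex and racial group displace a frozen backbone's feature
#' vectors. The configuration doubles as ground truth for audit recovery
#' tests: every injected shift and per-group disease effect size is known.
#'
#' The embedding model for scan \eqn{i} of patient \eqn{p} in group \eqn{g} is
#' \deqn{x_i = \sum_l y_{il}\,\beta_{gl}\,\sigma\, d_l + s_i\,\delta_{sex}\,\sigma\, d_{sex}
#'       + \gamma_g\,\sigma\, d_g + u_p + \epsilon_i,}
#' with \eqn{\epsilon_i \sim N(0, \sigma^2 I)}, patient effect
#' \eqn{u_p \sim N(0, \sigma_u^2 I)} shared across a patient's scans,
#' \eqn{y_{il}} the binary label, \eqn{s_i} the male indicator, and all effect
#' sizes (\eqn{\beta_{gl}}, \eqn{\delta_{sex}}, \eqn{\gamma_g}) expressed in
#' units of the noise standard deviation \eqn{\sigma}. The direction vectors
#' are orthogonalized (Gram-Schmidt) before use so that the injected disease,
#' sex and group shifts are statistically separable.
#'
#' Defaults emulate a CheXpert-like cohort: three racial groups with strong
#' imbalance, male/female split 0.55/0.45, age 63 +/- 17 years truncated to
#' 18-100, four condition labels with realistic prevalences, a 60/10/30
#' patient-level train/validation/test split and one to three scans per
#' patient.
#'
#' @param n_patients Number of patients.
#' @param scans_per_patient Integer scalar, or integer vector of values each
#'   patient's scan count is drawn from uniformly (default `1:3`).
#' @param group_names Racial group names (>= 2).
#' @param group_proportions Probabilities per group, summing to 1.
#' @param sex_proportions Named probabilities for `c(male, female)`; the first
#'   element is the sex receiving the `sex_shift` displacement.
#' @param age_mean_sd Numeric matrix (`n_groups` x 2) of per-group age mean and
#'   SD in years, or `NULL` for 63 +/- 17 in every group. Ages are truncated
#'   to \[18, 100\].
#' @param label_names Condition label names.
#' @param prevalence Matrix (`n_groups` x `n_labels`) of per-(group, label)
#'   prevalences, a vector of length `n_labels` recycled across groups, or
#'   `NULL` for defaults (0.10, 0.40, 0.12, 0.09 for the four default labels).
#' @param split_fractions Named train/validation/test fractions, summing to 1.
#' @param embed_dim Embedding dimension; must be at least the number of
#'   distinct direction vectors.
#' @param disease_directions Matrix (`embed_dim` x `n_labels`) of unit vectors;
#'   `NULL` for the leading standard basis vectors.
#' @param disease_effect_size Matrix (`n_groups` x `n_labels`) of non-negative
#'   per-(group, label) disease displacements (noise-SD units), a scalar or a
#'   length-`n_labels` vector recycled across groups. Default 1.5.
#' @param sex_direction Unit vector; `NULL` for the next standard basis vector.
#' @param sex_shift Non-negative displacement (noise-SD units) applied to the
#'   first sex category. Default 0.5.
#' @param group_directions Matrix (`embed_dim` x `n_groups`) of unit vectors;
#'   `NULL` for subsequent standard basis vectors.
#' @param group_shifts Non-negative per-group displacements (noise-SD units);
#'   default `c(0.4, 0.4, 0)` with the majority group as reference.
#' @param patient_effect_sd Non-negative SD of the shared per-patient random
#'   effect. Default 0.25.
#' @param noise_sd Positive SD of the isotropic scan-level noise. Default 1.
#' @param seed Integer seed; all generation is deterministic given it.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_patients = 200, seed = 7)
#' cohort <- generate_cohort(cfg)
#' emb <- generate_embeddings(cohort, cfg)
#' dim(emb)
#' @export
synthetic_config <- function(n_patients = 2000,
                             scans_per_patient = 1:3,
                             group_names = c("asian", "black", "white"),
                             group_proportions = c(0.14, 0.07, 0.79),
                             sex_proportions = c(male = 0.55, female = 0.45),
                             age_mean_sd = NULL,
                             label_names = c("no_finding", "pleural_effusion",
                                             "cardiomegaly", "pneumothorax"),
                             prevalence = NULL,
                             split_fractions = c(train = 0.6, validation = 0.1, test = 0.3),
                             embed_dim = 32,
                             disease_directions = NULL,
                             disease_effect_size = 1.5,
                             sex_direction = NULL,
                             sex_shift = 0.5,
                             group_directions = NULL,
                             group_shifts = c(0.4, 0.4, 0),
                             patient_effect_sd = 0.25,
                             noise_sd = 1,
                             seed = 1L) {
  if (length(n_patients) != 1 || n_patients < 1) abort("`n_patients` must be a positive integer.")
  n_groups <- length(group_names)
  if (n_groups < 2) abort("at least two group names are required.")
  if (length(group_proportions) != n_groups) {
    abort("`group_proportions` must have one entry per group.")
  }
  assert_probabilities(group_proportions, "group_proportions")
  assert_probabilities(sex_proportions, "sex_proportions")
  if (length(sex_proportions) != 2 || is.null(names(sex_proportions))) {
    abort("`sex_proportions` must be a named length-2 probability vector.")
  }
  assert_probabilities(split_fractions, "split_fractions")
  if (!all(c("train", "validation", "test") %in% names(split_fractions))) {
    abort("`split_fractions` needs train, validation and test entries.")
  }
  if (any(scans_per_patient < 1) || any(scans_per_patient != round(scans_per_patient))) {
    abort("`scans_per_patient` must be positive integer(s).")
  }
  n_labels <- length(label_names)
  if (n_labels < 1) abort("at least one label is required.")

  if (is.null(age_mean_sd)) {
    age_mean_sd <- matrix(rep(c(63, 17), each = n_groups), ncol = 2)
  }
  age_mean_sd <- matrix(age_mean_sd, ncol = 2, dimnames = list(group_names, c("mean", "sd")))

  if (is.null(prevalence)) {
    defaults <- c(no_finding = 0.10, pleural_effusion = 0.40,
                  cardiomegaly = 0.12, pneumothorax = 0.09)
    prevalence <- if (all(label_names %in% names(defaults))) {
      matrix(rep(defaults[label_names], each = n_groups), nrow = n_groups)
    } else {
      matrix(0.2, nrow = n_groups, ncol = n_labels)
    }
  }
  if (length(prevalence) == n_labels && !is.matrix(prevalence)) {
    prevalence <- matrix(rep(prevalence, each = n_groups), nrow = n_groups)
  }
  prevalence <- matrix(prevalence, nrow = n_groups, ncol = n_labels,
                       dimnames = list(group_names, label_names))
  if (any(prevalence < 0 | prevalence > 1)) abort("prevalences must lie in [0, 1].")

  n_directions <- n_labels + 1L + n_groups
  if (embed_dim < n_directions) {
    abort(sprintf(
      "`embed_dim` (%d) must be >= number of direction vectors (%d) so they can be orthogonalized.",
      embed_dim, n_directions
    ))
  }
  basis <- diag(embed_dim)
  if (is.null(disease_directions)) disease_directions <- basis[, seq_len(n_labels), drop = FALSE]
  if (is.null(sex_direction)) sex_direction <- basis[, n_labels + 1L]
  if (is.null(group_directions)) {
    group_directions <- basis[, n_labels + 1L + seq_len(n_groups), drop = FALSE]
  }
  disease_directions <- matrix(disease_directions, nrow = embed_dim,
                               dimnames = list(NULL, label_names))
  group_directions <- matrix(group_directions, nrow = embed_dim,
                             dimnames = list(NULL, group_names))
  assert_unit_vectors(disease_directions, "disease_directions")
  assert_unit_vectors(cbind(sex_direction), "sex_direction")
  assert_unit_vectors(group_directions, "group_directions")

  if (length(disease_effect_size) == 1) {
    disease_effect_size <- matrix(disease_effect_size, n_groups, n_labels)
  } else if (length(disease_effect_size) == n_labels && !is.matrix(disease_effect_size)) {
    disease_effect_size <- matrix(rep(disease_effect_size, each = n_groups), nrow = n_groups)
  }
  disease_effect_size <- matrix(disease_effect_size, nrow = n_groups, ncol = n_labels,
                                dimnames = list(group_names, label_names))
  if (length(group_shifts) != n_groups) abort("`group_shifts` must have one entry per group.")
  if (any(disease_effect_size < 0) || sex_shift < 0 || any(group_shifts < 0)) {
    abort("effect sizes and shifts must be non-negative.")
  }
  if (patient_effect_sd < 0) abort("`patient_effect_sd` must be non-negative.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")

  structure(list(
    n_patients = as.integer(n_patients),
    scans_per_patient = as.integer(scans_per_patient),
    group_names = group_names,
    group_proportions = stats::setNames(group_proportions, group_names),
    sex_proportions = sex_proportions,
    age_mean_sd = age_mean_sd,
    label_names = label_names,
    prevalence = prevalence,
    split_fractions = split_fractions[c("train", "validation", "test")],
    embed_dim = as.integer(embed_dim),
    disease_directions = disease_directions,
    disease_effect_size = disease_effect_size,
    sex_direction = as.numeric(sex_direction),
    sex_shift = sex_shift,
    group_directions = group_directions,
    group_shifts = stats::setNames(group_shifts, group_names),
    patient_effect_sd = patient_effect_sd,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d patients, %d-dim embeddings, seed %d\n",
              x$n_patients, x$embed_dim, x$seed))
  cat("  groups:", paste(sprintf("%s (%.2f, shift %.2f)", x$group_names,
                                 x$group_proportions, x$group_shifts),
                         collapse = ", "), "\n")
  cat("  labels:", paste(x$label_names, collapse = ", "), "\n")
  cat(sprintf("  sex shift %.2f along first sex category (%s)\n",
              x$sex_shift, names(x$sex_proportions)[1]))
  cat(sprintf("  noise sd %.2f, patient effect sd %.2f\n",
              x$noise_sd, x$patient_effect_sd))
  invisible(x)
}
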