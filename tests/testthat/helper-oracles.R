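# Independent oracles used across tests. These deliberately take the slow,
# obvious route so they stay independent of the package's implementations.

# O(n^2) brute-force two-sample KS: sup of |F_a - F_b| over every pooled point.
ks_brute_force <- function(a, b) {
  pooled <- c(a, b)
  max(vapply(pooled, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Benjamini-Yekutieli from the displayed formula, computed naively.
by_hand <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m * cm / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force AUC: all positive-negative pairs, ties count one half.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Small balanced-world config used by several tests: equal groups, one scan
# per patient, moderate prevalence, no injected shifts unless overridden.
null_config <- function(n_patients, embed_dim = 8, seed = 1, ...) {
  args <- list(
    n_patients = n_patients,
    scans_per_patient = 1L,
    group_proportions = rep(1 / 3, 3),
    prevalence = rep(0.3, 4),
    embed_dim = embed_dim,
    disease_effect_size = 0,
    sex_shift = 0,
    group_shifts = c(0, 0, 0),
    patient_effect_sd = 0,
    seed = seed
  )
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}
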