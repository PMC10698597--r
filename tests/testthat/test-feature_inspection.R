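# --- PCA -------------------------------------------------------------------

test_that("fit_pca handles rank-1, isotropic and completeness cases", {
  # data exactly on a line: first mode captures everything
  t <- seq(-1, 1, length.out = 50)
  line <- cbind(t * 3, t * 4) + matrix(rep(c(1, 2), each = 50), ncol = 2)
  p <- fit_pca(line)
  expect_equal(p$ev_ratio, c(1, 0), tolerance = 1e-12)

  # isotropic Gaussian: each ratio ~ 1/d
  set.seed(1)
  iso <- matrix(rnorm(10000 * 8), 10000, 8)
  p2 <- fit_pca(iso)
  expect_true(all(abs(p2$ev_ratio - 1 / 8) < 0.02))
  expect_equal(sum(p2$ev_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(p2$ev_ratio) <= 1e-12))
})

test_that("fit_pca satisfies the projection-result invariants", {
  set.seed(2)
  x <- matrix(rnorm(200 * 6), 200, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  p <- fit_pca(x)
  # orthonormal components
  expect_equal(unname(crossprod(p$rotation)), diag(6), tolerance = 1e-6)
  # reconstruction with all modes reproduces the centered data
  xc <- sweep(x, 2, p$center)
  expect_equal(p$coordinates %*% t(p$rotation), xc, tolerance = 1e-8)
  # ev ratios within [0,1], non-increasing, match a dense eigendecomposition
  expect_true(all(p$ev_ratio >= 0 & p$ev_ratio <= 1))
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$ev_ratio, ev / sum(ev), tolerance = 1e-8)
})

test_that("fit_pca variance target retains the minimal number of modes", {
  set.seed(3)
  x <- matrix(rnorm(500 * 10), 500, 10) %*% diag(sqrt(c(8, 4, 2, 1, rep(0.1, 6))))
  p <- fit_pca(x, var_target = 0.9)
  cums <- cumsum(p$ev_ratio_all)
  expect_gte(cums[p$n_modes], 0.9)
  if (p$n_modes > 1) expect_lt(cums[p$n_modes - 1], 0.9)
})

test_that("fit_pca rejects degenerate inputs", {
  expect_error(fit_pca(matrix(1, 5, 3)), "constant")
  expect_error(fit_pca(matrix(rnorm(9), 3, 3), n_modes = 3), "modes")
  expect_error(fit_pca(matrix(rnorm(4), 1, 4)), "2 rows")
})

test_that("component signs are deterministic (largest loading positive)", {
  set.seed(4)
  x <- matrix(rnorm(300), 100, 3)
  p1 <- fit_pca(x)
  p2 <- fit_pca(x[sample(100), ])
  for (j in 1:3) {
    peak <- which.max(abs(p1$rotation[, j]))
    expect_gt(p1$rotation[peak, j], 0)
  }
  expect_equal(abs(p1$rotation), abs(p2$rotation), tolerance = 1e-8)
})

# --- KS and BY -------------------------------------------------------------

test_that("ks_two_sample matches trivial cases and the brute-force oracle", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2), c(10, 11))$statistic, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")

  set.seed(5)
  for (i in 1:50) {
    a <- sample(c(rnorm(30), round(rnorm(5), 1)))  # include ties
    b <- c(rnorm(25, 0.3), a[1:3])
    expect_identical(ks_two_sample(a, b)$statistic, ks_brute_force(a, b))
  }
})

test_that("ks_two_sample is symmetric and agrees with the asymptotic reference", {
  set.seed(6)
  a <- rnorm(120)
  b <- rnorm(150, 0.4)
  k1 <- ks_two_sample(a, b)
  k2 <- ks_two_sample(b, a)
  expect_equal(k1$statistic, k2$statistic)
  expect_equal(k1$p_value, k2$p_value)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(k1$statistic, unname(ref$statistic))
  expect_equal(k1$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("BY adjustment matches the hand formula, dominates BH, preserves order", {
  expect_equal(adjust_benjamini_yekutieli(0.03), 0.03)  # c(1) = 1
  p4 <- c(0.01, 0.02, 0.03, 0.04)  # already sorted; c(4) = 25/12
  hand <- pmin(1, rev(cummin(rev(p4 * 4 * (25 / 12) / (1:4)))))
  expect_equal(adjust_benjamini_yekutieli(p4), hand, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_benjamini_yekutieli(p)
    expect_equal(adj, by_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(adj >= p - 1e-12 & adj <= 1))
  }
  expect_error(adjust_benjamini_yekutieli(c(0.5, 0)), "0, 1")
})

# --- balanced subsample ----------------------------------------------------

test_that("balanced_subsample draws per_group_n patients per group, one scan each", {
  cfg <- synthetic_config(n_patients = 900, group_proportions = rep(1 / 3, 3),
                          seed = 10)
  cohort <- generate_cohort(cfg)
  idx <- balanced_subsample(cohort, per_group_n = 100, seed = 2)
  expect_equal(nrow(idx), 300)
  expect_equal(as.vector(table(idx$group)), rep(100L, 3))
  expect_false(anyDuplicated(idx$patient_id) > 0)  # without replacement here
  expect_false(any(attr(idx, "with_replacement")))

  expect_equal(nrow(balanced_subsample(cohort, 0, seed = 2)), 0)
  expect_identical(idx, balanced_subsample(cohort, per_group_n = 100, seed = 2))

  # with replacement when a group is too small, and flagged
  small <- cohort[cohort$group != "asian" | cohort$patient_id %in%
                    head(unique(cohort$patient_id[cohort$group == "asian"]), 5), ]
  idx2 <- balanced_subsample(small, per_group_n = 50, seed = 1)
  expect_true(attr(idx2, "with_replacement")[["asian"]])
  expect_equal(sum(idx2$group == "asian"), 50)
})

# --- shift audit -----------------------------------------------------------

test_that("run_shift_audit produces a coherent jointly-adjusted report", {
  cfg <- synthetic_config(n_patients = 900, group_proportions = rep(1 / 3, 3),
                          prevalence = rep(0.3, 4), embed_dim = 12, seed = 12)
  cohort <- generate_cohort(cfg)
  emb <- generate_embeddings(cohort, cfg)
  cfgA <- audit_config(per_group_subsample = 120, seed = 5)
  audit <- run_shift_audit(emb, cohort, config = cfgA)
  res <- tidy(audit)

  comparisons <- shift_comparisons(cohort)
  expect_equal(nrow(res), nrow(comparisons) * 4)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  expect_identical(res$significant, res$p_adjusted < 0.05)
  expect_true(all(res$ks_statistic >= 0 & res$ks_statistic <= 1))
  expect_equal(sum(audit$tally$n_tests), nrow(res))

  # deterministic re-run
  audit2 <- run_shift_audit(emb, cohort, config = cfgA)
  expect_equal(tidy(audit2), res)

  # empty comparison list -> empty report
  empty <- run_shift_audit(emb, cohort,
                           comparisons = shift_comparisons(cohort)[0, ],
                           config = cfgA)
  expect_equal(nrow(tidy(empty)), 0)

  # unknown subgroup label -> error
  bad <- tibble::tibble(characteristic = "race", a = "martian", b = "white")
  expect_error(run_shift_audit(emb, cohort, comparisons = bad, config = cfgA),
               "unknown")
})

test_that("an injected sex shift is detected with high power", {
  cfg <- null_config(1200, seed = 14, sex_shift = 1,
                     sex_proportions = c(male = 0.5, female = 0.5))
  cohort <- generate_cohort(cfg)
  emb <- generate_embeddings(cohort, cfg)
  audit <- run_shift_audit(
    emb, cohort,
    comparisons = shift_comparisons(cohort, characteristics = "sex"),
    config = audit_config(per_group_subsample = 300, seed = 1)
  )
  res <- tidy(audit)
  # the shift lies in the span of the leading modes; at least one mode flags it
  expect_true(any(res$significant))
})

test_that("detection power is monotone in the injected shift magnitude", {
  reject_rate <- vapply(c(0, 0.25, 0.5, 1.0), function(delta) {
    hits <- vapply(1:20, function(r) {
      cfg <- null_config(600, seed = 4000 + r, sex_shift = delta,
                         sex_proportions = c(male = 0.5, female = 0.5))
      cohort <- generate_cohort(cfg)
      emb <- generate_embeddings(cohort, cfg)
      audit <- run_shift_audit(
        emb, cohort,
        comparisons = shift_comparisons(cohort, characteristics = "sex"),
        config = audit_config(per_group_subsample = 150, seed = r)
      )
      any(tidy(audit)$significant)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  # non-decreasing within Monte-Carlo slack; strong shift essentially certain
  expect_true(all(diff(reject_rate) >= -0.15))
  expect_lte(reject_rate[1], 0.1)
  expect_gte(reject_rate[4], 0.9)
})

# --- marginals and t-SNE ---------------------------------------------------

test_that("normalized marginals integrate to one on a common grid", {
  set.seed(15)
  df <- data.frame(value = c(rnorm(5000), rnorm(300, 2)),
                   subgroup = rep(c("big", "small"), c(5000, 300)))
  m <- normalized_marginals(df, "value", "subgroup")
  for (g in c("big", "small")) {
    sub <- m[m$subgroup == g, ]
    area <- sum((sub$density[-1] + sub$density[-nrow(sub)]) / 2 * diff(sub$x))
    expect_equal(area, 1, tolerance = 1e-3)
  }
  # common grid
  expect_identical(m$x[m$subgroup == "big"], m$x[m$subgroup == "small"])
  # standard normal density at 0
  at0 <- m[m$subgroup == "big", ]
  expect_lt(abs(at0$density[which.min(abs(at0$x))] - 1 / sqrt(2 * pi)), 0.05)
  # identical samples give identical densities
  df2 <- data.frame(value = rep(rnorm(100), 2),
                    subgroup = rep(c("a", "b"), each = 100))
  m2 <- normalized_marginals(df2, "value", "subgroup")
  expect_equal(m2$density[m2$subgroup == "a"], m2$density[m2$subgroup == "b"])
  expect_error(normalized_marginals(
    data.frame(value = c(1, 1, 2), subgroup = c("a", "a", "b")),
    "value", "subgroup"), "fewer than 2")
})

test_that("tsne_view is shaped, seeded and separates far-apart clusters", {
  set.seed(16)
  n <- 120
  clusters <- rep(c(0, 10), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 1] <- x[, 1] + clusters
  proj <- fit_pca(x, var_target = 0.99)
  cfgA <- audit_config(seed = 7)
  y1 <- tsne_view(proj, cfgA, max_iter = 300)
  expect_equal(dim(as.matrix(y1)), c(n, 2))
  expect_identical(y1, tsne_view(proj, cfgA, max_iter = 300))

  sil <- cluster::silhouette(as.integer(clusters > 0) + 1L,
                             dist(as.matrix(y1)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # projection must carry the retention target
  expect_error(tsne_view(fit_pca(x, n_modes = 3), cfgA), "retention")
})
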