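# --- threshold calibration -------------------------------------------------

test_that("calibrate_threshold admits exactly the target share of negatives", {
  op <- calibrate_threshold(seq(0.1, 1.0, by = 0.1), target_fpr = 0.20)
  expect_equal(op$achieved_fpr, 0.20)
  expect_equal(sum(seq(0.1, 1.0, by = 0.1) > op$threshold), 2)

  expect_equal(calibrate_threshold(rnorm(50), target_fpr = 0)$achieved_fpr, 0)
  op1 <- calibrate_threshold(rnorm(50), target_fpr = 1)
  expect_equal(op1$achieved_fpr, 1)

  # continuous scores: |achieved - target| <= 1/n_neg, achieved <= target
  set.seed(30)
  for (target in c(0.1, 0.2, 0.33)) {
    s <- rnorm(517)
    op <- calibrate_threshold(s, target_fpr = target)
    expect_lte(op$achieved_fpr, target)
    expect_lte(target - op$achieved_fpr, 1 / length(s))
  }
  expect_error(calibrate_threshold(numeric(0)), "no negative")
})

# --- subgroup metrics ------------------------------------------------------

test_that("subgroup metrics honor the pooled threshold and the J identity", {
  set.seed(31)
  n <- 6000
  g <- sample(c("x", "y"), n, replace = TRUE)
  y <- rbinom(n, 1, 0.4)
  s <- y * 2 + rnorm(n)                      # informative scores
  op <- calibrate_threshold(s[y == 0], 0.2)
  perf <- subgroup_metrics(s, y, g, op)
  expect_equal(nrow(perf), 2)
  expect_equal(perf$youden_j, perf$tpr - perf$fpr)
  expect_true(all(perf$defined))
  expect_true(all(perf$tpr >= 0 & perf$tpr <= 1))

  # null scores: J ~ 0 per subgroup at large n
  s0 <- rnorm(n)
  op0 <- calibrate_threshold(s0[y == 0], 0.2)
  perf0 <- subgroup_metrics(s0, y, g, op0)
  expect_true(all(abs(perf0$youden_j) < 0.05))

  # perfect classifier: TPR 1, FPR <= target in every subgroup
  sp <- y * 10 + runif(n)
  opp <- calibrate_threshold(sp[y == 0], 0.2)
  perfp <- subgroup_metrics(sp, y, g, opp)
  expect_true(all(perfp$tpr == 1))
  expect_true(all(perfp$fpr <= 0.2 + 1e-12))
  expect_true(all(perfp$youden_j >= 0.8 - 1e-12))
})

test_that("a subgroup missing a class is flagged undefined, not dropped", {
  s <- c(0.9, 0.8, 0.2, 0.1, 0.7, 0.6)
  y <- c(1, 1, 0, 0, 1, 1)     # subgroup "b" has no negatives
  g <- c("a", "a", "a", "a", "b", "b")
  op <- calibrate_threshold(s[y == 0], 0.2)
  perf <- subgroup_metrics(s, y, g, op)
  expect_equal(nrow(perf), 2)
  row_b <- perf[perf$subgroup == "b", ]
  expect_false(row_b$defined)
  expect_true(is.na(row_b$fpr) && is.na(row_b$auc))
  expect_false(is.na(row_b$tpr))
})

test_that("AUC matches brute force and is invariant to monotone transforms", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(c(rnorm(n - 3), round(rnorm(3), 1)))  # some ties
    expect_equal(embedaudit:::auc_rank(s, y), auc_brute_force(s, y),
                 tolerance = 1e-12)
    expect_equal(embedaudit:::auc_rank(exp(s), y),
                 embedaudit:::auc_rank(s, y), tolerance = 1e-12)
    expect_equal(embedaudit:::auc_rank(3 * s - 7, y),
                 embedaudit:::auc_rank(s, y), tolerance = 1e-12)
  }
})

# --- bootstrap -------------------------------------------------------------

test_that("bootstrap_ci basics: constant metric, determinism, patient clustering", {
  d <- data.frame(v = rep(0.7, 50), pid = rep(1:25, each = 2))
  ci <- bootstrap_ci(d, function(x) mean(x$v), n_boot = 100, seed = 1)
  expect_equal(ci$lower, 0.7)
  expect_equal(ci$upper, 0.7)

  set.seed(33)
  d2 <- data.frame(v = rnorm(80), pid = rep(1:40, each = 2))
  ci1 <- bootstrap_ci(d2, function(x) mean(x$v), n_boot = 300, seed = 5)
  expect_identical(ci1, bootstrap_ci(d2, function(x) mean(x$v),
                                     n_boot = 300, seed = 5))
  # unit resampling keeps a patient's rows together: with pid-constant values,
  # any resample mean is a mean of pair means
  d3 <- data.frame(v = rep(c(0, 1), each = 40), pid = rep(1:40, each = 2))
  ci3 <- bootstrap_ci(d3, function(x) {
    if (any(table(x$pid) %% 2 != 0)) return(NA_real_)
    mean(x$v)
  }, n_boot = 50, seed = 2, unit = "pid")
  expect_equal(ci3$n_redrawn, 0L)  # never splits a patient

  # undefined replicates get redrawn and counted
  d4 <- data.frame(v = c(1, rep(0, 4)))
  ci4 <- bootstrap_ci(d4, function(x) ifelse(any(x$v == 1), mean(x$v), NA_real_),
                      n_boot = 50, seed = 3)
  expect_gt(ci4$n_redrawn, 0)
})

test_that("subgroup_metrics_ci yields ordered intervals containing the point", {
  set.seed(34)
  n <- 1200
  g <- sample(c("x", "y"), n, replace = TRUE)
  y <- rbinom(n, 1, 0.5)
  s <- y * 1.5 + rnorm(n)
  pid <- sample(sprintf("p%03d", 1:400), n, replace = TRUE)
  op <- calibrate_threshold(s[y == 0], 0.2)
  perf <- subgroup_metrics_ci(s, y, g, op, patient_id = pid,
                              n_boot = 300, seed = 4)
  for (m in c("tpr", "fpr", "youden_j", "auc")) {
    lo <- perf[[paste0(m, "_lower")]]
    hi <- perf[[paste0(m, "_upper")]]
    expect_true(all(lo <= hi))
    expect_true(all(lo <= perf[[m]] + 1e-9 & perf[[m]] <= hi + 1e-9))
  }
})

# --- relative change -------------------------------------------------------

test_that("relative_change matches hand arithmetic and sums to zero", {
  rc <- relative_change(data.frame(subgroup = c("f", "m"),
                                   youden_j = c(0.6, 0.4)))
  expect_equal(rc$relative_change, c(0.2, -0.2))   # +/- 20% of the mean 0.5
  expect_equal(sum(rc$relative_change), 0, tolerance = 1e-12)

  eq <- relative_change(data.frame(subgroup = letters[1:3],
                                   youden_j = rep(0.37, 3)))
  expect_equal(eq$relative_change, rep(0, 3))

  set.seed(35)
  for (i in 1:10) {
    vals <- runif(sample(2:6, 1), 0.1, 0.9)
    rc <- relative_change(data.frame(subgroup = seq_along(vals), youden_j = vals))
    expect_equal(sum(rc$relative_change), 0, tolerance = 1e-12)
    expect_equal(mean(rc$relative_change), 0, tolerance = 1e-12)
  }

  expect_error(relative_change(data.frame(subgroup = "a", youden_j = 0.5)),
               "two subgroups")
  expect_error(relative_change(data.frame(subgroup = c("a", "b"),
                                          youden_j = c(-0.5, 0.5))), "zero")
})
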