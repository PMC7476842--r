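test_that("the ROC sweep recovers perfect, inverted, and tied orderings", {
  expect_equal(glance(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)))$auc, 1)
  expect_equal(glance(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)))$auc, 0)
  # ties: half-concordance, verified against exhaustive pair enumeration
  s <- c(3, 2, 2, 1)
  y <- c(1, 0, 1, 0)
  expect_equal(glance(roc_curve(s, y))$auc, brute_auc(s, y))
  expect_error(roc_curve(c(1, 2), c(1, 1)), "[Bb]oth classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random instances", {
  set.seed(29)
  for (i in 1:60) {
    n <- sample(6:60, 1)
    s <- sample(round(rnorm(n), 1))   # coarse rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(glance(roc_curve(s, y))$auc, brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  for (i in 1:10) {
    s <- rnorm(50)
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(glance(roc_curve(s, y))$auc, ref, tolerance = 1e-12)
  }
})

test_that("the ROC curve object is well-formed and sensitivity is monotone", {
  set.seed(31)
  r <- roc_curve(rnorm(40), rbinom(40, 1, 0.5))
  curve <- tidy(r)
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_gte(glance(r)$auc, 0)
  expect_lte(glance(r)$auc, 1)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("rank-sum p-values match exact enumeration and handle extremes", {
  got <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p_value, 0.1)
  expect_equal(got$p_value, enum_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(got$method, "exact")

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  set.seed(37)
  a <- rnorm(30) + 100
  b <- rnorm(30)
  expect_lt(rank_sum_test(a, b)$p_value, 1e-9)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("tertile enrichment builds the 2x3 table and Pearson chi-square", {
  # low tertile 15 RD / 5 pCR, mid 10/10, high 5/15
  scores <- 1:60
  labels <- c(rep(0, 15), rep(1, 5), rep(0, 10), rep(1, 10), rep(0, 5), rep(1, 15))
  out <- tertile_enrichment(scores, labels)
  expect_equal(unname(colSums(out$counts)), c(20, 20, 20))
  expect_equal(unname(out$counts["pCR", ]), c(5, 10, 15))
  expect_equal(out$df, 2)
  expect_equal(out$chi2, chi_square_kernel(unclass(out$counts)), tolerance = 1e-12)
  expect_equal(unname(out$pcr_rate["high"]), 0.75)

  # extreme association: all pCR in the top tertile
  extreme <- tertile_enrichment(1:30, rep(c(0, 1), c(20, 10)))
  expect_lt(extreme$p_value, 0.001)
  expect_error(tertile_enrichment(1:4, c(0, 1, 0, 1)), "6 samples")
})

test_that("tertile chi-square has calibrated type-I error under the null", {
  set.seed(43)
  rej <- mean(vapply(1:300, function(i) {
    s <- rnorm(120)
    y <- rbinom(120, 1, 0.4)
    tertile_enrichment(s, y)$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("the balanced random-forest CV is reproducible and detects leakage", {
  set.seed(47)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  feats <- data.frame(leak = y + rnorm(n, sd = 1e-3), age = rnorm(n, 50, 10))
  cv <- combined_classifier_cv(feats, y, folds = 5, repeats = 3, seed = 9, ntree = 100)
  cv2 <- combined_classifier_cv(feats, y, folds = 5, repeats = 3, seed = 9, ntree = 100)
  expect_identical(tidy(cv), tidy(cv2))
  expect_identical(cv$importances, cv2$importances)
  expect_gt(glance(cv)$mean_auc, 0.99)
  top <- cv$importances |>
    dplyr::group_by(repeat_id) |>
    dplyr::slice_max(importance, n = 1)
  expect_true(all(top$feature == "leak"))
})

test_that("an informative score beats clinical-only features on shared folds", {
  sim <- small_sim()
  sig <- build_rps_signature(sim$expression, sim$annotations)
  sc <- score_cohort(sim$expression, sig, n_perm = 100, seed = 31)
  ann <- sim$annotations[match(sc$sample_id, sim$annotations$sample_id), ]
  full <- data.frame(rps = sc$rps, age = ann$age, stage = ann$stage, grade = ann$grade)
  cv_full <- combined_classifier_cv(full, ann$response, folds = 5, repeats = 3,
                                    seed = 21, ntree = 150)
  cv_clin <- combined_classifier_cv(full[, -1], ann$response, folds = 5, repeats = 3,
                                    seed = 21, ntree = 150)
  expect_gt(glance(cv_full)$mean_auc, glance(cv_clin)$mean_auc)
})

test_that("CV validates class sizes and encodes ordinal clinical fields", {
  y <- rep(c(0, 1), c(25, 5))
  feats <- data.frame(x = rnorm(30))
  expect_error(combined_classifier_cv(feats, y, folds = 10, repeats = 1),
               "at least 10")
  y2 <- rbinom(60, 1, 0.5)
  feats2 <- data.frame(x = rnorm(60),
                       stage = sample(c("I", "II", "III", "unknown"), 60, TRUE))
  expect_message(
    cv <- combined_classifier_cv(feats2, y2, folds = 3, repeats = 1, ntree = 50),
    "unknown"
  )
  expect_lt(cv$n_samples, 60)
})

test_that("importance ANOVA matches the closed-form F statistic", {
  fake_cv <- structure(
    list(importances = tibble::tibble(
      repeat_id = rep(1:3, 2),
      feature = rep(c("a", "b"), each = 3),
      importance = c(1, 1, 1, 2, 2, 2) + c(1e-6, -1e-6, 0, 1e-6, -1e-6, 0)
    )),
    class = "rps_cv"
  )
  out <- importance_comparison(fake_cv)
  expect_lt(out$p_value, 1e-10)
  expect_equal(out$mean_importance$feature[1], "b")

  flat <- structure(
    list(importances = tibble::tibble(
      repeat_id = rep(1:3, 2), feature = rep(c("a", "b"), each = 3),
      importance = rep(1, 6)
    )),
    class = "rps_cv"
  )
  out_flat <- importance_comparison(flat)
  expect_equal(out_flat$f_statistic, 0)
  expect_equal(out_flat$p_value, 1)

  set.seed(53)
  rand <- structure(
    list(importances = tibble::tibble(
      repeat_id = rep(1:10, 3),
      feature = rep(c("a", "b", "c"), each = 10),
      importance = rnorm(30)
    )),
    class = "rps_cv"
  )
  got <- importance_comparison(rand)
  ref <- closed_form_anova(rand$importances$importance, rand$importances$feature)
  expect_equal(got$f_statistic, ref$f, tolerance = 1e-8)
  expect_equal(got$p_value, ref$p, tolerance = 1e-8)
})

test_that("paired AUC comparisons use the paired t-test", {
  got <- paired_auc_comparison(c(0.8, 0.8, 0.8), c(0.7, 0.6, 0.5))
  expect_equal(got$t_statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(got$df, 2)
  swapped <- paired_auc_comparison(c(0.7, 0.6, 0.5), c(0.8, 0.8, 0.8))
  expect_equal(swapped$t_statistic, -got$t_statistic)
  expect_error(paired_auc_comparison(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9)), "variance")
})
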