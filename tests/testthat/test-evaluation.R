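test_that("confusion metrics follow the standing-positive definitions", {
  perfect <- classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(unname(perfect), c(100, 100, 100))
  m <- classification_metrics(list(tp = 3, fn = 1, tn = 5, fp = 1))
  expect_equal(m[["sensitivity"]], 75)
  expect_equal(m[["specificity"]], 100 * 5 / 6)
  expect_equal(m[["accuracy"]], 80)
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  withr::with_seed(12, {
    for (i in 1:20) {
      cc <- list(tp = rpois(1, 20), fp = rpois(1, 5),
                 tn = rpois(1, 20), fn = rpois(1, 5))
      if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) next
      m <- classification_metrics(cc)
      total <- cc$tp + cc$fp + cc$tn + cc$fn
      expect_equal(m[["accuracy"]],
                   (m[["sensitivity"]] * (cc$tp + cc$fn) +
                      m[["specificity"]] * (cc$tn + cc$fp)) / total)
    }
  })
})

test_that("undefined metrics are reported as NA, never zero", {
  m <- classification_metrics(list(tp = 0, fn = 0, tn = 4, fp = 1))
  expect_true(is.na(m[["sensitivity"]]))
  expect_equal(m[["specificity"]], 80)
  expect_error(classification_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "all-zero")
})

test_that("cross-validation partitions the data into near-equal folds", {
  s <- make_mixture_samples(103, seed = 33)
  rep1 <- quiet(cross_validate(s, k = 10, seed = 7))
  sizes <- with(rep1$per_fold, tp + fp + tn + fn)
  expect_equal(sum(sizes), 103)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(rep1$per_fold[c("sensitivity", "specificity", "accuracy")] >= 0 &
                    rep1$per_fold[c("sensitivity", "specificity", "accuracy")] <= 100,
                  na.rm = TRUE))
})

test_that("cross-validation is seed-reproducible and averages its folds", {
  s <- make_mixture_samples(200, seed = 21)
  r1 <- quiet(cross_validate(s, k = 5, seed = 99))
  r2 <- quiet(cross_validate(s, k = 5, seed = 99))
  expect_identical(r1, r2)
  r3 <- quiet(cross_validate(s, k = 5, seed = 100))
  expect_false(identical(r1$per_fold, r3$per_fold))
  # averages recomputed independently over defined per-fold values
  for (col in c("sensitivity", "specificity", "accuracy")) {
    vals <- r1$per_fold[[col]]
    expect_equal(r1$averages[[col]], mean(vals[!is.na(vals)]))
  }
})

test_that("separable data cross-validates to perfect average metrics", {
  s <- make_samples(seq(1e-4, 3e-4, length.out = 20), seq(0.01, 0.03, length.out = 20))
  rep <- quiet(cross_validate(s, k = 10, seed = 1))
  expect_equal(unname(rep$averages), c(100, 100, 100))
  expect_error(cross_validate(s, k = 1), "k must be")
  expect_error(cross_validate(s[c(1:3, 21:22), ], k = 10), "at least k")
})

test_that("the velocity t-test uses the Welch statistic", {
  sym <- make_samples(c(1, 2, 3), c(1, 2, 3))
  tt <- velocity_ttest(sym)
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)

  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  tt2 <- velocity_ttest(make_samples(y, x))
  se <- sqrt(var(x) / 4 + var(y) / 4)
  expect_equal(tt2$t, (mean(x) - mean(y)) / se)  # hand-computed Welch t
  expect_equal(tt2$mean_active, mean(x))

  sep <- make_mixture_samples(400, seed = 2)
  tt3 <- velocity_ttest(sep)
  expect_lt(tt3$p_value, 0.001)
  expect_gt(tt3$mean_active, tt3$mean_recumbent)
  expect_true(tt3$significant)
  expect_error(velocity_ttest(make_samples(1e-4, c(0.01, 0.02))), ">= 2 samples")
})

test_that("the accuracy curve peaks at the exhaustive training accuracy", {
  wide <- make_mixture_samples(200, seed = 3)  # well-separated, all velocities > 0
  curve1 <- accuracy_curve(wide, min(wide$v_mps) / 2)
  expect_equal(curve1$accuracy, 100 * mean(wide$code == 1))  # everything classified 1

  s <- make_mixture_samples(500, sd0 = 5e-4, mu1 = 1.2e-3, sd1 = 8e-4, seed = 6)
  cand <- c(0, sort(unique(s$v_mps)))
  curve <- accuracy_curve(s, cand)
  expect_equal(max(curve$accuracy), fit_threshold_exhaustive(s)$train_accuracy)
})
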