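test_that("confusion metrics match hand-enumerated values", {
  # 2x2 table enumerated by hand: TP=2, FN=1, TN=2, FP=0
  m <- compute_metrics(c("CD", "CD", "CD", "control", "control"),
                       c("CD", "control", "CD", "control", "control"))
  expect_equal(m$tpr, 2 / 3)
  expect_equal(m$tnr, 1)
  expect_equal(m$wacc, 5 / 6)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 2 / 3)

  perfect <- compute_metrics(rep(c("CD", "control"), 4),
                             rep(c("CD", "control"), 4))
  expect_true(all(unlist(perfect) == 1))

  # per-class accuracies 0.57 / 0.60 average to 0.585 by the wACC formula
  truth <- c(rep("CD", 100), rep("control", 100))
  pred <- c(rep("CD", 57), rep("control", 43), rep("control", 60),
            rep("CD", 40))
  expect_equal(compute_metrics(truth, pred)$wacc, (0.57 + 0.60) / 2)
})

test_that("zero-denominator metrics are undefined markers, not zeros", {
  m <- compute_metrics(c("CD", "CD", "control"),
                       c("control", "control", "control"))
  expect_true(is.na(m$ppv))     # nothing predicted positive
  expect_equal(m$npv, 1 / 3)
  expect_equal(m$tpr, 0)
  all_cd <- compute_metrics(c("CD", "CD"), c("CD", "control"))
  expect_true(is.na(all_cd$tnr))
  expect_true(is.na(all_cd$wacc))
  expect_error(compute_metrics(character(), character()), "empty")
  expect_error(compute_metrics(c("CD", "dog"), c("CD", "cat")),
               "unknown label")
})

test_that("wACC equals plain accuracy on a class-balanced test set", {
  set.seed(61)
  truth <- rep(c("CD", "control"), each = 25)
  pred <- sample(c("CD", "control"), 50, replace = TRUE)
  expect_equal(compute_metrics(truth, pred)$wacc, mean(truth == pred))
})

test_that("holdout engine produces the configured number of repetitions,
           disjoint stratified splits, and is seed-reproducible", {
  dat <- antipodal_clusters(n_per_class = 25, seed = 10)
  res <- holdout_resample(dat, n_resamplings = 8, seed = 99,
                          control = quick_control())
  expect_equal(nrow(res), 8)
  expect_equal(res$resampling, 1:8)
  for (i in 1:8) {
    expect_length(intersect(res$train_ids[[i]], res$test_ids[[i]]), 0)
    expect_equal(res$n_test[i], 10)  # 5 per class at test_fraction 0.2
  }
  res2 <- holdout_resample(dat, n_resamplings = 8, seed = 99,
                           control = quick_control())
  expect_identical(res$test_ids, res2$test_ids)
  expect_equal(res$wacc, res2$wacc)
  res3 <- holdout_resample(dat, n_resamplings = 8, seed = 100,
                           control = quick_control())
  expect_false(identical(res$test_ids, res3$test_ids))
})

test_that("separable data yields retained repetitions with perfect wACC", {
  dat <- antipodal_clusters(n_per_class = 25, seed = 11)
  res <- holdout_resample(dat, n_resamplings = 10, seed = 7,
                          control = quick_control())
  expect_true(all(res$retained))
  expect_true(all(res$wacc == 1))
  expect_true(all(res$in_sample_wacc == 1))
})

test_that("retention rule never consults test data", {
  dat <- null_stratum(seed = 12)
  res <- holdout_resample(dat, n_resamplings = 12, seed = 3,
                          control = quick_control())
  expect_equal(res$retained, res$in_sample_wacc >= 0.5)
  # permuting all labels of held-out subjects cannot change retention,
  # since retention depends only on the training fit already recorded;
  # re-run with a label permutation applied to the test half of each split
  # is equivalent to checking the flag derives from in_sample_wacc alone
  expect_true(all(res$retained == (res$in_sample_wacc >= 0.5)))
})

test_that("relevance columns of every repetition sum to 1", {
  dat <- null_stratum(seed = 13)
  res <- holdout_resample(dat, n_resamplings = 6, seed = 5,
                          control = quick_control())
  R <- as.matrix(res[paste0("rel_", feature_schema()$feature_id)])
  expect_equal(unname(rowSums(R)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(R >= 0))
})

test_that("model summary aggregates metrics, chance test and retention", {
  dat <- antipodal_clusters(n_per_class = 25, seed = 14)
  res <- holdout_resample(dat, n_resamplings = 12, seed = 8,
                          control = quick_control())
  smry <- summarize_model(res)
  expect_equal(smry$n_resamplings, 12)
  m <- smry$metrics
  expect_setequal(m$metric, c("wacc", "ppv", "npv", "tpr", "tnr"))
  w <- m[m$metric == "wacc", ]
  expect_equal(w$mean, 1)
  expect_equal(w$n_used + w$n_undefined, 12)
  # all repetitions above chance -> tiny binomial p
  expect_lt(smry$chance_test$p_value, 0.001)
  expect_equal(smry$chance_test$cohens_g, 0.5)
})

test_that("chance test follows the exact binomial on constructed outcomes", {
  template <- holdout_resample(antipodal_clusters(n_per_class = 15, seed = 15),
                               n_resamplings = 4, seed = 2,
                               control = quick_control())
  fake <- function(waccs) {
    out <- template[rep(1, length(waccs)), ]
    out$wacc <- waccs
    out$retained <- TRUE
    out
  }
  # exactly half above chance, none equal -> g = 0, p = 1
  s <- summarize_model(fake(c(rep(0.6, 250), rep(0.4, 250))))
  expect_equal(s$chance_test$cohens_g, 0)
  expect_equal(s$chance_test$p_value, 1)
  # 465/500 above -> g = 0.43 and the exact binomial tail
  s2 <- summarize_model(fake(c(rep(0.7, 465), rep(0.3, 35))))
  expect_equal(s2$chance_test$cohens_g, 0.43)
  expect_equal(s2$chance_test$p_value,
               binom.test(465, 500, 0.5)$p.value)
  # undefined metrics are excluded and counted
  waccs <- c(NA, NA, rep(0.8, 8))
  s3 <- summarize_model(fake(waccs))
  w <- s3$metrics[s3$metrics$metric == "wacc", ]
  expect_equal(w$n_undefined, 2)
  expect_equal(w$mean, 0.8)
})

test_that("null data keeps mean test wACC at chance", {
  dat <- null_stratum(n_cd = 60, n_control = 90, seed = 16)
  res <- holdout_resample(dat, n_resamplings = 150, seed = 4,
                          control = quick_control())
  expect_equal(mean(res$wacc), 0.5, tolerance = 0.04)
})
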