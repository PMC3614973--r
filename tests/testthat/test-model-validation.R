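test_that("ROC/AUC matches hand-computed and oracle values", {
  r <- roc_and_auc(c(.9, .8, .2, .1), c("case", "case", "control", "control"))
  expect_equal(r$auc, 1.0)
  r2 <- roc_and_auc(c(.6, .2, .5, .3),
                    c("case", "case", "control", "control"))
  expect_equal(r2$auc, 0.5)  # 2 of 4 case/control pairs concordant
  # ties count one half
  r3 <- roc_and_auc(c(.5, .5), c("case", "control"))
  expect_equal(r3$auc, 0.5)
  # constant scores: diagonal ROC
  r4 <- roc_and_auc(rep(0.3, 6), rep(c("case", "control"), 3))
  expect_equal(r4$auc, 0.5)
  expect_equal(r4$roc_points$fpr, r4$roc_points$tpr)
})

test_that("trapezoidal AUC equals the concordant-pair fraction on random scores", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    labels <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels <- c("case", "control",
                                                labels[-(1:2)])
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # coarse grids force ties
    expect_equal(roc_and_auc(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone nondecreasing in both coordinates", {
  set.seed(41)
  scores <- runif(30)
  labels <- sample(c("case", "control"), 30, replace = TRUE, prob = c(.4, .6))
  pts <- roc_and_auc(scores, labels)$roc_points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- runif(40)
  labels <- factor(sample(c("control", "case"), 40, replace = TRUE),
                   levels = c("control", "case"))
  ours <- roc_and_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                           levels = c("control", "case"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("threshold metrics reproduce the clinical 2x2 baseline table", {
  # 27 of 35 patients score positive; 3 of 35 controls do
  scores <- c(rep(1, 27), rep(0, 8), rep(1, 3), rep(0, 32))
  labels <- factor(c(rep("case", 35), rep("control", 35)),
                   levels = c("control", "case"))
  tm <- threshold_metrics(scores, labels)
  expect_equal(tm$sensitivity, 27 / 35, tolerance = 1e-12)
  expect_equal(tm$specificity, 32 / 35, tolerance = 1e-12)
  expect_equal(round(tm$sensitivity, 2), 0.77)
  expect_equal(round(tm$specificity, 2), 0.91)
  expect_equal(tm$ppv, 27 / 30)
  expect_equal(tm$npv, 32 / 40)
  expect_false(tm$degenerate)
})

test_that("threshold metrics handle separation and degeneracy", {
  sep <- threshold_metrics(c(.9, .8, .2, .1),
                           c("case", "case", "control", "control"))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$ppv, 1)
  expect_equal(sep$npv, 1)
  deg <- threshold_metrics(rep(.5, 6), rep(c("case", "control"), 3))
  expect_true(deg$degenerate)
  expect_equal(deg$sensitivity, 1)
  expect_equal(deg$specificity, 0)
})

test_that("the forest separates separable data and is seed-reproducible", {
  feats <- null_feature_table(15, seed = 1)
  shift <- ifelse(feats$group == "case", 8, -8)  # disjoint ranges everywhere
  for (f in feature_names()) feats[[f]] <- feats[[f]] + shift
  fit <- fit_forest(feats, seed = 11)
  sc <- predict(fit, feats)
  expect_true(all(sc[feats$group == "case"] >= 0.9))
  expect_true(all(sc[feats$group == "control"] <= 0.1))
  fit2 <- fit_forest(feats, seed = 11)
  expect_identical(sc, predict(fit2, feats))
  # boundary mtry: bagged trees still valid
  fit_bag <- fit_forest(feats, mtry = 18, seed = 2)
  expect_s3_class(fit_bag, "eeg_forest")
  expect_error(fit_forest(feats, mtry = 19), "mtry")
  one_class <- feats[feats$group == "case", ]
  expect_error(fit_forest(one_class), "both classes")
})

test_that("bootstrap validation produces a coherent report", {
  feats <- null_feature_table(12, seed = 3)
  feats$path_mean <- feats$path_mean + ifelse(feats$group == "case", 2.5, 0)
  rep <- bootstrap_validate(feats, B = 30, n_trees = 100, seed = 4)
  m <- rep$metrics
  expect_setequal(m$metric, c("auc", "sensitivity", "specificity", "ppv", "npv"))
  expect_true(all(m$estimate >= m$ci_lo - 1e-12 &
                    m$estimate <= m$ci_hi + 1e-12))
  expect_true(all(m$ci_lo >= 0 & m$ci_hi <= 1))
  expect_true(all(diff(rep$roc_curve$tpr) >= -1e-12))
  expect_gt(m$estimate[m$metric == "auc"], 0.8)  # strong planted signal
  # determinism
  rep2 <- bootstrap_validate(feats, B = 30, n_trees = 100, seed = 4)
  expect_equal(rep$metrics, rep2$metrics)
})

test_that("permuted labels give chance-level corrected AUC", {
  set.seed(55)
  base <- null_feature_table(20, seed = 8)
  base$strength_mean <- base$strength_mean +
    ifelse(base$group == "case", 3, 0)
  base$group <- sample(base$group)  # destroy the signal
  rep <- bootstrap_validate(base, B = 60, n_trees = 100, seed = 6)
  auc <- rep$metrics$estimate[rep$metrics$metric == "auc"]
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("point estimates are stable in B", {
  feats <- null_feature_table(12, seed = 9)
  feats$closeness_mean <- feats$closeness_mean +
    ifelse(feats$group == "case", 2, 0)
  r_small <- bootstrap_validate(feats, B = 15, n_trees = 100, seed = 2)
  r_big <- bootstrap_validate(feats, B = 120, n_trees = 100, seed = 2)
  a_small <- r_small$metrics[r_small$metrics$metric == "auc", ]
  a_big <- r_big$metrics[r_big$metrics$metric == "auc", ]
  ci_w <- max(a_small$ci_hi - a_small$ci_lo, a_big$ci_hi - a_big$ci_lo)
  expect_lt(abs(a_small$estimate - a_big$estimate), ci_w)
})

test_that("tidy, glance and JSON serialization expose the report", {
  feats <- null_feature_table(10, seed = 12)
  rep <- bootstrap_validate(feats, B = 12, n_trees = 50, seed = 3)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 5L)
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_bootstrap, 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed, c("metrics", "roc_curve", "settings"))
  expect_equal(parsed$settings$mtry, 5)
  plt <- autoplot(rep)
  expect_s3_class(plt, "ggplot")
})

test_that("the optimism-corrected mode runs and stays in range", {
  feats <- null_feature_table(10, seed = 21)
  feats$strength_max <- feats$strength_max +
    ifelse(feats$group == "case", 2, 0)
  rep <- bootstrap_validate(feats, B = 20, n_trees = 50, seed = 5,
                            mode = "optimism")
  m <- rep$metrics
  expect_true(all(m$estimate >= 0 & m$estimate <= 1))
  expect_identical(rep$mode, "optimism")
})
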