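test_that("a planted perfect feature is recovered out of fold", {
  n <- 120
  feats <- noise_features(n, 10, seed = 11)
  set.seed(12)
  y <- rnorm(n, 25, 4)
  feats[[2]] <- y # one feature identical to the outcome
  conf <- simple_confounds(n)
  cfg <- prediction_config(outer_folds = 5, inner_folds = 5, n_lambda = 50, seed = 1)
  fit <- nested_cv_elastic_net(feats, y, conf, cfg)
  expect_gt(cor(fit$predictions$predicted_oof, y), 0.99)
  expect_gt(fit$delta_r2, 0.9)
})

test_that("pure-noise features add nothing beyond confounds", {
  deltas <- purrr::map_dbl(1:10, function(s) {
    n <- 200
    feats <- noise_features(n, 15, seed = 100 + s)
    conf <- simple_confounds(n, seed = 200 + s)
    set.seed(300 + s)
    y <- rnorm(n)
    cfg <- prediction_config(outer_folds = 5, inner_folds = 3, n_lambda = 20,
                             seed = s, thresh = 1e-5)
    nested_cv_elastic_net(feats, y, conf, cfg)$delta_r2
  })
  expect_lt(abs(mean(deltas)), 0.05)
})

test_that("fold bookkeeping keeps predictions strictly out of fold", {
  n <- 80
  feats <- noise_features(n, 8)
  conf <- simple_confounds(n)
  set.seed(5)
  y <- rnorm(n)
  cfg <- prediction_config(outer_folds = 8, inner_folds = 3, n_lambda = 20, seed = 9)
  fit <- nested_cv_elastic_net(feats, y, conf, cfg)
  pr <- fit$predictions
  # every subject predicted exactly once, folds partition the sample
  expect_equal(sum(is.na(pr$predicted_oof)), 0)
  expect_equal(sort(unique(pr$fold)), 1:8)
  expect_equal(as.vector(table(pr$fold)), rep(10L, 8))
  # leakage probe: changing one held-out subject's outcome must not change
  # the predictions of the fold that held it out
  y2 <- y
  victim <- which(pr$fold == 3)[1]
  y2[victim] <- y2[victim] + 50
  fit2 <- nested_cv_elastic_net(feats, y2, conf, cfg)
  same_fold <- which(fit2$predictions$fold == 3)
  expect_equal(fit2$predictions$predicted_oof[same_fold],
               pr$predicted_oof[same_fold], tolerance = 1e-10)
})

test_that("predictions shrink toward the mean and runs are reproducible", {
  n <- 150
  feats <- noise_features(n, 30, seed = 31)
  conf <- simple_confounds(n, seed = 32)
  set.seed(33)
  y <- as.matrix(feats[-1])[, 1] * 0.5 + rnorm(n)
  cfg <- prediction_config(outer_folds = 5, inner_folds = 5, n_lambda = 30, seed = 3)
  fit1 <- nested_cv_elastic_net(feats, y, conf, cfg)
  fit2 <- nested_cv_elastic_net(feats, y, conf, cfg)
  expect_identical(fit1$predictions, fit2$predictions)
  expect_identical(fit1$lambdas, fit2$lambdas)
  expect_lt(sd(fit1$predictions$predicted_oof), sd(y))
})

test_that("constant outcomes and malformed inputs are refused", {
  feats <- noise_features(40, 5)
  conf <- simple_confounds(40)
  expect_error(nested_cv_elastic_net(feats, rep(1, 40), conf), "constant")
  conf_na <- conf
  conf_na$age[1] <- NA
  expect_error(nested_cv_elastic_net(feats, rnorm(40), conf_na), "missing")
  expect_error(nested_cv_elastic_net(feats, rnorm(40), conf,
                                     prediction_config(outer_folds = 25)),
               "outer_folds")
})

test_that("weight stability applies the retention threshold at the boundary", {
  fit <- structure(list(
    weights = matrix(
      c(rep(1, 8), 0, 0, # 8/10 folds
        rep(1, 7), 0, 0, 0, # 7/10 folds
        rep(0, 10)),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("f_keep", "f_drop", "f_zero"), NULL)
    ),
    cfg = prediction_config()
  ), class = "stress_enet")
  st <- weight_stability(fit, threshold = 0.8)
  expect_equal(st$feature, "f_keep")
  expect_equal(st$stability, 0.8)
  all_zero <- weight_stability(fit, threshold = 1e-9)
  expect_false("f_zero" %in% all_zero$feature)
})

test_that("the permutation test is valid under exchangeability and refuses tiny B", {
  n <- 100
  feats <- noise_features(n, 12, seed = 41)
  conf <- simple_confounds(n, seed = 42)
  set.seed(43)
  y <- 0.5 * conf$age / 10 + rnorm(n)
  cfg <- prediction_config(outer_folds = 3, inner_folds = 3, n_lambda = 12,
                           n_perm = 199, seed = 44, thresh = 1e-4)
  pt <- permutation_test(feats, y, conf, cfg)
  expect_length(pt$null_delta_r2, 199)
  expect_gte(pt$p_perm, 1 / 200)
  expect_lte(pt$p_perm, 1)
  # null data: observed statistic sits inside its own null distribution
  expect_gt(pt$p_perm, 0.01)
  expect_error(
    permutation_test(feats, y, conf, prediction_config(n_perm = 50)),
    "100"
  )
})

test_that("permutation detects a strong planted effect", {
  n <- 150
  feats <- noise_features(n, 10, seed = 51)
  conf <- simple_confounds(n, seed = 52)
  set.seed(53)
  x <- as.matrix(feats[-1])[, 3]
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n) # feature-outcome r = 0.5
  cfg <- prediction_config(outer_folds = 5, inner_folds = 3, n_lambda = 20,
                           n_perm = 199, seed = 54, thresh = 1e-5)
  pt <- permutation_test(feats, y, conf, cfg)
  expect_lt(pt$p_perm, 0.05)
  expect_gt(pt$observed_delta_r2, max(pt$null_r2_bounds))
})

test_that("leave-feature-set-out importance isolates the signal group", {
  n <- 160
  feats <- noise_features(n, 12, seed = 61) # 4 groups x 3 features
  set.seed(62)
  sig_cols <- grepl("reg1", names(feats))
  y <- rowSums(as.matrix(feats[sig_cols & names(feats) != "participant_id"])) / 2 +
    rnorm(n)
  conf <- simple_confounds(n, seed = 63)
  cfg <- prediction_config(outer_folds = 5, inner_folds = 3, n_lambda = 30, seed = 64)
  imp <- feature_set_importance(feats, y, conf, cfg)
  expect_equal(nrow(imp), 4)
  expect_equal(imp$group[1], "reg1")
  full_delta <- attr(imp, "r2_full")
  expect_gt(imp$importance[1], 0.5 * full_delta)
  noise_imp <- imp$importance[imp$group != "reg1"]
  expect_lt(max(abs(noise_imp)), 0.1)
  expect_error(
    feature_set_importance(feats, y, conf, cfg, grouping = list(bad = "nope")),
    "unknown"
  )
})

test_that("cross-sex transfer mirrors how the effect was planted", {
  n <- 240
  sex <- rep(c("female", "male"), each = n / 2)
  base <- noise_features(n, 10, seed = 71)
  conf <- simple_confounds(n, seed = 72)
  conf$sex <- sex
  x <- as.matrix(base[-1])[, 1]
  cfg <- prediction_config(outer_folds = 5, inner_folds = 3, n_lambda = 30, seed = 73)
  # shared mechanism: same sign in both sexes
  set.seed(74)
  y_shared <- 0.8 * x + rnorm(n, 0, 0.6)
  tx1 <- cross_sex_transfer(base, y_shared, conf, sex, cfg)
  expect_true(all(tx1$transfer$r > 0))
  # opposite mechanism: sign flips by sex
  set.seed(75)
  y_opp <- ifelse(sex == "female", 1, -1) * x + rnorm(n, 0, 0.6)
  tx2 <- cross_sex_transfer(base, y_opp, conf, sex, cfg)
  expect_true(all(tx2$transfer$r <= 0))
  # stratified results drop sex from the confounds and stay finite
  expect_equal(nrow(tx2$stratified), 2)
  expect_true(all(is.finite(tx2$stratified$r2_full)))
  expect_error(cross_sex_transfer(base, y_shared, conf,
                                  c(rep("female", n - 5), rep("male", 5)), cfg),
               "n < 10")
})

test_that("tidiers and plots summarize fits coherently", {
  n <- 60
  feats <- noise_features(n, 6)
  conf <- simple_confounds(n)
  set.seed(81)
  y <- rnorm(n)
  cfg <- prediction_config(outer_folds = 5, inner_folds = 3, n_lambda = 20, seed = 82)
  fit <- nested_cv_elastic_net(feats, y, conf, cfg)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$delta_r2, fit$delta_r2)
  expect_s3_class(autoplot(fit), "ggplot")
  cfg$n_perm <- 100
  pt <- permutation_test(feats, y, conf, cfg)
  expect_s3_class(autoplot(pt), "ggplot")
  expect_equal(tidy(pt)$p_perm, pt$p_perm)
})
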