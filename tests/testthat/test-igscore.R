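test_that("auc_roc matches the Mann-Whitney definition on the worked examples", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_roc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  # 4 woman-man pairs: 3 wins, 0 ties -> 0.75 (brute oracle agrees)
  s <- c(0.9, 0.4, 0.6, 0.1)
  sex <- c(1, 1, 0, 0)
  expect_equal(auc_roc(s, sex), 0.75)
  expect_equal(auc_roc(s, sex), brute_auc(s, sex))
})

test_that("auc_roc agrees with the exhaustive pairwise oracle, ties included", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sex <- c(0, 1, sample(0:1, n - 2, TRUE))  # both classes guaranteed
    scores <- round(runif(n), sample(1:2, 1)) # rounding forces ties
    expect_equal(auc_roc(scores, sex), brute_auc(scores, sex))
  }
})

test_that("auc_roc requires both classes", {
  expect_error(auc_roc(runif(5), rep(1, 5)), "both sexes")
})

test_that("logistic scores satisfy the calibration identity and the intercept-only case", {
  co <- generate_cohort(soep_like_config(800, seed = 21))
  fit <- fit_logit(co)
  expect_equal(mean(fit$scores), mean(co$sex), tolerance = 1e-6)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  # all covariables constant -> every score is the observed proportion
  df <- make_cohort_df(30, seed = 1)
  sch <- default_covariable_schema()
  for (nm in names(sch)) df[[nm]] <- sch[[nm]]$categories[1]
  co2 <- cohort_table(df)
  fit2 <- fit_logit(co2)
  expect_equal(unname(fit2$scores), rep(mean(co2$sex), 30),
               tolerance = 1e-8)
})

test_that("a covariable identical to sex yields perfect separation", {
  df <- make_cohort_df(60, seed = 2)
  df$sex <- rep(c("man", "woman"), 30)
  df$partner <- ifelse(df$sex == "woman", "yes", "no")
  co <- cohort_table(df)
  fit_g <- fit_igscore_gbm(co, list(n_rounds = 25, bag_fraction = 1,
                                    min_bucket = 5, min_split = 10),
                           seed = 1)
  expect_equal(fit_g$auc, 1.0)
  expect_gt(min(fit_g$scores[co$sex == 1]), max(fit_g$scores[co$sex == 0]))
  expect_warning(fit_l <- fit_igscore_logistic(co), "separation")
  expect_equal(fit_l$auc, 1.0)
  expect_true(fit_l$hyperparameters$separation_fallback)
})

test_that("single-sex cohorts are an estimation error and all-missing covariables are dropped", {
  df <- make_cohort_df(20, seed = 3)
  df$sex <- "man"
  expect_error(fit_igscore_gbm(cohort_table(df)), "each sex")
  df2 <- make_cohort_df(60, seed = 4)
  df2$lonely <- NA
  co <- cohort_table(df2)
  expect_warning(fit <- fit_igscore_gbm(co, list(n_rounds = 10), seed = 1),
                 "lonely")
  expect_identical(fit$dropped, "lonely")
})

test_that("permuting sex labels drives both methods into the null band", {
  co <- generate_cohort(soep_like_config(4000, seed = 31))
  set.seed(99)
  df <- as.data.frame(co)
  df$sex <- sample(df$sex)
  perm <- cohort_table(df)
  # out-of-fold scores: no in-sample optimism, so the band is tight
  fl <- fit_logit(perm, cross_fit = TRUE, seed = 2)
  expect_gt(fl$auc, 0.45)
  expect_lt(fl$auc, 0.55)
  fg <- fit_igscore_gbm(perm, list(n_rounds = 60), seed = 1,
                        cross_fit = TRUE)
  expect_gt(fg$auc, 0.45)
  expect_lt(fg$auc, 0.55)
})

test_that("AUC responds monotonically to the gendering strength", {
  auc_l <- auc_g <- numeric(0)
  for (g in c(0, 0.5, 1, 2)) {
    co <- generate_cohort(synthetic_config(3000, gamma = g, seed = 17))
    auc_l <- c(auc_l, fit_logit(co)$auc)
    auc_g <- c(auc_g, fit_igscore_gbm(co, list(n_rounds = 60),
                                      seed = 1)$auc)
  }
  expect_true(all(diff(auc_l) > -0.02))
  expect_true(all(diff(auc_g) > -0.02))
  expect_gt(auc_l[4], auc_l[1])
  expect_gt(auc_g[4], auc_g[1])
})

test_that("the boosted fit outperforms or matches logistic on the gendered preset", {
  co <- generate_cohort(soep_like_config(4000, seed = 51))
  fl <- fit_logit(co)
  fg <- fit_igscore_gbm(co, list(n_rounds = 100), seed = 1)
  expect_gte(fg$auc, fl$auc - 0.01)
})

test_that("cross-validated round selection picks from the grid deterministically", {
  co <- generate_cohort(soep_like_config(1200, seed = 61))
  fit <- fit_igscore_gbm(co, list(n_rounds = 40, cv_folds = 2,
                                  round_grid = c(10, 20, 40)), seed = 5)
  expect_true(fit$hyperparameters$n_rounds %in% c(10, 20, 40))
  fit2 <- fit_igscore_gbm(co, list(n_rounds = 40, cv_folds = 2,
                                   round_grid = c(10, 20, 40)), seed = 5)
  expect_identical(fit$scores, fit2$scores)
})
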