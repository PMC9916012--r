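test_that("common support applies the min/max rule", {
  scores <- c(a = 0.1, b = 0.3, c = 0.8, d = 0.2, e = 0.5, f = 0.9)
  sex <- c(0, 0, 0, 1, 1, 1)
  sup <- common_support(scores, sex)
  expect_equal(sup$lower, 0.2)
  expect_equal(sup$upper, 0.8)
  expect_identical(sup$n_excluded, 2L)
  expect_setequal(sup$excluded_ids, c("a", "f"))
})

test_that("identical score sets give full overlap and trimming is idempotent", {
  scores <- c(rep(c(0.2, 0.5, 0.7), 2))
  names(scores) <- letters[1:6]
  sex <- rep(0:1, each = 3)
  sup <- common_support(scores, sex)
  expect_identical(sup$n_excluded, 0L)
  # idempotence on a generated cohort: re-applying the recorded trim
  co <- generate_cohort(soep_like_config(2000, seed = 13))
  f <- fit_logit(co)
  sup1 <- common_support(f$scores, co$sex)
  sup2 <- common_support(f$scores[sup1$keep], co$sex[sup1$keep],
                         bounds = sup1)
  expect_identical(sup2$n_excluded, 0L)
  # re-derived bounds can only move inward, never outward
  sup3 <- common_support(f$scores[sup1$keep], co$sex[sup1$keep])
  expect_gte(sup3$lower, sup1$lower)
  expect_lte(sup3$upper, sup1$upper)
})

test_that("empty overlap is an error", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  expect_error(common_support(scores, c(0, 0, 1, 1)), "common support")
  expect_error(common_support(scores, c(0, 0, 0, 0)), "both sexes")
})

test_that("stratify splits into equal blocks in ascending score order", {
  scores <- setNames(seq(0.05, 0.95, by = 0.1), letters[1:10])
  asg <- stratify(scores, 5)
  expect_identical(asg$sizes, rep(2L, 5))
  expect_identical(unname(asg$stratum), rep(1:5, each = 2))
  expect_length(asg$cutpoints, 4L)
  means <- tapply(scores, asg$stratum, mean)
  expect_true(all(diff(means) > 0))
})

test_that("tied scores split deterministically by record id, with a warning", {
  scores <- setNames(rep(0.5, 11), sprintf("r%02d", 1:11))
  expect_warning(asg <- stratify(scores, 4), "tied")
  expect_true(max(asg$sizes) - min(asg$sizes) <= 1L)
  expect_identical(sum(asg$sizes), 11L)
})

test_that("stratification is permutation invariant", {
  co <- generate_cohort(soep_like_config(1500, seed = 23))
  f <- fit_logit(co)
  asg <- quiet_stratify(f$scores, 5)
  set.seed(1)
  perm <- sample(length(f$scores))
  asg2 <- quiet_stratify(f$scores[perm], 5)
  expect_identical(asg$stratum[names(asg2$stratum)], asg2$stratum)
})

test_that("strata partition the sample and respect bounds on K", {
  scores <- setNames(runif(40), sprintf("x%02d", 1:40))
  for (K in c(2, 4, 7)) {
    asg <- quiet_stratify(scores, K)
    expect_identical(sort(names(asg$stratum)), sort(names(scores)))
    expect_identical(sum(asg$sizes), 40L)
    expect_true(max(asg$sizes) - min(asg$sizes) <= 1L)
  }
  expect_error(stratify(scores, 41), "exceed")
  expect_error(stratify(scores, 1), "at least 2")
})

test_that("select_k returns the argmin of imbalanced cells with ties to smaller K", {
  co <- generate_cohort(soep_like_config(2500, seed = 33))
  f <- fit_logit(co)
  tr <- trim_support(co, f$scores)
  sel <- suppressWarnings(select_k(tr$cohort, tr$scores, k_range = 4:7))
  expect_identical(nrow(sel$diagnostics), 4L)
  expect_identical(sel$diagnostics$K, 4:7)
  # independent recomputation of the counts per K
  recount <- vapply(4:7, function(K) {
    asg <- quiet_stratify(tr$scores, K)
    count_imbalanced(quiet_balance(tr$cohort, asg), 0.1, "strata")
  }, integer(1))
  expect_identical(sel$diagnostics$n_imbalanced, recount)
  best <- (4:7)[which.min(recount)]  # which.min breaks ties low
  expect_identical(sel$K, best)
  expect_identical(sel$assignment$K, best)
})

test_that("select_k skips candidates with single-sex strata and errors when none work", {
  df <- make_cohort_df(40, seed = 44)
  df$sex <- rep(c("man", "woman"), each = 20)
  co <- cohort_table(df)
  scores <- setNames(c(seq(0.01, 0.20, length.out = 20),
                       seq(0.80, 0.99, length.out = 20)), co$record_id)
  expect_warning(expect_error(select_k(co, scores, k_range = 4), "feasible"),
                 "fewer than two")
})

test_that("null cohorts make all candidate K equally balanced, tie-break to K = 4", {
  co <- null_cohort(3000, seed = 77)
  f <- fit_logit(co)
  tr <- trim_support(co, f$scores)
  sel <- suppressWarnings(select_k(tr$cohort, tr$scores))
  expect_identical(sel$K,
                   sel$diagnostics$K[which.min(sel$diagnostics$n_imbalanced)])
})
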