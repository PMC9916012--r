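test_that("smd matches a hand-computed oracle and the trivial cases", {
  x_men <- c(1, 1, 0, 0)
  x_women <- c(1, 0, 0, 0)
  ref <- sqrt((var(x_men) + var(x_women)) / 2)   # sqrt((1/3 + 1/4)/2)
  expect_equal(smd(x_men, x_women, ref), (0.5 - 0.25) / ref)
  expect_equal(smd(x_men, x_women, ref),
               smd_oracle(c(x_men, x_women), rep(0:1, each = 4)))
  expect_equal(smd(c(1, 0), c(0, 1), 0.5), 0)
  expect_warning(v <- smd(c(1, 1), c(1, 1), 0), "constant")
  expect_equal(v, 0)
})

test_that("imbalance classification applies the 0.10/0.20 thresholds exactly", {
  cls <- classify_smd(c(0, 0.10, 0.100001, 0.20, 0.200001, 1))
  expect_identical(as.character(cls),
                   c("negligible", "negligible", "low", "low",
                     "unbalanced", "unbalanced"))
})

test_that("balance_table agrees with from-formula recomputation on a small cohort", {
  co <- generate_cohort(soep_like_config(500, seed = 55))
  f <- fit_logit(co)
  asg <- quiet_stratify(f$scores, 3)
  bt <- quiet_balance(co, asg)
  schema <- attr(co, "schema")
  n_cells <- sum(vapply(schema, function(cv) length(cv$categories),
                        integer(1))) * 4L  # total + 3 strata
  expect_identical(nrow(bt), n_cells)
  stratum <- asg$stratum[co$record_id]
  set.seed(8)
  some <- bt[sample(nrow(bt), 60), ]
  for (i in seq_len(nrow(some))) {
    row <- some[i, ]
    ind <- as.numeric(co[[row$covariable]] == row$category)
    ref <- sqrt((var(ind[co$sex == 0], na.rm = TRUE) +
                 var(ind[co$sex == 1], na.rm = TRUE)) / 2)
    rows <- if (row$scope == "total") seq_len(nrow(co)) else
      which(stratum == as.integer(sub("stratum ", "", row$scope)))
    expected <- (mean(ind[rows][co$sex[rows] == 0], na.rm = TRUE) -
                 mean(ind[rows][co$sex[rows] == 1], na.rm = TRUE)) / ref
    expect_equal(row$smd, expected, tolerance = 1e-12)
  }
})

test_that("swapping sex labels negates every SMD", {
  co <- generate_cohort(soep_like_config(600, seed = 66))
  f <- fit_logit(co)
  asg <- quiet_stratify(f$scores, 3)
  bt <- quiet_balance(co, asg)
  df <- as.data.frame(co)
  df$sex <- 1L - df$sex
  co_swapped <- cohort_table(df)
  bt2 <- quiet_balance(co_swapped, asg)
  expect_equal(bt2$smd, -bt$smd, tolerance = 1e-12)
})

test_that("SMDs are invariant to exact duplication of every record", {
  co <- generate_cohort(soep_like_config(300, seed = 88))
  f <- fit_logit(co)
  asg <- quiet_stratify(f$scores, 2)
  bt <- quiet_balance(co, asg)
  df <- as.data.frame(co)
  df2 <- rbind(df, df)
  df2$record_id <- sprintf("d%04d", seq_len(nrow(df2)))
  co2 <- cohort_table(df2)
  scores2 <- setNames(rep(unname(f$scores), 2), co2$record_id)
  asg2 <- quiet_stratify(scores2, 2)
  bt2 <- quiet_balance(co2, asg2)
  # n-1 variances differ slightly between n and 2n; tolerance reflects that
  expect_equal(bt2$smd, bt$smd, tolerance = 0.01)
})

test_that("count_imbalanced counts cells above the threshold in the right scopes", {
  tbl <- data.frame(
    covariable = "v", category = letters[1:4],
    scope = c("total", "stratum 1", "stratum 1", "stratum 2"),
    smd = c(0.5, 0.15, -0.15, 0.05))
  tbl$abs_smd <- abs(tbl$smd)
  tbl$class <- classify_smd(tbl$abs_smd)
  class(tbl) <- c("balance_table", "data.frame")
  expect_identical(count_imbalanced(tbl, 0.1, "strata"), 2L)
  expect_identical(count_imbalanced(tbl, 0.2, "strata"), 0L)
  expect_identical(count_imbalanced(tbl, 0.1, "total"), 1L)
  expect_identical(count_imbalanced(tbl, 0.1, "all"), 3L)
  tbl0 <- tbl
  tbl0$abs_smd <- 0
  expect_identical(count_imbalanced(tbl0, 0.1, "all"), 0L)
})

test_that("single-sex scopes yield NA rows with a warning", {
  df <- make_cohort_df(20, seed = 9)
  df$sex <- c(rep("man", 10), rep("woman", 10))
  co <- cohort_table(df)
  scores <- setNames(c(seq(0.1, 0.28, length.out = 10),
                       seq(0.7, 0.88, length.out = 10)), co$record_id)
  asg <- stratify(scores, 2)
  expect_warning(bt <- balance_table(co, asg), "single sex")
  expect_true(all(is.na(bt$smd[bt$scope != "total"])))
  expect_false(anyNA(bt$smd[bt$scope == "total"]))
})
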