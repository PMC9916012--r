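test_that("prevalence point estimates and exact CIs match the binomial oracle", {
  pe <- prevalence_ci(738, 10654)
  expect_equal(round(pe$prevalence, 2), 6.93)
  oracle <- 100 * binom.test(738, 10654)$conf.int
  expect_equal(c(pe$ci_low, pe$ci_high), as.vector(oracle),
               tolerance = 1e-12)
  # the published male-dominated FMD row, display-rounded
  pe2 <- prevalence_ci(206, 3806)
  expect_equal(round(c(pe2$prevalence, pe2$ci_low, pe2$ci_high), 2),
               c(5.41, 4.72, 6.18))
  pe0 <- prevalence_ci(0, 100)
  expect_equal(pe0$prevalence, 0)
  expect_equal(pe0$ci_low, 0)
  expect_error(prevalence_ci(5, 0), "positive")
  expect_error(prevalence_ci(7, 5), "x")
})

test_that("wilson and wald intervals are available and ordered sensibly", {
  for (m in c("exact", "wilson", "wald")) {
    pe <- prevalence_ci(20, 200, method = m)
    expect_lte(pe$ci_low, pe$prevalence)
    expect_gte(pe$ci_high, pe$prevalence)
  }
})

test_that("diff_proportions reproduces the published FMD contrasts and CIs", {
  # traditional gender group: S1 men vs SK women
  tr <- diff_proportions(206, 3806, 579, 4305)
  expect_equal(round(tr$diff, 2), -8.04)
  expect_equal(round(c(tr$ci_low, tr$ci_high), 2), c(-9.31, -6.77))
  # male-dominated stratum: S1 men vs S1 women
  md <- diff_proportions(206, 3806, 102, 816)
  expect_equal(round(md$diff, 2), -7.09)
  expect_equal(round(c(md$ci_low, md$ci_high), 2), c(-9.54, -4.63))
  expect_true(tr$significant_at_5pct)
})

test_that("diff_proportions is antisymmetric and zero on equal proportions", {
  z <- diff_proportions(30, 300, 10, 100)
  expect_equal(z$diff, 0)
  expect_equal(z$ci_low, -z$ci_high)
  set.seed(12)
  for (i in 1:10) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    x1 <- rbinom(1, n1, 0.2); x2 <- rbinom(1, n2, 0.3)
    a <- diff_proportions(x1, n1, x2, n2)
    b <- diff_proportions(x2, n2, x1, n1)
    expect_equal(a$diff, -b$diff)
    expect_equal(a$ci_low, -b$ci_high, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("the corrected CI contains the uncorrected Wald CI", {
  set.seed(13)
  for (i in 1:10) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    x1 <- rbinom(1, n1, 0.15); x2 <- rbinom(1, n2, 0.25)
    cc <- diff_proportions(x1, n1, x2, n2, correct = TRUE)
    un <- diff_proportions(x1, n1, x2, n2, correct = FALSE)
    expect_lte(cc$ci_low, un$ci_low)
    expect_gte(cc$ci_high, un$ci_high)
  }
})

test_that("p-values agree with first-principles Yates chi-square and prop.test", {
  tables <- list(c(206, 3806, 579, 4305), c(206, 3806, 102, 816),
                 c(30, 322, 102, 816), c(5, 50, 10, 40),
                 c(0, 20, 5, 25), c(12, 12, 3, 30), c(1, 10, 9, 10))
  set.seed(14)
  for (i in 1:8) {
    n1 <- sample(10:400, 1); n2 <- sample(10:400, 1)
    tables[[length(tables) + 1]] <- c(rbinom(1, n1, 0.3), n1,
                                      rbinom(1, n2, 0.1), n2)
  }
  for (tb in tables) {
    d <- diff_proportions(tb[1], tb[2], tb[3], tb[4])
    expect_equal(d$p_value, yates_p_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    pt <- suppressWarnings(prop.test(c(tb[1], tb[3]), c(tb[2], tb[4])))
    expect_equal(d$p_value, pt$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate contrasts are flagged instead of tested", {
  d <- diff_proportions(0, 50, 0, 80)
  expect_true(d$degenerate)
  expect_true(is.na(d$p_value))
  expect_false(d$significant_at_5pct)
  expect_error(diff_proportions(1, 0, 1, 10), "positive")
})

test_that("gender_group_contrasts emits the full scheme with traceable counts", {
  co <- generate_cohort(soep_like_config(2500, seed = 71))
  f <- fit_logit(co)
  tr <- trim_support(co, f$scores)
  asg <- quiet_stratify(tr$scores, 5)
  gc <- gender_group_contrasts(tr$cohort, asg)
  expect_setequal(unique(gc$contrasts$pair), contrast_pairs())
  expect_identical(nrow(gc$contrasts), 28L)  # 7 pairs x 4 indicators
  # counts trace back to countable cohort rows, per-indicator denominators
  stratum <- asg$stratum[tr$cohort$record_id]
  for (ind in outcome_names()) {
    y <- tr$cohort[[ind]]
    men1 <- tr$cohort$sex == 0 & stratum == 1 & !is.na(y)
    row <- gc$contrasts[gc$contrasts$indicator == ind &
                        gc$contrasts$pair == "male_dominated", ]
    expect_identical(row$x1, sum(y[men1]))
    expect_identical(row$n1, sum(men1))
    prev <- gc$prevalence[gc$prevalence$indicator == ind &
                          gc$prevalence$group == "S1_men", ]
    expect_identical(prev$x, as.integer(row$x1))
    expect_identical(prev$n, as.integer(row$n1))
  }
})

test_that("contrasts touching an empty cell are skipped with a warning", {
  df <- make_cohort_df(60, seed = 73)
  df$sex <- rep(c("man", "woman"), each = 30)
  co <- cohort_table(df)
  # S1 mixes sexes; the top stratum of 20 is all women -> SK_men empty
  scores <- setNames(c(seq(0.10, 0.60, length.out = 30),
                       seq(0.12, 0.30, length.out = 10),
                       seq(0.70, 0.95, length.out = 20)), co$record_id)
  asg <- stratify(scores, 3)
  w <- capture_warnings(
    gc <- gender_group_contrasts(co, asg, indicators = "fmd"))
  expect_true(any(grepl("empty group", w)))
  expect_false("female_dominated" %in% gc$contrasts$pair)
  expect_false("non_traditional" %in% gc$contrasts$pair)
  expect_true(all(c("male_dominated", "traditional", "women_S1_vs_SK") %in%
                  gc$contrasts$pair))
})

test_that("display formatting follows the rounded-before-differencing convention", {
  co <- generate_cohort(soep_like_config(1200, seed = 75))
  f <- fit_logit(co)
  tr <- trim_support(co, f$scores)
  asg <- quiet_stratify(tr$scores, 4)
  gc <- gender_group_contrasts(tr$cohort, asg)
  disp <- format_contrast_table(gc)
  expect_equal(disp$diff_display,
               round(100 * disp$x1 / disp$n1, 2) -
                 round(100 * disp$x2 / disp$n2, 2),
               tolerance = 1e-9)
  raw <- format_contrast_table(gc, diff_from_rounded = FALSE)
  expect_equal(raw$diff_display, round(raw$diff, 2), tolerance = 1e-9)
})
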