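# shared fixtures and independent oracles, built in code

# a small valid raw cohort data.frame (character columns, as read from CSV)
make_cohort_df <- function(n = 6L, seed = 42L) {
  set.seed(seed)
  schema <- default_covariable_schema()
  df <- data.frame(record_id = sprintf("p%03d", seq_len(n)),
                   sex = sample(c("man", "woman"), n, TRUE),
                   stringsAsFactors = FALSE)
  for (nm in names(schema)) {
    df[[nm]] <- sample(schema[[nm]]$categories, n, TRUE)
  }
  for (oc in outcome_names()) df[[oc]] <- sample(0:1, n, TRUE)
  df
}

# exhaustive pairwise AUC oracle (ties count half)
brute_auc <- function(scores, sex) {
  w <- scores[sex == 1]
  m <- scores[sex == 0]
  tot <- 0
  for (a in w) for (b in m) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(w) * length(m))
}

# SMD oracle straight from the formula, with explicit n-1 variances
smd_oracle <- function(ind, sex) {
  xm <- ind[sex == 0]
  xw <- ind[sex == 1]
  ref <- sqrt((stats::var(xm, na.rm = TRUE) + stats::var(xw, na.rm = TRUE)) / 2)
  (mean(xm, na.rm = TRUE) - mean(xw, na.rm = TRUE)) / ref
}

# first-principles Yates chi-square p-value for a 2x2 table of
# successes/failures (classic margin formula)
yates_p_oracle <- function(x1, n1, x2, n2) {
  a <- as.numeric(x1); b <- as.numeric(n1 - x1)
  c <- as.numeric(x2); d <- as.numeric(n2 - x2)
  n <- a + b + c + d
  num <- n * (max(0, abs(a * d - b * c) - n / 2))^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stats::pchisq(num / den, df = 1, lower.tail = FALSE)
}

quiet_stratify <- function(...) suppressWarnings(stratify(...))
quiet_balance <- function(...) suppressWarnings(balance_table(...))

fit_logit <- function(cohort, ...) suppressWarnings(
  fit_igscore_logistic(cohort, ...))

# trim a cohort to the support of a fit, returning cohort + scores
trim_support <- function(cohort, scores) {
  sup <- common_support(scores, cohort$sex)
  list(cohort = cohort[sup$keep, ], scores = scores[sup$keep],
       support = sup)
}
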