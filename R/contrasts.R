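#' Prevalence with a 95% confidence interval
#'
#' Point estimate is `100 * x / n` percent; the default interval is the
#' exact binomial (Clopper-Pearson) interval, which matched published
#' reference intervals on spot checks; Wilson and Wald are available.
#'
#' @param x event count.
#' @param n denominator (> 0).
#' @param conf confidence level, default 0.95.
#' @param method `"exact"`, `"wilson"` or `"wald"`.
#' @param group optional group label.
#' @return an object of class `prevalence_estimate`: `group`, `x`, `n`,
#'   `prevalence`, `ci_low`, `ci_high` (all percentages at full precision).
#' @export
prevalence_ci <- function(x, n, conf = 0.95, method = "exact",
                          group = NULL) {
  method <- match.arg(method, c("exact", "wilson", "wald"))
  x <- as.numeric(x)
  n <- as.numeric(n)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (x < 0 || x > n) stop("`x` must lie in [0, n]", call. = FALSE)
  p <- x / n
  ci <- switch(method,
    exact = as.vector(stats::binom.test(x, n, conf.level = conf)$conf.int),
    wilson = as.vector(stats::prop.test(x, n, conf.level = conf,
                                        correct = FALSE)$conf.int),
    wald = {
      z <- stats::qnorm(1 - (1 - conf) / 2)
      se <- sqrt(p * (1 - p) / n)
      c(max(0, p - z * se), min(1, p + z * se))
    })
  structure(list(group = group, x = as.integer(x), n = as.integer(n),
                 prevalence = 100 * p, ci_low = 100 * ci[1L],
                 ci_high = 100 * ci[2L], conf = conf, method = method),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%s%.2f%% (%d/%d) [%.2f, %.2f]\n",
              if (is.null(x$group)) "" else paste0(x$group, ": "),
              x$prevalence, x$x, x$n, x$ci_low, x$ci_high))
  invisible(x)
}

#' Difference of two proportions with continuity correction
#'
#' Computes `diff = 100 * (x1/n1 - x2/n2)` percentage points, the Wald
#' interval with Yates continuity correction
#' `diff +/- 100 * (z * sqrt(p1 q1 / n1 + p2 q2 / n2) + (1/n1 + 1/n2) / 2)`,
#' and the p-value of the chi-square test for equality of two proportions
#' with continuity correction (one degree of freedom) — the classical
#' `prop.test` procedure, implemented from the formulas.
#'
#' @param x1,n1 events and denominator of group A.
#' @param x2,n2 events and denominator of group B.
#' @param conf confidence level.
#' @param correct apply the continuity correction (default `TRUE`).
#' @param pair optional contrast label.
#' @param indicator optional indicator name.
#' @return an object of class `contrast_result`: `pair`, `indicator`,
#'   `diff`, `ci_low`, `ci_high` (percentage points), `p_value`,
#'   `significant_at_5pct`, `degenerate`, plus the input counts.
#' @export
diff_proportions <- function(x1, n1, x2, n2, conf = 0.95, correct = TRUE,
                             pair = NULL, indicator = NULL) {
  x1 <- as.numeric(x1); n1 <- as.numeric(n1)
  x2 <- as.numeric(x2); n2 <- as.numeric(n2)
  if (n1 <= 0 || n2 <= 0) stop("denominators must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("counts must lie within their denominators", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  delta <- p1 - p2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  width <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (correct) width <- width + (1 / n1 + 1 / n2) / 2
  ci <- c(max(-1, delta - width), min(1, delta + width))
  degenerate <- (x1 == 0 && x2 == 0) || (x1 == n1 && x2 == n2)
  p_value <- if (degenerate) NA_real_ else
    yates_chisq_p(x1, n1, x2, n2, correct = correct)
  structure(list(pair = pair, indicator = indicator,
                 x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                 diff = 100 * delta, ci_low = 100 * ci[1L],
                 ci_high = 100 * ci[2L], p_value = p_value,
                 significant_at_5pct = !is.na(p_value) && p_value < 0.05,
                 degenerate = degenerate, conf = conf, correct = correct),
            class = "contrast_result")
}

# chi-square test for equality of two proportions (df = 1) from the 2x2
# table of successes/failures, with Yates correction capped at |O - E|
yates_chisq_p <- function(x1, n1, x2, n2, correct = TRUE) {
  O <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) return(NA_real_)
  cc <- if (correct) min(0.5, abs(O - E)) else 0
  stat <- sum((abs(O - E) - cc)^2 / E)
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("%s%s%+.2f pp [%.2f, %.2f], p = %s%s\n",
              if (is.null(x$pair)) "" else paste0(x$pair, " "),
              if (is.null(x$indicator)) "" else paste0(x$indicator, ": "),
              x$diff, x$ci_low, x$ci_high,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value,
                                                          digits = 3),
              if (isTRUE(x$significant_at_5pct)) " *" else ""))
  invisible(x)
}

#' Pair labels of the gender-group contrast scheme
#'
#' S1 is the male-dominated (lowest-score) stratum and SK the
#' female-dominated (highest-score) stratum. "Traditional gender" compares
#' S1 men with SK women (stereotype-concordant profiles), "non-traditional"
#' SK men with S1 women (stereotype-discordant). Group A - group B order:
#' men minus women for the sex contrasts, S1 minus SK otherwise.
#'
#' @return character vector of the seven pair labels.
#' @export
contrast_pairs <- function() {
  c("full_sample", "traditional", "male_dominated", "female_dominated",
    "non_traditional", "women_S1_vs_SK", "men_S1_vs_SK")
}

#' Full gender-group prevalence panel and contrast scheme
#'
#' For each health indicator, prevalence (with exact binomial CIs) is
#' estimated for men and women in the full trimmed sample, the
#' male-dominated stratum (S1) and the female-dominated stratum (SK), using
#' per-indicator denominators (records with a non-missing indicator value).
#' The seven contrasts of [contrast_pairs()] are then computed with
#' [diff_proportions()]. Contrasts touching an empty cell are skipped with
#' a warning.
#'
#' @param cohort a (trimmed) `cohort_table`.
#' @param assignment a `stratum_assignment` covering `cohort`.
#' @param indicators indicator names, default all four.
#' @param conf confidence level.
#' @param ci_method prevalence CI method, see [prevalence_ci()].
#' @return an object of class `gender_contrasts`: `prevalence` (data.frame
#'   panel), `contrasts` (data.frame, one row per pair x indicator), and
#'   the underlying `contrast_result` objects in `$details`.
#' @export
gender_group_contrasts <- function(cohort, assignment,
                                   indicators = outcome_names(),
                                   conf = 0.95, ci_method = "exact") {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(assignment, "stratum_assignment"))
  idx <- match(cohort$record_id, names(assignment$stratum))
  if (anyNA(idx)) {
    stop("assignment does not cover every cohort record", call. = FALSE)
  }
  stratum <- unname(assignment$stratum[idx])
  K <- assignment$K
  groups <- list(
    full_men = cohort$sex == 0L,
    full_women = cohort$sex == 1L,
    S1_men = cohort$sex == 0L & stratum == 1L,
    S1_women = cohort$sex == 1L & stratum == 1L,
    SK_men = cohort$sex == 0L & stratum == K,
    SK_women = cohort$sex == 1L & stratum == K
  )
  pair_def <- list(
    full_sample = c("full_men", "full_women"),
    traditional = c("S1_men", "SK_women"),
    male_dominated = c("S1_men", "S1_women"),
    female_dominated = c("SK_men", "SK_women"),
    non_traditional = c("SK_men", "S1_women"),
    women_S1_vs_SK = c("S1_women", "SK_women"),
    men_S1_vs_SK = c("S1_men", "SK_men")
  )
  prev_rows <- list()
  contrast_rows <- list()
  details <- list()
  for (ind in indicators) {
    y <- cohort[[ind]]
    counts <- lapply(groups, function(g) {
      obs <- g & !is.na(y)
      c(x = sum(y[obs]), n = sum(obs))
    })
    for (gname in names(counts)) {
      ct <- counts[[gname]]
      if (ct["n"] == 0L) next
      pe <- prevalence_ci(ct["x"], ct["n"], conf = conf, method = ci_method,
                          group = gname)
      prev_rows[[length(prev_rows) + 1L]] <- data.frame(
        indicator = ind, group = gname, x = pe$x, n = pe$n,
        prevalence = pe$prevalence, ci_low = pe$ci_low,
        ci_high = pe$ci_high, stringsAsFactors = FALSE)
    }
    for (pair in names(pair_def)) {
      a <- counts[[pair_def[[pair]][1L]]]
      b <- counts[[pair_def[[pair]][2L]]]
      if (a["n"] == 0L || b["n"] == 0L) {
        warning("contrast ", pair, " (", ind,
                ") skipped: empty group", call. = FALSE)
        next
      }
      cr <- diff_proportions(a["x"], a["n"], b["x"], b["n"], conf = conf,
                             pair = pair, indicator = ind)
      details[[paste(pair, ind, sep = ".")]] <- cr
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        indicator = ind, pair = pair,
        x1 = as.integer(cr$x1), n1 = as.integer(cr$n1),
        x2 = as.integer(cr$x2), n2 = as.integer(cr$n2),
        diff = cr$diff, ci_low = cr$ci_low, ci_high = cr$ci_high,
        p_value = cr$p_value,
        significant_at_5pct = cr$significant_at_5pct,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(prevalence = do.call(rbind, prev_rows),
                 contrasts = do.call(rbind, contrast_rows),
                 details = details, K = K),
            class = "gender_contrasts")
}

#' Format a contrast table for display
#'
#' Rounds to two decimals (half-up). With `diff_from_rounded = TRUE` (the
#' default) the displayed difference is the difference of the *displayed*
#' (2-decimal) prevalences, so a printed prevalence panel and its contrast
#' table are internally consistent for the reader — the convention observed
#' in published reference tables. Internal values remain full precision.
#'
#' @param gc a `gender_contrasts` object.
#' @param diff_from_rounded logical, see above.
#' @return data.frame with display columns appended.
#' @export
format_contrast_table <- function(gc, diff_from_rounded = TRUE) {
  stopifnot(inherits(gc, "gender_contrasts"))
  ct <- gc$contrasts
  if (diff_from_rounded) {
    ct$diff_display <- round_half_up(100 * ct$x1 / ct$n1, 2L) -
      round_half_up(100 * ct$x2 / ct$n2, 2L)
  } else {
    ct$diff_display <- round_half_up(ct$diff, 2L)
  }
  ct$ci_display <- sprintf("[%.2f, %.2f]", round_half_up(ct$ci_low, 2L),
                           round_half_up(ct$ci_high, 2L))
  ct
}

# round half away from zero at `digits` decimals (display convention)
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' @export
print.gender_contrasts <- function(x, ...) {
  cat(sprintf("<gender_contrasts> K = %d; %d prevalence rows, %d contrasts\n",
              x$K, nrow(x$prevalence), nrow(x$contrasts)))
  invisible(x)
}
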