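#' Standardized mean difference between men and women
#'
#' `smd` computes `(mean(men) - mean(women)) / sd_reference` for a numeric
#' (typically 0/1 category-indicator) variable, excluding missing values
#' pairwise. The reference standard deviation is supplied by the caller —
#' by convention `sqrt((s2_men + s2_women) / 2)` computed once on the full
#' trimmed sample — so stratum-level SMDs stay comparable across scopes.
#'
#' @param x_men,x_women numeric values for men and women.
#' @param sd_reference positive standard deviation used as denominator.
#' @return signed SMD; 0 (with a warning) when `sd_reference` is 0.
#' @export
smd <- function(x_men, x_women, sd_reference) {
  if (is.na(sd_reference) || sd_reference <= 0) {
    warning("constant indicator: SMD defined as 0", call. = FALSE)
    return(0)
  }
  (mean(x_men, na.rm = TRUE) - mean(x_women, na.rm = TRUE)) / sd_reference
}

#' Pooled reference standard deviation of an indicator
#'
#' @param x indicator values.
#' @param sex 0/1 vector.
#' @return `sqrt((s2_men + s2_women)/2)` with the usual n-1 variances.
#' @export
pooled_sd <- function(x, sex) {
  v_m <- stats::var(x[sex == 0L], na.rm = TRUE)
  v_w <- stats::var(x[sex == 1L], na.rm = TRUE)
  sqrt((v_m + v_w) / 2)
}

#' Classify imbalance of an absolute SMD
#'
#' Thresholds: |SMD| <= 0.10 negligible, 0.10 < |SMD| <= 0.20 low,
#' |SMD| > 0.20 unbalanced.
#'
#' @param abs_smd absolute SMD values.
#' @return factor with levels negligible, low, unbalanced.
#' @export
classify_smd <- function(abs_smd) {
  cut(abs_smd, breaks = c(-Inf, 0.10, 0.20, Inf),
      labels = c("negligible", "low", "unbalanced"))
}

#' Covariable balance between men and women, overall and per stratum
#'
#' Every covariable category is expanded to a 0/1 indicator (no omitted
#' reference category, matching per-category reporting) and its SMD is
#' computed in the total trimmed sample and within each stratum, always
#' standardised by the full-sample pooled SD of that indicator. Records with
#' a missing value on a covariable are excluded from that covariable's
#' indicators only. Scopes containing a single sex yield `NA` rows with a
#' warning.
#'
#' @param cohort a `cohort_table` (trimmed to the analysis sample).
#' @param assignment a `stratum_assignment` covering `cohort` (matched by
#'   record id).
#' @return an object of class `balance_table`: a data.frame with columns
#'   `covariable`, `category`, `scope` ("total" or "stratum k"), `smd`,
#'   `abs_smd`, `class`.
#' @export
balance_table <- function(cohort, assignment) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(assignment, "stratum_assignment"))
  idx <- match(cohort$record_id, names(assignment$stratum))
  if (anyNA(idx)) {
    stop("assignment does not cover every cohort record", call. = FALSE)
  }
  stratum <- unname(assignment$stratum[idx])
  K <- assignment$K
  schema <- attr(cohort, "schema")
  sex <- cohort$sex
  scopes <- c("total", paste("stratum", seq_len(K)))
  scope_rows <- c(list(seq_len(nrow(cohort))),
                  lapply(seq_len(K), function(k) which(stratum == k)))
  one_sex <- vapply(scope_rows,
                    function(r) length(unique(sex[r])) < 2L, logical(1))
  if (any(one_sex)) {
    warning("scope(s) with a single sex: ",
            paste(scopes[one_sex], collapse = ", "),
            "; SMD undefined there", call. = FALSE)
  }
  rows <- list()
  for (nm in names(schema)) {
    f <- cohort[[nm]]
    for (cat in schema[[nm]]$categories) {
      ind <- as.numeric(f == cat)  # NA propagates (pairwise deletion)
      sd_ref <- pooled_sd(ind, sex)
      for (s in seq_along(scopes)) {
        r <- scope_rows[[s]]
        val <- if (one_sex[s] || is.na(sd_ref)) NA_real_ else {
          if (sd_ref <= 0) 0 else
            suppressWarnings(smd(ind[r][sex[r] == 0L],
                                 ind[r][sex[r] == 1L], sd_ref))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(covariable = nm, category = cat, scope = scopes[s],
                     smd = val, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$abs_smd <- abs(out$smd)
  out$class <- classify_smd(out$abs_smd)
  class(out) <- c("balance_table", "data.frame")
  attr(out, "K") <- K
  out
}

#' Count imbalanced balance-table cells
#'
#' @param table a `balance_table`.
#' @param threshold count cells with |SMD| strictly above this value.
#' @param scopes `"strata"` (stratum scopes only, the criterion used to
#'   select K), `"total"`, or `"all"`.
#' @return integer count (NA cells are not counted).
#' @export
count_imbalanced <- function(table, threshold = 0.1, scopes = "strata") {
  scopes <- match.arg(scopes, c("strata", "total", "all"))
  sel <- switch(scopes,
                strata = table$scope != "total",
                total = table$scope == "total",
                all = rep(TRUE, nrow(table)))
  sum(table$abs_smd[sel] > threshold, na.rm = TRUE)
}

#' @export
print.balance_table <- function(x, ...) {
  tab <- table(x$scope, x$class, useNA = "no")
  cat(sprintf("<balance_table> %d cells over %d scopes\n",
              nrow(x), length(unique(x$scope))))
  print(tab)
  invisible(x)
}
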