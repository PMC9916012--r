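#' Common-support trimming of the score distribution
#'
#' The region of common support is the closed score interval where both
#' sexes have observations: `lower` is the larger of the two sex-specific
#' minima and `upper` the smaller of the two maxima. Records strictly
#' outside `[lower, upper]` have a covariable combination that (within the
#' sample) identifies their sex with certainty and are excluded before
#' stratification.
#'
#' The trim is a one-pass rule: bounds are derived once and applied once
#' (iterating the derivation to a fixed point can cascade and empty small
#' samples). Re-applying the *same* trim is idempotent: pass the recorded
#' `bounds` to exclude no one from an already-trimmed sample.
#'
#' @param scores numeric scores, named by record id (names optional).
#' @param sex 0/1 vector (1 = woman).
#' @param bounds optional `support_bounds` (or `c(lower, upper)`) to apply
#'   instead of deriving new bounds from `scores`.
#' @return an object of class `support_bounds`: `lower`, `upper`,
#'   `n_excluded`, `excluded_ids`, `keep` (logical vector).
#' @export
common_support <- function(scores, sex, bounds = NULL) {
  stopifnot(length(scores) == length(sex))
  sex <- as.integer(sex)
  if (!any(sex == 0L) || !any(sex == 1L)) {
    stop("common support needs both sexes present", call. = FALSE)
  }
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  if (!is.null(bounds)) {
    lower <- if (inherits(bounds, "support_bounds")) bounds$lower else
      bounds[1L]
    upper <- if (inherits(bounds, "support_bounds")) bounds$upper else
      bounds[2L]
  } else {
    lower <- max(min(scores[sex == 0L]), min(scores[sex == 1L]))
    upper <- min(max(scores[sex == 0L]), max(scores[sex == 1L]))
  }
  if (lower > upper) {
    stop("empty region of common support: the score separates the sexes ",
         "completely; consider fewer or weaker covariables", call. = FALSE)
  }
  keep <- scores >= lower & scores <= upper
  structure(list(lower = lower, upper = upper,
                 n_excluded = sum(!keep),
                 excluded_ids = ids[!keep], keep = keep),
            class = "support_bounds")
}

#' @export
print.support_bounds <- function(x, ...) {
  cat(sprintf("<support_bounds> [%.4f, %.4f], %d record(s) excluded\n",
              x$lower, x$upper, x$n_excluded))
  invisible(x)
}

#' Partition records into K equal-size score strata
#'
#' Records are sorted by `(score, record_id)` (the stable tie-break makes
#' the record-to-stratum map independent of input order) and split into `K`
#' contiguous blocks whose sizes differ by at most one. Stratum 1 holds the
#' lowest scores (the "male-dominated" end), stratum `K` the highest
#' ("female-dominated").
#'
#' @param scores numeric scores named by record id.
#' @param K integer number of strata (>= 2).
#' @return an object of class `stratum_assignment`: `K`, `cutpoints` (K-1
#'   boundary scores), `stratum` (integer 1..K named by record id, in input
#'   order), `sizes`.
#' @export
stratify <- function(scores, K) {
  K <- as.integer(K)
  n <- length(scores)
  if (K < 2L) stop("`K` must be at least 2", call. = FALSE)
  if (K > n) stop("`K` cannot exceed the number of records", call. = FALSE)
  ids <- names(scores)
  if (is.null(ids)) ids <- sprintf("%d", seq_len(n))
  ord <- order(scores, ids, method = "radix")
  stratum_sorted <- as.integer(ceiling(seq_len(n) * K / n))
  cut_idx <- vapply(seq_len(K - 1L),
                    function(k) max(which(stratum_sorted == k)), integer(1))
  cutpoints <- scores[ord][cut_idx]
  if (any(scores[ord][cut_idx] == scores[ord][cut_idx + 1L])) {
    warning("tied scores span a stratum boundary; ties were broken by ",
            "record_id", call. = FALSE)
  }
  stratum <- integer(n)
  stratum[ord] <- stratum_sorted
  names(stratum) <- ids
  structure(list(K = K, cutpoints = unname(cutpoints), stratum = stratum,
                 sizes = tabulate(stratum, K)),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat(sprintf("<stratum_assignment> K = %d, sizes: %s\n", x$K,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Select the number of strata by balance diagnostics
#'
#' For each candidate `K` the cohort is stratified on the scores and the
#' number of covariable-category-by-stratum cells with |SMD| > `threshold`
#' is counted ([count_imbalanced()], stratum scopes only). The `K` with the
#' fewest imbalanced cells wins; ties go to the smaller `K`. Candidates with
#' any stratum containing fewer than two records of either sex are skipped
#' with a warning.
#'
#' @param cohort a (trimmed) `cohort_table`.
#' @param scores numeric scores named by record id, aligned with `cohort`.
#' @param k_range integer candidates, default `4:7`.
#' @param threshold imbalance threshold on |SMD|, default 0.1.
#' @return an object of class `k_selection`: `K` (the winner),
#'   `diagnostics` (one row per candidate), `assignment` (the winning
#'   `stratum_assignment`).
#' @export
select_k <- function(cohort, scores, k_range = 4:7, threshold = 0.1) {
  stopifnot(inherits(cohort, "cohort_table"),
            length(scores) == nrow(cohort))
  diag <- data.frame(K = as.integer(k_range), feasible = NA,
                     n_imbalanced = NA_integer_)
  assignments <- list()
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    asg <- stratify(scores, K)
    counts <- table(factor(asg$stratum, levels = seq_len(K)), cohort$sex)
    if (ncol(counts) < 2L || any(counts < 2L)) {
      warning("K = ", K, " skipped: a stratum has fewer than two records ",
              "of one sex", call. = FALSE)
      diag$feasible[i] <- FALSE
      next
    }
    bt <- balance_table(cohort, asg)
    diag$feasible[i] <- TRUE
    diag$n_imbalanced[i] <- count_imbalanced(bt, threshold = threshold,
                                             scopes = "strata")
    assignments[[as.character(K)]] <- asg
  }
  if (!any(diag$feasible, na.rm = TRUE)) {
    stop("no candidate K is feasible", call. = FALSE)
  }
  ok <- which(diag$feasible)
  best <- ok[which.min(diag$n_imbalanced[ok])]  # which.min ties -> first
  structure(list(K = diag$K[best], diagnostics = diag,
                 assignment = assignments[[as.character(diag$K[best])]]),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> K* = %d\n", x$K))
  print(x$diagnostics)
  invisible(x)
}
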