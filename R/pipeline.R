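#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: input (a cohort CSV path,
#' a preset name `"soep_like"`/`"null"`, or a [synthetic_config()]), score
#' method, hyperparameters, number of strata (`"auto"` selects from
#' `k_range` by balance diagnostics), prevalence CI method, output
#' directory and seed. The seed is recorded in every output artifact.
#'
#' @param input cohort CSV path, preset name, or `synthetic_config`.
#' @param n cohort size when `input` is a preset name.
#' @param method `"gbm"` or `"logistic"`.
#' @param hyperparameters passed to [fit_igscore_gbm()].
#' @param k `"auto"` or a fixed integer number of strata.
#' @param k_range candidates for automatic selection.
#' @param ci_method prevalence CI method.
#' @param out_dir output directory, or `NULL` for no files.
#' @param seed integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "soep_like", n = 23000,
                            method = c("gbm", "logistic"),
                            hyperparameters = list(), k = "auto",
                            k_range = 4:7, ci_method = "exact",
                            out_dir = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.character(input) && !file.exists(input) &&
      !input %in% c("soep_like", "null")) {
    stop("`input` must be an existing CSV file, \"soep_like\", \"null\" ",
         "or a synthetic_config", call. = FALSE)
  }
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (is.na(k) || k < 2L) stop("`k` must be \"auto\" or >= 2", call. = FALSE)
  }
  structure(list(input = input, n = as.integer(n), method = method,
                 hyperparameters = hyperparameters, k = k,
                 k_range = as.integer(k_range), ci_method = ci_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Load or generate the cohort, estimate the intersectional gender-score,
#' trim to common support, choose and apply the stratification, assess
#' covariable balance, and compute the prevalence panel and gender-group
#' contrasts. Counts are logged at every filtering step so the sample
#' accounting (input n, trimmed n, per-stratum n) is auditable, and when
#' records are trimmed their covariable profile is summarised (the trimmed
#' group is a substantive output, not waste). All tabular artifacts are
#' written as CSV and metadata as JSON under `config$out_dir` when set.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list bundle: `cohort`, `fit`, `support`,
#'   `trimmed`, `assignment`, `k_selection`, `balance`, `contrasts`,
#'   `distribution`, `excluded_profile`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[igscore] ", sprintf(...))
  cohort <- if (inherits(config$input, "synthetic_config")) {
    generate_cohort(config$input, seed = config$seed)
  } else if (config$input %in% c("soep_like", "null")) {
    cfg <- if (config$input == "null") null_config(config$n, config$seed)
           else soep_like_config(config$n, seed = config$seed)
    generate_cohort(cfg)
  } else {
    load_cohort(config$input)
  }
  say("input cohort: n = %d (%.1f%% women)", nrow(cohort),
      100 * mean(cohort$sex))

  fit <- if (config$method == "gbm") {
    fit_igscore_gbm(cohort, config$hyperparameters, seed = config$seed)
  } else {
    fit_igscore_logistic(cohort, seed = config$seed)
  }
  say("%s score fitted, in-sample AUC-ROC = %.4f", config$method, fit$auc)

  support <- common_support(fit$scores, cohort$sex)
  say("common support [%.4f, %.4f]: %d excluded, analysis n = %d",
      support$lower, support$upper, support$n_excluded,
      nrow(cohort) - support$n_excluded)
  trimmed <- cohort[support$keep, , drop = FALSE]
  attr(trimmed, "schema") <- attr(cohort, "schema")
  class(trimmed) <- class(cohort)
  tscores <- fit$scores[support$keep]
  excl_profile <- if (support$n_excluded > 0) {
    excluded_profile(cohort, support)
  } else NULL

  ksel <- NULL
  if (identical(config$k, "auto")) {
    ksel <- select_k(trimmed, tscores, k_range = config$k_range)
    assignment <- ksel$assignment
    say("selected K = %d (imbalanced cells: %s)", ksel$K,
        paste(ksel$diagnostics$n_imbalanced, collapse = ", "))
  } else {
    assignment <- stratify(tscores, config$k)
  }
  bal <- balance_table(trimmed, assignment)
  gc <- gender_group_contrasts(trimmed, assignment,
                               ci_method = config$ci_method)
  dist <- score_distribution_summary(fit$scores, cohort$sex)

  stab <- table(factor(assignment$stratum[match(trimmed$record_id,
                                                names(assignment$stratum))],
                       levels = seq_len(assignment$K)), trimmed$sex)
  p_men <- stab[, "0"] / rowSums(stab)
  summary_text <- c(
    sprintf("seed: %d", config$seed),
    sprintf("input n: %d; excluded (no common support): %d; analysis n: %d",
            nrow(cohort), support$n_excluded, nrow(trimmed)),
    sprintf("K = %d strata; sizes: %s", assignment$K,
            paste(assignment$sizes, collapse = ", ")),
    sprintf("male-dominated stratum S1: %.0f%% men, %.0f%% women",
            100 * p_men[1L], 100 * (1 - p_men[1L])),
    sprintf("female-dominated stratum S%d: %.0f%% men, %.0f%% women",
            assignment$K, 100 * p_men[assignment$K],
            100 * (1 - p_men[assignment$K])))
  if (!quiet) for (ln in summary_text) message("[igscore] ", ln)

  manifest <- list(
    package_version = as.character(utils::packageVersion("igscore")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = config[c("input", "n", "method", "k", "ci_method")],
    input_n = nrow(cohort), n_excluded = support$n_excluded,
    analysis_n = nrow(trimmed), K = assignment$K,
    stratum_sizes = assignment$sizes)
  manifest$config$input <- if (inherits(config$input, "synthetic_config"))
    "synthetic_config" else config$input
  manifest$config_hash <- config_hash(manifest$config)

  bundle <- list(cohort = cohort, fit = fit, support = support,
                 trimmed = trimmed, assignment = assignment,
                 k_selection = ksel, balance = bal, contrasts = gc,
                 distribution = dist, excluded_profile = excl_profile,
                 manifest = manifest, summary = summary_text)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     na = "")
  }
  w(data.frame(record_id = names(bundle$fit$scores),
               score = unname(bundle$fit$scores),
               sex = bundle$cohort$sex), "scores.csv")
  w(data.frame(record_id = names(bundle$assignment$stratum),
               stratum = unname(bundle$assignment$stratum)),
    "assignment.csv")
  w(as.data.frame(unclass(bundle$balance)), "balance.csv")
  w(bundle$contrasts$prevalence, "prevalence.csv")
  w(format_contrast_table(bundle$contrasts), "contrasts.csv")
  w(bundle$distribution, "score_distribution.csv")
  if (!is.null(bundle$excluded_profile)) {
    w(bundle$excluded_profile, "excluded_profile.csv")
  }
  if (!is.null(bundle$k_selection)) {
    w(bundle$k_selection$diagnostics, "k_diagnostics.csv")
  }
  support <- bundle$support[c("lower", "upper", "n_excluded",
                              "excluded_ids")]
  jsonlite::write_json(support, file.path(out_dir, "support.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(bundle$summary, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Binned score distribution by sex and overlap coefficient
#'
#' Bins the scores of men and women into `bins` equal-width bins over
#' `[0, 1]` and reports the overlap coefficient: the sum of bin-wise minima
#' of the two normalised binned densities (1 = identical distributions,
#' 0 = disjoint supports). This is the tabular counterpart of the usual
#' density-plot inspection of score overlap.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param sex 0/1 vector.
#' @param bins number of bins, default 50.
#' @return data.frame (`bin`, `lower`, `upper`, `n_men`, `n_women`,
#'   `d_men`, `d_women`) with the overlap coefficient in
#'   `attr(, "overlap")`.
#' @export
score_distribution_summary <- function(scores, sex, bins = 50L) {
  stopifnot(length(scores) == length(sex))
  sex <- as.integer(sex)
  if (!any(sex == 0L) || !any(sex == 1L)) {
    stop("both sexes must be present", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(scores, breaks, rightmost.closed = TRUE),
                   1L), bins)
  n_men <- tabulate(idx[sex == 0L], bins)
  n_women <- tabulate(idx[sex == 1L], bins)
  d_men <- n_men / sum(n_men)
  d_women <- n_women / sum(n_women)
  out <- data.frame(bin = seq_len(bins), lower = breaks[-(bins + 1L)],
                    upper = breaks[-1L], n_men = n_men, n_women = n_women,
                    d_men = d_men, d_women = d_women)
  attr(out, "overlap") <- sum(pmin(d_men, d_women))
  out
}

#' Covariable profile of the trimmed records
#'
#' Category frequencies (percent of non-missing, within the excluded set)
#' for every schema covariable plus the sex split, characterising the
#' records outside the region of common support.
#'
#' @param cohort the full (untrimmed) `cohort_table`.
#' @param support a `support_bounds` from [common_support()].
#' @return data.frame (`covariable`, `category`, `n`, `pct`).
#' @export
excluded_profile <- function(cohort, support) {
  stopifnot(inherits(support, "support_bounds"))
  ex <- cohort[!support$keep, , drop = FALSE]
  if (nrow(ex) == 0L) return(NULL)
  schema <- attr(cohort, "schema")
  rows <- list(data.frame(covariable = "sex",
                          category = c("man", "woman"),
                          n = c(sum(ex$sex == 0L), sum(ex$sex == 1L)),
                          pct = 100 * c(mean(ex$sex == 0L),
                                        mean(ex$sex == 1L)),
                          stringsAsFactors = FALSE))
  for (nm in names(schema)) {
    f <- ex[[nm]]
    tab <- table(f)
    denom <- sum(!is.na(f))
    if (denom == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      covariable = nm, category = names(tab), n = as.integer(tab),
      pct = 100 * as.integer(tab) / denom, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
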