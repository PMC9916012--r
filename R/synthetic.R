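#' Synthetic cohort configuration
#'
#' The generator draws a stated world in which the analysis assumptions can
#' be switched on and off: sex is Bernoulli(`p_woman`); each categorical
#' covariable is drawn from `softmax(log(baseline) + sex * gamma * shift)`,
#' so `gamma = 0` makes men's and women's covariable distributions identical
#' while larger `gamma` strengthens the "gendering" of the covariable
#' profile; each binary health indicator follows a logistic model
#' `logit(P(y=1)) = b0 + b_sex * sex + b_prof * profile`, where `profile` is
#' a fixed linear score of the (pre-missingness) covariable categories (see
#' [profile_weights()]); missingness is applied completely at random per
#' column afterwards.
#'
#' @param n number of records.
#' @param p_woman proportion of women in (0, 1).
#' @param gamma global multiplier (>= 0) on the sex-covariable log-odds
#'   shifts.
#' @param baseline named list (one element per schema covariable) of
#'   baseline category probabilities, each summing to 1.
#' @param shifts named list of per-category log-odds offsets added for
#'   women (scaled by `gamma`).
#' @param outcome_models named list (one element per outcome) of lists with
#'   `b0`, `b_sex`, `b_prof` on the log-odds scale.
#' @param missingness named numeric vector of per-covariable MCAR rates in
#'   `[0, 1)`.
#' @param outcome_missingness named numeric vector of per-outcome MCAR
#'   rates.
#' @param seed integer seed stored with the configuration.
#' @param schema a `covariable_schema`.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n, p_woman = 0.54, gamma = 1,
                             baseline = NULL, shifts = NULL,
                             outcome_models = NULL,
                             missingness = NULL, outcome_missingness = NULL,
                             seed = 1L,
                             schema = default_covariable_schema()) {
  preset <- soep_like_parameters()
  if (is.null(baseline)) baseline <- preset$baseline
  if (is.null(shifts)) shifts <- preset$shifts
  if (is.null(outcome_models)) outcome_models <- preset$outcome_models
  if (is.null(missingness)) missingness <- preset$missingness
  if (is.null(outcome_missingness)) {
    outcome_missingness <- preset$outcome_missingness
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(p_woman) || p_woman <= 0 || p_woman >= 1) {
    stop("`p_woman` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma < 0) {
    stop("`gamma` must be >= 0", call. = FALSE)
  }
  for (nm in names(schema)) {
    k <- length(schema[[nm]]$categories)
    p <- baseline[[nm]]
    if (is.null(p) || length(p) != k || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      stop("baseline probabilities for `", nm,
           "` must be ", k, " non-negative values summing to 1",
           call. = FALSE)
    }
    if (is.null(shifts[[nm]])) shifts[[nm]] <- numeric(k)
    if (length(shifts[[nm]]) != k) {
      stop("shift vector for `", nm, "` must have length ", k, call. = FALSE)
    }
    if (is.null(missingness[[nm]])) missingness[[nm]] <- 0
    if (missingness[[nm]] < 0 || missingness[[nm]] >= 1) {
      stop("missingness rate for `", nm, "` must lie in [0, 1)", call. = FALSE)
    }
  }
  for (oc in outcome_names()) {
    m <- outcome_models[[oc]]
    if (is.null(m) || !all(c("b0", "b_sex", "b_prof") %in% names(m))) {
      stop("outcome model for `", oc,
           "` must provide b0, b_sex and b_prof", call. = FALSE)
    }
    if (is.null(outcome_missingness[[oc]])) outcome_missingness[[oc]] <- 0
  }
  structure(list(n = n, p_woman = p_woman, gamma = gamma,
                 baseline = baseline[names(schema)],
                 shifts = shifts[names(schema)],
                 outcome_models = outcome_models[outcome_names()],
                 missingness = unlist(missingness[names(schema)]),
                 outcome_missingness =
                   unlist(outcome_missingness[outcome_names()]),
                 seed = as.integer(seed), schema = schema),
            class = "synthetic_config")
}

# Parameter values of the survey-like preset. Baselines approximate the
# category frequencies of a large German adult household panel; shift signs
# and rough magnitudes reproduce the direction of the published sex
# contrasts (employment and occupational status strongly gendered, migration
# background / disability / urbanity only weakly). They are a stated world,
# not estimates.
soep_like_parameters <- function() {
  baseline <- list(
    age_group      = c(.16, .15, .16, .20, .15, .12, .06),
    employment     = c(.50, .05, .02, .03, .06, .26, .003, .05, .027),
    occupation     = c(.29, .38, .06, .08, .005, .04, .145),
    education      = c(.28, .55, .12, .05),
    partner        = c(.62, .38),
    children       = c(.26, .74),
    migration      = c(.74, .18, .08),
    language       = c(.90, .10),
    lonely         = c(.10, .90),
    disability     = c(.10, .90),
    urbanity       = c(.70, .30),
    household_help = c(.06, .09, .85)
  )
  baseline <- lapply(baseline, function(p) p / sum(p))
  shifts <- list(
    age_group      = c(0, 0, 0, 0, 0, 0.05, 0.25),
    employment     = c(-1.2, 2.2, 1.2, 0, 0, 0.1, 3.0, 0, 3.4),
    occupation     = c(-1.3, 0.7, -0.1, -0.4, 1.5, 0, 0.4),
    education      = c(-0.10, 0.15, 0, 0),
    partner        = c(-0.25, 0),
    children       = c(0.30, 0),
    migration      = c(0, 0.05, 0.05),
    language       = c(0.03, 0),
    lonely         = c(0.35, 0),
    disability     = c(-0.05, 0),
    urbanity       = c(0.02, 0),
    household_help = c(0.25, 0.15, 0)
  )
  # FMD and self-rated health carry both sex- and profile-attributable
  # signal, depression is purely profile-driven (the attenuation case),
  # hypertension purely sex-driven; base prevalences sit in the 5-25% band.
  outcome_models <- list(
    fmd          = list(b0 = stats::qlogis(0.07), b_sex = 0.35, b_prof = 0.45),
    depression   = list(b0 = stats::qlogis(0.05), b_sex = 0,    b_prof = 0.55),
    srh_not_good = list(b0 = stats::qlogis(0.15), b_sex = 0,    b_prof = 0.30),
    hypertension = list(b0 = stats::qlogis(0.21), b_sex = -0.40, b_prof = 0)
  )
  missingness <- c(age_group = 0, employment = .01, occupation = .03,
                   education = .01, partner = .005, children = .005,
                   migration = .01, language = .005, lonely = .01,
                   disability = .005, urbanity = 0, household_help = .01)
  outcome_missingness <- c(fmd = .006, depression = 0, srh_not_good = .002,
                           hypertension = 0)
  list(baseline = baseline, shifts = shifts, outcome_models = outcome_models,
       missingness = missingness, outcome_missingness = outcome_missingness)
}

#' Survey-like and null preset configurations
#'
#' `soep_like_config` is the default stated world: n = 23,000, 54% women,
#' `gamma = 1` with strong employment/occupation shifts, outcome models
#' mixing sex- and profile-attributable signal, and small MCAR missingness.
#' `null_config` is the same world with `gamma = 0` and all sex effects
#' removed, so covariable distributions and outcome prevalences are
#' identical for men and women by construction.
#'
#' @inheritParams synthetic_config
#' @return a `synthetic_config`.
#' @export
soep_like_config <- function(n = 23000, p_woman = 0.54, gamma = 1,
                             seed = 1L) {
  synthetic_config(n = n, p_woman = p_woman, gamma = gamma, seed = seed)
}

#' @rdname soep_like_config
#' @export
null_config <- function(n, seed = 1L) {
  preset <- soep_like_parameters()
  models <- lapply(preset$outcome_models, function(m) {
    m$b_sex <- 0
    m
  })
  synthetic_config(n = n, gamma = 0, outcome_models = models, seed = seed)
}

#' Fixed latent-profile weights
#'
#' The latent profile score underlying the synthetic outcome models is a
#' linear combination of covariable-category indicators with these fixed
#' weights (positive = "feminized" category). The raw weighted sum is
#' standardised with the fixed constants `attr(,"center")` and
#' `attr(,"scale")` (chosen once so the profile has roughly mean 0 and
#' standard deviation 1 under the survey-like preset) — nothing is
#' re-estimated from data, so the generator's ground truth is fully
#' reproducible.
#'
#' @return named list of per-category weight vectors with standardisation
#'   constants attached as attributes.
#' @export
profile_weights <- function() {
  w <- list(
    age_group      = c(0, 0, 0, 0, 0, 0, 0.1),
    employment     = c(-1.0, 1.0, 0.6, -0.1, 0, 0.1, 1.6, 0, 1.6),
    occupation     = c(-0.7, 0.4, -0.1, -0.2, 0.8, 0, 0.3),
    education      = c(-0.1, 0.1, 0, 0),
    partner        = c(-0.1, 0),
    children       = c(0.2, 0),
    migration      = c(0, 0, 0),
    language       = c(0, 0),
    lonely         = c(0.2, 0),
    disability     = c(0, 0),
    urbanity       = c(0, 0),
    household_help = c(0.1, 0.1, 0)
  )
  attr(w, "center") <- PROFILE_CENTER
  attr(w, "scale") <- PROFILE_SCALE
  w
}

# standardisation constants for the raw profile sum (see profile_weights)
PROFILE_CENTER <- 0.5207
PROFILE_SCALE <- 1.0845

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [synthetic_config()] stated world. Identical
#' configuration and seed give byte-identical tables. `null_cohort(n, seed)`
#' is shorthand for generating from [null_config()].
#'
#' @param config a `synthetic_config`.
#' @param seed optional integer overriding `config$seed`.
#' @param n number of records (for `null_cohort`).
#' @return a `cohort_table` with attribute `"profile"` holding the latent
#'   per-record profile score (ground truth, not part of the data model).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
  schema <- config$schema
  n <- config$n
  sex <- stats::rbinom(n, 1L, config$p_woman)
  men <- which(sex == 0L)
  women <- which(sex == 1L)
  codes <- list()
  for (nm in names(schema)) {
    k <- length(schema[[nm]]$categories)
    lp <- log(config$baseline[[nm]])
    pm <- softmax(lp)
    pw <- softmax(lp + config$gamma * config$shifts[[nm]])
    v <- integer(n)
    v[men] <- sample.int(k, length(men), replace = TRUE, prob = pm)
    v[women] <- sample.int(k, length(women), replace = TRUE, prob = pw)
    codes[[nm]] <- v
  }
  w <- profile_weights()
  raw <- numeric(n)
  for (nm in names(schema)) raw <- raw + w[[nm]][codes[[nm]]]
  profile <- (raw - attr(w, "center")) / attr(w, "scale")
  out <- data.frame(record_id = sprintf("r%06d", seq_len(n)), sex = sex,
                    stringsAsFactors = FALSE)
  for (nm in names(schema)) {
    out[[nm]] <- schema[[nm]]$categories[codes[[nm]]]
  }
  for (oc in outcome_names()) {
    m <- config$outcome_models[[oc]]
    p <- stats::plogis(m$b0 + m$b_sex * sex + m$b_prof * profile)
    out[[oc]] <- stats::rbinom(n, 1L, p)
  }
  for (nm in names(schema)) {
    r <- config$missingness[[nm]]
    if (r > 0) out[[nm]][stats::runif(n) < r] <- NA
  }
  for (oc in outcome_names()) {
    r <- config$outcome_missingness[[oc]]
    if (r > 0) out[[oc]][stats::runif(n) < r] <- NA
  }
  cohort <- cohort_table(out, schema)
  attr(cohort, "profile") <- profile
  attr(cohort, "config_seed") <- as.integer(seed)
  cohort
}

#' @rdname generate_cohort
#' @export
null_cohort <- function(n, seed = 1L) {
  generate_cohort(null_config(n, seed = seed))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Read a synthetic configuration from a JSON file
#'
#' The declarative text format mirrors the arguments of
#' [synthetic_config()]; absent fields fall back to the survey-like preset.
#'
#' @param path JSON file path.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[intersect(names(x),
                      c("n", "p_woman", "gamma", "baseline", "shifts",
                        "outcome_models", "missingness",
                        "outcome_missingness", "seed"))]
  do.call(synthetic_config, args)
}
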