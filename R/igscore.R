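#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a randomly chosen woman's score exceeds a
#' randomly chosen man's, with ties counted half.
#'
#' @param scores numeric vector of scores.
#' @param sex 0/1 vector (1 = woman), same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, sex) {
  stopifnot(length(scores) == length(sex))
  keep <- !is.na(scores) & !is.na(sex)
  scores <- scores[keep]
  sex <- as.integer(sex[keep])
  n1 <- sum(sex == 1L)
  n0 <- sum(sex == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both sexes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[sex == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Estimate the intersectional gender-score
#'
#' The intersectional gender-score of a record is the predicted probability
#' of being recorded as a woman conditional on the schema covariables.
#' `fit_igscore_gbm` uses the package's gradient-boosted-tree learner
#' (Bernoulli deviance, depth-limited trees on the categorical covariables,
#' per-split default-direction handling of missing values — no imputation or
#' row deletion). `fit_igscore_logistic` fits a main-effects logistic
#' regression on one-hot covariables with an explicit "(missing)" category
#' per covariable.
#'
#' Scores are in-sample by default (fit and scored on the same records,
#' matching single-cohort usage) and the reported AUC is computed on those
#' scores; `cross_fit = TRUE` instead scores each record out-of-fold (5
#' folds), which removes in-sample optimism.
#'
#' @param cohort a `cohort_table`.
#' @param hyperparameters named list overriding any of `n_rounds` (150),
#'   `shrinkage` (0.05), `max_depth` (3), `min_bucket` (10), `min_split`
#'   (20), `bag_fraction` (0.5), `cv_folds` (0 = no cross-validated round
#'   selection; if > 0, rounds are selected by CV-AUC over `round_grid`),
#'   `round_grid` (seq(25, n_rounds, 25)).
#' @param seed integer seed for bagging / fold assignment.
#' @param cross_fit logical; score out-of-fold instead of in-sample.
#' @return an object of class `igscore_fit` with elements `method`, `scores`
#'   (named by record_id, in `[0,1]`), `auc`, `hyperparameters`, `seed`,
#'   `n_used`, `dropped` (covariables dropped as all-missing), `model`.
#' @export
fit_igscore_gbm <- function(cohort, hyperparameters = list(), seed = 1L,
                            cross_fit = FALSE) {
  hp <- utils::modifyList(
    list(n_rounds = 150L, shrinkage = 0.05, max_depth = 3L,
         min_bucket = 10L, min_split = 20L, bag_fraction = 0.5,
         cv_folds = 0L, round_grid = NULL),
    hyperparameters)
  enc <- encode_covariables(cohort)
  y <- cohort$sex
  check_two_sexes(y)
  set.seed(as.integer(seed))
  fit_args <- list(n_rounds = hp$n_rounds, shrinkage = hp$shrinkage,
                   max_depth = hp$max_depth, min_bucket = hp$min_bucket,
                   min_split = hp$min_split, bag_fraction = hp$bag_fraction)
  if (hp$cv_folds > 0L) {
    grid <- hp$round_grid
    if (is.null(grid)) grid <- seq(25L, hp$n_rounds, by = 25L)
    hp$n_rounds <- do.call(gbt_cv_rounds,
                           c(list(X = enc$X, y = y, grid = grid,
                                  folds = hp$cv_folds),
                             fit_args[names(fit_args) != "n_rounds"]))
    fit_args$n_rounds <- hp$n_rounds
  }
  if (cross_fit) {
    folds <- 5L
    fold_id <- sample(rep_len(seq_len(folds), length(y)))
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      hold <- which(fold_id == f)
      m <- do.call(gbt_fit, c(list(X = enc$X, y = y, watch_rows = hold),
                              fit_args))
      scores[hold] <- gbt_predict(m, enc$X[hold, , drop = FALSE])
    }
    model <- NULL
  } else {
    model <- do.call(gbt_fit, c(list(X = enc$X, y = y), fit_args))
    scores <- gbt_predict(model, enc$X)
  }
  names(scores) <- cohort$record_id
  new_igscore_fit("gbm", scores, y, hp, seed, enc$dropped, model,
                  cross_fit = cross_fit)
}

#' @rdname fit_igscore_gbm
#' @export
fit_igscore_logistic <- function(cohort, cross_fit = FALSE, seed = 1L) {
  y <- cohort$sex
  check_two_sexes(y)
  df <- logistic_frame(cohort)
  dropped <- attr(df, "dropped")
  fit_one <- function(train, score_rows) {
    dat <- data.frame(.sex = y)
    for (nm in names(df)) dat[[nm]] <- df[[nm]]
    form <- if (ncol(dat) > 1L) .sex ~ . else .sex ~ 1
    fit <- withCallingHandlers(
      stats::glm(form, data = dat[train, , drop = FALSE],
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    # glm can converge on separated data without warning: check the fit
    cf <- stats::coef(fit)
    if (!isTRUE(fit$converged) || any(abs(cf[!is.na(cf)]) > 10) ||
        any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)) {
      separated <<- TRUE
    }
    list(fit = fit,
         scores = stats::predict(fit, newdata = dat[score_rows, , drop = FALSE],
                                 type = "response"))
  }
  separated <- FALSE
  if (cross_fit) {
    set.seed(as.integer(seed))
    fold_id <- sample(rep_len(1:5, length(y)))
    scores <- numeric(length(y))
    for (f in 1:5) {
      hold <- which(fold_id == f)
      scores[hold] <- fit_one(which(fold_id != f), hold)$scores
    }
    model <- NULL
  } else {
    res <- fit_one(seq_along(y), seq_along(y))
    scores <- res$scores
    model <- res$fit
  }
  if (separated) {
    warning("possible separation in logistic fit; refitting with a ",
            "ridge penalty of 1e-6", call. = FALSE)
    X <- stats::model.matrix(~., df)
    beta <- ridge_logistic(X, y, lambda = 1e-6)
    scores <- as.vector(stats::plogis(X %*% beta))
    model <- list(ridge_coefficients = beta)
  }
  names(scores) <- cohort$record_id
  new_igscore_fit("logistic", scores, y,
                  list(separation_fallback = separated), seed, dropped,
                  model, cross_fit = cross_fit)
}

# covariables as factors with an explicit "(missing)" level where needed;
# all-missing and constant columns are dropped with a warning
logistic_frame <- function(cohort) {
  schema <- attr(cohort, "schema")
  df <- list()
  dropped <- character(0)
  for (nm in names(schema)) {
    f <- cohort[[nm]]
    if (all(is.na(f))) {
      dropped <- c(dropped, nm)
      next
    }
    if (anyNA(f)) {
      f <- addNA(f)
      levels(f)[is.na(levels(f))] <- "(missing)"
    }
    f <- droplevels(f)
    if (nlevels(f) < 2L) {
      dropped <- c(dropped, nm)
      next
    }
    df[[nm]] <- f
  }
  if (length(dropped)) {
    warning("dropped covariable(s) with no usable variation: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(df, optional = TRUE)
  attr(out, "dropped") <- dropped
  out
}

encode_covariables <- function(cohort) {
  schema <- attr(cohort, "schema")
  dropped <- names(schema)[vapply(names(schema),
                                  function(nm) all(is.na(cohort[[nm]])),
                                  logical(1))]
  if (length(dropped)) {
    warning("dropped all-missing covariable(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(names(schema), dropped)
  X <- vapply(keep, function(nm) {
    v <- as.integer(cohort[[nm]])
    v[is.na(v)] <- 0L
    v
  }, integer(nrow(cohort)))
  list(X = X, dropped = dropped)
}

check_two_sexes <- function(sex) {
  if (length(unique(sex)) < 2L || min(table(sex)) < 2L) {
    stop("score estimation needs at least two records of each sex",
         call. = FALSE)
  }
}

ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L,
                           tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(lambda, p)
  pen[1L, 1L] <- 0  # intercept unpenalised
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) {
      beta <- new
      break
    }
    beta <- new
  }
  as.vector(beta)
}

new_igscore_fit <- function(method, scores, sex, hyperparameters, seed,
                            dropped, model, cross_fit = FALSE) {
  stopifnot(all(scores >= 0 & scores <= 1))
  structure(list(method = method, scores = scores,
                 auc = auc_roc(scores, sex),
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed), n_used = length(scores),
                 dropped = dropped, cross_fit = cross_fit, model = model),
            class = "igscore_fit")
}

#' @export
print.igscore_fit <- function(x, ...) {
  cat(sprintf("<igscore_fit> method = %s, n = %d, AUC-ROC = %.4f%s\n",
              x$method, x$n_used, x$auc,
              if (x$cross_fit) " (out-of-fold)" else " (in-sample)"))
  invisible(x)
}
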