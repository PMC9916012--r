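#' Covariable schema
#'
#' A covariable schema declares, for each intersectional covariable, its name,
#' the ordered set of admissible category labels, and whether missing values
#' are allowed. The default schema carries the twelve sociocultural,
#' sociodemographic and socioeconomic covariables used to estimate the
#' intersectional gender-score: age group (7 bands), employment status (9),
#' occupational status (7), education (4), partner in household, children
#' under 16 in household, migration background (3), household language,
#' feeling lonely, disability status, urbanity/rurality, and household help
#' (3).
#'
#' @param covariables named list; each element a list with `categories`
#'   (character vector of unique labels) and optionally `missing_allowed`
#'   (default `TRUE`).
#' @return an object of class `covariable_schema`.
#' @examples
#' sch <- default_covariable_schema()
#' names(sch)
#' sch$employment$categories
#' @export
covariable_schema <- function(covariables) {
  if (!is.list(covariables) || is.null(names(covariables)) ||
      any(!nzchar(names(covariables)))) {
    stop("`covariables` must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(covariables))) {
    stop("duplicate covariable names in schema", call. = FALSE)
  }
  out <- lapply(covariables, function(cv) {
    cats <- as.character(cv$categories)
    if (length(cats) < 2L) {
      stop("each covariable needs at least two categories", call. = FALSE)
    }
    if (anyDuplicated(norm_label(cats))) {
      stop("category labels must be unique within a covariable", call. = FALSE)
    }
    list(categories = cats,
         missing_allowed = isTRUE(cv$missing_allowed) || is.null(cv$missing_allowed))
  })
  structure(out, class = "covariable_schema")
}

#' @rdname covariable_schema
#' @export
default_covariable_schema <- function() {
  covariable_schema(list(
    age_group = list(categories = c("18-29", "30-39", "40-49", "50-59",
                                    "60-69", "70-79", "80+")),
    employment = list(categories = c("full-time", "part-time", "occasional",
                                     "work and education", "education",
                                     "retired", "maternity/parental leave",
                                     "unemployed", "housewife/-husband")),
    occupation = list(categories = c("blue-collar", "white-collar",
                                     "civil servant", "freelancer",
                                     "helping family", "apprenticeship",
                                     "else")),
    education = list(categories = c("high", "medium", "low", "else")),
    partner = list(categories = c("yes", "no")),
    children = list(categories = c("yes", "no")),
    migration = list(categories = c("none", "direct", "indirect")),
    language = list(categories = c("german", "other")),
    lonely = list(categories = c("often", "seldom/never")),
    disability = list(categories = c("yes", "no")),
    urbanity = list(categories = c("urban", "rural")),
    household_help = list(categories = c("yes regularly", "yes sometimes",
                                         "no"))
  ))
}

#' Names of the binary health indicators
#'
#' @return character vector of the four indicator column names.
#' @export
outcome_names <- function() {
  c("fmd", "depression", "srh_not_good", "hypertension")
}

# label normalisation used for all matching: trim + case-fold
norm_label <- function(x) tolower(trimws(x))

#' Read / write a covariable schema file
#'
#' The schema file is a declarative plain-text format with one covariable per
#' line: `name: category | category | ...`. Lines starting with `#` are
#' ignored. A trailing `!` on a name marks the covariable as not allowing
#' missing values.
#'
#' @param path file path.
#' @param schema a `covariable_schema`.
#' @return `read_schema` returns a `covariable_schema`; `write_schema`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  covs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("malformed schema line: ", ln, call. = FALSE)
    }
    name <- trimws(parts[1L])
    miss <- !endsWith(name, "!")
    name <- sub("!$", "", name)
    cats <- trimws(strsplit(paste(parts[-1L], collapse = ":"),
                            "|", fixed = TRUE)[[1]])
    covs[[name]] <- list(categories = cats, missing_allowed = miss)
  }
  covariable_schema(covs)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "covariable_schema"))
  lines <- vapply(names(schema), function(nm) {
    tag <- if (schema[[nm]]$missing_allowed) nm else paste0(nm, "!")
    paste0(tag, ": ", paste(schema[[nm]]$categories, collapse = " | "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# cohort table

#' Construct a cohort table
#'
#' A cohort table holds one row per respondent: a unique `record_id`, binary
#' `sex` (0 = man, 1 = woman; the score predicts the probability of being
#' recorded as a woman), one factor column per schema covariable (missing
#' allowed), and the four binary health indicators `fmd`, `depression`,
#' `srh_not_good`, `hypertension` (0/1/NA).
#'
#' @param df data.frame with columns `record_id`, `sex`, the schema
#'   covariables (character or factor) and optionally the outcome columns.
#' @param schema a `covariable_schema`; defaults to
#'   [default_covariable_schema()].
#' @return an object of class `cohort_table` (a data.frame).
#' @export
cohort_table <- function(df, schema = default_covariable_schema()) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("cohort must be a data.frame with at least one row", call. = FALSE)
  }
  if (is.null(df$record_id)) {
    df$record_id <- sprintf("r%06d", seq_len(nrow(df)))
  }
  df$record_id <- as.character(df$record_id)
  if (anyDuplicated(df$record_id)) {
    stop("record_id must be unique", call. = FALSE)
  }
  if (is.null(df$sex)) stop("cohort is missing the `sex` column", call. = FALSE)
  sex <- parse_sex(df$sex)
  if (anyNA(sex)) {
    bad <- which(is.na(sex))
    stop("sex missing or unrecognised in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  out <- data.frame(record_id = df$record_id, sex = sex,
                    stringsAsFactors = FALSE, check.names = FALSE)
  issues <- character(0)
  for (nm in names(schema)) {
    if (is.null(df[[nm]])) {
      stop("cohort is missing covariable column `", nm, "`", call. = FALSE)
    }
    cats <- schema[[nm]]$categories
    raw <- as.character(df[[nm]])
    raw[!is.na(raw) & !nzchar(trimws(raw))] <- NA
    idx <- match(norm_label(raw), norm_label(cats))
    bad <- which(!is.na(raw) & is.na(idx))
    if (length(bad)) {
      issues <- c(issues, sprintf(
        "column `%s`, row %d: unknown category \"%s\"", nm, bad, raw[bad]))
    }
    out[[nm]] <- factor(cats[idx], levels = cats)
  }
  if (length(issues)) {
    stop("invalid category labels:\n  ",
         paste(utils::head(issues, 10L), collapse = "\n  "),
         if (length(issues) > 10L)
           sprintf("\n  ... and %d more", length(issues) - 10L) else "",
         call. = FALSE)
  }
  for (oc in outcome_names()) {
    v <- if (is.null(df[[oc]])) rep(NA_integer_, nrow(df)) else
      parse_binary(df[[oc]], oc)
    out[[oc]] <- v
  }
  structure(out, schema = schema,
            class = c("cohort_table", "data.frame"))
}

parse_sex <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!out %in% c(0L, 1L)] <- NA_integer_
    return(out)
  }
  key <- norm_label(as.character(x))
  men <- c("0", "m", "man", "men", "male")
  women <- c("1", "w", "f", "woman", "women", "female")
  ifelse(key %in% women, 1L, ifelse(key %in% men, 0L, NA_integer_))
}

parse_binary <- function(x, col) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    out <- as.integer(x)
    if (any(!is.na(out) & !out %in% c(0L, 1L))) {
      stop("column `", col, "` must be binary 0/1", call. = FALSE)
    }
    return(out)
  }
  key <- norm_label(as.character(x))
  key[!nzchar(key) | key == "na"] <- NA
  out <- ifelse(is.na(key), NA_integer_,
                ifelse(key %in% c("1", "yes"), 1L,
                       ifelse(key %in% c("0", "no"), 0L, NA_integer_)))
  bad <- which(!is.na(key) & !key %in% c("0", "1", "yes", "no"))
  if (length(bad)) {
    stop("column `", col, "`, row ", bad[1L],
         ": unrecognised binary value \"", key[bad[1L]], "\"", call. = FALSE)
  }
  out
}

#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(names(x) %in% names(out))) {
    attr(out, "schema") <- attr(x, "schema")
    class(out) <- class(x)
  }
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d records, %.1f%% women, %d covariables\n",
              nrow(x), 100 * mean(x$sex), length(attr(x, "schema"))))
  for (oc in outcome_names()) {
    n <- sum(!is.na(x[[oc]]))
    if (n > 0) {
      cat(sprintf("  %-13s %5.2f%%  (n = %d)\n", oc,
                  100 * mean(x[[oc]], na.rm = TRUE), n))
    }
  }
  invisible(x)
}

#' Load and write cohort CSV files
#'
#' `load_cohort` reads a comma-separated UTF-8 file with a header row naming
#' `sex`, the schema covariables, and (optionally) the outcome columns.
#' Category labels are matched case-insensitively after trimming whitespace;
#' missing values are encoded as empty cells (or any string in `na`). Raw
#' ordinal outcome responses are binarized automatically via
#' [binarize_outcomes()] when detected. `write_cohort` writes the validated
#' table back in canonical column order; `write_cohort(load_cohort(f))`
#' reproduces `f` up to column order and label canonicalisation.
#'
#' @param path CSV file path.
#' @param schema a `covariable_schema`.
#' @param na character vector of strings read as missing.
#' @param cohort a `cohort_table`.
#' @return `load_cohort` returns a `cohort_table`; `write_cohort` returns
#'   `path` invisibly.
#' @export
load_cohort <- function(path, schema = default_covariable_schema(),
                        na = c("", "NA")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        na.strings = na, fileEncoding = "UTF-8")
  if (is.null(df$sex)) {
    stop("input file has no `sex` column", call. = FALSE)
  }
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("input file is missing covariable column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # raw ordinal responses (e.g. "often", "satisfactory") are binarized first
  raw_out <- intersect(c(outcome_names(), "srh"), names(df))
  if (length(raw_out) && needs_binarization(df[raw_out])) {
    bin <- binarize_outcomes(df[raw_out])
    df[raw_out] <- NULL
    df[names(bin)] <- bin
  }
  cohort_table(df, schema)
}

needs_binarization <- function(raw) {
  vals <- norm_label(unlist(lapply(raw, as.character), use.names = FALSE))
  vals <- vals[!is.na(vals) & nzchar(vals)]
  any(!vals %in% c("0", "1", "yes", "no"))
}

#' @rdname load_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- attr(cohort, "schema")
  out <- data.frame(record_id = cohort$record_id,
                    sex = c("man", "woman")[cohort$sex + 1L],
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(schema)) out[[nm]] <- as.character(cohort[[nm]])
  for (oc in outcome_names()) out[[oc]] <- cohort[[oc]]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Binarize raw health-indicator responses
#'
#' Frequent mental distress (feeling sad in the last four weeks) is coded 1
#' for "very often"/"often" and 0 for "occasionally"/"rarely"/"very rarely".
#' Self-rated health (`srh`, emitted as `srh_not_good`) is coded 1 for
#' "bad"/"poor" and 0 for "satisfactory"/"good"/"very good". Depression and
#' hypertension lifetime diagnoses map "yes" to 1 and "no" to 0. Missing
#' responses propagate to missing. Already-binary 0/1 or yes/no input is
#' passed through unchanged, so the operation is idempotent.
#'
#' @param raw data.frame with any of the columns `fmd`, `srh` (or
#'   `srh_not_good`), `depression`, `hypertension` holding raw responses.
#' @return data.frame of integer 0/1/NA columns named as in
#'   [outcome_names()] (only those present in `raw`).
#' @export
binarize_outcomes <- function(raw) {
  stopifnot(is.data.frame(raw))
  maps <- list(
    fmd = c("very often" = 1, "often" = 1, "occasionally" = 0,
            "rarely" = 0, "very rarely" = 0),
    srh_not_good = c("bad" = 1, "poor" = 1, "satisfactory" = 0,
                     "good" = 0, "very good" = 0),
    depression = c(yes = 1, no = 0),
    hypertension = c(yes = 1, no = 0)
  )
  out <- list()
  for (nm in names(raw)) {
    target <- if (nm == "srh") "srh_not_good" else nm
    if (!target %in% names(maps)) next
    map <- maps[[target]]
    key <- norm_label(as.character(raw[[nm]]))
    key[!nzchar(key) | key == "na"] <- NA
    v <- unname(map[key])
    passthrough <- !is.na(key) & key %in% c("0", "1")
    v[passthrough] <- as.numeric(key[passthrough])
    bad <- which(!is.na(key) & is.na(v) & !passthrough)
    if (length(bad)) {
      stop("column `", nm, "`, row ", bad[1L],
           ": unrecognised response \"", raw[[nm]][bad[1L]], "\"",
           call. = FALSE)
    }
    out[[target]] <- as.integer(v)
  }
  as.data.frame(out, optional = TRUE)
}
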