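#' Published reference counts (SOEP 2017 case study)
#'
#' Aggregate event counts and denominators transcribed from the published
#' tables of the SOEP 2017 intersectional gender-score case study (the
#' microdata themselves are access-restricted): per health indicator, the
#' number of events `x` and the per-indicator denominator `n` for men and
#' women in the full analysis sample, the male-dominated stratum (`S1`) and
#' the female-dominated stratum (`SK`), plus the sample accounting before
#' and after common-support trimming. These are inputs for desk
#' reproduction of the published prevalence differences — feed them to
#' [diff_proportions()] — not outputs of this package.
#'
#' @return a list with data.frames `counts` (`indicator`, `group`, `x`,
#'   `n`) and `sample` (`quantity`, `men`, `women`).
#' @examples
#' ref <- reference_counts()
#' fmd <- subset(ref$counts, indicator == "fmd")
#' with(fmd, diff_proportions(x[group == "S1_men"], n[group == "S1_men"],
#'                            x[group == "SK_women"], n[group == "SK_women"]))
#' @export
reference_counts <- function() {
  dir <- system.file("extdata", package = "igscore")
  list(
    counts = utils::read.csv(file.path(dir, "soep2017_reference_counts.csv"),
                             stringsAsFactors = FALSE),
    sample = utils::read.csv(file.path(dir, "soep2017_reference_sample.csv"),
                             stringsAsFactors = FALSE)
  )
}
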