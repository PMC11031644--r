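#' Packaged fixtures from the published field study
#'
#' `make_fixture("table2")` returns the study's aggregate catch-composition
#' table (19 species by 4 arms, totals 69,758 HLC / 27,359 SHK / 97,117
#' combined) as a [count_table] holding a single pseudo-stratum. It supports
#' composition and concordance-style summaries only: with one stratum there is
#' no replication, so the model-fitting stage refuses it.
#'
#' @param name Fixture name; currently `"table2"`.
#' @return A [count_table].
#' @export
make_fixture <- function(name = "table2") {
  known <- c("table2")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  path <- system.file("extdata", "table2_counts.csv", package = "trapeff",
                      mustWork = TRUE)
  read_counts(path)
}

#' Published summary tables of the field study
#'
#' Returns transcriptions of the study's printed summary tables as data.frames:
#' `"strata"` (per-species totals, strata counts and rank concordance
#' coefficients against indoor HLC), `"linear"` (linear-model efficiency
#' medians with 95% credible intervals, outdoor:indoor ratio and DIC for both
#' variants) and `"power"` (power-model alpha-prime and gamma estimates;
#' `NA` where printed as unreliable due to sparse data). These are inputs for
#' eligibility checks and qualitative comparisons; the underlying raw nightly
#' data are deposited externally and are not shipped.
#'
#' @param name One of `"strata"`, `"linear"`, `"power"`.
#' @return A data.frame.
#' @export
study_table <- function(name = c("strata", "linear", "power")) {
  name <- match.arg(name)
  file <- switch(name,
                 strata = "table4_strata_ccc.csv",
                 linear = "table5_linear.csv",
                 power = "table6_power.csv")
  path <- system.file("extdata", file, package = "trapeff", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
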