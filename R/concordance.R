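#' Rank concordance correlation coefficient
#'
#' Converts the two matched count vectors to ranks (ties get average ranks)
#' and computes Lin's concordance correlation coefficient on the rank vectors:
#' 2 cov(r_x, r_y) / (var(r_x) + var(r_y) + (mean r_x - mean r_y)^2), with
#' population (1/n) moments. Because only ranks enter, the statistic is
#' invariant to any strictly monotone transformation of the raw counts, which
#' suits heavily skewed, zero-rich catch data.
#'
#' @param reference Counts per stratum for the reference arm.
#' @param candidate Counts per stratum for the candidate arm, same stratum
#'   order.
#' @return A number in \[-1, 1\].
#' @export
rank_ccc <- function(reference, candidate) {
  stopifnot(is.numeric(reference), is.numeric(candidate),
            length(reference) == length(candidate))
  n <- length(reference)
  if (n < 2L) stop("at least two paired strata are required")
  if (any(reference < 0) || any(candidate < 0)) stop("counts must be >= 0")
  rx <- rank(reference, ties.method = "average")
  ry <- rank(candidate, ties.method = "average")
  vx <- mean((rx - mean(rx))^2)
  vy <- mean((ry - mean(ry))^2)
  if (vx == 0 && vy == 0) {
    stop("both rank vectors are constant; concordance is undefined")
  }
  cxy <- mean((rx - mean(rx)) * (ry - mean(ry)))
  2 * cxy / (vx + vy + (mean(rx) - mean(ry))^2)
}

#' Per-species, per-arm rank concordance table
#'
#' For every species and every non-reference arm, computes [rank_ccc] between
#' that arm's counts and the reference arm's counts over the species' included
#' strata (strata with a positive catch by any arm). Species for which the
#' statistic is undefined are reported with `NA` and a reason rather than
#' raised as errors.
#'
#' @param table A [count_table].
#' @param reference_arm An [arm_key]; default indoor HLC.
#' @return A data.frame with columns `species`, `arm`, `n_strata`, `ccc`,
#'   `note`.
#' @export
ccc_table <- function(table, reference_arm = arm_key("HLC", "indoor")) {
  stopifnot(inherits(table, "count_table"))
  species <- sort(unique(as.data.frame(table)$species))
  ref_label <- arm_label(reference_arm)
  out <- list()
  for (sp in species) {
    m <- to_species_matrix(table, sp, reference_arm)
    others <- setdiff(m$arm_labels, ref_label)
    for (arm in others) {
      res <- tryCatch(
        list(ccc = rank_ccc(m$counts[, ref_label], m$counts[, arm]), note = ""),
        error = function(e) list(ccc = NA_real_, note = conditionMessage(e)))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, arm = arm, n_strata = m$n_strata,
        ccc = res$ccc, note = res$note)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
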