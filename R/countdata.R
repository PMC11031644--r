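#' Arm key: one (method, location) collection arm
#'
#' An arm is a combination of a collection method (e.g. `"HLC"`, `"SHK"`) and a
#' deployment location (`"indoor"` or `"outdoor"`). The four arms of the field
#' design are \{HLC, SHK\} x \{indoor, outdoor\}; indoor HLC is the conventional
#' reference arm against which efficiencies are expressed.
#'
#' @param method Collection-method label, e.g. `"HLC"` or `"SHK"`.
#' @param location `"indoor"` or `"outdoor"`.
#' @return An object of class `arm_key`.
#' @examples
#' arm_key("HLC", "indoor")
#' @export
arm_key <- function(method, location = c("indoor", "outdoor")) {
  stopifnot(is.character(method), length(method) == 1L, nzchar(method))
  location <- match.arg(location)
  structure(list(method = method, location = location), class = "arm_key")
}

#' @export
format.arm_key <- function(x, ...) paste(x$method, x$location)

#' @export
print.arm_key <- function(x, ...) {
  cat("<arm>", format(x), "\n")
  invisible(x)
}

arm_label <- function(arm) {
  if (inherits(arm, "arm_key")) format(arm) else as.character(arm)
}

same_arm <- function(a, b) identical(format(a), format(b))

.required_cols <- c("species", "method", "location", "site", "night", "count")

#' Construct a validated stratified count table
#'
#' The universal input container: one row per (species, method, location, site,
#' night) with the number of mosquitoes caught that night by that arm. A
#' stratum is one (site, night) sampling occasion; an arm is one
#' (method, location) pair.
#'
#' @param records A data.frame with columns `species`, `method`, `location`,
#'   `site`, `night`, `count`.
#' @return A `count_table` (a validated data.frame).
#' @details Validation enforces: all required columns present; `location` in
#'   \{indoor, outdoor\}; counts non-negative integers; no duplicated
#'   (species, method, location, site, night) key.
#' @export
count_table <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.required_cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, .required_cols]
  for (col in c("species", "method", "location", "site", "night")) {
    records[[col]] <- as.character(records[[col]])
  }
  bad_loc <- !records$location %in% c("indoor", "outdoor")
  if (any(bad_loc)) {
    stop("invalid location at row(s) ", paste(which(bad_loc), collapse = ", "),
         ": must be 'indoor' or 'outdoor'")
  }
  cnt <- suppressWarnings(as.numeric(records$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != floor(cnt)
  if (any(bad)) {
    stop("count must be a non-negative integer; offending row(s): ",
         paste(which(bad), collapse = ", "))
  }
  records$count <- as.integer(cnt)
  key <- do.call(paste, c(records[c("species", "method", "location", "site", "night")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    dups <- which(key %in% key[duplicated(key)])
    stop("duplicate (species, method, location, site, night) key; clashing row(s): ",
         paste(dups, collapse = ", "))
  }
  rownames(records) <- NULL
  class(records) <- c("count_table", "data.frame")
  records
}

#' Read a stratified count table from CSV
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row).
#' @param schema Optional named character vector remapping canonical column
#'   names to the file's column names, e.g.
#'   `c(species = "taxon", count = "n")`. Unmentioned columns keep their
#'   canonical names.
#' @return A validated [count_table].
#' @export
read_counts <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  colmap <- stats::setNames(.required_cols, .required_cols)
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    unknown <- setdiff(names(schema), .required_cols)
    if (length(unknown) > 0L) {
      stop("schema names must be canonical columns; unknown: ",
           paste(unknown, collapse = ", "))
    }
    colmap[names(schema)] <- schema
  }
  missing_cols <- colmap[!colmap %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("input lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- stats::setNames(raw[, colmap, drop = FALSE], names(colmap))
  count_table(records)
}

#' Write a count table to CSV
#'
#' Writes in the canonical schema so that [read_counts] round-trips records
#' exactly.
#'
#' @param table A [count_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' List the arms present in a count table
#'
#' @param table A [count_table].
#' @return A data.frame with columns `method`, `location` and a `label` column,
#'   one row per distinct arm, sorted by label.
#' @export
arms <- function(table) {
  stopifnot(inherits(table, "count_table"))
  a <- unique(as.data.frame(table)[, c("method", "location")])
  a$label <- paste(a$method, a$location)
  a <- a[order(a$label), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' List the strata (site, night pairs) present in a count table
#'
#' @param table A [count_table].
#' @return A data.frame with columns `site`, `night`, one row per distinct
#'   stratum, sorted.
#' @export
strata <- function(table) {
  stopifnot(inherits(table, "count_table"))
  s <- unique(as.data.frame(table)[, c("site", "night")])
  s <- s[order(s$site, s$night), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Total catch per species and arm
#'
#' Sums counts over all strata, reproducing the composition table of a study
#' report (species by arm totals).
#'
#' @param table A [count_table].
#' @return An integer matrix indexed `[species, arm]`; arm columns are labelled
#'   `"<method> <location>"`.
#' @export
species_arm_totals <- function(table) {
  stopifnot(inherits(table, "count_table"))
  df <- as.data.frame(table)
  if (nrow(df) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  arm <- paste(df$method, df$location)
  tot <- tapply(df$count, list(species = df$species, arm = arm), sum, default = 0L)
  mode(tot) <- "integer"
  tot[order(rownames(tot)), order(colnames(tot)), drop = FALSE]
}

#' Genus composition of one method's catch
#'
#' Proportion of a method's total catch (both locations pooled) contributed by
#' each genus.
#'
#' @param table A [count_table].
#' @param method Method label, e.g. `"HLC"`.
#' @param genus_map Optional named character vector mapping species to genus.
#'   By default the genus is the first whitespace-delimited token of the
#'   species label.
#' @return Named numeric vector of proportions summing to 1.
#' @export
genus_composition <- function(table, method, genus_map = NULL) {
  stopifnot(inherits(table, "count_table"), is.character(method))
  df <- as.data.frame(table)
  df <- df[df$method == method, , drop = FALSE]
  if (nrow(df) == 0L || sum(df$count) == 0L) {
    stop("method '", method, "' has zero total catch; composition undefined")
  }
  if (is.null(genus_map)) {
    genus <- sub("\\s.*$", "", df$species)
  } else {
    genus <- unname(genus_map[df$species])
    if (anyNA(genus)) {
      stop("species without genus mapping: ",
           paste(unique(df$species[is.na(genus)]), collapse = ", "))
    }
  }
  tot <- tapply(df$count, genus, sum)
  p <- tot / sum(df$count)
  p[order(names(p))]
}

#' Per-species stratum-by-arm count matrix for modelling
#'
#' Builds the matrix fed to the efficiency models: rows are the strata in which
#' the species was caught by at least one arm (all-zero strata carry no
#' information about relative efficiency and are dropped); within an included
#' stratum every arm of the table's sampling frame is zero-filled if absent.
#'
#' @param table A [count_table].
#' @param species Species label present in the table.
#' @param reference_arm An [arm_key]; default indoor HLC.
#' @return An object of class `species_stratum_table`: a list with elements
#'   `species`, `counts` (integer matrix `[stratum, arm]`), `arm_labels`,
#'   `reference_arm`, `reference_index`, `n_strata`.
#' @export
to_species_matrix <- function(table, species,
                              reference_arm = arm_key("HLC", "indoor")) {
  stopifnot(inherits(table, "count_table"))
  df <- as.data.frame(table)
  if (!species %in% df$species) stop("species not present in table: ", species)
  frame_arms <- arms(table)
  ref_label <- arm_label(reference_arm)
  if (!ref_label %in% frame_arms$label) {
    stop("reference arm not present in table: ", ref_label)
  }
  frame_strata <- strata(table)
  stratum_id <- function(site, night) paste(site, night, sep = " | ")
  all_strata <- stratum_id(frame_strata$site, frame_strata$night)

  sp <- df[df$species == species, , drop = FALSE]
  counts <- matrix(0L, nrow = length(all_strata), ncol = nrow(frame_arms),
                   dimnames = list(all_strata, frame_arms$label))
  if (nrow(sp) > 0L) {
    i <- match(stratum_id(sp$site, sp$night), all_strata)
    j <- match(paste(sp$method, sp$location), frame_arms$label)
    counts[cbind(i, j)] <- sp$count
  }
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  structure(list(species = species,
                 counts = counts,
                 arm_labels = colnames(counts),
                 reference_arm = reference_arm,
                 reference_index = match(ref_label, colnames(counts)),
                 n_strata = nrow(counts)),
            class = "species_stratum_table")
}

#' @export
print.species_stratum_table <- function(x, ...) {
  cat("<species_stratum_table>", x$species, "-", x$n_strata, "strata x",
      length(x$arm_labels), "arms (reference:", arm_label(x$reference_arm), ")\n")
  invisible(x)
}

#' Species eligible for model fitting by the minimum-strata rule
#'
#' A species enters the efficiency models only if it occurred in at least
#' `min_strata` sampling occasions (strata with a positive catch by any arm).
#'
#' @param x A [count_table], or a data.frame with columns `species` and
#'   `n_strata` (printed strata metadata).
#' @param min_strata Minimum number of strata (default 10).
#' @return Character vector of eligible species labels, with the per-species
#'   strata counts attached as the `n_strata` attribute.
#' @export
filter_by_strata <- function(x, min_strata = 10) {
  if (!is.numeric(min_strata) || length(min_strata) != 1L || min_strata < 1) {
    stop("min_strata must be a single integer >= 1")
  }
  if (inherits(x, "count_table")) {
    species <- sort(unique(as.data.frame(x)$species))
    n_strata <- vapply(species, function(s) to_species_matrix(x, s)$n_strata,
                       integer(1))
  } else if (is.data.frame(x) && all(c("species", "n_strata") %in% names(x))) {
    species <- as.character(x$species)
    n_strata <- stats::setNames(as.numeric(x$n_strata), species)
  } else {
    stop("x must be a count_table or a data.frame with species and n_strata")
  }
  eligible <- species[!is.na(n_strata) & n_strata >= min_strata]
  structure(eligible, n_strata = n_strata)
}
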