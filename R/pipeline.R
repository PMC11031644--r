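#' Configuration for an end-to-end analysis run
#'
#' @param input Path to a counts CSV, or a [count_table] directly.
#' @param schema Optional column-name map passed to [read_counts].
#' @param reference_arm An [arm_key]; default indoor HLC.
#' @param min_strata Minimum strata for model eligibility (default 10).
#' @param level Credibility level for all intervals (default 0.95).
#' @param settings An [mcmc_settings]; per-species chain seeds are derived
#'   deterministically from its `seed`.
#' @param outdir Output directory for report files, or `NULL` to return
#'   reports without writing.
#' @param genus_map Optional named character vector (or path to a two-column
#'   CSV `species,genus`) mapping species to genus for composition summaries.
#' @param pairwise If `TRUE`, fit each candidate arm against the reference in
#'   a separate two-arm model instead of one joint fit sharing the latent
#'   densities across arms (default `FALSE`, the joint fit).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input,
                            schema = NULL,
                            reference_arm = arm_key("HLC", "indoor"),
                            min_strata = 10,
                            level = 0.95,
                            settings = mcmc_settings(),
                            outdir = NULL,
                            genus_map = NULL,
                            pairwise = FALSE) {
  stopifnot(inherits(reference_arm, "arm_key"), inherits(settings, "mcmc_settings"),
            is.logical(pairwise), length(pairwise) == 1L)
  if (is.character(genus_map) && length(genus_map) == 1L && file.exists(genus_map)) {
    gm <- utils::read.csv(genus_map, stringsAsFactors = FALSE)
    genus_map <- stats::setNames(gm$genus, gm$species)
  }
  structure(list(input = input, schema = schema, reference_arm = reference_arm,
                 min_strata = min_strata, level = level, settings = settings,
                 outdir = outdir, genus_map = genus_map, pairwise = pairwise),
            class = "analysis_config")
}

config_provenance <- function(config) {
  list(reference_arm = arm_label(config$reference_arm),
       min_strata = config$min_strata,
       level = config$level,
       pairwise = config$pairwise,
       mcmc = unclass(config$settings),
       input = if (is.character(config$input)) config$input else "in-memory table")
}

species_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * index) %% 2147483647)
}

round_cols <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

fit_one_variant <- function(sst, variant, config, seed) {
  spec <- model_spec(variant = variant, reference_arm = config$reference_arm,
                     min_strata = config$min_strata)
  settings <- mcmc_settings(n_chains = config$settings$n_chains,
                            n_warmup = config$settings$n_warmup,
                            n_draws = config$settings$n_draws,
                            seed = seed)
  fit <- suppressWarnings(fit_efficiency(sst, spec, settings))
  summ <- suppressWarnings(summarize_fit(fit, level = config$level))
  list(fit = fit, summary = summ)
}

#' Run the complete trap-efficiency analysis
#'
#' Ingests a stratified count table, writes composition and rank-concordance
#' summaries for every species, applies the minimum-strata eligibility rule,
#' fits the linear and power efficiency models per eligible species (seeded
#' deterministically per species), classifies efficiency and proportionality,
#' and computes outdoor:indoor ratios. Per-species fit failures are recorded
#' in that species' report and do not abort the run.
#'
#' When `config$outdir` is set, writes `composition.csv`, `concordance.csv`,
#' `efficiency_linear.csv`, `efficiency_power.csv` (numeric columns rounded to
#' two decimals), `reports.json` (full precision) and `runlog.jsonl`.
#'
#' @param config An [analysis_config].
#' @return Invisibly, a list of per-species reports (class `trapeff_reports`)
#'   with the composition and concordance tables attached as attributes.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  table <- if (inherits(config$input, "count_table")) {
    config$input
  } else {
    read_counts(config$input, config$schema)
  }
  runlog <- list(c(list(event = "config"), config_provenance(config)))

  totals <- species_arm_totals(table)
  methods <- sort(unique(arms(table)$method))
  comp_rows <- list()
  for (sp in rownames(totals)) {
    for (arm in colnames(totals)) {
      ml <- strsplit(arm, " ", fixed = TRUE)[[1]]
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        level = "species", name = sp, method = ml[1], location = ml[2],
        count = totals[sp, arm], proportion = NA_real_)
    }
  }
  for (m in methods) {
    gc <- tryCatch(genus_composition(table, m, config$genus_map),
                   error = function(e) NULL)
    if (is.null(gc)) next
    m_total <- sum(totals[, grepl(paste0("^", m, " "), colnames(totals)),
                          drop = FALSE])
    for (g in names(gc)) {
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        level = "genus", name = g, method = m, location = "both",
        count = round(gc[[g]] * m_total), proportion = gc[[g]])
    }
  }
  composition <- do.call(rbind, comp_rows)
  rownames(composition) <- NULL

  concordance <- ccc_table(table, config$reference_arm)

  eligible <- filter_by_strata(table, config$min_strata)
  n_strata_all <- attr(eligible, "n_strata")
  species <- sort(unique(as.data.frame(table)$species))
  ref_label <- arm_label(config$reference_arm)

  reports <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    sst <- to_species_matrix(table, sp, config$reference_arm)
    rep_i <- list(species = sp,
                  n_strata = sst$n_strata,
                  totals = totals[sp, , drop = TRUE],
                  ccc = concordance[concordance$species == sp, , drop = FALSE],
                  eligible = sp %in% eligible,
                  reason = NULL, linear = NULL, power = NULL, exophagy = NULL)
    if (!rep_i$eligible) {
      rep_i$reason <- sprintf("below min_strata (%d < %d)",
                              sst$n_strata, as.integer(config$min_strata))
      runlog[[length(runlog) + 1L]] <- list(event = "species_skipped",
                                            species = sp,
                                            n_strata = sst$n_strata,
                                            reason = rep_i$reason)
      reports[[sp]] <- rep_i
      next
    }
    seed_i <- species_seed(config$settings$seed, i)
    fit_block <- function(variant) {
      if (!config$pairwise) {
        fr <- fit_one_variant(sst, variant, config, seed_i)
        return(list(summary = fr$summary, fits = list(fr$fit)))
      }
      # pairwise: one two-arm model per candidate arm, then stack summaries
      cand <- setdiff(sst$arm_labels, ref_label)
      parts <- list()
      fits <- list()
      for (k in seq_along(cand)) {
        df <- as.data.frame(table)
        keep <- paste(df$method, df$location) %in% c(ref_label, cand[k]) &
          df$species == sp
        sub <- count_table(df[keep, , drop = FALSE])
        sst_k <- to_species_matrix(sub, sp, config$reference_arm)
        fr <- fit_one_variant(sst_k, variant, config, species_seed(seed_i, k))
        s <- as.data.frame(fr$summary)
        parts[[k]] <- s[!s$reference, , drop = FALSE]
        fits[[k]] <- fr$fit
      }
      ref_row <- data.frame(arm = ref_label, reference = TRUE, alpha = 1,
                            alpha_lo = 1, alpha_hi = 1, gamma = 1,
                            gamma_lo = 1, gamma_hi = 1)
      summ <- do.call(rbind, c(list(ref_row), parts))
      dics <- vapply(fits, function(f) suppressWarnings(dic(f)), numeric(3))
      summ <- structure(summ, class = c("posterior_summary", "data.frame"),
                        variant = variant,
                        dic = sum(dics["dic", ]), pD = sum(dics["pD", ]),
                        converged = all(vapply(fits, `[[`, logical(1),
                                               "converged")),
                        level = config$level, species = sp)
      list(summary = summ, fits = fits)
    }
    lin <- tryCatch(fit_block("linear"), error = function(e) e)
    pow <- tryCatch(fit_block("power"), error = function(e) e)
    if (inherits(lin, "error")) {
      rep_i$reason <- paste("linear fit failed:", conditionMessage(lin))
    } else {
      rep_i$linear <- list(summary = lin$summary,
                           dic = attr(lin$summary, "dic"),
                           pD = attr(lin$summary, "pD"),
                           converged = attr(lin$summary, "converged"),
                           labels = classify_efficiency(lin$summary))
      methods_both <- Filter(function(m) {
        all(paste(m, c("indoor", "outdoor")) %in% sst$arm_labels)
      }, unique(sub(" (indoor|outdoor)$", "", sst$arm_labels)))
      if (!config$pairwise && length(methods_both) > 0L) {
        rep_i$exophagy <- lapply(stats::setNames(methods_both, methods_both),
                                 function(m) exophagy_ratio(lin$fits[[1]], m,
                                                            config$level))
      }
    }
    if (inherits(pow, "error")) {
      rep_i$reason <- paste(c(rep_i$reason,
                              paste("power fit failed:", conditionMessage(pow))),
                            collapse = "; ")
    } else {
      rep_i$power <- list(summary = pow$summary,
                          dic = attr(pow$summary, "dic"),
                          pD = attr(pow$summary, "pD"),
                          converged = attr(pow$summary, "converged"),
                          proportionality = assess_proportionality(pow$summary))
    }
    runlog[[length(runlog) + 1L]] <- list(
      event = "species_fitted", species = sp, n_strata = sst$n_strata,
      seed = seed_i,
      dic_linear = if (!is.null(rep_i$linear)) rep_i$linear$dic else NA,
      dic_power = if (!is.null(rep_i$power)) rep_i$power$dic else NA,
      converged_linear = if (!is.null(rep_i$linear)) rep_i$linear$converged else NA,
      converged_power = if (!is.null(rep_i$power)) rep_i$power$converged else NA)
    reports[[sp]] <- rep_i
  }

  out <- structure(reports, class = "trapeff_reports",
                   composition = composition, concordance = concordance,
                   config = config_provenance(config))
  if (!is.null(config$outdir)) {
    write_reports(out, config$outdir, runlog)
  }
  invisible(out)
}

summary_wide <- function(reports, which = c("linear", "power")) {
  which <- match.arg(which)
  rows <- list()
  for (rep_i in reports) {
    blk <- rep_i[[which]]
    if (is.null(blk)) next
    s <- as.data.frame(blk$summary)
    s <- s[!s$reference, , drop = FALSE]
    row <- data.frame(species = rep_i$species, n_strata = rep_i$n_strata)
    for (k in seq_len(nrow(s))) {
      key <- gsub(" ", "_", tolower(s$arm[k]))
      row[[paste0(key, "_alpha")]] <- s$alpha[k]
      row[[paste0(key, "_alpha_lo")]] <- s$alpha_lo[k]
      row[[paste0(key, "_alpha_hi")]] <- s$alpha_hi[k]
      if (which == "power") {
        row[[paste0(key, "_gamma")]] <- s$gamma[k]
        row[[paste0(key, "_gamma_lo")]] <- s$gamma_lo[k]
        row[[paste0(key, "_gamma_hi")]] <- s$gamma_hi[k]
        row[[paste0(key, "_proportionality")]] <-
          unname(blk$proportionality[s$arm[k]])
      } else {
        row[[paste0(key, "_label")]] <- unname(blk$labels[s$arm[k]])
      }
    }
    if (which == "linear" && !is.null(rep_i$exophagy)) {
      for (m in names(rep_i$exophagy)) {
        row[[paste0("ratio_out_in_", m)]] <- rep_i$exophagy[[m]]$point
      }
    }
    row$dic <- blk$dic
    row$converged <- blk$converged
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) return(data.frame())
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
  do.call(rbind, rows)
}

write_reports <- function(reports, outdir, runlog) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(round_cols(attr(reports, "composition"), 4),
                   file.path(outdir, "composition.csv"), row.names = FALSE)
  utils::write.csv(round_cols(attr(reports, "concordance"), 2),
                   file.path(outdir, "concordance.csv"), row.names = FALSE)
  utils::write.csv(round_cols(summary_wide(reports, "linear"), 2),
                   file.path(outdir, "efficiency_linear.csv"), row.names = FALSE)
  utils::write.csv(round_cols(summary_wide(reports, "power"), 2),
                   file.path(outdir, "efficiency_power.csv"), row.names = FALSE)
  json_reports <- lapply(reports, function(r) {
    list(species = r$species, n_strata = r$n_strata,
         totals = as.list(r$totals), eligible = r$eligible,
         reason = r$reason,
         linear = if (!is.null(r$linear)) {
           list(summary = as.data.frame(r$linear$summary), dic = r$linear$dic,
                pD = r$linear$pD, converged = r$linear$converged,
                labels = as.list(r$linear$labels))
         },
         power = if (!is.null(r$power)) {
           list(summary = as.data.frame(r$power$summary), dic = r$power$dic,
                pD = r$power$pD, converged = r$power$converged,
                proportionality = as.list(r$power$proportionality))
         },
         exophagy = r$exophagy)
  })
  jsonlite::write_json(json_reports, file.path(outdir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(outdir, "runlog.jsonl"), open = "wt")
  on.exit(close(con))
  for (entry in runlog) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  invisible(outdir)
}

#' @export
print.trapeff_reports <- function(x, ...) {
  cat("<trapeff_reports>", length(x), "species;",
      sum(vapply(x, `[[`, logical(1), "eligible")), "model-eligible\n")
  for (r in x) {
    cat(sprintf("  %-28s strata %3d  %s\n", r$species, r$n_strata,
                if (r$eligible) "fitted" else r$reason))
  }
  invisible(x)
}
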