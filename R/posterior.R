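#' Equal-tailed posterior point estimate and credible interval
#'
#' Point estimate is the posterior median; the interval is equal-tailed at
#' quantiles (1-level)/2 and 1-(1-level)/2, computed with the default
#' interpolation rule (`stats::quantile` type 7) on the supplied scale.
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return Named numeric vector `c(point, lo, hi)`.
#' @export
posterior_interval <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number strictly between 0 and 1")
  }
  stopifnot(is.numeric(draws), length(draws) >= 1L)
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(point = stats::median(draws), lo = qs[1], hi = qs[2])
}

#' Summarize a fitted efficiency model
#'
#' Per-arm posterior medians and equal-tailed credible intervals for alpha (and
#' gamma under the power variant), computed on the natural (not log) scale,
#' plus DIC and the convergence flag. The reference arm appears with its
#' structurally fixed alpha = gamma = 1.
#'
#' @param fit A [trapeff_fit].
#' @param level Credibility level in (0, 1); default 0.95.
#' @return An object of class `posterior_summary`: a data.frame with one row
#'   per arm (columns `arm`, `reference`, `alpha`, `alpha_lo`, `alpha_hi`,
#'   `gamma`, `gamma_lo`, `gamma_hi`) carrying attributes `variant`, `dic`,
#'   `pD`, `converged`, `level`, `species`.
#' @export
summarize_fit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "trapeff_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number strictly between 0 and 1")
  }
  min_per_chain <- min(vapply(fit$chains, nrow, integer(1)))
  if (min_per_chain < 500L) {
    stop("summaries require at least 500 retained draws per chain (got ",
         min_per_chain, ")")
  }
  ref <- arm_label(fit$reference_arm)
  rows <- list(data.frame(arm = ref, reference = TRUE,
                          alpha = 1, alpha_lo = 1, alpha_hi = 1,
                          gamma = 1, gamma_lo = 1, gamma_hi = 1))
  for (arm in fit$candidate_arms) {
    a <- posterior_interval(fit$draws[, paste0("alpha.", arm)], level)
    if (fit$spec$variant == "power") {
      g <- posterior_interval(fit$draws[, paste0("gamma.", arm)], level)
    } else {
      g <- c(point = 1, lo = 1, hi = 1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, reference = FALSE,
      alpha = a[["point"]], alpha_lo = a[["lo"]], alpha_hi = a[["hi"]],
      gamma = g[["point"]], gamma_lo = g[["lo"]], gamma_hi = g[["hi"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  d <- dic(fit)
  structure(out, class = c("posterior_summary", "data.frame"),
            variant = fit$spec$variant, dic = d[["dic"]], pD = d[["pD"]],
            converged = fit$converged, level = level, species = fit$species)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>", attr(x, "species"), "-", attr(x, "variant"),
      "variant;", sprintf("%d%%", round(100 * attr(x, "level"))),
      "equal-tailed intervals; DIC =", round(attr(x, "dic"), 2),
      "(pD =", paste0(round(attr(x, "pD"), 2), ");"),
      if (attr(x, "converged")) "converged" else "NOT converged", "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Deviance information criterion of a fitted model
#'
#' Conditional-deviance DIC: for each retained draw, the deviance is
#' -2 times the Poisson log likelihood of every observed count given that
#' draw's fitted means (lambda_i for the reference arm,
#' (alpha_m lambda_i)^gamma_m for candidates). pD is the mean deviance minus
#' the deviance at a plug-in point, and DIC = mean deviance + pD. Lower is
#' better. The plug-in follows the BUGS-style convention of posterior means of
#' the sampled nodes, which live on the log scale here; the plug-in for
#' \{lambda_i, alpha_m, gamma_m\} is therefore their geometric posterior mean.
#' (Natural-scale means are unstable plug-ins for the heavy-tailed efficiency
#' posteriors the power variant produces when the exponent is weakly
#' identified.)
#'
#' @param fit A [trapeff_fit].
#' @return Named numeric vector `c(dic, pD, mean_deviance)`. If the fit is
#'   flagged unconverged a warning is attached.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "trapeff_fit"))
  if (!fit$converged) {
    warning("DIC computed from a fit flagged as not converged", call. = FALSE)
  }
  draws <- fit$draws
  n <- fit$n_strata
  arms_ <- fit$candidate_arms
  lam <- draws[, paste0("lambda.", seq_len(n)), drop = FALSE]
  deviance_at <- function(lam_row, alpha_row, gamma_row) {
    ll <- sum(stats::dpois(fit$x, lam_row, log = TRUE))
    for (m in seq_along(arms_)) {
      ll <- ll + sum(stats::dpois(fit$y[, m],
                                  (alpha_row[m] * lam_row)^gamma_row[m],
                                  log = TRUE))
    }
    -2 * ll
  }
  alpha <- draws[, paste0("alpha.", arms_), drop = FALSE]
  gamma <- if (fit$spec$variant == "power") {
    draws[, paste0("gamma.", arms_), drop = FALSE]
  } else {
    matrix(1, nrow(draws), length(arms_))
  }
  dev <- vapply(seq_len(nrow(draws)), function(d) {
    deviance_at(lam[d, ], alpha[d, ], gamma[d, ])
  }, numeric(1))
  dbar <- mean(dev)
  geo_mean <- function(m) exp(colMeans(log(m)))
  dhat <- deviance_at(geo_mean(lam), geo_mean(alpha), geo_mean(gamma))
  pd <- dbar - dhat
  c(dic = dbar + pd, pD = pd, mean_deviance = dbar)
}

# Accept either a posterior_summary or a plain data.frame of printed estimates.
.summary_frame <- function(summary, needed, variant_required = NULL) {
  if (inherits(summary, "posterior_summary")) {
    v <- attr(summary, "variant")
    if (!is.null(variant_required) && !identical(v, variant_required)) {
      stop("this classification requires a ", variant_required,
           "-variant fit (got ", v, ")")
    }
  }
  if (!all(needed %in% names(summary))) {
    stop("summary must contain columns: ", paste(needed, collapse = ", "))
  }
  as.data.frame(summary)
}

#' Classify per-arm efficiency against the reference
#'
#' An arm samples at a credibly higher rate than the reference when the lower
#' 95% bound of alpha exceeds 1, credibly lower when the upper bound is below
#' 1, and is otherwise comparable (interval straddles 1, the value indicating
#' non-difference).
#'
#' @param summary A `posterior_summary` from a linear-variant fit, or any
#'   data.frame with columns `alpha`, `alpha_lo`, `alpha_hi` (e.g. printed
#'   study estimates).
#' @return Character vector of labels in \{"higher", "comparable", "lower"\},
#'   named by arm when an `arm` column is present.
#' @export
classify_efficiency <- function(summary) {
  df <- .summary_frame(summary, c("alpha", "alpha_lo", "alpha_hi"), "linear")
  lab <- ifelse(df$alpha_lo > 1, "higher",
                ifelse(df$alpha_hi < 1, "lower", "comparable"))
  names(lab) <- if ("arm" %in% names(df)) df$arm else rownames(df)
  lab
}

#' Assess proportional versus density-dependent sampling
#'
#' Under the power variant, sampling is proportional when the 95% credible
#' interval for the exponent gamma contains 1 (boundary inclusive); an interval
#' excluding 1 indicates density-dependent trap performance.
#'
#' @param summary A `posterior_summary` from a power-variant fit, or a
#'   data.frame with columns `gamma`, `gamma_lo`, `gamma_hi`.
#' @return Character vector of labels in \{"proportional", "density-dependent"\},
#'   named by arm when an `arm` column is present.
#' @export
assess_proportionality <- function(summary) {
  df <- .summary_frame(summary, c("gamma", "gamma_lo", "gamma_hi"), "power")
  lab <- ifelse(df$gamma_lo <= 1 & df$gamma_hi >= 1,
                "proportional", "density-dependent")
  names(lab) <- if ("arm" %in% names(df)) df$arm else rownames(df)
  lab
}

#' Outdoor-to-indoor efficiency ratio of one method
#'
#' Computes alpha_outdoor / alpha_indoor draw-wise and summarizes the ratio
#' with the posterior median and equal-tailed interval; the ratio of the
#' per-arm posterior medians is reported alongside. A ratio above 1 indicates
#' the method catches relatively more outdoors (exophagic biting).
#'
#' @param fit A [trapeff_fit] whose arms include both locations of `method`
#'   (the reference arm counts with alpha identically 1).
#' @param method Method label, e.g. `"SHK"`.
#' @param level Credibility level; default 0.95.
#' @return A list with `point`, `lo`, `hi` (draw-wise ratio summary) and
#'   `ratio_of_medians`.
#' @export
exophagy_ratio <- function(fit, method, level = 0.95) {
  stopifnot(inherits(fit, "trapeff_fit"))
  arm_draws <- function(loc) {
    lbl <- paste(method, loc)
    if (identical(lbl, arm_label(fit$reference_arm))) {
      return(rep(1, nrow(fit$draws)))
    }
    col <- paste0("alpha.", lbl)
    if (!col %in% colnames(fit$draws)) {
      stop("arm not present in fit: ", lbl)
    }
    fit$draws[, col]
  }
  a_out <- arm_draws("outdoor")
  a_in <- arm_draws("indoor")
  pi_ <- posterior_interval(a_out / a_in, level)
  list(point = pi_[["point"]], lo = pi_[["lo"]], hi = pi_[["hi"]],
       ratio_of_medians = stats::median(a_out) / stats::median(a_in))
}
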