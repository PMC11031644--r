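# Independent brute-force oracles and small data builders used across tests.

# A small two-site, three-night table with two arms and two species.
tiny_table <- function() {
  count_table(data.frame(
    species = rep(c("Aedes demo", "Culex demo"), each = 8),
    method = rep(rep(c("HLC", "SHK"), each = 4), 2),
    location = "indoor",
    site = rep(c("s1", "s1", "s2", "s2"), 4),
    night = rep(c("n1", "n2"), 8),
    count = c(3, 0, 5, 2, 1, 0, 2, 1,
              0, 0, 7, 1, 0, 0, 3, 0)))
}

# Build a species_stratum_table directly from a reference vector and a
# candidate count matrix (columns = candidate arm labels).
make_sst <- function(x, y, ref = c("HLC", "indoor"),
                     cand = list(c("SHK", "indoor"))) {
  y <- as.matrix(y)
  stopifnot(length(cand) == ncol(y))
  n <- length(x)
  recs <- data.frame(species = "toy species", method = ref[1],
                     location = ref[2], site = "s1",
                     night = sprintf("n%03d", seq_len(n)), count = x)
  for (m in seq_along(cand)) {
    recs <- rbind(recs, data.frame(
      species = "toy species", method = cand[[m]][1],
      location = cand[[m]][2], site = "s1",
      night = sprintf("n%03d", seq_len(n)), count = y[, m]))
  }
  to_species_matrix(count_table(recs), "toy species",
                    arm_key(ref[1], ref[2]))
}

# Brute-force log posterior: explicit loops over strata and arms, written
# against the model's definition rather than the package's vectorized code.
brute_force_lp <- function(x, y, params, priors, variant) {
  y <- as.matrix(y)
  if (params$sigma <= 0) return(-Inf)
  lp <- 0
  for (i in seq_along(x)) {
    lam_i <- exp(params$log_lambda[i])
    lp <- lp + dnorm(params$log_lambda[i], params$mu, params$sigma, log = TRUE)
    lp <- lp + dpois(x[i], lam_i, log = TRUE)
    for (m in seq_len(ncol(y))) {
      a <- exp(params$log_alpha[m])
      g <- if (variant == "power") exp(params$log_gamma[m]) else 1
      lp <- lp + dpois(y[i, m], (a * lam_i)^g, log = TRUE)
    }
  }
  lp <- lp + dnorm(params$mu, priors$mu_location, priors$mu_scale, log = TRUE)
  lp <- lp + log(2) + dnorm(params$sigma, 0, priors$sigma_scale, log = TRUE)
  for (m in seq_len(ncol(y))) {
    lp <- lp + dnorm(params$log_alpha[m], priors$log_alpha_location,
                     priors$log_alpha_scale, log = TRUE)
    if (variant == "power") {
      lp <- lp + dnorm(params$log_gamma[m], priors$log_gamma_location,
                       priors$log_gamma_scale, log = TRUE)
    }
  }
  lp
}

# Direct-formula concordance oracle: ranks with average ties, Lin's
# coefficient with population moments, computed step by step.
brute_force_ccc <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  n <- length(ra)
  ma <- sum(ra) / n
  mb <- sum(rb) / n
  va <- sum((ra - ma)^2) / n
  vb <- sum((rb - mb)^2) / n
  sab <- sum((ra - ma) * (rb - mb)) / n
  2 * sab / (va + vb + (ma - mb)^2)
}

# A degenerate fit object whose draws are one repeated parameter point;
# exercises summaries and DIC without MCMC.
constant_fit <- function(x, y, n_draws = 1000) {
  y <- as.matrix(y)
  n <- length(x)
  lam <- pmax(x, 0.5)
  draws <- cbind(mu = mean(log(lam)), sigma = 1,
                 matrix(1, n_draws, ncol(y),
                        dimnames = list(NULL, paste0("alpha.cand", seq_len(ncol(y))))),
                 matrix(rep(lam, each = n_draws), n_draws, n,
                        dimnames = list(NULL, paste0("lambda.", seq_len(n)))))
  draws[, "mu"] <- mean(log(lam))
  structure(list(draws = draws,
                 chains = list(draws[1:(n_draws / 2), , drop = FALSE],
                               draws[(n_draws / 2 + 1):n_draws, , drop = FALSE]),
                 diagnostics = data.frame(parameter = "mu", rhat = 1, ess = n_draws),
                 converged = TRUE, species = "constant",
                 candidate_arms = paste0("cand", seq_len(ncol(y))),
                 reference_arm = arm_key("HLC", "indoor"),
                 x = x, y = y, n_strata = n,
                 spec = model_spec("linear"),
                 settings = mcmc_settings(seed = 1),
                 data_fingerprint = "constant"),
            class = "trapeff_fit")
}

# Shared fast MCMC settings for tests.
fast_mcmc <- function(seed, warmup = 1000) {
  mcmc_settings(n_chains = 2, n_warmup = warmup, n_draws = 1000, seed = seed)
}
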