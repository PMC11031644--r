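test_that("log posterior matches a brute-force evaluation at random points", {
  x <- c(4L, 0L, 11L)
  y <- cbind(c(2L, 1L, 6L), c(0L, 0L, 3L))
  sst <- make_sst(x, y, cand = list(c("SHK", "indoor"), c("SHK", "outdoor")))
  priors <- prior_set()
  withr::with_seed(2024, {
    for (variant in c("linear", "power")) {
      spec <- model_spec(variant)
      for (k in 1:20) {
        params <- list(mu = rnorm(1, 0, 2),
                       sigma = runif(1, 0.1, 3),
                       log_alpha = rnorm(2, 0, 1),
                       log_gamma = rnorm(2, 0, 0.5),
                       log_lambda = rnorm(3, 1, 1))
        expect_equal(log_posterior(sst, params, spec),
                     brute_force_lp(x, y, params, priors, variant),
                     tolerance = 1e-8)
      }
    }
  })
  # sigma <= 0 is outside the support
  expect_identical(log_posterior(sst, list(mu = 0, sigma = -1,
                                           log_alpha = c(0, 0),
                                           log_lambda = c(0, 0, 0)),
                                 model_spec("linear")), -Inf)
})

test_that("fits are reproducible and refuse degenerate inputs", {
  cfg <- scenario_config("abundant-proportional", seed = 12)
  sst <- to_species_matrix(simulate_counts(cfg)$table, cfg$species_label)
  f1 <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(5))
  f2 <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(5))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(6))
  expect_false(identical(f1$draws, f3$draws))

  # too few strata
  tiny <- make_sst(c(3L, 1L), cbind(c(1L, 0L)))
  expect_error(fit_efficiency(tiny, model_spec("linear"), fast_mcmc(1)),
               "at least 3 strata")
  # all-zero reference column
  zero_ref <- make_sst(c(0L, 0L, 0L, 0L), cbind(c(1L, 2L, 0L, 3L)))
  expect_error(fit_efficiency(zero_ref, model_spec("linear"), fast_mcmc(1)),
               "unidentifiable")
})

test_that("a candidate arm duplicating the reference has alpha near 1", {
  withr::with_seed(3, x <- rpois(30, exp(rnorm(30, 2, 0.5))))
  sst <- make_sst(x, cbind(x))
  fit <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(4))
  s <- summarize_fit(fit)
  row <- s[!s$reference, ]
  expect_lt(row$alpha_lo, 1)
  expect_gt(row$alpha_hi, 1)
})

test_that("an all-zero candidate arm drives alpha towards zero", {
  withr::with_seed(9, x <- rpois(30, 8))
  sst <- make_sst(x, cbind(rep(0L, 30)))
  # log(alpha) drifts in its prior tail here, so R-hat flags are expected
  fit <- suppressWarnings(fit_efficiency(sst, model_spec("linear"), fast_mcmc(4)))
  s <- suppressWarnings(summarize_fit(fit))
  row <- s[!s$reference, ]
  expect_lt(row$alpha, 0.05)
  expect_lt(row$alpha_hi, 0.1)
})

test_that("posterior intervals follow the documented quantile rule", {
  pi_ <- posterior_interval(as.numeric(1:100), level = 0.90)
  expect_equal(pi_[["point"]], 50.5)
  expect_equal(pi_[["lo"]], 5.95)
  expect_equal(pi_[["hi"]], 95.05)
  degen <- posterior_interval(rep(2, 500))
  expect_equal(unname(degen), c(2, 2, 2))
  expect_error(posterior_interval(1:10, level = 1), "between 0 and 1")
  expect_error(posterior_interval(1:10, level = 0), "between 0 and 1")
})

test_that("summaries carry intervals on the alpha scale and respect the draw floor", {
  fit <- constant_fit(c(5L, 3L, 8L), cbind(c(2L, 1L, 4L)))
  s <- summarize_fit(fit)
  expect_s3_class(s, "posterior_summary")
  expect_true(all(s$alpha_lo <= s$alpha & s$alpha <= s$alpha_hi))
  expect_identical(s$alpha[s$reference], 1)
  short <- constant_fit(c(5L, 3L, 8L), cbind(c(2L, 1L, 4L)), n_draws = 400)
  expect_error(summarize_fit(short), "500 retained draws")
  expect_error(summarize_fit(fit, level = 2), "between 0 and 1")
})

test_that("a degenerate posterior has pD of zero", {
  fit <- constant_fit(c(5L, 3L, 8L), cbind(c(2L, 1L, 4L)))
  d <- dic(fit)
  expect_equal(d[["pD"]], 0, tolerance = 1e-9)
  expect_equal(d[["dic"]], d[["mean_deviance"]], tolerance = 1e-9)
})

test_that("efficiency classification reproduces the printed study calls", {
  tab5 <- study_table("linear")
  shk_in <- data.frame(alpha = tab5$shk_indoor, alpha_lo = tab5$shk_indoor_lo,
                       alpha_hi = tab5$shk_indoor_hi)
  rownames(shk_in) <- tab5$species
  lab <- classify_efficiency(shk_in)
  expect_identical(unname(lab[tab5$species == "Aedes fryeri"]), "higher")
  expect_identical(unname(lab[tab5$species == "Mansonia uniformis"]), "lower")
  shk_out <- data.frame(alpha = tab5$shk_outdoor, alpha_lo = tab5$shk_outdoor_lo,
                        alpha_hi = tab5$shk_outdoor_hi)
  lab_out <- classify_efficiency(shk_out)
  expect_identical(unname(lab_out[tab5$species == "Anopheles ziemanni"]), "comparable")
})

test_that("proportionality assessment reads the gamma interval, boundary closed", {
  tab6 <- study_table("power")
  shk_in <- data.frame(gamma = tab6$shk_indoor_gamma,
                       gamma_lo = tab6$shk_indoor_gamma_lo,
                       gamma_hi = tab6$shk_indoor_gamma_hi)
  lab <- assess_proportionality(shk_in)
  expect_identical(unname(lab[tab6$species == "Culex pipiens"]), "proportional")
  expect_identical(unname(lab[tab6$species == "Culex tritaeniorhynchus"]),
                   "density-dependent")
  # boundary interval (1, 1) counts as proportional
  expect_identical(unname(assess_proportionality(
    data.frame(gamma = 1, gamma_lo = 1, gamma_hi = 1))), "proportional")
  # variant guard: a linear-fit summary cannot be assessed for proportionality
  lin <- summarize_fit(constant_fit(c(5L, 3L, 8L), cbind(c(2L, 1L, 4L))))
  expect_error(assess_proportionality(lin), "power")
})

test_that("exophagy ratio recovers the outdoor:indoor contrast", {
  cfg <- simulation_config(
    200, mu = 2, sigma = 0.5,
    arms = data.frame(method = "SHK", location = c("indoor", "outdoor"),
                      alpha = c(0.5, 2), gamma = 1),
    seed = 14)
  sst <- to_species_matrix(simulate_counts(cfg)$table, cfg$species_label)
  fit <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(15))
  r <- exophagy_ratio(fit, "SHK")
  expect_lt(abs(r$point - 4) / 4, 0.2)
  expect_lt(abs(r$ratio_of_medians - 4) / 4, 0.2)
  expect_error(exophagy_ratio(fit, "CDC"), "not present")
  # for the reference method the indoor arm is the unit reference itself,
  # so no outdoor HLC arm exists in this two-arm design
  expect_error(exophagy_ratio(fit, "HLC"), "HLC outdoor")
})

test_that("doubling candidate counts doubles the efficiency estimate", {
  cfg <- scenario_config("abundant-proportional", seed = 77)
  sim <- simulate_counts(cfg)
  sst <- to_species_matrix(sim$table, cfg$species_label)
  doubled <- sst
  cand <- setdiff(colnames(sst$counts), "HLC indoor")
  doubled$counts[, cand] <- 2L * doubled$counts[, cand]
  f1 <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(8))
  f2 <- fit_efficiency(doubled, model_spec("linear"), fast_mcmc(8))
  a1 <- summarize_fit(f1)
  a2 <- summarize_fit(f2)
  ratio <- a2$alpha[!a2$reference] / a1$alpha[!a1$reference]
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("linear and power fits agree when sampling is proportional", {
  cfg <- scenario_config("abundant-proportional", seed = 55, n_strata = 100)
  sst <- to_species_matrix(simulate_counts(cfg)$table, cfg$species_label)
  fl <- fit_efficiency(sst, model_spec("linear"), fast_mcmc(16))
  fp <- suppressWarnings(
    fit_efficiency(sst, model_spec("power"), fast_mcmc(16, warmup = 2000)))
  sl <- summarize_fit(fl)
  sp <- suppressWarnings(summarize_fit(fp))
  al <- sl$alpha[!sl$reference]
  ap <- sp$alpha[!sp$reference]
  expect_lt(abs(log(ap / al)), 0.25)
  expect_identical(unname(assess_proportionality(sp)[2]), "proportional")
})

test_that("exchangeable indoor/outdoor arms give exophagy intervals around 1", {
  # both candidate arms observe the same Poisson law, so the 95% ratio
  # interval should contain 1 in the large majority of replicates
  contains <- vapply(23:27, function(s) {
    withr::with_seed(s, {
      lam <- exp(rnorm(40, 2, 0.5))
      x <- rpois(40, lam)
      y <- cbind(rpois(40, lam), rpois(40, lam))
    })
    sst <- make_sst(x, y, cand = list(c("SHK", "indoor"), c("SHK", "outdoor")))
    fit <- suppressWarnings(
      fit_efficiency(sst, model_spec("linear"), fast_mcmc(19)))
    r <- exophagy_ratio(fit, "SHK")
    r$lo < 1 && r$hi > 1
  }, logical(1))
  expect_gte(sum(contains), 3)
})
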