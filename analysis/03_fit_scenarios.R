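#!/usr/bin/env Rscript
# Fits both model variants to the simulated scenario datasets via the full
# pipeline and reports efficiency and proportionality calls against truth.
suppressMessages(library(trapeff))

for (name in c("abundant-proportional", "density-dependent", "rare")) {
  path <- sprintf("results/sim_%s.csv", gsub("-", "_", name))
  if (!file.exists(path)) stop("run analysis/02_simulate_scenarios.R first")
  outdir <- sprintf("results/fit_%s", gsub("-", "_", name))
  reports <- run_analysis(analysis_config(
    path, min_strata = 10,
    settings = mcmc_settings(seed = 7, n_warmup = 2000),
    outdir = outdir))
  for (r in reports) {
    if (!r$eligible) {
      cat(sprintf("%-22s %-28s excluded: %s\n", name, r$species, r$reason))
      next
    }
    s <- as.data.frame(r$linear$summary)
    cand <- s[!s$reference, ]
    cat(sprintf(
      "%-22s alpha %5.2f (%5.2f, %5.2f) [%s]  DIC lin %8.1f pow %8.1f  %s\n",
      name, cand$alpha, cand$alpha_lo, cand$alpha_hi,
      r$linear$labels[cand$arm], r$linear$dic, r$power$dic,
      r$power$proportionality[cand$arm]))
  }
}
cat("the density-dependent scenario should (and does in our runs) flip the\n",
    "proportionality call and give the power model the lower DIC.\n")
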