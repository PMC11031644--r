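# Simulation scenario registry. Each scenario fixes the generative parameters of
# the Poisson-lognormal model: per-stratum log-density ~ Normal(mu, sigma^2),
# reference counts Poisson(lambda_i), candidate counts Poisson((alpha*lambda_i)^gamma).
# Parameter regimes echo magnitudes reported for the field study's species
# (see the methods vignette); n_strata may be overridden per call.
abundant-proportional:
  description: >
    Abundant species sampled proportionally at half the reference efficiency
    (Ma. uniformis-like regime used for parameter-recovery and coverage studies).
  n_strata: 35
  mu: 2.0
  sigma: 0.5
  species_label: "synthetic abundant-proportional"
  arms:
    - {method: SHK, location: indoor, alpha: 0.5, gamma: 1.0}
efficient-outdoor:
  description: >
    Candidate trap outperforming the indoor reference outdoors (An.
    pharoensis-like regime, sparse indoor reference catch).
  n_strata: 34
  mu: 0.0
  sigma: 1.0
  species_label: "synthetic efficient-outdoor"
  arms:
    - {method: SHK, location: outdoor, alpha: 11.8, gamma: 1.0}
density-dependent:
  description: >
    Candidate yield scaling super-linearly with density (Cx.
    tritaeniorhynchus-like regime; exponent well above one).
  n_strata: 34
  mu: 3.4
  sigma: 1.0
  species_label: "synthetic density-dependent"
  arms:
    - {method: SHK, location: indoor, alpha: 0.13, gamma: 1.96}
rare:
  description: >
    Rare species present in few strata with an efficient candidate trap
    (Ae. fryeri-like regime).
  n_strata: 12
  mu: -1.0
  sigma: 1.0
  species_label: "synthetic rare"
  arms:
    - {method: SHK, location: indoor, alpha: 2.97, gamma: 1.0}
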