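# socbuffer

Social network, survival, and dispersal analyses of maternal loss in
group-living primates.

## The problem

In most social mammals with extended mother–offspring co-residence,
maternal loss after weaning still reduces fitness, with the orphan's
degraded social environment — lost integration, rank, and knowledge —
suspected as the mechanism. Some species, though, may *buffer* that loss:
other group members strengthen their relationships with the orphan and no
survival cost is detectable. Testing this requires an unusually wide
inferential chain, which this package implements end to end for
focal-sampled populations such as long-term mountain gorilla monitoring
programmes:

- **Association networks** from 10-minute focal scans: Simple Ratio Index
  (SRI) edges, where the SRI of a dyad is the number of focal scans of
  either member on which the pair associated (within 2 m, or in affiliative
  contact) divided by the two members' summed focal-scan counts; paired
  183-day pre/post windows around each maternal-loss incident; a strict
  ">12 scans in both windows" node filter.
- **Change in network position**: normalized binary degree, weighted
  degree, and eigenvector centrality; a mixed model
  `delta ~ orphan + age + deviance + s(scans) + (1 | incident)`; and
  two-tailed **node-label permutation** inference (orphan labels permuted
  among immatures within the same incident,
  `P_null = 2 x #(null t beyond observed t) / N`).
- **Dyadic relationship change**: spline-smoothed mixed models of per-dyad
  SRI change with partner age-sex classes (dominant male as reference),
  age-mate, maternal-sibling, and paternity terms.
- **Survival**: Cox proportional hazards with the orphan class as a
  time-varying covariate (episode-split at loss age, Efron ties), and a
  Bayesian **Siler** mortality trajectory analysis
  (`h(x) = a0 e^{-a1 x} + c + b0 e^{b1 x}`) with three covariate
  structures compared by DIC.
- **Dispersal / reproduction / dominance**: binomial GLMs for natal
  dispersal, a Gaussian GLM on `sqrt(age at first birth - 8)`, a binomial
  GLM for first-offspring infant survival, and descriptive
  dominance-attainment proportions.
- A seeded **synthetic-data generator** that emulates the focal sampling
  design (50-minute focals, 10-minute scans, latent dyadic association
  probabilities, orphan-effect injection, Siler lifespans), so the whole
  pipeline is testable and calibratable with no field data.

## Worked example

Simulate a monitored population with one maternal-loss incident per group,
inject a proximity boost on orphan–dominant-male dyads, and run the
pipeline:

```r
library(socbuffer)

cfg <- run_config(
  seed = 7, window_days = 40, n_sets = 20, thin = 5,
  mcmc_chains = 2, mcmc_iter = 3000,
  population = population_config(n_groups = 2, group_size_range = c(13, 16),
                                 study_years = 3, seed = 7))
res <- full_run(cfg, verbose = FALSE)

res$permutation
#> Node-label permutation test: Est = -0.015 +/- 0.045, t = -0.331, p = 0.741, P_null = 0.9 (20 sets)

res$dic
#>          model      dic  delta_dic converged
#> 1         null 35.51359 0.00000000      TRUE
#> 2 prop_hazards 35.54774 0.03415385      TRUE
```

The permutation report pairs the mixed-model estimate (here: orphans'
normalized weighted-degree change differed from non-orphans' by
−0.015 ± 0.045) with the permutation p-value; this configuration injects
no orphan effect, and accordingly neither is significant and the DIC table
prefers the covariate-free survival model — the generating truth. The
classed dispersal model on the packaged reference counts reproduces its
published coefficients exactly:

```r
fit_dispersal_glm(gorilla_dispersal_counts()$female)
#> GLM (binomial-logit), n = 3
#>                      est    se     z     p
#> (Intercept)       -0.511 0.365 -1.40 0.162
#> classinfant        0.693 0.707  0.98 0.327
#> classjuv_subadult  1.609 0.894  1.80 0.072
```

`vignettes/social-buffering-methods.Rmd` documents the models, priors,
permutation scheme, generator assumptions, and limitations.

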