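---
title: "Methods: networks, permutation inference, and survival models for maternal loss"
author: "socbuffer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: networks, permutation inference, and survival models for maternal loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socbuffer)
```

## The scientific problem

In long-lived social mammals, losing the mother after weaning can still be
costly: mothers shape their offspring's social integration, rank, and access
to resources long after nutritional independence. Whether a species' social
organisation *buffers* that loss is an empirical question with two halves:

1. **Fitness**: do orphans survive, disperse, reproduce, or attain dominance
   differently from non-orphans?
2. **Social response**: do orphans' relationships with remaining group
   members change after the loss, and with whom?

This package implements the full inferential chain used to answer both
halves for group-living primates monitored with focal-animal sampling, as in
long-term mountain gorilla field programmes: association networks from focal
scans, node-label permutation inference on changes in network position,
spline-smoothed mixed models of dyadic relationship change, Cox proportional
hazards with a time-varying orphan covariate, a Bayesian Siler mortality
trajectory analysis compared by DIC, and binomial/Gaussian GLMs for
dispersal and reproduction. A seeded synthetic-data generator emulates the
sampling design so every stage can be exercised and calibrated without
field data.

## Data model

- **Roster**: one row per individual — id, group, sex, birth and death (or
  censoring) dates, mother and father id (`unknown` allowed), dominant-male
  flag. Ages are decimal years with 365.25-day years.
- **Focal scans**: one row per 10-minute instantaneous scan within a
  50-minute focal follow — date, group, focal id, the set of ids within
  2 m (*proximity*), and the set in affiliative contact (*contact*).
  Contact implies proximity, so the contact set is always a subset.
- **Maternal-loss incidents**: group, date, the mother, and the orphans
  aged 2–8 years at the loss. Orphan classes are binned by age at loss:
  infant [2, 4), juvenile [4, 6), subadult [6, 8). Losses are the death
  *or permanent transfer* of the mother; both remove her from the group's
  networks, so the generator treats them identically.

## Association networks

Edges are the **Simple Ratio Index**: with exactly one focal per scan, the
SRI of a dyad is the number of scans of either member on which the pair
associated, divided by the summed focal-scan counts of the two members.
This is the "proportion of sampling periods of either individual in which
the pair associated" dialect of the association-index family; joint-focal
scans cannot occur under this protocol, so no joint term is needed.

For each incident we build one network per period and association type over
two 183-day calendar windows: *pre* ends the day before the loss, *post*
starts on the loss day (the boundary day is assigned to post). The node set
is identical in both periods: individuals with **strictly more than 12**
focal scans in *both* windows. Orphans' mothers are excluded from both
networks (they are absent post, and their pre-period dyads with the orphans
are extracted separately as a descriptive quantity). If an orphan itself
fails the scan threshold, the incident carries inadequate data and is
dropped — mirroring the real studies' use of a subset of all recorded
incidents.

Node metrics are binary degree, weighted degree, and eigenvector centrality
of the weighted adjacency, each scaled by the maximum over *all* nodes in
the network (eigenvector centrality is implicitly max-normalized, so the
degree metrics are normalized the same way). The leading eigenvector is
computed by a dense symmetric eigendecomposition: networks here have tens
of nodes at most, the dense solve is exact, and — unlike ARPACK with a
random start — it is bit-reproducible, which the end-to-end reproducibility
contract requires. On disconnected networks the score concentrates on the
dominant component; isolated nodes score 0 before re-normalization.

## Change in network position and permutation inference

For every immature (2–8 years at the incident) in every usable incident we
compute the pre-to-post change in each normalized metric, plus a
regression-to-the-mean guard: the *deviance* of the individual's pre value
from the mean pre value over immatures in its network. The change model is

> delta ~ orphan + age + deviance + s(total focal scans) + (1 | incident)

fitted by REML with `lme4`. The smooth is an unpenalized cubic B-spline
basis with 5 functions (shrinking automatically when a small sample cannot
support 5); replicating a specific penalized-GAMM smoother is a non-goal —
the inference rides on the orphan term, not the smoother's wiggles. If the
mixed fit fails the model falls back to the fixed-effect spline regression
with a warning.

Because network metrics of individuals in the same network are not
independent, the orphan t-statistic is referenced against a **node-label
permutation null**: orphan labels are permuted only among immatures within
the same incident, the identical model is refitted on each permuted label
set, and the observed t is compared with the null t distribution. The
two-tailed p is `2 x #(null > observed) / N` above the null median and
`2 x #(null < observed) / N` below it; ties count as neither, at the median
both formulas are evaluated and the larger reported, and the result is
capped at 1.

The permutation stream is a thinned chain: each elementary move picks an
incident at random and swaps the labels of two of its immatures drawn
*with replacement*, every 200th state being emitted (10,000 sets by
default). The with-replacement draw makes some moves no-ops, which keeps
the chain aperiodic even for an incident with exactly two immatures —
a deterministic two-cycle thinned at an even lag would otherwise never
leave its starting state. Per-incident orphan counts are conserved by
construction, and incidents whose immatures are all orphans (or all
non-orphans) are excluded upstream, since their labels cannot be permuted.

## Dyadic relationship change

The dyadic table has one record per (immature, group member, association
type): the change in SRI weight across the loss, with partner age-sex class
assigned at the loss date (infant, juvenile, subadult by sex, blackback,
adult female, and adult males split into the single dominant male versus
subordinates — the dominant male is the reference level throughout).
Mother–offspring dyads are excluded, as are non-orphans' dyads whose
partner is an orphan (those changes are confounded by the partner's own
response). Three models share the same machinery:

- **All immatures**: orphan status, partner class, and their interaction,
  with immature age and sex, a mean-focal-scans spline, and random
  intercepts for immature-in-incident-in-group and partner. The
  orphan-by-class interaction is the quantity of interest: it asks whether
  orphans' relationships with a class changed more than other immatures'
  relationships with the same class, in the same groups, over the same
  periods.
- **Orphans only**: age, sex, age-mate (strictly within 2 years of age),
  maternal sibling, partner class, and class-by-sibling interaction.
- **Adult males only**: dominance, sibling, paternity, and the
  dominance-by-sibling interaction. The dominance-by-paternity interaction
  is deliberately absent: where dominant males sire most offspring the two
  are collinear. Records with unknown paternity are excluded.

The random-slope shorthand "(Group | ID)" that GAMM packages print is
realized here as nested random intercepts (immature within group, plus
partner); the grouping structure, not the slope, carries the
non-independence. Wald Z with normal-based p-values are reported — with
hundreds of dyads and the degrees of freedom ambiguity of mixed models,
the normal reference is the standard reporting choice, and it is flagged
as such in the output.

## Survival

**Cox.** Everyone enters the risk set at age 2 (deaths before 2 are
excluded: unweaned infants cannot survive alone, so earlier losses are not
comparable); the orphan class is a time-varying covariate realized by
episode-splitting each orphan's record at the loss age. Estimation is
`survival::coxph` with Efron ties (ages recorded to days make ties rare
but possible). Classes can be the four-level coding or the merged
juvenile/subadult coding used when subadult samples are small. Monotone
partial likelihoods (no events in a class) are flagged as separation.

**Bayesian Siler trajectory.** The Siler hazard
`h(x) = a0 exp(-a1 x) + c + b0 exp(b1 x)` sums decaying infant mortality, a
constant background, and exponential senescence. The likelihood of a
left-truncated, right-censored record is `h(exit)^event * S(exit | entry)`
with the closed-form cumulative hazard. Orphans are truncated at their loss
age, non-orphans at 2. Three covariate structures are compared by DIC:
no covariates; proportional hazards (one log-hazard-ratio per orphan
class); and class-specific multipliers on all five Siler parameters. The
proportional-hazards variant with all effects at zero reproduces the null
likelihood exactly (a nesting identity the tests check).

Sampling is adaptive random-walk Metropolis on log-parameters: the first
half of burn-in adapts component-wise step sizes toward 44% acceptance,
the second half switches to full-covariance proposals estimated from the
chain history (scaled 2.38²/d toward 23.4% acceptance) — the Siler
likelihood has strongly correlated ridges (a0 with a1, b0 with b1) on
which component-wise proposals mix poorly. Priors are weakly informative:
half-normal(1) on the hazard-level parameters a0, c, b0, half-normal(2)
on the rates a1, b1, and standard normal on covariate effects. DIC uses
Spiegelhalter's pD = mean deviance − deviance at the posterior mean, and a
split-chain R-hat above 1.1 flags the fit (and its DIC) as unreliable.
Defaults are 2 chains of 6,000 iterations with 50% burn-in — calibration
experiments at n = 500 lifespans converge well within that budget; longer
runs are a config change. Birth-date uncertainty (±90-day windows in real
rosters) is not modelled; dates are taken as given, a known limitation.

## Dispersal, reproduction, dominance

Natal dispersal (females: before first birth; males: before 16 years, the
median male dispersal age) is a logistic GLM on orphan class with the
juvenile/subadult classes merged. The packaged reference counts
(`gorilla_dispersal_counts()`) are reconstructed from published class
percentages and sample sizes; because a saturated one-factor logistic model
has closed-form coefficients (log-odds differences) and standard errors
(square roots of summed reciprocal cell counts), this fit is exactly
reproducible and serves as the package's desk-checkable anchor, e.g.:

```{r table3}
fit_dispersal_glm(gorilla_dispersal_counts()$female)
```

Age at first birth uses the response `sqrt(age - 8)` — 8 years is the
earliest recorded age at first birth and the square root symmetrizes the
right skew; ages at or below 8 are a domain error, not silently clamped.
First-offspring infant survival (to 4 years) is a logistic GLM on maternal
age at first birth, dispersal, and orphan class. Dominance attainment is a
descriptive proportion only — males surviving in-population to 23 years
(the oldest observed age of first dominance), scored 1 for a dominance
tenure of at least six *consecutive* months — deliberately without a test,
as orphan-class cells with three or five males cannot support one.

## The synthetic generator

The generator is the package's study stand-in, and its defaults are the
study conditions, not tuning knobs:

- Several groups of 18–30 animals (one dominant male, subordinate males,
  adult females, immatures with in-roster mothers), one maternal-loss
  incident per group with at least one orphan-aged offspring and one
  unrelated immature.
- Latent per-scan dyadic association probabilities, independent across
  scans, with contact ≤ proximity; mother–offspring and
  dominant-male–immature dyads get elevated baselines. Independence keeps
  the SRI's expectation equal to the latent probability, so additive
  orphan effects on the probability scale map one-to-one onto expected
  SRI changes — that is why effects are additive on probability rather
  than log-odds.
- 24 scans per group-day (about 4 monitored hours of 10-minute scans),
  which at these group sizes yields focal-scan totals per individual per
  6-month window on the order of 150–300, the scale of the real
  monitoring programme's reported means.
- Siler lifespans (defaults a0 = 0.1, a1 = 1.2, c = 0.01, b0 = 0.002,
  b1 = 0.12 — a plausible great-ape schedule with senescence from the
  thirties), an optional proportional orphan hazard, and logistic
  dispersal outcomes with configurable class offsets.
- One master integer seed; every module derives its own sub-stream by
  stable string hashing, so adding a stage never perturbs another stage's
  draws.

Mid-level generators (`simulate_change_records()`,
`simulate_dyad_records()`) emit model-ready tables directly at the study's
sampling frame — 19 incidents, 28 orphans, 108 non-orphan immatures for
node-level changes; ~30 orphans with ~24 partners each for dyads — with
noise scales chosen so the orphan coefficient's standard error lands near
0.03 on the SRI-change scale, matching the order of the published models.
Calibration experiments (type-I rates, power, parameter recovery) run on
these; the full focal-scan pipeline is exercised end-to-end at smaller
scale. What the generator does *not* emulate: temporal autocorrelation in
associations, observation error in partner detection, group fission or
inter-group transfer dynamics, and seasonal sampling gaps. Passing
calibration here therefore shows the inferential machinery is correct
under the design's assumptions, not that those assumptions hold in any
particular field dataset.

## Numerical and design choices

- Strict "> 12 scans" read literally: an individual with exactly 12 scans
  in either window is excluded.
- SRI denominator is the sum of the two members' focal counts; monotone in
  added association scans; symmetric by construction.
- Lifespan sampling inverts the closed-form cumulative hazard by root
  finding (tolerance 1e-10); a proportional hazard effect scales the
  target cumulative hazard.
- Degenerate inputs short-circuit: an all-zero network warns and returns
  zero metrics; a constant response returns zero coefficients; an all-zero
  effect configuration is the exact null.
- Permutation ties (`observed == null value`) count as neither greater nor
  lesser, per the two-tailed formulas; `p` is capped at 1.
- Episode splitting keeps left-truncation exact: pre-loss episodes carry
  the non-orphan class and no event.
- Problem sizes in the shipped tests: 200 replicate datasets with 100
  permutation sets each for null calibration, 50 for power; 20 replicates
  of n = 500 lifespans at 2 chains × 6,000 iterations for survival-model
  calibration; 50 replicates for dyadic coefficient recovery. These are
  the package's chosen verification scales; the analysis defaults (10,000
  permutation sets) remain the reporting standard.

## Known limitations

- The permutation null conditions on the observed networks; it does not
  address sampling error in the SRI weights themselves (data-stream
  permutations would, and are out of scope).
- Normal-based p-values for mixed and binomial models; small-sample exact
  inference is not attempted.
- The Siler sampler is a general-purpose Metropolis scheme; pathological
  configurations (e.g. near-zero hazards with heavy censoring) can stall
  and are flagged by R-hat rather than repaired automatically.
- Dominance labels are inputs (from displacement-based ratings upstream);
  the package does not compute dominance hierarchies.
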