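---
title: "Models and methods behind swarmevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swarmevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmevol)
```

`swarmevol` implements the quantitative pipeline of a microbial
social-evolution experiment: growth kinetics, actor–recipient competition
statistics, phenotype-based clonal diversity, metabolome normalization and
differential selection, and suppressor-mutation classification. This vignette
documents the models, the defaults and why they were chosen, the numerical
conventions, and what the synthetic-data generators do and do not establish.

## Growth kinetics

The estimator is deliberately simple and fixed: find the first time point
with OD ≥ 0.01, take that point and the following nine (10 points at
10-minute sampling ≈ 1.5 h), and report the OLS slope of ln OD against time
in hours.

Decisions where the procedure was underdetermined:

* *Crossing rule.* "Reached OD 0.01" is read as the first index with
  OD ≥ threshold, no interpolation; `include_crossing = FALSE` shifts the
  window one point later for users who read "after" exclusively.
* *Fit.* OLS on natural-log OD. Nothing more elaborate (e.g. a full logistic
  fit) is attempted because the windowing rule itself defines the quantity.
* *Short series.* If fewer than 10 points remain after the crossing, the fit
  uses what remains (≥ 2) and sets `truncated = TRUE` rather than silently
  dropping the well; a never-crossing well is a hard, named error so plate
  sweeps (`plate_growth_rates()`) can report it per well.
* *Blanks.* No background subtraction by default; a `blank` argument exists
  but is off because the source procedure does not mention one.
* *Windows inside a logistic curve.* On a noise-free logistic trajectory the
  windowed estimate is biased low by roughly the mean of OD/K across the
  window. With the default threshold 0.01 the bias is below 1% only when the
  carrying capacity K is a few hundred times the threshold; the tests use
  K = 10 (three orders of magnitude above threshold) for the 1% oracle.

A flat window (constant OD) returns rate 0 with `fit_r2 = NA` and an
`r2_undefined` flag: R² is meaningless when the response has zero variance.

## Actor–recipient statistics

Per technical replicate: actor fractions at start and end, their difference,
and the recipient's end total. Aggregation is flat over all 9 replicates
(3 biological × 3 technical) because the assay is reported with a single
n = 9; no nested variance model is fitted. The 95% CI is t-based on the 9
values — the simplest interval consistent with that flat design.

**Sign convention.** The printed formula, (start fraction) − (final
fraction), is *positive when the actor declines*, while the narrative calls a
declining actor's outcome a net *negative* benefit. Both readings are
implemented (`sign_convention = "printed"` (default) or `"gain"`); neither is
silently preferred, and results record which was used.

**Neutral-control matching.** Recipient benefit divides by the
neutral-control recipient total of the same biological replicate when one
exists, else by the pooled control mean — the closest pairing with a graceful
fallback.

## Clonal diversity

Isolates are clustered on their six liquid-culture channels (absorbance at
600/690/310 nm; GFP 488/525; pyoverdine 405/465; 340/440) by agglomerative
clustering; clusters are the groups connected after removing merges above the
cutoff (for single linkage this equals connected components of the
distance-≤-cutoff graph, which is how the tests brute-force-verify it).
The score is 100 × clusters-represented / isolates-sampled per population.

Unstated choices, all explicit arguments recorded in the output:

* *Linkage and metric*: single linkage, Euclidean — the Matlab `linkage`
  defaults, hence the most plausible reconstruction.
* *Standardization*: channels are z-scored by default because raw absorbance
  and fluorescence live on scales that differ by orders of magnitude.
  Z-scoring has a side effect worth knowing: channels that carry no signal
  are inflated to unit variance, so when only a subset of channels separates
  the strains, very noisy panels can swamp the cutoff. The acceptance script
  therefore clusters its constructed panels on the raw feature scale
  (`standardize = FALSE`), where the planted geometry (within-cluster spread
  0.05, between-cluster separation 30) brackets the cutoff.
* *The cutoff 1.12* is meaningful only on the feature scale it was chosen
  for; it is a configuration value, not a constant of nature.

Populations with other than 8 isolates are scored with their own count as
denominator and flagged `nonstandard_n`.

## Metabolome normalization and differential selection

The concentration model assumes each (strain, batch) group differs from the
others by one multiplicative scale factor, identifiable because the majority
of metabolites are unchanged:

$$\log E[\text{peakArea}] = \mu_{\text{metabolite}} + \beta_{\text{strain}} +
\gamma_{\text{batch}} + (\beta\gamma)_{\text{strain,batch}}$$

* *Dialects.* The default fits OLS on log areas; `dialect = "glm"` fits a
  Gaussian GLM with log link on the raw areas (warm-started from the OLS
  solution). On balanced noise-free data both return offsets equal to
  differences of group mean log areas — the oracle the tests enforce. Under
  multiplicative (log-normal) noise, however, squared error on the raw scale
  is dominated by the few most abundant metabolites, which inflates the
  offset variance severalfold; that is why OLS on logs is the default rather
  than the raw-scale GLM.
* *Leakage and the two-stage fit.* Metabolites that truly change between
  strains bias the group offsets by (sum of their effects)/(number of
  metabolites). With 10 four-fold effects among 142 metabolites that bias
  reaches ~0.06 log units — larger than the ~0.015 sampling noise of the
  offsets. `fit_scaling_model_robust()` makes the model's own assumption
  operational: fit, flag changed metabolites, refit on the unchanged
  majority (the same logic as median-of-ratios normalization in RNA-seq).
  Across 50 simulations at study scale the two-stage fit recovers all
  offsets to < 0.05; a single pass does not, and the single-pass bias is a
  real property of the printed model, not a bug.
* *Selection.* Per-metabolite one-way ANOVA across strains on log normalized
  areas. "Multiple hypothesis correction with an alpha of 0.01 and an n of
  142" is implemented as Bonferroni — the only correction fully determined
  by (α, n); Holm is available. `n_tests` defaults to the table's metabolite
  count. The ANOVA runs on the log scale because the model is
  multiplicative. Constant metabolites get p = 1 and a flag instead of NaN.
* *Display conventions.* Row standardization uses the sample (n−1) standard
  deviation; constant rows map to zeros with a flag. Clustergrams use
  Euclidean distance with average linkage on both axes (recorded in the
  object); per-strain difference panels are computed on log areas, not on
  the row-standardized scale.
* *Ingestion.* Zero/missing peak areas are dropped with a message, never
  imputed.

## Variant filtering and suppressor classes

Coordinates are 1-based inclusive throughout. A call is an artifact if its
reported position (indels included — only the position decides) lies inside
any excluded region; the reporter-fusion span itself must be supplied by the
user, since it depends on the reference genome used. Classification is by
locus label, with an hfq "promoter" window of 300 bp upstream by default —
the observed promoter mutations have no printed bounds, so the window is
configurable. An isolate hitting both *crc* and *hfq* is reported as a
conflict, because the experiment's observed pattern (every isolate exactly
one of the two) is a finding the pipeline must be able to falsify, not
enforce. Configuration is read from JSON (`read_loci_config()`).

## What the generators emulate — and what a green test does not establish

All generator distributions are stand-ins; the source experiments state no
noise model for any measurement.

* *Growth curves*: logistic with additive Gaussian measurement noise floored
  at 0 — the simplest saturating form consistent with plate-reader data. No
  lag phase, no well-to-well drift.
* *Competitions*: the actor frequency follows the logistic update
  $p' = p e^{sg} / (p e^{sg} + 1 - p)$; plating is multinomial at a fixed
  depth per time point. Defaults: the 25:1 actor:recipient inoculum
  (start fraction 25/26), 10 generations (a plausible 24-h swarm expansion),
  depth 1000. Because the depth is fixed, recipient *totals* in simulation
  track frequency, not absolute growth — recipient-benefit ratios from
  simulated data are frequency proxies.
* *Metabolomes*: log-normal areas,
  exp(baseline + strain effect + log scale + noise), baseline log abundance
  N(10, 2), noise SD 0.2 on the log scale (moderate LC-MS technical
  variation, CV ≈ 20%), scale factors uniform on [0.5, 2], 10 of 142
  metabolites changed four-fold, each in one random non-reference strain.
  Real LC-MS data additionally has censoring at the detection limit,
  correlated metabolites and heavier tails; none of that is emulated, so the
  recovery and error-rate results certify the estimators under the stated
  model only.
* *Phenotype panels*: cluster centroids sit at `separation` along the
  channel axes (recycled with growing magnitude beyond six clusters), so all
  centroid pairs are at least `separation` apart; isolates get isotropic
  Gaussian noise and are dealt to populations round-robin. At
  separation/noise = 20 with six clusters the default pipeline recovers the
  planted partition exactly; at ratio 10 an occasional outlier isolate
  splits off under single linkage (adjusted Rand ≈ 0.975) — a property of
  single-linkage cutting, documented rather than hidden.

All generators are pure functions of their seed and restore the caller's RNG
stream.

## Known limitations

* The 1.12 cutoff and the channel set entering the authors' dendrogram are
  not recoverable from the source; defaults are reconstructions.
* The scaling model assumes one scale factor per (strain, batch) group — a
  per-sample drift term is deliberately absent because the printed formula
  has no sample term.
* `benefit_to_recipient` from simulated competitions reflects frequencies,
  not absolute recipient growth (see above).
* No spatial or agent-based swarming model, no read-level sequence
  simulation, and no mass-spectral preprocessing: the pipeline starts at
  extracted peak areas and tabulated variant calls.
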