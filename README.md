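# swarmevol

Quantitative analysis of microbial social-evolution experiments.

When a bacterium such as *Pseudomonas aeruginosa* swarms, it secretes costly
public goods (rhamnolipid surfactants) that benefit every cell nearby.
Experimental-evolution studies of this behavior generate a characteristic mix
of data: plate-reader growth curves, colony-count competition assays between a
helping "actor" strain and a non-producing "recipient", phenotype panels of
evolved isolates, LC-MS metabolite peak-area tables, and variant-call tables
from whole-genome sequencing of suppressor mutants. `swarmevol` implements the
downstream quantitative pipeline for all five, plus a synthetic-data module
that generates each input with known ground truth so every stage can be
validated end to end.

## The statistics at the core

**Growth rate.** The exponential rate is the OLS slope of ln OD versus time
(h) over the first 10 time points at/after the culture reaches OD 0.01
(10-minute sampling).

**Social fitness.** With actor fraction p = (actor cells)/(total cells),

- benefit to actor = p_start − p_final (printed convention; a switch provides
  the "gain" convention p_final − p_start),
- benefit to recipient = (recipient total with actor)/(recipient total with a
  neutral competitor),

aggregated flat over 3 biological × 3 technical replicates (n = 9) with a
t-based 95% CI.

**Clonal diversity.** Isolates are clustered on their liquid-culture
absorbance/fluorescence channels by agglomerative clustering cut at linkage
distance 1.12; each population's diversity score is
100 × (clusters represented)/(isolates sampled), i.e. 12.5%–100% for 8
isolates.

**Metabolome normalization and selection.** Sample-concentration scale
factors come from the log-link model

    log(peakArea) ~ mutant_id * experiment_id + metabolite_id

fitted under the assumption that most metabolites are unchanged (log-scale
OLS by default; a Gaussian GLM with log link on raw areas is available, and a
two-stage `fit_scaling_model_robust()` refits after excluding metabolites
flagged as changed). Areas are divided by exp(group offset); changed
metabolites are then selected by per-metabolite one-way ANOVA across strains
with Bonferroni control (significant ⇔ p < α/n, default α = 0.01, n = 142).
Row-standardized matrices and dual-dendrogram clustergrams support the
heat-map view; `strain_difference_panel()` reports per-strain mean log
differences versus the wild type for significant metabolites.

**Variant filtering.** Calls inside the reporter-fusion region (1-based,
inclusive) are excluded as artifacts; isolates are then classified by
suppressor locus — *crc*, *hfq* (including a configurable promoter window
upstream, default 300 bp), other — with hard conflict flags when one isolate
hits both.

## Worked example

```r
library(swarmevol)

## growth kinetics
gc <- simulate_growth_curve(rate = 0.7, od0 = 0.0025, carrying_capacity = 1.2,
                            noise_sd = 0.002, seed = 3, strain_id = "WT")
exponential_growth_rate(gc)
#> <growth_rate_fit> rate 0.6687 / h (10 points from index 14)  R^2 = 0.9600

## metabolome: simulate -> normalize -> select
truth <- metabolome_truth(seed = 11)           # 142 metabolites, 5 strains,
sim <- simulate_metabolome(truth)              # 2 batches x 3 replicates
model <- fit_scaling_model_robust(sim$table, reference_strain = "WT")
normalized <- normalize_peak_areas(sim$table, model)
hits <- select_changed_metabolites(normalized, alpha = 0.01, reference_strain = "WT")
sum(hits$significant)
#> [1] 10            # exactly the 10 planted 4-fold effects, no false positives

## phenotype diversity
panel <- simulate_phenotype_panel(n_clusters = 6, separation = 10,
                                  noise_sd = 0.5, seed = 5)
diversity_score(hierarchical_clusters(panel))
#> <diversity_report> percent of distinct phenotype clusters per population
#>  population n_isolates n_clusters score nonstandard_n
#>           1          8          6    75         FALSE
#>           ...                          (6 of 8 possible clusters present)

## actor-recipient assay with a selection coefficient of 0.08/generation
tr <- competition_truth(selection_coefficient = 0.08, generations = 10,
                        sampling_depth = 5000)
aggregate_assay(simulate_social_assay(tr, seed = 9))
#> <social_benefit> n = 9 replicates (printed sign convention)
#>   benefit to actor:     -0.0207  [-0.0224, -0.0190]
#>   benefit to recipient: 0.4821  [0.4549, 0.5093]
```

The negative "benefit to actor" means the actor *gained* frequency under the
printed sign convention (start − final). The recipient ratio below 1 reflects
that the simulator resamples a fixed plating depth, so recipient counts track
frequency, not absolute growth.

## Acceptance script

`scripts/acceptance.R` rebuilds the two analytic anchor values of the
diversity score from scratch: it simulates a phenotype panel whose isolates
form a single cluster and one whose isolates are all phenotypically distinct,
runs the hierarchical clustering at cutoff 1.12, scores the populations, and
writes the two percentages as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
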