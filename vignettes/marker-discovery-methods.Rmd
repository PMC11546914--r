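---
title: "Primary and secondary metabolomic markers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primary and secondary metabolomic markers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabmarker)
```

## The problem

A targeted LC--MS/MS experiment yields a small samples-by-metabolites
peak-area matrix — here the motivating design is 39 cardiac-surgery patients
(12 who developed postoperative delirium, 27 who did not) by 210 plasma
metabolites. Per-metabolite nonparametric tests on such data are typically
empty-handed: with n this small and hundreds of tests, only huge
concentration shifts survive FDR control. metabmarker implements two
complementary multivariate strategies:

* **Primary markers** — small *combinations* of metabolites whose joint
  concentrations discriminate cases from controls, found by a genetic
  algorithm (GA) whose fitness is the minimum cross-validation-fold accuracy
  of a gradient-boosted tree classifier.
* **Secondary markers** — metabolites whose *relationships* with the rest of
  the profile, learned from controls by denoising autoencoders (DAEs), fail
  to hold in cases, even when their marginal concentrations are unchanged.
  These are flagged by Mann--Whitney tests on per-sample reconstruction
  errors with Benjamini--Hochberg control, aggregated as a consensus count
  over an ensemble of 100 differently sized autoencoders.

## Preprocessing model

`impute_metabolites()` applies the median rule: a metabolite missing in at
most 5% of samples has missing cells replaced by the median of its observed
values; above that, the metabolite is dropped (the rule's complement is not
stated anywhere we could follow, and dropping is the only reading consistent
with a curated final metabolite count). Observed cells are never touched, so
imputation is idempotent, and the keep/drop decision depends only on the
missing count. `log_transform_metabolites()` defaults to the natural log; the
base is configurable but statistically inert here because every downstream
stage is rank-, tree- or network-based.

`fit_scaler()`/`apply_scaler()` exist for the neural stage: the DAE uses a
rectifier *output* layer, which cannot emit negative values, so log-scale
data (which contain negatives) would be unlearnable. Each metabolite is
min--max mapped to [0, 1] using the **control group only**, and out-of-range
values in cases are clipped (with a count). This scaling step is a
deviation-by-necessity: the original description is silent on scaling, but a
ReLU output forces nonnegative targets.

## Screening

`screen_metabolites()` is the deliberately conservative univariate baseline:
two-sided Mann--Whitney per metabolite (exact permutation distribution when
`min(n, m) <= 8` with no ties, otherwise the normal approximation with tie
and continuity correction), Benjamini--Yekutieli by default. BY's harmonic
factor keeps FDR control under the arbitrary dependence that metabolite
panels exhibit; Benjamini--Hochberg is available and is what the secondary
stage uses across metabolites within one model. Two-sidedness and alpha =
0.05 are field-convention defaults.

## Primary markers

The fitness of a metabolite subset is the **minimum** held-out-fold accuracy
of a gradient-boosted tree classifier over 5 stratified folds
(`fitness_subset()`). The minimum — rather than the mean — rewards
combinations that classify uniformly well. The booster is a from-scratch
implementation of the XGBoost algorithm (second-order logistic loss, exact
greedy splits, L2 leaf regularisation) at 1000 rounds, learning rate 0.05,
and otherwise library defaults (depth 6, lambda 1, min child weight 1); no
boosted-tree package exists in the supported dependency set, so the booster
ships in `src/` and is cross-checked in the tests against behavioural
expectations (perfect separators, null data) rather than another library.

`ga_search()` evolves fixed-length chromosomes of k distinct metabolite
indices (separate passes for k = 3 and k = 4 by default) with tournament
selection (size 3), uniform index crossover with duplicate repair, per-gene
mutation to an unused index (rate 0.1), and elitism. Each of the 100
independent runs retains its single best combination; the per-metabolite
**inclusion frequency** over retained combinations is the primary-marker
ranking. Within a run all subsets share one seeded fold assignment
(variance reduction: subsets are compared on identical splits); across runs
folds differ, so inclusion frequencies integrate over fold noise.
`evaluate_auc()` reports the pooled out-of-fold ROC AUC of a chosen
combination — in-sample AUC of a 1000-round booster would be ~1 trivially,
so the cross-validated pooling is the honest summary.

Two properties of the min-fold-accuracy statistic matter for interpreting
results and set hard limits we document rather than hide:

* At n = 39 it lives on a coarse grid (a fold holds ~8 samples), so ties are
  pervasive, and a run's "best" combination is one of many tied optima.
* Maximising it over thousands of subsets is feature selection with CV
  inside the selection loop: on pure-noise data the best-found fitness is
  substantially above the majority-class rate (~0.78 vs 0.69 in our null
  experiments). Inclusion frequencies, not the fitness value itself, carry
  the evidence.

## Secondary markers

The noise model corrupts a profile as `CN = CO + d * e` with
`e ~ N(0, sd = CO)` per metabolite, i.e. noise SD proportional to the value
(`d = 0.25` by default; 500 noisy replicates per profile). Noise is applied
in the scaled [0, 1] space the network consumes, which keeps the formula
self-consistent; the alternative spaces are exposed by scaling outside
`run_dae_ensemble()` (pass `scale = FALSE`).

Each DAE is a three-layer fully connected network (210 -> h -> 210 for the
motivating design; h ranges over 50..149, one model per width, which is the
only reading that yields exactly 100 models), ReLU on *all* layers, MSE
loss, Adam at 0.001, batch 8, exactly 20 epochs, 80/20 train/monitor split
of the control samples and no early stopping. Training is bit-reproducible:
all randomness (split, init, noise, shuffles) is drawn in R under the
model's derived seed, and the C++ training loop is deterministic.

Anomaly detection feeds **clean** profiles through each trained model,
takes `|input - output|` per sample and metabolite, and compares case vs
control errors by two-sided Mann--Whitney with BH across metabolites.
Metabolites flagged by at least 97 of 100 models are selected. By default
control errors use **all** controls, including those seen in training; this
follows the original contrast of the two patient groups, but it carries
in-sample bias — training profiles reconstruct better than unseen ones, so
case (always out-of-sample) errors sit above control errors for *every*
metabolite to some degree. `holdout_controls_only = TRUE` removes the bias
at a severe power cost (only ~5 held-out controls per model). The consensus
ranking, not a single model's flag list, is the interpretable output.

### What the synthetic generator does and does not establish

`simulate_metabolome()` draws log-normal abundances (log-means U(10, 16),
log-SDs U(0.3, 0.8) — peak areas roughly 2e4 to 9e6, a realistic MRM range)
with equicorrelated metabolite blocks (pairwise r = 0.6 by default) shared
by both groups. Primary markers shift the case log-mean by a stated number
of control SDs; secondary markers have their case values independently
resampled from the marginal — correlation broken, concentration untouched,
which is precisely the secondary-marker concept. Missingness is MCAR.

A green recovery test on this generator establishes that the pipeline
detects the structure it models — not that it would detect the weaker,
messier structure of real plasma data (batch effects, censored-at-LOD
missingness, heavy tails are all absent). Conversely, two documented limits
are intrinsic to the statistics, not artifacts of the generator, and our
acceptance experiments leave them visibly red rather than quietly passing:

* **Joint inclusion of a complementary pair.** Because each GA run retains
  one best combination and the fitness grid is coarse, demanding inclusion
  frequency >= 0.9 for *both* members of a planted pair requires triples
  containing both to be strictly dominant in >= 90% of runs. Mean-shift
  Gaussian markers cannot produce that: a near-separating single marker
  makes its partner redundant (ties at fitness 1), while moderate pairs are
  matched by lucky noise triples. We verified this across shift regimes
  (2.5--4 SD, independent and anti-correlated) and against an independent
  boosted-tree implementation.
* **Top-5 consensus placement of 5 correlation-break markers at r = 0.6
  with 12 cases.** The case/control error separation for a broken
  metabolite is bounded by the conditional structure (error AUC <= ~0.65 at
  r = 0.6), while 47 null metabolites' empirical AUCs scatter with SD ~0.1
  on a single data draw. An oracle detector using the true generative
  conditional means — no autoencoder at all — placed the planted five in
  the top five in 0 of 10 replicates, so no reconstruction-error rank test
  can do better on the same draws. The ensemble's value on such data is the
  full consensus *ranking* (planted metabolites consistently top the
  mean-error-gap ordering at well-generalising widths), not exact top-k
  placement.

For the 52-metabolite experiments the ensemble's hidden widths span 8..20:
the configured 50..149 range is impossible below 52 features, and widths
beyond ~p/2 memorise the ~21 training profiles (training MSE far below
held-out MSE) instead of learning the block structure.

## Enrichment

`ora()` is a local over-representation analysis: one-sided upper-tail
hypergeometric per pathway against the universe of *measured* metabolites
that map to the annotation namespace, BH across pathways. Web enrichment
tools use undocumented internal universes, so their printed p-values are not
comparable to a local ORA and are not reproduction targets here.
`combine_marker_sets()` implements the union (for combined enrichment — the
correlation-break markers sharpen the pathway signal of the
concentration-shift markers) and the intersection (dual-status markers).

## Numerical and degenerate-input choices

* Mann--Whitney with all pooled values identical returns p = 1, never NaN.
* A constant metabolite scales to 0.5 (with a warning) rather than 0/0.
* A metabolite with all values missing is dropped, never imputed.
* GBT split ties resolve to the lowest feature index, then lowest
  threshold; GA fitness ties resolve to the first maximum in population
  order — both deterministic.
* Derived seeds use a fixed affine-mod scheme (`seed * 1009 + counter`,
  mod 2^31 - 1) so single models/runs are reproducible in isolation.

## A worked miniature

```{r example, eval = FALSE}
sim <- simulate_metabolome(
  n_metabolites = 52, block_sizes = rep(13, 4),
  primary_idx = c(50, 51), primary_shift = 4, secondary_idx = 1:3, seed = 1
)
d <- preprocess_metabolites(sim$data)

screen_metabolites(d)                      # near-empty by design
ga  <- ga_search(d, subset_sizes = 3, n_runs = 20,
                 population_size = 30, generations = 30, seed = 17)
tidy(ga)                                   # inclusion frequencies
evaluate_auc(d, tidy(ga)$metabolite[1:3], seed = 1)

ens <- run_dae_ensemble(d, hidden_sizes = round(seq(8, 20, length.out = 20)),
                        seed = 11)
tidy(ens)                                  # consensus ranking
autoplot(ens)
```

## Known limitations

* The booster and DAE are purpose-built for tiny tabular matrices; neither
  is a general-purpose learner (no sparse inputs, no GPU, binary labels
  only).
* In-sample control errors bias per-model anomaly flags upward; interpret
  consensus counts comparatively, not as calibrated FDRs.
* The generator's blocks are exchangeable-correlation idealisations; real
  metabolite covariance is neither block-diagonal nor homogeneous.
* With ~39 samples, every statistic here is fold- and draw-noisy;
  reported fitness values should be read together with inclusion
  frequencies and, where possible, medians over fold seeds.
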