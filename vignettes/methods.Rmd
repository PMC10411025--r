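---
title: "Methods: comparing search-query volume with registry case counts for rare diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing search-query volume with registry case counts for rare diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(querycase)
```

## The problem

Rare-disease epidemiology suffers from two complementary biases. Hospital
registries under-ascertain: difficult diagnoses (metabolite panels,
pathology, genetic testing) mean missing and delayed case reports, with the
shortfall varying strongly by disease. Search-query volume over-ascertains:
queries come not only from patients but from clinicians, students, and the
publicity-curious, so a film or a news cycle can inflate a disease's
apparent size severalfold. Neither source alone yields patient counts that
can be trusted, but comparing the two *rankings* — which diseases look large
in each system — is informative and far more robust than comparing counts,
because within-year ranking cancels any system-wide multiplicative bias.

`querycase` implements that comparison as a pipeline: keyword matching of a
query log, patient estimation from query share, annual two-system ranking,
interval coding of ranking differences, stability statistics, a
categorical-factor GLM, and a two-category classification.

## From queries to patient estimates

A disease lexicon lists, per disease, a stable id and the keywords (name,
English name, synonyms, aliases) that identify it in query text. Entries can
be flagged `excluded` — used when a rare-disease name overlaps a common
condition so its query traffic would be meaningless — and are dropped at
load with a report.

Text is normalized with Unicode NFKC, lowercased, and whitespace-collapsed;
CJK text has no case and is passed through without segmentation. A query
matches a disease when any normalized keyword occurs as a contiguous
substring of the normalized query. Whole-query equality is available
(`mode = "exact"`) but substring containment is the default: real queries
overwhelmingly append terms ("symptoms", "treatment", "what is ..."), and
equality would discard most disease-related traffic. A query matching *k*
diseases increments all *k* counts while the annual total `Q_y` counts it
once; dropping ambiguous queries would require an arbitrary precedence
rule. Repeated identical queries count separately — the estimator below
multiplies an *event* share by population, so event counting is the
consistent choice. The tally is a single streaming pass over the log in
fixed-size chunks, so memory does not grow with log length.

Search popularity is the query share `p_{d,y} = q_{d,y}/Q_y`, and the
search-estimated patient count is `N̂_{d,y} = p_{d,y} · P_y` with `P_y` the
population. The estimator assumes search users are a random sample of the
population; `N̂` is kept real-valued internally and rounded only in reports,
so downstream rankings never depend on rounding order.

## Ranking comparison

Within each year and system, diseases are ranked by patient count
descending, rank 1 largest. Ties are broken by ascending disease id: ranks
must be strict permutations of `1..D` for fixed-size rank blocks and
set-valued RDG membership to be well defined. The ranking difference
`δ = r^S − r^C` is coded into ranking-difference groups by
`(−∞,−τ) → 0`, `[−τ,τ] → 1`, `(τ,∞) → 2`, with both boundaries of the
central interval closed and `τ = 20` by default (adjustable to research
needs; raising `τ` can only grow group 1).

Consistency is summarised by blocking diseases into groups of 20 by search
rank and correlating block-mean search ranks with block-mean case ranks
(Pearson), per year. For a disease count that is an exact multiple of the
block size, correlating against block means or block indices is equivalent
(equal spacing); the block-mean form also covers a ragged final block, which
is retained rather than merged so every disease contributes. With fewer than
two blocks, or zero variance across block means, the correlation is
undefined and reported as `NA` with a warning. Stability over time is
summarised by the sizes of adjacent-year intersections of each RDG's
membership and by the sets of diseases persistently in the top 10 of each
system.

## The GLM

The model is `RDG ~ C(year) + C(disease group)` on disease-year
observations, with the RDG code (0/1/2) as a numeric response, fitted as a
Gaussian-family identity-link GLM (ordinary least squares) with Wald
`z = β/SE` and two-sided normal p-values. Two modelling choices deserve
justification because they were genuinely open:

* **Family/link.** An ordinal response might suggest a multinomial or
  ordinal model, but those produce per-level coefficient *sets* and
  intercepts on a logit scale. A single coefficient per factor level plus an
  intercept near the grand mean of the codes (≈ 1) is exactly the shape of a
  least-squares fit, so Gaussian/identity is the default; the coded response
  is treated as a numeric score.
* **Factor coding.** Default treatment coding absorbs one reference level
  per factor; a coefficient table listing *all* year levels and *all*
  disease-group levels alongside an intercept can only come from sum-to-zero
  effects coding, in which each level's coefficient is its deviation from
  the grand mean. The package fits with `contr.sum` and reconstructs the
  omitted level as minus the sum of the others, with its standard error from
  the coefficient covariance (`Var(−Σβ) = 1'V1`). Treatment coding remains
  available via `coding = "treatment"`.

The disease factor defaults to three groups formed by each disease's RDG in
a baseline year (the earliest), keeping the design small and interpretable;
a full per-disease dummy mode exists (`disease_factor = "disease"`) but is
off by default. Empty baseline groups are dropped with a warning.

## Classification

Diseases are classified per disease, but RDG is per disease-year, so a
reduction policy is needed. The default takes the majority code across
years, breaking ties toward the code observed most recently (recent years
best reflect the current relationship); a baseline-year policy is available.
The reduced code maps to two categories: code 0 → category 2 (high search
rank, low registry rank: publicity inflation and/or under-diagnosis
suspected — these diseases need patient identification among searchers or
better diagnostic support); codes 1 and 2 → category 1 (registry considered
relatively comprehensive — these diseases suit computational prediction of
patient numbers from search data).

## The synthetic scenario

Real query logs and the national registry are inaccessible, so the package
generates stand-ins with the statistical structure the analysis assumes:

* **Prevalence** per disease is log-normal (`prevalence_logmu`,
  `prevalence_logsigma`, cases per person): cross-disease prevalence spans
  orders of magnitude, and a heavy-tailed law reproduces the very skewed
  patient-count distributions that make rank-based comparison attractive.
  True patients are `T_{d,y} = round(prevalence_d · P_y)`.
* **Queries**: expected matching volume is `search_rate · T_{d,y} · π_{d,y}`
  with `π` a publicity multiplier, equal to `publicity_spike_scale` with
  probability `publicity_spike_prob` per disease-year and 1 otherwise;
  realized line counts are Poisson. Each emitted line embeds exactly one
  keyword of exactly one disease in a small query template, and generated
  lexicons are collision-free by construction, so round-trip tests can
  demand exact count recovery. Background lines that match nothing are added
  per year.
* **Registry**: a per-disease reporting rate `ρ_d` ~
  Beta(`reporting_alpha`, `reporting_beta`) (or a point mass via
  `reporting_rho`) models heterogeneous ascertainment; reported counts are
  Binomial(`T`, `ρ`). Poisson for queries and Binomial for reporting are the
  simplest laws consistent with a rate-per-patient narrative; the true laws
  of the real systems are unknown, and these are stand-ins.

All randomness derives from one seed through named sub-streams (lexicon,
prevalence, publicity, reporting, log emission, registry emission), so
emitting one artifact never perturbs the draws of another and every output
is reproducible file-for-file. The generator also exposes the noise-free
expectations and the ground-truth RDG table and classification obtained by
running the ranking analysis on those expectations; the ground-truth
category applies the same default (majority) policy as the pipeline, so the
noise-free oracle isolates the data path rather than the aggregation
policy.

### Default scenario

`default_scenario()` fixes the study conditions: 120 active diseases plus
one excluded lexicon entry (a 121-entry catalog with one stated exclusion),
years 2016–2019, near-census Chinese population figures (1.392–1.410
billion), prevalence log-normal with median 8 × 10⁻⁷ cases/person and
log-sd 1.3, publicity spikes in 15% of disease-years at ×8, and Beta(2, 2)
reporting rates. The query stream is desk-scale: `search_rate = 0.05`
queries per patient-year plus 20,000 background queries per year, giving a
log of roughly 150,000 lines over four years. Rankings are invariant to a
common rescaling of query volume (popularity is a share), so a
proportionally larger stream would produce the same rank analysis with
slightly less Poisson jitter; the chosen scale keeps a full run around ten
seconds on one CPU. Under these defaults roughly 70–80% of disease-years
fall in RDG 1, with the remainder split between groups 0 (publicity-spiked)
and 2 — the qualitative regime the method is designed for, where the two
systems agree on the bulk of diseases and disagreement is informative.

### What the generator does not emulate

No user-level structure (sessions, identities, deduplication), no regional
or demographic structure, no query-language variety beyond templates, no
cross-disease keyword ambiguity, and no serial correlation of publicity
across years. Passing tests therefore demonstrate that the pipeline's
statistics are computed correctly and that the method behaves as designed
under its own assumptions — not that the assumptions hold for real search
logs, where keyword collisions, bursty non-Poisson traffic and
market-share drift would all add error that only real data can quantify.

## Numerical and testing choices

Problem sizes are chosen for exactness and speed: oracle comparisons use
brute-force re-implementations (counting-based ranks, loop-built blocks and
intersections, hand-built normal equations) on instances of up to 10
diseases, where enumeration is trivially correct; GLM agreement is asserted
to 10⁻⁸; coefficient-recovery simulations use the 480-observation balanced
panel (120 diseases × 4 years, groups of 40) over 20 seeds and test the
across-seed mean of each estimate against its injected value at three
standard errors of that mean; generator moment checks use expectations of
1,000–10,000 with 10–20 replicates at three standard errors. Degenerate
inputs are handled explicitly: zero total query volume and missing
population years are errors naming the year; single-block consistency and
zero-variance block means give `NA` correlations with warnings; empty
baseline RDG groups are dropped with warnings; malformed log lines and
unknown registry ids are skipped and counted.

## Limitations

Rank-based comparison deliberately discards magnitude: it cannot detect a
bias common to all diseases in one system. The classification inherits the
cutoff `τ`; diseases near the boundary can change category under small
perturbations, so `τ` should be chosen (and reported) per research need.
The Gaussian treatment of an ordinal response is a descriptive device, not
a probability model for individual codes. And the synthetic calibration is
a stand-in: conclusions about real search and registry systems require the
real data.
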