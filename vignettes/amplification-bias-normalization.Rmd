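---
title: "Correcting multiplex-PCR amplification bias with synthetic-template spike-ins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting multiplex-PCR amplification bias with synthetic-template spike-ins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otsp)
library(dplyr)
```

## The problem

Bulk TCRβ repertoire sequencing from genomic DNA enriches the recombined
CDR3 locus with a multiplex PCR: 20 V-segment forward primers crossed with
13 J-segment reverse primers, 260 primer pairs in all. Each pair amplifies
with its own efficiency, so the raw read count of a clonotype confounds its
true abundance with the efficiency of the primer pair that amplified it.
Left uncorrected, this amplification bias distorts every downstream
repertoire metric.

`otsp` implements the computational core of an open protocol that measures
and removes this bias with spike-in controls: 260 synthetic templates (STs),
one per primer pair, 200 bp double-stranded DNA fragments added to the
reaction in equimolar amounts. After sequencing, ST reads are recognized by
a 9 bp universal barcode shared by all templates and assigned to their
template by a 16 bp template-specific barcode. Because the ST input is
equimolar, any spread in ST counts within a sample is amplification bias,
and measuring it per primer pair yields a correction factor.

## The count model

The replicate counts of one template across the samples of a batch are
modelled as negative binomial, `C ~ NB(m, d)`, parameterized by the mean
`m > 0` and dispersion `d >= 0` with

    E(C) = m,    var(C) = m + d m^2.

`d = 0` recovers the Poisson; on a log--log mean--variance plot the model
line approaches slope 2 at large means (`log v ~ log d + 2 log m`), which is
the signature checked by `mean_variance_table()` and by the acceptance
script. The maximum-likelihood estimate of `m` is the arithmetic mean of the
counts; `d` is estimated per template by maximizing the profile
log-likelihood on `[0, d_max]` (bounded scalar optimization, tolerance
`1e-8`, `d_max = 10`), clipping to 0 for under-dispersed data. The panel's
common dispersion is the **median** of the per-template estimates — a
deliberate robust choice rather than a pooled MLE — and a value near 0.125
with similar per-template dispersions indicates a sequencing process under
statistical control.

## Scaling factors and normalization

Two routes produce per-primer-pair scaling factors, both averaging exactly
1:

* **Batch-mean** factors `SF_i = C_i. / C..` — the template's mean count
  across the batch over the grand mean (`batch_scaling_factors()`).
* **NB-mean** factors `m_i / m_bar` from a fitted panel or pooled batches
  (`nb_scaling_factors()`). On a single batch these coincide exactly with
  the batch-mean factors because the NB mean MLE is the arithmetic mean;
  their value is that they can be estimated once from ST-only data and
  applied to later samples sequenced *without* spike-ins, saving cost and
  sequencing depth.

Normalization divides each primer-pair clonotype total by its factor,
`C'_i = C_i / SF_i`, and redistributes `C'_i` to the pair's clonotypes in
proportion to their raw counts. Within-pair proportions are untouched
(exactly); between-pair abundances shift by the factor ratios. Normalized
counts are kept real-valued — rounding would break the exact conservation
of the ST grand total under batch-mean normalization. A primer pair that
carries clonotype counts but has no usable factor (an all-zero ST row) is a
hard error: silently mixing corrected and uncorrected scales would corrupt
diversity metrics.

Batches sequenced at different equimolar ST concentrations are pooled by
`pool_batches()`: each batch's mean vector is divided by its own grand mean
(absorbing the concentration), averaged across batches weighted by sample
count, and rescaled to unit mean. The rule is scale-invariant by
construction and reduces to the single-batch MLE; it is this package's own
pooling choice, stated here because the weighting is not forced by the
model.

## Primer-pair dependence diagnostics

Each primer pair shares a primer with 32 others, so pair efficiencies need
not be separable into V and J effects. `pearson_residuals()` quantifies
departure from independence on the 20 x 13 grid of pooled template means:
`E = row total x column total / grand total`, residual `(O - E) / sqrt(E)`,
with the sum of squared residuals equal to the classic contingency
chi-squared statistic. Pooled means, not a single sample, are the default
input so sampling noise does not masquerade as interaction; hierarchical
clustering (average linkage, Euclidean distance — pinned for
reproducibility, since nothing in the model prefers one linkage) orders the
heatmap so interacting primer groups appear as blocks.
`independence_spread_bound()` gives the Monte-Carlo floor for
post-normalization spread if counts were truly independent; observed
spreads below it are evidence of positive dependence, which in practice
*helps* normalization.

## Repertoire metrics

Metrics consume clone frequencies, so they are insensitive to whether
normalized pseudo-counts are re-scaled to sum to 1. The package uses the
field-standard definitions: Shannon diversity `H = -sum(p log p)` in nats
(base 2 via an argument), clonality `1 - H / log(R)` for `R` clones, the
maximum clonal frequency, and the summed frequency of hyperexpanded clones
above a configurable threshold (default frequency 0.01, a common
repertoire-tool convention). These exact formula choices are this package's
own, documented assumptions. Replicate dropout is tabulated over exact
`(CDR3 nucleotide, V, J)` keys, optionally restricted to each replicate's
most frequent clones.

## What the simulator emulates — and what it does not

The generators exist so every stage is testable end to end without
sequencing data, and their defaults are the study conditions the method
targets:

* `sample_bias_model()`: separable V x J efficiencies with log-means
  spanning 4 natural-log units (~50-fold between weakest and strongest
  pair), base mean 1000, common dispersion 0.125, on the 20 x 13 panel —
  the observed scale of multiplex bias and overdispersion. An optional
  multiplicative interaction matrix injects non-separable structure.
* `simulate_st_counts()`: independent gamma--Poisson draws (shape `1/d`,
  scale `m d`), which matches `var = m + d m^2` exactly; `d = 0`
  short-circuits to Poisson. Batches of 20 samples mirror the ST-only
  design size.
* `simulate_repertoire()`: clone counts NB-distributed around
  `depth * freq * m_pair / sum(freq * m)` — bias enters as a multiplicative
  efficiency on true frequencies.
* `generate_fixture_fastq()`: single pre-merged reads (pair merging is
  upstream of this package) with the universal barcode directly flanking
  the specific barcode at randomized offsets, uniform substitution errors,
  constant placeholder qualities, and a truth table for exact scoring.

Not modelled: sequencing-error spectra beyond uniform substitutions, PCR
chimeras, ST–genomic-DNA competition (depth is exposed as a knob instead),
and paired-end structure. Passing tests therefore demonstrate the
statistical machinery is correct under the stated model, not that the model
captures every artefact of real libraries — the dependence diagnostics
above exist precisely because real panels violate separability.

## Numerical and design choices

* **Barcode matching** is windowed Levenshtein distance at tolerance 1 —
  one substitution, insertion, or deletion — over *all* read offsets and,
  by default, both orientations. Ties between windows resolve to the
  leftmost position (determinism); note that with tolerance 1 a window one
  base left of an exact barcode copy also qualifies via a deletion, so the
  reported offset is the leftmost qualifying window, not necessarily the
  exact copy's offset. Reads flagged as ST (universal barcode present) but
  not uniquely assignable to one template are counted as ambiguous and
  dropped, never fractionally allocated. Random non-ST sequence has a small
  per-read chance of a spurious universal-barcode hit at tolerance 1; such
  reads end up ambiguous and are excluded from clonotype analysis, a
  conservative loss.
* **Generated designs** enforce pairwise edit distance >= 3 between
  specific barcodes (so tolerance-1 assignment is provably unambiguous) and
  distance >= 3 between the universal barcode and every same-length window
  of every specific barcode, by rejection sampling. Real designs with their
  own barcodes are accepted and validated.
* **Indexing**: primer pairs are ordered J-fastest and indexed 1-based (the
  R convention); all files on disk carry explicit `v_name`/`j_name` columns
  so nothing outside the package depends on the index convention.
* **Spread statistics** read "two-fold differences" as the Q3/Q1 ratio with
  type-7 quantiles (pinned for reproducibility), with the CV reported
  alongside.
* **Degenerate inputs**: all-zero templates are excluded from the common
  dispersion, the panel mean, and the factor set (with warnings); all-zero
  rows/columns are dropped before residuals; a single-clone repertoire has
  clonality 1 by convention (with a warning).

## Problem sizes used in the test suite

The suite exercises the full design scale where the claim depends on it:
dispersion recovery uses 50 replicate panels of 260 templates x 20 samples
(median common dispersion within 25% of the true 0.125), and the two-fold
post-normalization spread check runs at 260 x 20 with the default bias
model. Oracle comparisons (edit-distance DP, contingency chi-square,
Poisson closed forms) run on small randomized cases where exhaustive
independent computation is feasible.

## Worked example

```{r example}
panel <- default_panel()
model <- sample_bias_model(panel, seed = 1)
st <- simulate_st_counts(model, n_samples = 20, seed = 2)

fit <- fit_panel(st)
glance(fit)

sf <- nb_scaling_factors(fit)
spread_report(st, sf)
```

```{r plots, fig.width = 6, fig.height = 4}
plot_mean_variance(mean_variance_table(st, fit$common_dispersion))
autoplot(cluster_order(pearson_residuals(vj_table(pool_batches(st), panel))))
```

## Known limitations

* The pooling rule and the Monte-Carlo independence floor are surrogates
  for quantities that could be derived analytically under stronger
  assumptions; both are documented above and tested for their defining
  invariances rather than against a closed form.
* Clonotype assembly is consumed, never performed: the package ingests the
  tabular exports of an external assembler and trusts its V/J calls.
* Dependence between primer pairs is diagnosed, not modelled; factors
  remain per-pair scalars.
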