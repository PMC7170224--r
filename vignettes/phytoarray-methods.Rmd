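---
title: "Strain-resolved microarray metatranscriptomics with phytoarray"
author: "phytoarray authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved microarray metatranscriptomics with phytoarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoarray)
```

## The problem this package addresses

High-resolution environmental functional-gene microarrays read out the
transcriptional state of a mixed microbial community at the level of
individual strains: each oligonucleotide probe targets a strain-specific
gene, several probes interrogate each gene target, and targets roll up
through strains into major phylogroups (e.g. high-light and low-light
adapted *Prochlorococcus*, *Synechococcus*, photosynthetic eukaryotes,
heterotrophic bacteria). A typical experiment incubates replicate
bottles of one source water mass with different nutrient amendments
(nitrate, ammonium, urea, iron, iron plus nitrogen, filtered deep
water) and asks which taxa changed the transcription of which
functional gene programs — nitrogen stress, phosphorus stress, iron
stress, photosynthesis, carbon fixation — relative to unamended
controls.

`phytoarray` implements the full analysis chain for such data as a
tested, reusable pipeline, together with a synthetic-community
generator carrying a complete ground-truth ledger, so that every stage
can be exercised and scored at desk scale.

## Data model

Two S4 classes carry the data. `ArrayDesign` is the
probe → target → strain → phylogroup hierarchy plus the control-probe
roster; validity checks enforce that every probe maps to exactly one
target, every target to one strain, every strain to one phylogroup, and
that control probes map to no target. `PhytoArraySet` extends
`SummarizedExperiment` with two mandatory assays — `log2` (normalized
target-level intensities) and `detected` (per-cell detection calls) —
with the target annotation as row data, the sample sheet as column
data, and normalization provenance in the metadata.

## Preprocessing

**Probe summarization.** Probe intensities are floored at 1, log2
transformed, and each target's probe rows are combined by median
polish: an additive fit of overall + probe + sample effects whose
overall-plus-sample component is the robust summary (the probe effects
absorb constant per-probe affinities). Single-probe targets pass
through as `log2(intensity)`.

**Quantile normalization.** Target-level columns are forced to the
across-sample mean of order statistics (ties receive the mean of the
quantile values they span). The order — summarize first, then
normalize target-level columns — matches the upstream tool chain this
pipeline emulates; the conventional probe-level-first order is
available via `normalize_level = "probe"`. Quantile normalization
assumes most genes do not change and that changes are roughly
balanced; with strongly one-sided effects it compresses fold changes
toward zero (we measure roughly 0.08 log2 compression when ~10% of a
column shifts in one direction). The set-level analysis is competitive
(members against non-members of the same phylogroup), which removes
most of this common-mode distortion; the abundance-artifact filter
below removes the rest.

**Detection calling.** A target is detected in a sample when its
summarized value strictly exceeds `mean + k*sd` of the sample's
negative-control probe log2 intensities (`detection_k`, default 2).
The exact criterion of the original array software is unpublished, so
this rule is a documented, config-exposed stand-in; detection is
called on the pre-normalization scale so the thresholds and the values
share units.

## Community composition

A strain is *present* in a sample when at least five of its targets
are detected there, or at least half (ceiling, config-exposed) when it
has fewer than five targets. Per-strain relative transcript abundance
is the strain's share of the sample's total detected linear-scale
signal divided by its number of array targets, scaled to 1e5 — a
per-target-normalized score that is invariant to global rescaling of a
sample. Phylogroup transcript proportions are per-sample shares of
detected signal, averaged over replicates; they are also the source of
the set-level abundance term below. Transcript sums use linear-scale
values of detected cells only; undetected cells are background.

## Single-gene differential expression

Each treatment at T24 is contrasted against the T24 controls (and T24
controls against T0 controls). Per target the log2 fold change is the
difference of condition means. Gene variances are pooled within the
contrast and shrunk toward a prior fitted across genes by the
method of moments on log variances (a scaled inverse-chi-square prior;
the moment matching reproduces the standard empirical-Bayes squeeze,
and the test collapses to a plain pooled-variance t when moderation is
off). The test statistic

\[ t = \frac{|\widehat{\log_2 FC}| - \log_2(1.2)}{SE} \]

is referred one-sided to a t distribution on the moderated degrees of
freedom, testing H0: |FC| ≤ 1.2 — a fold-change-threshold
("TREAT-style") test, so that significance requires the fold change to
be *significantly greater than* 1.2, not merely different from 1. DE
calls require BH-adjusted p < 0.05 *and* |FC| > 1.2. BH is applied per
contrast (config `bh_scope`), since contrasts are reported separately;
targets detected in no sample of a contrast are excluded from the test
and from the BH family.

## Ensemble gene-set analysis

Gene sets pair a scope (phylogroup, or a single strain) with a
functional response label — Fe stress, N stress, P stress,
photosynthesis, RuBisCO, light stress — whose member genes are fixed
rosters of marker symbols (`geneSetRosters()`). Four competitive base
statistics compare member targets with the non-member targets of the
same phylogroup: the rank-sum of moderated t statistics, the mean
member t, the count of DE members, and the two-sample
Kolmogorov–Smirnov statistic. Four method families (rank, mean, count,
distribution) stand in for a larger algorithm ensemble at desk scale.

**Calibration.** The four statistics are computed on the same data and
are therefore correlated, and the DE-count component is degenerate
when few genes are DE; transforming their p-values through the
Beta distribution of an order statistic of *independent* uniforms
would produce a combined p that is far from uniform under the null. The
ensemble therefore works on one shared scheme of `n_perm` random
member draws (gene permutation — the competitive null): every draw's
four statistics become empirical p-values against the draw
distribution, each draw is combined by Wilkinson's r-th smallest p
(default r = 2, "at least two methods agree"; config-exposed since the
upstream choice is not recoverable), and the observed combination is
ranked among the draws. The resulting ensemble p is uniform under the
competitive null by construction; both it (`p_combined`, used for
significance) and the direct Beta-transform of the reportable base
p-values (`p_wilkinson`) are returned. Combined p-values are
BH-adjusted across all (set, contrast) pairs at α = 0.01.

**Abundance-artifact filter.** Because a fixed amount of cDNA is
hybridized per array, a whole-taxon abundance increase depresses every
other taxon's apparent signal. For each set the average member fold
change \(a_g\) (geometric mean, `2^mean(log2FC)`) is compared with the
phylogroup's average fold change over all detected targets
\(a_{tot}\): an up-call is retained only if \(a_g/a_{tot} > 1\), a
down-call only if \(a_g/a_{tot} < 1\). Filtered sets stay in the
output with `retained = FALSE`. Whether the upstream averaging was
linear or log-scale is unstated there; the geometric-mean reading is
used consistently here, and \(a_{tot}\) averages detected targets
only. A response is additionally classed "large" (thick arrow in the
summary table) when \(a_g > 1.2\) for up-sets or \(a_g < 1/1.2\) for
down-sets.

## Co-expression modules

Across the 20 T24 samples, targets detected in at least 75% of them
enter an unsigned weighted network: adjacency \(|cor|^\beta\), where
β is the smallest candidate power whose connectivity distribution is
approximately scale-free (signed R² ≥ 0.8 of the log-log
frequency-connectivity fit). The candidate grid starts at the smallest
power that suppresses background sampling correlation — with n samples
a null correlation sits near \(2/\sqrt{n}\) at two sigma, and the floor
is the smallest β with \((2/\sqrt{n})^\beta \le 0.01\) (β ≥ 6 at
n = 20) — because on small sample sizes the scale-free fit alone
cannot distinguish an under-thresholded dense network from a sparse
modular one. Adjacency is converted to topological overlap
(`computeTOM`), dissimilarity `1 - TOM` is clustered by average
linkage, and the tree is cut statically at 0.98 of the maximum merge
height; TOM dissimilarities concentrate near 1, so the informative
splits sit just below the top of the tree (static cutting at a low
fraction of the tree height leaves every gene a singleton). Clusters
smaller than `min_module_size` (10) are left unassigned. Static
cutting instead of dynamic tree cutting is a deliberate simplification;
`cut_height_frac` is config-exposed. Each module is summarized by its
eigengene: the unit-norm first principal component of the standardized
member submatrix, sign-fixed to correlate positively with the module
mean profile.

## Ordination

Sample metatranscriptomes are compared by Euclidean distance over the
normalized log2 levels of all targets detected in at least one sample;
undetected cells enter at their normalized values rather than as
zeros, since the distance is defined over the whole detected universe.
Non-metric multidimensional scaling minimizes Kruskal stress-1 by
SMACOF majorization: embedded distances are isotonically regressed on
the dissimilarity order (primary tie treatment: ties unconstrained,
implemented by breaking ties with the current embedded distances), and
the configuration is updated by the Guttman transform until the stress
change falls below 1e-6 (500-iteration cap). The best of one
classical-scaling start plus 20 seeded random starts is reported; no
automatic data transformation is applied. Per-treatment distance
summaries are medians over all (treatment sample, reference sample)
pairs against the T0 controls, excluding self-pairs, ordered by
increasing median.

## The synthetic community and what it does (not) show

`simulateDesign()` builds a reduced multi-strain array: by default
five phylogroups (HL- and LL-adapted picocyanobacteria, a
*Synechococcus*-like group, photosynthetic eukaryotes represented
mostly by RuBisCO targets, and a *Pelagibacter*-like heterotroph group
carrying proteorhodopsin and Fe-stress genes) of 8 strains each,
12–18 targets per strain, 2–4 probes per target, 40 negative-control
and 8 spike-in probes — roughly 500 targets and 1500 probes, a
desk-scale analog of an array with hundreds of strains.

`simulateExperiment()` draws, for sample *s*, target *i*, probe *j*:

\[ \log_2 I = \mu_i + \delta_{i,t(s)} + a_j + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma_{resid}) \]

with target baselines \(\mu_i \sim N(10, 1.5)\) (log2 units), probe
affinities \(a_j \sim N(0, 0.3)\) constant across samples, residual
noise \(\sigma_{resid} = 0.25\), and a lognormal linear-scale readout.
Additive Gaussian noise on the log2 scale is the simplest model with
the correct support for the downstream log2 analysis. Targets of
absent strains, and targets whose noiseless signal falls below the
detection floor (background mean + 2.5 background SD, i.e. 7.25 when
background is N(6, 0.5)), are replaced by background draws — censoring
at background makes ground-truth detectability a clean binary. Strain
absence (10% expected) is drawn once per strain and holds across all
samples because the incubation bottles subsample one source community;
per-sample dropout would inject replicate variance that this
experimental design does not have. The replicate plan is the study
layout: 3 T0 controls and 3 replicates per T24 condition except 2 for
ammonium, 23 samples in all.

Implanted effects (`defaultTruthConfig()`) mirror the qualitative
response pattern of an N-limited late-summer community: HL
picocyanobacterial N-stress genes down and RuBisCO up after ammonium
and urea; *Synechococcus* and eukaryote RuBisCO/photosynthesis up
under nitrate; urea-transporter (*urtA*) genes up across all
picocyanobacterial strains in filtered deep water as one shared
profile, carved out of the set-level effects so the cross-strain block
is genuinely correlated; and a pure abundance shift (+0.5 log2 on
*every* target of the heterotroph group in the Fe treatment) to
exercise the artifact filter without entangling the regulated
scenarios. Default magnitude is ±0.6 log2; the emulated study reports
directions only, so magnitudes are documented placeholders chosen to
sit near the pipeline's detection limit at n = 3, σ = 0.25.

Passing recovery tests on this generator shows that the pipeline's
inference machinery is calibrated and can recover effects of the
implanted kind at realistic noise; it does not show robustness to
features the generator omits — sequence-level cross-hybridization,
spatial array artifacts, dye effects, heteroscedastic probe noise, or
compositional coupling beyond the global equal-cDNA constraint.

## Numerical choices and degenerate inputs

* Intensities are floored at 1 before log2; no background subtraction.
* Detection uses a strict inequality, so a value exactly at the
  threshold is not detected.
* "At least half" in the strain-presence rule is the ceiling (2 of 3).
* Sets with fewer than two detected members (or fewer than two
  non-members) in a contrast are skipped with a message.
* A degenerate set universe (all statistics equal) yields p = 1 for
  the rank-based methods.
* Permutation p-values use the add-one estimator, so the smallest
  attainable ensemble p is `1/(n_perm + 1)`; `n_perm` (default 10,000)
  bounds the resolution of BH at the set level.
* Isotonic regression pools adjacent violators exactly; median polish
  iterates to a 1e-9 relative tolerance.
* NMDS with fewer classical-scaling dimensions than requested pads the
  start with zero columns; a run that never meets the stress tolerance
  returns its best configuration with a warning.
* All stochastic steps (simulation, permutation draws, NMDS restarts)
  are driven by explicit seeds; identical seeds and configuration give
  byte-identical pipeline outputs.

## Problem sizes used in the test suite

The bundled checks run at desk scale: the study fixture is the default
generator (about 40 strains, 500–600 targets, 23 samples); single-gene
calibration uses 2,000 boundary-null genes; ensemble-null calibration
uses 200 random member sets at 2,000 permutation draws; the set-level
false-call rate is measured over 20 replicate simulations of a reduced
community (5 strains per phylogroup, 2,000 draws); determinism is
checked on a 4-strain-per-group run. These sizes keep the whole suite
in the minutes range on one CPU while leaving each check's Monte Carlo
error well inside its decision margin.

## Known limitations

* The detection rule, the base-test battery, and all network
  parameters are documented stand-ins for unpublished upstream
  choices; conclusions that hinge on their exact values should be
  checked against the config-exposed alternatives.
* Quantile normalization's unbalanced-DE compression is mitigated, not
  removed, by the competitive set tests and the artifact filter.
* The strain-level set scope tests each strain against its whole
  phylogroup universe; paralog-level heterogeneity within a strain is
  not modelled.
* Joint normalization of two studies ("concatenate then
  quantile-normalize") is supported only as an experimental mode of
  the reader/normalizer chain and is not separately validated.
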