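---
title: "Methods: QTL mapping and integrated candidate-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping and integrated candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlprio)
```

This vignette documents the statistical machinery of `qtlprio`: the models,
the tunable parameters and their defaults, what the synthetic panel does and
does not emulate, and the numerical and design choices made where the
methodology left room.

## The setting

A recombinant inbred (RI) panel — the motivating case is the BXD mouse
panel — consists of lines that are each a fixed, homozygous mosaic of two
parental genomes (coded here 0 for the B and 1 for the D allele). Because
every line's genome is fixed, phenotypes, plasma metabolites and tissue
transcriptomes can be measured repeatedly and across conditions (here,
control versus sleep deprivation) on the same genotypes, and mapped against
a shared marker map. The package covers the analysis chain: genotype QC,
QTL scans of strain-level traits, eQTL maps, differential expression and
correlation, candidate-gene prioritization inside QTL regions, and network
summaries.

## Genotype handling

`read_geno()` ingests the GeneNetwork `.geno` dialect. Heterozygous (`H`)
calls are treated as missing: RI lines are expected homozygous, and residual
heterozygosity carries no stable mapping information in a two-allele coding.
`genotype_qc()` drops markers missing in more than 10% of strains (the
`max_missing` default) and collapses consecutive markers with identical
strain-distribution patterns, keeping the first by position — identical
patterns are statistically interchangeable, so the choice of representative
only affects the reported position, and taking the first is deterministic.
An upstream variant-calling quality filter belongs to the calling pipeline,
not this package; the QC report carries a `qual_prefiltered` flag so that
provenance can be recorded.

## QTL scanning

`lod_scan()` regresses the trait on the allele code marker by marker:
`LOD = (n_m/2) log10(RSS0/RSS1)` over the `n_m` strains with both a trait
value and a genotype call at the marker. For fully informative homozygous
lines, single-marker regression yields the same LOD at marker positions as
EM interval mapping; with a dense merged map, pseudomarker imputation
between markers buys little, so it is deliberately not performed. Numerical
choices:

* a perfect fit (`RSS1 = 0`) is reported as `lod_max = 50`, preserving peak
  ordering without infinities;
* markers with fewer than `min_n = 8` usable strains are flagged untested
  (`NA`) rather than contributing unstable estimates;
* peak ties break toward the lowest Mb position, making peak choice
  deterministic.

`qtl_scan()` adds genome-wide significance from `n_perm = 1000` trait
shuffles, using the never-zero estimator `(1 + r)/(1 + N)` on the
genome-wide maximum LOD. The tier labels follow the panel literature's
convention (0.05 / 0.10 / 0.63); the quantity is a per-trait genome-wide
adjusted p-value — no further correction is applied across traits, which
preserves sensitivity at the cost of family-wise control over the whole
phenotype battery, and is the convention this methodology inherits. Support
intervals take the contiguous run of markers within `drop = 1.5` LOD of the
peak and extend one marker beyond on each side, clipped at chromosome ends.

Effect sizes come in two estimators. Method 1, `effect_size_closed_form()`,
is the closed form `1 - 10^(-(2/n) LOD)`; `n` is an explicit argument
because which individuals enter a scan (lines only, or lines plus parentals
and F1s) varies between studies. Method 2, `effect_size_drop_one()`, fits
the full additive model over all peak markers and attributes to each QTL the
R² lost on removing it; with linked QTLs the attributions sum to less than
the full-model R², which is the expected behavior, and exactly collinear
peak markers are refused with an error naming the pair. Note both estimators
describe the between-strain (genetic) portion of the variance.
`heritability()` is the one-way ANOVA intraclass estimator with the harmonic
mean of replicates per strain, clipped to [0, 1] — a deliberate
variance-components stand-in adequate for strain-replicate designs.

## eQTL mapping

`cis_scan()` tests each gene against the markers inside a 2 Mb window.
The window is anchored on the gene center by default (`anchor = "center"`),
with a TSS-anchored alternative; the center matches how genes are positioned
for prioritization. The gene-level statistic is the minimum nominal p over
window markers; its null distribution comes from `n_perm = 1000`
permutations of expression across strains, smoothed by a maximum-likelihood
Beta fit to the permutation minima (method-of-moments start; on any fit
failure the empirical `(1 + r)/(1 + N)` estimator is used instead — the two
agree within Monte-Carlo error, the Beta fit just interpolates below the
1/(N+1) resolution floor). q-values across genes use the Storey λ = 0.5
plug-in for π0, which reduces to Benjamini–Hochberg when π0 estimates at 1.
`trans_scan()` applies a hard nominal threshold of 1e-4 to every
(gene, marker) pair outside the cis window, so cis and trans partition each
gene's testable markers. `differential_cis_scan()` maps the per-strain
SD − Ctr contrast, i.e. genotype-by-condition interactions.

## Differential expression and correlations

`differential_expression()` is a per-gene Welch t-test on log-CPM with BH
adjustment. This is a behavioral, not numerical, stand-in for a moderated
empirical-Bayes fit: the prioritizer consumes only an adjusted-p column, and
any DE table with that column can be substituted. Correlations
(`trait_molecule_correlation()`) are computed on strain-level values
(line means), matching the line-level design of the mapping; baseline
phenotypes pair with control molecular data and recovery/contrast phenotypes
with the sleep-deprivation data. `partial_correlation()` residualizes both
variables on a genotype covariate before correlating — the device used to
strip cis-eQTL-driven confounding from gene–gene edges.
`quantile_threshold()` implements the data-driven "top fraction" cutoffs
with the higher order-statistic convention, so a threshold never admits more
than the nominal fraction.

## The integrated prioritization score

For each gene overlapping a QTL region (inclusive overlap with the 1.5-LOD
support interval, or an explicitly supplied region):

1. **Raw statistics.** The QTL component evaluates the −log10 adjusted-p
   curve — a step function taking the nearest marker's value, ties to the
   left marker — at the gene center, at the gene's significant cis-eQTL
   marker, and at its damaging-variant position, and keeps the maximum.
   The max rule reconciles the two stated conventions (center by default,
   associated marker when its evidence is stronger) in a single monotone
   rule. The other four components are the cis q-value, the variant damage
   score, the DE adjusted p, and the correlation p; genes without a record
   enter at the null value (p = 1, score 0).
2. **Normalization.** p-like statistics become −log10 values; each
   component is clamped at its 95th percentile over the region's genes
   (winsorization quantile configurable) and min–max rescaled to [0, 1].
   A constant component maps to all zeros — it carries no ranking
   information. The winsorization keeps one extreme gene (say a q-value of
   1e-17) from compressing everyone else to ≈0.
3. **Henikoff weighting.** Scores are discretized into 10 equal-width bins
   (configurable; 10 bins resolve the normalized scale finely enough to
   distinguish evidence patterns while keeping symbol counts stable at
   region sizes of tens of genes) and the five rows are weighted by
   position-based diversity: in each gene column, a row holding a symbol
   shared by `k` rows among `r` distinct symbols contributes `1/(r·k)`,
   and row weights are the normalized column sums. Identical (redundant)
   rows split their contribution, which is exactly the desired correction
   for intrinsically correlated analyses such as a cis-eQTL inside a
   phQTL region.
4. **Integration and significance.** `I(g) = Σ w_k s_k(g)`; the weighted
   sum is the form consistent with weights on the simplex and scores in
   [0, 1]. Each of `n_perm = 10,000` permutations independently reshuffles
   every normalized score column across genes (normalization is a per-region
   monotone map, so permuting normalized scores and permuting raw statistics
   give essentially the same max-statistic null), re-discretizes, recomputes
   the weights, and records the maximum integrated score; the significance
   threshold is the 95th quantile of these maxima and genes strictly above
   it are flagged. Permuted columns are drawn from the sorted column values,
   which makes the null — and hence the threshold — exactly invariant to
   relabeling the genes. A single-gene region has no permutation null and
   is reported unflagged with a warning.

Per QTL and tissue, the reported candidate is the top-ranked significant
gene.

## Networks

`phenotype_modules()` clusters phenotypes on `1 − |Spearman ρ|` with average
linkage, cut at 0.3. The absolute value is an interpretation choice: it
makes modules invariant to the sign and any monotone transform of a
phenotype, and pairs naturally with the `|ρ| ≥ 0.7` edge rule of
`module_network()` (a 0.3 cut on `1 − |ρ|` admits exactly the `|ρ| ≥ 0.7`
pairs). Superclusters are connected components of the filtered graph that
span more than one module — a components rule chosen for determinism where
the methodology names the grouping only loosely. `build_hivegraph()`
assembles the four-axis graph (genetic, metabolite, and one axis per
tissue): inclusion by the top-0.5% correlation threshold (realized values
from a full dataset, e.g. 0.510/0.485, can be passed as overrides), radial
coordinate equal to the within-axis rank of the SD log2 fold change scaled
to (0, 1] (the stated convention is only monotone; rank is the
scale-free choice), gene–gene edges at the top 0.05% and gene–metabolite
edges at the top 0.5% of their absolute (partial) correlations. Rendering
(`autoplot()`) is a thin schematic; the tested artifact is the graph
structure and its JSON/GraphML exports.

## The synthetic panel

`simulate_ri_genotypes()` draws each strain as an independent two-state
Markov chain along the chromosome with switch probability
`R = 4r/(1 + 6r)`, `r` from Haldane's map function — the classical
expansion of the map for RI lines produced by sibling mating, chosen
because the emulated panels are bred that way. An `allele_freq` parameter
tilts the stationary allele frequency away from the default 50/50 balance
via detailed-balance switch rates, emulating the imbalanced regions real
panels show. `simulate_phenotype()` plants additive QTLs scaled against the
empirical marker variance so each contributes its stated fraction of
strain-level variance, with Gaussian strain-level residual noise topping the
variance to 1 and Gaussian replicate noise sized to hit a target
heritability — Gaussian because it is the simplest model satisfying the
pipeline's assumptions. `simulate_expression()` composes baseline, cis
(allele-linear), condition (log2 fold change), phenotype-linked and noise
terms on the log-CPM scale.

`simulate_candidate_scenario()` is the end-to-end benchmark: 33 strains
(the emulated panel size), one metabolite-like trait with a planted QTL
contributing 60% of strain variance (enough for the scan to place the peak
reliably at that panel size), and 31 genes tiled over a 20 Mb region — one
carrying all five lines of evidence, the rest none or deliberately partial
(a mild cis effect, a mild SD response, a benign variant). The scrambled
variant scatters the evidence across decoys as a negative control.

What the simulator does **not** emulate: linkage disequilibrium structure
beyond the marker-to-marker Markov chain, count-level noise (expression is
generated directly on the log scale with homoskedastic Gaussian noise,
whereas real log-CPM has mean–variance dependence), correlated phenotype
batteries, batch effects, and epistasis. Tests passing on this panel
therefore validate the statistical machinery — calibration of the
permutation nulls, recovery of planted signals, exactness of the closed
forms — not robustness to those real-data pathologies.

## Problem sizes and determinism

The test suite and acceptance checks run at deliberately moderate sizes
chosen as representative for desk validation: panels of 33 strains (200–300
for recombination-fraction checks), 60–85 markers, regions of ~31 genes,
1,000 permutations for scans and cis maps (10,000 for a single
demonstration prioritization, 1,000 when prioritization is repeated across
50 seeds or 1,000 null regions). Every stochastic step takes an explicit
integer seed and is reproducible bit-for-bit; the pipeline demo writes
byte-identical outputs for identical seeds.

## Known limitations

* No covariate adjustment (e.g. expression PCs) in the eQTL maps.
* No epistasis scans; the additive drop-one model is the only multi-QTL
  device.
* The DE stand-in does not moderate variances; at very small strain counts
  a moderated fit would be more powerful.
* Heritability uses the intraclass stand-in, not a kinship-based mixed
  model; with 33 lines and balanced replicates the two are close, but the
  estimator ignores relatedness among lines.
* The hiveplot quantile thresholds are computed within whatever correlation
  set is supplied; with few molecules the "top 0.05%" of pairs can be a
  single edge.
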