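---
title: "Classifying longitudinal DNA methylation stability with reference intervals"
author: "methylRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying longitudinal DNA methylation stability with reference intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylRI)
```

## The problem

Clinical epigenetics interprets differences in blood DNA methylation
between groups — patients versus controls, exposed versus unexposed — on
the assumption that a CpG's methylation level is otherwise reasonably
stationary within a person. Dense repeated-measures designs (the setting
emulated here: two individuals, two blood sample types — PBMCs and a
purified monocyte fraction — assayed at 24 timepoints over 84 days on a
450k-style array) let one ask directly which CpGs drift, oscillate or
switch on that time scale, and which are effectively constant.

`methylRI` classifies CpGs by a **within-individual reference interval
(RI)**: for one CpG in one (individual, tissue) series, the difference
between the 95th and 5th percentiles of its methylation percentage across
the timepoints. The RI is a robust range — unlike a variance it has the
units of the data (percentage points of methylation) and is insensitive to
a single outlying visit. Categories are fixed bands of the RI:

| category     | rule                | interpretation                           |
|--------------|---------------------|------------------------------------------|
| stable       | RI < 1              | flat to within measurement noise          |
| unclassified | 1 ≤ RI < 10         | ordinary low-level fluctuation            |
| dynamic      | 10 ≤ RI < 50        | substantial smooth fluctuation            |
| hyperdynamic | RI ≥ 50             | switching between near-0 and near-100     |

A separate, cohort-level axis uses the **between-individual RI** (the same
P95 − P5 statistic computed across a population, supplied as a reference
table): CpGs with between-individual RI above 30 are flagged as **common
DNA methylation variation (CDMV)**. The two axes are deliberately
independent: the category comes only from the within-individual RI, the
CDMV flag only from the between-individual RI.

## Percentile convention and numerical choices

The percentile is computed by linear interpolation between order
statistics at rank $1 + (n - 1)q$ (the most common convention; `quantile()`
type 7). For a constant series the RI is exactly 0; with 24 timepoints the
P95 rank is 22.85, so a single extreme visit among 24 cannot move the RI on
its own. The statistic is permutation invariant in time and scales
affinely, and the implementation is pinned against an independent
sort-and-interpolate oracle in the test suite.

Band edges are half-open: the dynamic band is $[10, 50)$ and RI = 50
belongs to hyperdynamic (forced by the ≥ 50 definition); the lower dynamic
edge is inclusive by convention and matters only on a set of measure zero.
The CDMV rule is strict (`between_ri > 30`). The mean methylation level
reported per CpG is the arithmetic mean over timepoints.

## The probe-exclusion cascade

Three filters run before any RI is computed, in a fixed order so that each
excluded CpG is attributed to exactly one reason and the accounting sums
to the probe universe:

1. **Missingness** — a CpG is dropped if it has a missing value in *any*
   dataset of any series.
2. **SNP overlap** — probes with a recorded overlapping-SNP minor allele
   frequency ≥ 0.05 are dropped (inclusive threshold); probes without a
   recorded SNP are kept.
3. **Cell-type association** — bulk blood methylation is a mixture over
   cell types, so a CpG whose apparent level tracks the composition is not
   measuring intrinsic temporal dynamics. For each series the fit of an
   intercept-only linear model is compared with a multiple regression on
   the six estimated cell-type proportions (CD4+ T, CD8+ T, NK, B,
   monocytes, granulocytes) by an ANOVA F-test; the CpG is flagged in that
   series when the raw p-value is below 0.05 (no multiple-testing
   correction, by design: the filter should be liberal in excluding).

Because estimated compositions sum to approximately one, the six
proportions are nearly collinear with the intercept. The fit therefore
uses a rank-revealing (pivoted QR) least-squares solve and takes the
numerical rank of the design as the full-model degrees of freedom, rather
than arbitrarily dropping one cell type. Degenerate responses follow fixed
conventions: a constant response gives p = 1 (never flagged), an exactly
fitted non-constant response gives p = 0 (flagged), both with a warning.

The filter tests each (individual, tissue) series separately over its own
timepoints and excludes on the **union** of flags. Whether the original
analysis pooled all datasets or ran per series is not documented; the
union rule was chosen as the conservative option for downstream stability
claims — every retained CpG is unassociated with composition in every
series. Its cost is a higher null exclusion rate (about $1 - 0.95^4
\approx 19\%$ of composition-independent CpGs at four series), which the
pipeline reports transparently in its accounting.

## Annotation and probe characterization

Probes are annotated by interval overlap (strand-ignored, since CpG
methylation is symmetric) against a track of CpG-context classes — island,
shore, shelf, open sea, mutually exclusive by construction — and genic
features (promoter, 1–5 kb upstream, 5'UTR, exons, introns, ±100 bp
exon–intron boundary windows, 3'UTR; intergenic when nothing overlaps).
Coordinates are 0-based half-open internally (BED native); probe manifest
positions are 1-based and converted on read, with a bit-exact round trip.

Because a CpG can carry several genic annotations (e.g. the promoter of
one gene and an exon of its neighbour), per-category genic composition
uses **fractional counting**: a CpG with $k$ genic annotations contributes
$1/k$ to each, so totals are conserved — the fractional counts of a
category sum exactly to its number of CpGs. Context composition uses whole
counts (one context per CpG). Each category is further characterized by
its Infinium design-I fraction (Fisher exact test against the all-probe
background) and its probe GC content (two-sided Wilcoxon rank-sum against
the remaining probes; the original analysis states only "significantly
greater", so a robust rank test on bounded fractions was chosen).

## EWAS marker enrichment

To ask whether a stability category is over- or under-represented among
published epigenome-wide association markers, the package computes the
category's **marker likelihood** (marker CpGs divided by non-marker CpGs
within the category) and compares it with the full retained probe
background by a 2×2 Fisher exact test. Conventions, all tested against
oracles:

* the odds ratio is the cross-product $(ad)/(bc)$, matching the
  likelihood-ratio framing (the exact test supplies only the p-value, on
  the raw counts);
* the two-sided p sums hypergeometric probabilities of all tables at most
  as probable as the observed one (with a $10^{-7}$ relative tolerance);
* zero cells trigger the Haldane–Anscombe +0.5 correction for the odds
  ratio and its Woolf variance only;
* the background **includes** the category (a category-excluded background
  would give slightly different odds ratios; the inclusive convention
  matches the likelihood-versus-all-probes framing).

Trait-level analyses select traits with at least 5 studies and at least
100 distinct marker CpGs, compute one log odds ratio per study against the
common probe background, and pool them with the **DerSimonian–Laird**
random-effects estimator; **Cochran's Q** (chi-square, $k-1$ df, threshold
0.05) assesses between-study heterogeneity. The hyperdynamic category is
excluded from trait-level analyses — its category sizes are too small for
study-level tables. Raw and Benjamini–Hochberg-adjusted p-values are
reported side by side across the trait × category cells, since the choice
of correction is not fixed by the source analysis.

## What the synthetic cohort emulates

`generate_cohort()` produces the full input bundle with a ground-truth
ledger. Its defaults are the study conditions: 2 individuals × 2 sample
types × 24 timepoints over 84 days; six-cell-type composition estimates
per timepoint (mean-reverting perturbations around tissue baselines, with
the monocyte series dominated by the monocyte fraction); roughly 80% of
CpGs with RI < 5 and small minorities in the stable, dynamic
(smooth oscillation with peak-to-trough in 10–50) and hyperdynamic
(two-state switching with per-timepoint switch probability 0.3) regimes;
about 3% cell-driven CpGs whose level is the convolution of composition
with fixed cell-type-specific levels (drawn uniformly on [0, 100] to make
the filter's power measurable); 5% SNP-tagged probes; and a multi-study,
multi-trait marker catalog with planted category-level odds ratios
(defaults: 0.7 for stable, 3 for dynamic, 1 elsewhere, mirroring the
qualitative published pattern).

Design choices worth knowing:

* **Seeds.** One master seed; each component derives a child seed by a
  fixed counter scheme, so any component can be regenerated alone and
  byte-identical outputs are guaranteed for identical configurations.
* **Bounded scale.** Noise and offsets act directly on the 0–100 scale
  with clipping rather than through a logit transform — the RI is
  percentile-based, so clipping artifacts are tolerable — but shifts and
  noise attenuate near the boundaries by $\sqrt{4m(1-m)}$ of the mean
  level $m$, as on any bounded scale. This keeps "pinned" CpGs genuinely
  flat instead of producing clipping artifacts.
* **Cross-tissue synchrony.** Dynamic and hyperdynamic trajectories share
  one latent signal per individual across that individual's tissues, with
  independent tissue noise on top, so fluctuation patterns are
  synchronized between PBMC and monocyte series within an individual.
* **Between-individual RI.** Drawn per category so that essentially no
  stable CpGs are CDMV, roughly a third of dynamic and a fifth of
  hyperdynamic CpGs are, and CDMV CpGs are numerous enough that dynamic
  CpGs form only a few percent of them; for intermediate CpGs the CDMV
  probability grows with the CpG's own effective noise, reflecting the
  correlation between within- and between-individual variability.
* **Category–context coupling.** Stable CpGs are preferentially placed in
  CpG islands and dynamic CpGs in open sea, so the annotation stage has a
  realistic signal to find.

What the generator does **not** emulate: probe hybridization chemistry and
raw intensities, normalization artifacts, genotypes (only a MAF tag),
cell-subtype structure beyond six types, and any real linkage between
specific traits and genomic location. Passing recovery tests therefore
demonstrates that the pipeline's statistics behave as designed under the
stated regimes — not that real data meet those regimes.

## Problem sizes and calibration checks

The packaged checks run the pipeline at 20,000 CpGs × 4 series — large
enough that a 5% binomial rate is estimated to ±0.6 percentage points and
every stage (including annotation and trait-level meta-analysis) runs on
non-trivial inputs, while a full run stays around a minute. At those sizes
the suite verifies: ≥ 95% / ≥ 80% / ≥ 90% recovery of planted stable /
dynamic / hyperdynamic classes; a cell-type filter type-I error of
0.05 ± 0.01 over 5,000 null CpGs and ≥ 90% exclusion of planted
cell-driven CpGs; detection of a planted trait-level odds ratio of 3 for
dynamic CpGs with a DerSimonian–Laird CI excluding 1; about 5% of
(trait, category) cells rejecting under a planted odds ratio of 1; and
≥ 90% CI coverage of the true log odds ratio over 200 replicates.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(input_dir = "run/in", output_dir = "run/out",
                       generator = generator_config(master_seed = 7,
                                                    n_cpgs = 2000))
res <- run_pipeline(cfg)
#> simulate: wrote synthetic bundle to run/in
#> qc: 2000 probes; 8 with missing values, 95 overlapping SNPs and 417
#>   associated with cell-type components were removed; 1480 retained
#> ri: 5920 (CpG, series) records; 799 stable, 155 dynamic, 28 hyperdynamic
#>   assignments; 276 CDMV CpGs
#> annotate: 1480 retained probes annotated; 128 composition rows
#> ewas: 17 enrichment rows; 54 (trait, category) meta-analysis cells
head(res$categories)
res$likelihood_overall
```

## Known limitations

* Only two individuals are emulated, so between-individual RI must come
  from an external reference table, exactly as in the motivating design;
  intraclass correlation coefficients are deliberately not offered.
* The union rule for the cell-type filter is conservative; with many
  series it removes an increasing fraction of null CpGs.
* The per-study odds ratios use one common probe background; study-
  specific backgrounds (each study's own array content) are not modelled.
* The PCA overview uses the retained (post-filter) CpG set, centered and
  unscaled; whether the original overview preceded filtering is not
  documented, and the choice is exposed through the `retained` argument.
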