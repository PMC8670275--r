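# methylRI

Classifies CpG sites by the temporal stability of their blood DNA
methylation level in dense repeated-measures array data, and asks what the
resulting stability categories are — where they sit in the genome, what
their probes look like, and how likely they are to appear as published
EWAS markers.

The package is written for epigenomics analysts working with longitudinal
450k/EPIC-style data (or evaluating study designs for such data): it
implements the full analysis pipeline for a design of 2 individuals × 2
blood sample types (PBMC, monocytes) × 24 timepoints over 84 days, and
ships a synthetic-cohort generator emulating that design, so everything
runs and is testable without access to restricted individual-level data.

## The statistics at its core

**Within-individual reference interval (RI).** For CpG *j* in one
(individual, tissue) series with methylation percentages
*x*₁…*x*ₙ over *n* timepoints,

> RI = P₉₅(x) − P₅(x)

with percentiles by linear interpolation between order statistics at rank
1 + (*n* − 1)*q*. CpGs are **stable** (RI < 1), **dynamic**
(10 ≤ RI < 50) or **hyperdynamic** (RI ≥ 50, binary switching between
near-0 and near-100); the rest are unclassified. The same statistic
computed across a population (between-individual RI, supplied as a
reference table) flags **CDMV** CpGs (common DNA methylation variation,
between-individual RI > 30).

**Probe-exclusion cascade.** Before RI computation: CpGs with any missing
value in any dataset; probes overlapping SNPs with MAF ≥ 0.05; and CpGs
whose level tracks blood cell-type composition — tested per series by an
ANOVA F-test comparing an intercept-only model against a multiple
regression on the six estimated cell-type proportions
(F = [(SSE₀ − SSE₁)/(df₁ − df₀)] / [SSE₁/(n − df₁)], rank-revealing df,
flag at p < 0.05, exclusion on the union over series).

**Annotation with fractional counting.** Each CpG gets one CpG-context
class (island/shore/shelf/open sea) and ≥ 1 genic annotation; a CpG with
*k* genic annotations contributes 1/*k* to each, so per-category counts
are conserved.

**EWAS marker enrichment.** Per category: likelihood = markers /
non-markers, compared with the all-probe background by Fisher's exact
test (cross-product OR, Haldane–Anscombe +0.5 only when a cell is zero,
exact p on raw counts). Per trait (≥ 5 studies, ≥ 100 marker CpGs): one
log-OR per study, pooled by DerSimonian–Laird random effects
(τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))), with Cochran's Q
heterogeneity at p < 0.05.

## Worked example

```r
library(methylRI)
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
```

The QC line is the exclusion accounting: of 2,000 simulated probes, 8 had
missing values, 95 overlapped common SNPs, 417 tracked cell-type
composition, and 1,480 enter the RI analysis. Each retained CpG is then
categorized per series:

```r
head(res$categories[, c("cpg_id", "series", "within_ri", "category", "cdmv")], 4)
#>     cpg_id     series within_ri     category  cdmv
#> 1 cg000001 A_monocyte  4.773653 unclassified FALSE
#> 2 cg000002 A_monocyte  7.802745 unclassified  TRUE
#> 3 cg000003 A_monocyte  0.703957       stable FALSE
#> 4 cg000005 A_monocyte  2.230083 unclassified FALSE
```

`cg000003` varies by less than one percentage point across the 24 visits
(stable); `cg000002` fluctuates moderately within this person but is
highly variable between people (CDMV). Enrichment among the synthetic
EWAS catalog (which plants an odds ratio of 3 for dynamic CpGs):

```r
subset(res$likelihood_overall, set %in% c("dynamic.A_PBMC", "island"))
#>              set  a  b likelihood odds_ratio ci_low ci_high  p_value
#> 5 dynamic.A_PBMC 24 10      2.400      4.457  2.115    9.39 3.68e-05
#> 14        island 35 98      0.357      0.663  0.444    0.99 4.53e-02
```

Dynamic CpGs in sample A's PBMCs are markedly enriched among markers
(likelihood 2.40 versus 0.59 in the background; OR 4.46, CI excluding 1),
while island CpGs are slightly depleted — the planted pattern recovered.
`res$meta_by_trait` holds the per-trait DerSimonian–Laird pooled odds
ratios with Cochran's Q.

A thin command-line wrapper with subcommands (`simulate`, `validate`,
`qc`, `ri`, `annotate`, `ewas`, `run-all`) is installed at
`inst/scripts/methylri.R`.

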