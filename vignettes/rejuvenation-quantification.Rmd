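---
title: "Quantifying transcriptomic rejuvenation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptomic rejuvenation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejuvr)
```

## The design and its two contrasts

Heterochronic parabiosis joins the circulation of a young and an aged animal;
in a four-arm SAMP8/SAMR1 design, each organ yields single-nucleus profiles
for `Iso-R1`, `Iso-P8`, `Het-R1` and `Het-P8` animals. The package quantifies
rejuvenation through two differential-expression contrasts per cell type:
**SEA** (`Iso-P8` vs `Iso-R1`), the transcriptomic footprint of accelerated
aging, and **REJ** (`Het-P8` vs `Iso-P8`), the footprint of exposure to young
circulation. Genes the intervention pushes back toward the young state appear
with opposite signs in the two contrasts; the package's central statistic is
the fraction of aging DEGs so reversed.

## Quality control and normalization

Cells are kept when their detected-feature count lies strictly between 500
and 8000 and their total count strictly between 500 and 20,000 — "fewer
than"/"more than" are read as strict inequalities, so boundary cells are
retained. Mitochondrial genes (identifier prefix `mt-`, matched
case-insensitively, the mouse convention) are removed *after* cell filtering;
whether the feature thresholds should see mitochondrial counts is genuinely
open, and this package resolves it by filtering cells first, which means a
second application of `qc_filter()` can in principle remove a cell whose
feature count straddled the threshold through its mitochondrial genes.
An optional barcode exclusion list stands in for manual curation of
low-quality cells, for which no published criterion exists.

Normalization is the standard global-scaling convention: counts divided by
the cell total, scaled to 10,000, then `log1p`. The scale factor is
configurable; nothing downstream depends on its exact value because the DE
test is rank-based and fold changes are ratios.

## Differential expression

For each contrast and cell type, genes enter testing when detected in at
least 10% of either group's cells *and* in at least 5 cells across both
groups combined (the combined-detection reading of the marker-test gate,
documented as an interpretation). Two-sided Wilcoxon rank-sum p-values use
exact enumeration when both groups have at most 25 tie-free observations and
the tie-corrected normal approximation with continuity correction otherwise;
fully degenerate input yields *p* = 1. Benjamini–Hochberg adjustment is
applied per contrast and cell type over exactly the tested genes — the
adjustment universe is not stated in the source convention, and a
per-contrast universe keeps scopes independent.

The reported effect size is the `avg_log2FC` dialect of the standard marker
test: `log2(mean(expm1(x_a)) + 1) − log2(mean(expm1(x_b)) + 1)` over
log-normalized values. A difference-of-mean-logs alternative is available via
`fc_method = "meanlog"`. The expm1 dialect shrinks estimates for genes with
low expression; in simulations this attenuation, not test power, is what
keeps weak planted effects (|log2FC| near 0.5 on genes below ~0.3 mean
counts/cell) under the 0.25 DEG gate. DEG calls require
`|avg_log2FC| > 0.25` and adjusted *P* < 0.05; positive fold changes mean
higher expression in the first-named group, so "SEA upregulated" means
elevated in `Iso-P8`.

## Reversed and rescued genes

For every SEA DEG the REJ estimate is inspected. *Reversed*: opposite sign
with `|avg_log2FC| > 0.1`; by default REJ adjusted significance is also
required, since the source convention computes REJ "by the same procedure"
and defines rescue via REJ DEG membership — a flag
(`require_rej_significance = FALSE`) drops the requirement for sensitivity
analysis. *Rescued*: opposite sign with `|avg_log2FC| > 0.25` and adjusted
*P* < 0.05, i.e. an opposite-direction REJ DEG; rescued genes are a subset of
reversed genes by construction. SEA DEGs absent from the REJ tested set are
not reversed. Reversal ratios (Rev-Up, Rev-Down) are percentages per
direction; display values use round-half-up to the integer, which reproduces
all published organ-level figures exactly (`verify_printed_ratios()`), while
exact fractions are always retained.

Organ-level ratios pool all cells of an organ into one contrast by default
(`organ_level = TRUE` in `run_config()`); a union over per-cell-type DEG
tables is available by summarizing the per-scope outputs instead.

## Transcriptional noise: the CV delta

For a cell type, the 1500 highly variable genes (selected on the pooled cells
of the three groups involved; the count reuses the integration convention, as
none is stated for this step) define a difference vector
`d_g = |mean_a(g) − mean_b(g)|` of log-normalized group means. The CV is
`sd(d) × (1/mean(d))` (sample sd), and
`delta_cv = CV(Iso-R1, Iso-P8) − CV(Iso-R1, Het-P8)` on the same HVG set. The
phrase "absolute differences in expression for each gene across cells in the
two groups" is ambiguous between group-mean and cell-level constructions;
this package implements the group-mean reading and does not guess further. A
zero mean difference makes the CV undefined (`NA`), never zero.

A caution about the delta's sign, established with the bundled simulator: the
CV of the difference vector is *non-monotone* in the fraction of HVGs that
carry real effects. When effects are rare among HVGs, removing them lowers
the CV (positive delta under rejuvenation); when a large fraction of HVGs
carry effects — as in the simulator's default conditions, where 400 of 2000
genes are planted and 1500 HVGs are drawn from those 2000 — *partially*
removing them (reverted fraction 0.6) leaves rare large effects among noise,
which maximizes relative dispersion and makes the delta negative. At full
reversal the delta is positive again. Simulation-based checks of the delta's
sign therefore certify the construction, not a universal direction; in real
transcriptomes (1500 HVGs from ~20,000 genes, effects sparse) the
rare-effect regime applies.

## Similarity, modules and identity scores

Group similarity is the Pearson correlation (via `stats::cor`) of per-group
mean-expression vectors over a gene set, typically the SEA ∪ REJ DEG union;
an optional row-scaled copy serves display. Cross-subtype DEG modules map
each (gene, direction) to the subset of subtypes where it is a DEG with that
direction; modules are enumerated canonically — up-modules first, subsets in
binary order with subtype *i* contributing bit `2^(i-1)` — giving at most
`2(2^S − 1)` modules (14 for three subtypes) with stable ids across runs.

Identity scores use the standard expression-matched control scheme: genes are
binned into 24 equal-frequency bins by dataset-wide mean expression; each set
gene draws 100 control genes with replacement (seeded) from its bin; a cell's
score is its mean set expression minus its mean control expression, keeping
draw multiplicity. The score is invariant to adding a constant to a cell's
expression vector. The bin/control counts follow the widely used default; the
seed is a first-class argument so scores are reproducible.

## Highly variable genes

`select_hvg()` ranks genes by standardized variance: a trend of log10
variance on log10 mean is fitted across positive-variance genes (loess with
span 0.3 and degree 2; a quadratic polynomial when fewer than 32 genes are
available, where loess is unstable), values are standardized by the
trend-expected standard deviation and clipped at `sqrt(n_cells)`, and the
variance of the standardized values is ranked. Ties break by gene identifier;
constant genes are never selected.

## The simulator

`simulate_parabiosis()` draws negative-binomial counts with
`variance = mu + mu²/dispersion` (dispersion shared across genes), lognormal
baseline gene means (meanlog 0, sdlog 1.2 — giving a realistic mean of ~1–2
counts per gene per cell and ~3000-count cells) and lognormal library-size
factors (sdlog 0.3). `Iso-P8` multiplies planted genes' means by
`2^(±log2FC)` with effects drawn uniformly from [0.5, 1.5]; `Het-P8` equals
`Iso-P8` except for an *exactly* `round(f·n)` subsample of planted genes per
direction whose effect is attenuated toward the baseline by the reversal
completeness (default 1: full return to the young mean); `Het-R1` is an
independent draw from the baseline model. Defaults are 2000 genes, 300 cells
per group per cell type and 200 planted DEGs per direction. Every
(cell type, group) pair uses its own RNG stream derived from the master seed,
so adding a group never perturbs existing draws, and reversal is mean-level
attenuation rather than resampling, so the true REJ log2 fold change is
analytically known. The ground-truth ledger records baseline means, planted
directions, effect sizes and reversal flags.

What the simulator does *not* emulate: doublets, ambient contamination,
batch effects, zero-inflation beyond the NB, per-gene dispersion variation
(available as an extension point but off by default), and spatial zonation —
hepatocyte zones are modeled only as distinct cell types. Passing recovery
tests therefore demonstrates that the statistics behave correctly under a
clean NB world with known truth, not that any particular real dataset meets
these assumptions.

## Numerical and testing choices

Exactness cutoff 25 for the rank-sum test; continuity correction in the
approximate branch; round-half-up (`floor(x + 0.5)`) for display percentages;
deterministic row order in DEG tables (adjusted p, then gene id);
identifier-keyed operations throughout, so gene/cell order never matters;
degenerate inputs (all-zero cells, zero-variance genes, empty directions)
yield defined `NA`/warning behaviour rather than errors where the quantity is
genuinely undefined. Test problem sizes were chosen as the smallest that make
the statistical assertions stable: 20 seeds × (1000 genes, 100+100 cells) for
null calibration, 10 seeds at the full default design for reversal-fraction
recovery, 5000 cells for mean-convergence checks (asserted in aggregate —
per-gene NB noise at that depth exceeds a 2% tolerance for low-mean genes),
and full enumeration oracles wherever group sizes permit.

## Known limitations

Differential expression pools cells within (organ, cell type, group) across
animals; `sample_id` is carried for future stratification but no pseudobulk
or mixed-model option is provided, so animal-level pseudoreplication is not
addressed. The composite "rejuvenation impact" some displays combine from DEG
number, CV and reversal ratio has no stated formula, so the package emits the
three components side by side and does not invent an index. GO/pathway
enrichment, regulon inference, cell-communication, pseudotime and program
discovery are out of scope and belong to external tools.
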