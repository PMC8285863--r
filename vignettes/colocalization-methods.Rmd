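---
title: "Methods: joining, collapsing, and testing GWAS/eQTL colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joining, collapsing, and testing GWAS/eQTL colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlcoloc)
```

## The analysis model

`qtlcoloc` works entirely on summary statistics. Its unit of analysis is the
**locus variant**: a GWAS variant inside the locus of interest (the gene's
coordinates ± a flank, default 200 kb), annotated with the gene's cis-eQTL
evidence by exact variant-id match. Everything downstream — the enrichment
test, the P–P correlation, and all five panel types — consumes this one
table.

Two qualification rules partition the variants:

* a variant **is an eQTL** of the gene when its (tissue-collapsed) eQTL
  p-value satisfies `p_eQTL ≤ sigpvalue_eqtl` (default 0.05). The inclusive
  bound means a variant exactly at the threshold counts;
* a variant **is GWAS-significant** when `p_GWAS < sigpvalue_gwas`
  (default 5e-8, the conventional genome-wide threshold). The strict bound
  mirrors the threshold's role as a cut line drawn on the main panel: points
  on the line are not above it.

The two conventions differ deliberately and are fixed package-wide.

### Assumptions the inputs must satisfy

The schemas carry no allele columns, so the package must assume that the
GWAS effect (BETA) and the eQTL normalized effect size (NES, the slope of
the expression-on-genotype regression, alternative vs reference allele) are
reported **relative to the same allele** for every shared variant. If a
user's pipelines disagree on the effect allele for some variants, the
congruence classification for those variants will be silently wrong — there
is no way to detect this from the inputs. Harmonize before import.

Coordinates are 1-based inclusive throughout (the PLINK/GTEx convention);
the locus membership test is `start ≤ bp ≤ stop`.

## Tissue collapsing

For pan-tissue (`tissue = "all"`) or multi-tissue analyses, per-tissue eQTL
records are reduced to one record per variant:

* **min** (default): the record of the tissue with the smallest p-value —
  each variant's strongest eQTL effect, agnostic of tissue. p and NES always
  come from the *same* tissue. Ties on p are broken by larger |NES|, then by
  tissue name, making the result deterministic.
* **median / mean**: element-wise median/mean of p and of NES across the
  tissues in which the variant was tested (tissues without a record for the
  variant do not contribute). Averaging p-values has no inferential
  interpretation — it is a visualization summary, taken at face value.
* **meta**: a sample-size weighted Z (Stouffer–Liptak) combination,
  `z_i = sign(NES_i)·Φ⁻¹(1 − p_i/2)`, `w_i = √n_i`,
  `Z = Σw_i z_i / √(Σw_i²)`, `p = 2(1 − Φ(|Z|))`. Two design points:
  * the classical weighted Z-test is directionless; we **sign the z-scores
    by the NES direction** so that tissues with opposite effects cancel
    rather than reinforce. Congruence semantics require a direction, and an
    unsigned combination would overstate evidence for variants with
    discordant tissue effects. Users comparing against a directionless
    meta-analysis should expect larger combined p-values here for
    discordant variants (exactly p = 1 for two equal-n, equal-p studies
    with opposite signs).
  * no combined NES exists, so meta-collapsed variants are drawn at a fixed
    marker size and are excluded from the congruence split.

  Meta requires a sample size per record (column N). Without it the package
  refuses unless `assume_equal_n = TRUE` (then all weights are equal), a
  deliberate, visible opt-in because equal weighting can misrank tissues
  with very different power.

A single selected tissue bypasses collapsing entirely, whatever the method.

## The two statistics

**Enrichment.** The 2×2 table (GWAS-significant vs not) × (eQTL vs not) is
tested with a two-sided Fisher exact test (point-probability rule, via
`stats::fisher.test`; the test suite checks it against an independent
`lchoose`-based hypergeometric enumeration to 1e-12 relative error). If a
significance margin is empty — no significant variants, or all of them —
the result is flagged degenerate and p is reported as 1 with a warning
rather than erroring, so locus screens keep running.

In congruence mode two separate tables are tested: congruous-eQTLs vs
non-eQTLs, and incongruous-eQTLs vs non-eQTLs. eQTL variants of the *other*
class (or with an undefined direction) are excluded from each stratum's
table; non-eQTL variants are shared by both.

**P–P correlation.** Pearson r between `−log10 p_eQTL` and `−log10 p_GWAS`
over qualifying eQTL variants, with the p-value from the usual t transform
on n − 2 degrees of freedom, and the least-squares line on the same
coordinates. The log scale is the scale of the plot and of interest: raw
p-values would concentrate near the origin and the correlation would be
driven by a handful of extreme points. Variants failing `sigpvalue_eqtl`
are excluded — the correlation describes the variants shown in the panel.
Fewer than 3 points yields a flagged "undefined" result, not an error.

p-values of exactly 0 (as some pipelines print) are clamped to 1e-300 on
input, with a warning, so `−log10` stays finite.

**Lead variant.** With LD data, P–P points are colored by R² to a lead
variant: the user's choice (validated against both the GWAS and LD tables)
or the "upper-right-most" P–P point — the variant maximizing
`−log10 p_eQTL + −log10 p_GWAS`, ties broken by the larger GWAS coordinate,
then lexicographically. In congruence-plus-LD mode each stratum gets its own
lead. Variants sharing no LD pair with the lead get R² = 0 (absence of a
pair in PLINK output usually means R² below the reporting threshold).

## LD filtering and the heatmap

LD pairs are kept when both endpoints are qualifying eQTL variants in the
locus and `R² > r2min` (strict; default 0.1 — the boundary had to be fixed
one way, and strict inequality matches "in LD with", i.e. exceeding the
threshold). Variants are then thinned to those in LD with at least `ldmin`
(default 10) other variants — degree in the filtered pair graph, computed
after the locus restriction. With `ldmin = 0` even isolated variants stay.
Both filters are monotone: raising either threshold never enlarges the kept
set (property-tested). The R² matrix is symmetric with unit diagonal and 0
for unobserved pairs; conflicting duplicate R² values for one pair are an
error, not a silent overwrite.

When nothing survives (or fewer than 2 variants), the heatmap is skipped
with a warning and the figure falls back to the no-LD layout.

## The figure

Layout is a pure function of two flags: no LD → 4 panels (main, gene track,
enrichment, P–P); LD → 5 (heatmap inserted); LD + congruence → 6 (separate
congruous/incongruous P–P panels). Congruence *without* LD superimposes
both strata in a single P–P panel with per-stratum regression lines. The
main panel, gene track and heatmap share identical x limits.

Choices the source material left open, fixed here:

* Color ramps: a single warm (YlOrRd) ramp for eQTL significance by
  default; in congruence mode a blue ramp for congruous and a red ramp for
  incongruous variants (computed per stratum and applied as identity fill,
  since one ggplot fill scale cannot carry two gradients). The LD heatmap
  uses the warm ramp, or greyscale with `ldcolor = "black"`.
* Marker grammar: grey squares for non-eQTL variants; triangles point up
  for `BETA > 0`, down for `BETA < 0`; area scales with |NES|, optionally
  pinned by `nes_size_limits` to keep sizes comparable across figures.
* Geometry: width 12 in without LD, 14 in with LD; height = width × 0.75
  (basic) or × 0.9 (LD layouts); gene-track height weight 2 by default
  (raise it for gene-dense loci). Output at `res` dpi (default 300).
* The output name is the dot-separated template
  `<gene>.<trait>.<tissue>.<Congruent|NoCongruence>.<LD|NoLD>.qtlcoloc.<fmt>`
  with tissue rendered as `PanTissue` (all tissues), `MultiTissue` (a
  list), or the tissue name.

Rendering is deterministic: the same inputs produce byte-identical PNGs
(cairo device, fixed dpi), which the test suite asserts.

## The synthetic-locus simulator

`simulate_locus()` generates all four input tables with known truth. The
locus has `n_variants` evenly spaced variants in `n_blocks` equal LD
blocks; within a block, genotype correlation decays as `rho^|i−j|` (AR(1)),
zero across blocks — the simplest structure that exercises the R²/degree
filters meaningfully. Summary statistics follow the standard model for
GWAS z-scores: `z = λ·r(·, causal) + ε` with `ε ~ MVN(0, Σ)` where Σ is the
same LD correlation, so marginal z-scores are standard normal under the
null while neighboring variants co-vary as they do in real data. Effect
sizes are scaled as `z/√N` (`N` = 100,000 for the GWAS, per-tissue sample
sizes of 300–500 for the eQTLs), giving NES magnitudes of order 0.1–1,
GTEx-like. LD pairs are emitted as `r² = rho^(2|i−j|)` down to 0.01.

Defaults — 300 variants, 3 blocks, ρ = 0.9, signal strengths λ_gwas = 12
and λ_eqtl = 10, shared causal variant at the middle of the central block
(which the one-gene coordinate table spans) — describe a clearly
colocalized locus: causal-variant z-scores around 10–12, i.e. far beyond
both thresholds, the regime the display is designed for. With
`shared_causal = FALSE` the eQTL signal moves to the first block:
overlapping peaks driven by different variants, the classic false-positive
scenario for naive colocalization reading.

What the simulator does **not** emulate: allele-frequency spectra,
imputation quality gradients, cross-block ("long-range") LD, multiple
causal variants per signal, winner's-curse inflation, or sample overlap
between GWAS and eQTL studies. Tests passing on these fixtures therefore
validate the *arithmetic and the contracts*, not robustness to every
real-data pathology.

A note on testing the null: the test suite checks marginal uniformity of
null p-values with a Kolmogorov–Smirnov test on an LD-thinned variant
subset (spacing 50, residual correlation ≈ 5e-3) pooled across seeds,
because KS assumes independent observations and within-block variants are
strongly correlated by construction.

## Problem sizes used by the tests

The suite runs the statistical oracles at full prescribed size (500 random
Fisher tables, 200 random point sets, 100 collapse fixtures with up to 20
tissues, 100 random LD graphs of up to 200 variants) and the
shared-vs-distinct recovery experiment at 50 paired replicates of the
default 300-variant locus; figure tests use a 120-variant locus at 96 dpi.
The full suite completes in about half a minute on one core.

## Known limitations

* No colocalization posterior model: the statistics here are descriptive
  and threshold-dependent; use coloc/eCAVIAR-class methods for formal
  inference.
* No allele harmonization or liftover; inputs must share a build and an
  effect-allele convention.
* Rankings report raw correlation p-values with no multiple-testing
  correction across genes/tissues.
* The bundled gene table is a small convenience set for examples and tests;
  real analyses should supply a full coordinate table for their build.
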