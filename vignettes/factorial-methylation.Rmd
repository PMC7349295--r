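---
title: "Factorial analysis of sex-biased DNA methylation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial analysis of sex-biased DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

Sex differences in DNA methylation confound three factors: gonadal sex
phenotype, the number of X chromosomes, and the presence of a Y. A
factorial mouse cohort separates them with five groups — XX females,
XY sex-reversed females, XY males, XO females, and XX *Paf*-carrier
females — and four pairwise comparisons (baseline first):

| comparison | contrast |
|---|---|
| XX.F vs XY.M | phenotype + X dosage + Y |
| XY.F vs XY.M | phenotype only (both XY) |
| XX.F vs XY.F | X dosage + Y (both female phenotype) |
| XXPaf.F vs XO.F | X dosage only (both female, no Y) |

A differential site shared by the right subset of comparisons is assigned
a class: `x_dosage` when present in all three X-dosage-sensitive
comparisons, `y_linked` when present in the two Y-sensitive comparisons
but absent from the pure X-dosage contrast, `phenotype` when present in
both phenotype-sensitive comparisons. Sites can satisfy several rules;
explicit precedence (`x_dosage > y_linked > phenotype`) makes the classes
disjoint. Both the rules and the precedence are configuration
(`default_class_rules()`), because any fixed reading of "shared across
comparisons" embeds a resolution choice that should be visible and
overridable.

## The per-CpG test

Counts at CpG `i` in replicate `j` are modeled as beta-binomial:
`m_ij ~ BetaBin(t_ij, mu, rho)`, where `rho` is the intra-class
correlation capturing biological replicate variance. The test statistic at
a site compares window-smoothed group levels:

* **Smoothing**: counts are pooled over all of a group's replicates within
  ±250 bp of the site (uniform weights, no kernel). The window width
  (500 bp, default) matches the spatial correlation scale of methylation.
* **Variance**: for pooled depth `T`,
  `v = mu(1-mu) * (1 + (T-1) phi) / T`, where `phi` is a method-of-moments
  intra-class correlation derived from the Pearson X² of *all* per-CpG,
  per-replicate count pairs in the window against the pooled level:
  `c_hat = max(1, X² / (n_obs - 1))`, `phi = (c_hat - 1)/(T - 1)`.
* **Wald statistic**: `(mu_other - mu_baseline) / sqrt(v_b + v_o)`, p from
  the two-sided normal tail. No multiple-testing correction at the CpG
  level; calling instead uses the fixed stringent cutoff `p < 1e-5`
  together with `|delta| > 0.20` (both strict).

Two estimator choices deserve comment. First, the overdispersion factor is
estimated from site-by-replicate count pairs rather than from replicate
window totals: with 2–3 replicates the latter has 1–2 degrees of freedom
and is far too noisy — simulation at the default operating point
(3 vs 3, 20×, `rho = 0.05`) shows the replicate-total variant mis-calibrates
the null (fraction of p < 0.05 ≈ 0.073 and worse), while the
count-pair variant achieves ≈ 0.056 with power ≈ 0.999 for a 0.30 shift
over 12 CpGs. Second, `c_hat` is floored at 1 (phi at 0): variance is never
deflated below binomial. When both groups are degenerate (`mu` of 0 or 1
with `phi = 0`) the variance is floored at `1/(4T)` per group so extreme
separation still yields a finite, highly significant statistic.

This is deliberately *not* a reimplementation of the Bayesian shrinkage
used by established WGBS callers; it is the minimal fully specified
smoothed-proportion Wald test, and its calibration is asserted by the test
suite rather than assumed.

## Region calling

Two independent strategies, then a union:

* **Scan caller** (`call_dmr_scan()`): seeds are CpGs with `p < 1e-5`;
  maximal same-direction runs with consecutive seeds ≤ 300 bp apart form
  candidates (300 bp ≈ the smoothing span; configurable). Candidates must
  span ≥ 50 bp and ≥ 3 CpGs, have ≥ 50% significant CpGs, and
  `|mean delta| > 0.20`. Surviving same-direction regions within 100 bp
  (gap ≤ 100, inclusive) are merged, and all four constraints are
  re-asserted after merging, so every emitted region satisfies them. The
  run-construction rule (link gap, significant fraction) is a
  reconstruction — only the output constraints are externally fixed — and
  both knobs are exposed.
* **Tile caller** (`call_dmr_tiles()`): non-overlapping 300 bp windows,
  per-CpG depth filter `[10, 500]` before pooling, two-proportion Pearson
  chi-square deflated by a per-tile overdispersion factor
  `c_hat = max(1, replicate-level X²/df)`, q-values by Benjamini–Hochberg.
  BH replaces the SLIM adjustment of the reference tool: SLIM is not
  specified tightly enough for faithful reimplementation, BH is standard
  and conservative, and the difference is confined to tile q-values.
  Tiles need ≥ 1 CpG (configurable).
* **Union** (`union_dmr()`): all scan regions, plus tile regions that
  overlap no scan region by ≥ 1 bp.

Region-level set operations (intersection across comparisons,
classification) use ≥ 1 bp overlap, the closest analogue of exact-position
matching at the site level; stringency is configurable.

## The synthetic cohort

`simulate_cohort()` generates the *stated world* in which the pipeline's
recovery properties are defined — its defaults are fixed once, from the
design being emulated and from realism arguments, and are not tuning
knobs:

* **Groups**: 3 replicates per group, 2 for XXPaf.F. Coverage
  Poisson(20) truncated at ≥ 1 (the cohort's stated mean coverage);
  missingness is exercised separately by a 5% per-sample site dropout.
* **Genome**: chr1 (3 Mb autosome), chrX (1.5 Mb), chrY (0.3 Mb);
  background 10 CpGs/kb plus 30 one-kb CpG islands at 80 CpGs/kb.
  Background methylation 0.85, islands 0.10 — the bimodal marginal of a
  real methylome.
* **Noise**: beta-binomial with `rho = 0.05`; binomial-only noise would
  make every test trivially easy. XXPaf.F can carry inflated `rho`
  (mixed genetic background); off by default so acceptance runs test the
  homogeneous design.
* **Planted effects**: 8 regions per class, 300 bp wide, `delta = 0.30`,
  sign −1 (affected groups lose methylation), placed outside islands and
  non-overlapping. Phenotype effects apply to XY.M on autosomes; X-dosage
  effects to XX.F and XXPaf.F on chrX; Y-linked effects to XY.M and XY.F.
  Each planted region carries 12 CpGs (40/kb) — the CpG-shore-like
  density where regulatory differential methylation concentrates in real
  data; sparser regions would sit below any caller's information floor at
  20× and 3 replicates. chrY CpGs exist only in Y-carrier samples.
* **Expression coupling**: one gene body covers each phenotype region;
  with probability 0.8 it receives an opposite-direction log2 fold change
  of 2 (plus N(0, 0.2) noise, padj « 0.05) in the two comparisons where
  sex phenotype differs. DEG tables for null genes carry N(0, 0.3) fold
  changes and uniform padj ≥ 0.1. The generator emits DEG truth directly;
  it does not simulate read counts for expression.
* **Repeats**: family densities mirror genomic reality scaled to the toy
  genome (B1/Alu ≈ 0.94/kb, L1 ≈ 0.31/kb, MIR ≈ 0.42/kb, ERVK ≈ 0.1/kb).
  A family with bias multiplier `m > 1` redirects a fraction
  `q = (m-1)p0/(1-p0)` of its elements onto planted regions, producing
  `m`× the uniform overlap rate in expectation; `m < 1` thins planted
  overlaps by rejection.

What a green recovery test does establish: at the stated operating point,
the caller chain finds 300 bp, 0.30-shift, CpG-dense regions with
sensitivity ≥ 0.8 and precision ≥ 0.9, and the factorial set algebra
assigns ≥ 90% of recovered regions their true class. What it does not
establish: performance on sparse-CpG regions, small effect sizes
(< 0.20 is excluded by the thresholds by construction), non-uniform
coverage, SNP artifacts, or real inter-individual structure beyond a
single intra-class correlation.

## Enrichment null

Repeat enrichment compares observed (region, element) overlap pair counts
with 1000 sets of 300 bp random regions matched on distance to the
nearest gene body (bins: 0, (0,1 kb], (1,10 kb], (10,100 kb], > 100 kb —
log-spaced; the matching reference's exact scheme is not public, so the
bins are a design decision and configurable). A family is enriched when
observed exceeds the null in > 995 of 1000 permutations (strict;
995 is not enriched), depleted symmetrically. Counting is per element
pair — a region overlapping two L1 copies counts twice — with a 0/1
per-region switch available. Distance is measured to the nearest gene
*body* (not TSS); regions on geneless chromosomes cannot be matched and
raise an error rather than being silently dropped.

## Numerical and convention decisions

* Intervals are 0-based half-open (BED); CpG positions are 1-based
  (cytosine report). One conversion utility (`pos_to_bed()` /
  `bed_to_pos()`) is used everywhere and boundary-tested.
* Input call tables are assumed strand-collapsed per CpG dyad; duplicate
  positions are an error (upstream fault), never silently merged.
* All strict/inclusive boundaries follow the stated rules: depth bounds
  inclusive, sDMC thresholds strict, merge gap inclusive at 100,
  enrichment incidence strict at > 99.5%.
* Nearest-distance conventions follow `GenomicRanges::distanceToNearest`
  (bases strictly between; abutting features have distance 0).
* The hypergeometric enrichment p is the upper tail `P(X >= observed)`;
  depletion is reported separately as the lower tail. Expected overlap is
  the closed form `n1*n2/N`.
* Yates continuity correction is applied in `directional_association()`;
  this choice is anchored by exact reproduction of both reference
  contingency-table p-values (2.511e-11 and 1.478e-8) and cross-checked
  against `stats::chisq.test` in the suite.
* The DEG-enrichment universe is mandatory explicit configuration: the
  expectation `n1*n2/N` is meaningless without knowing `N`, and no
  default can be both honest and invisible.
* Pipeline stage seeds derive from the master seed by fixed per-stage
  offsets, so any stage can be rerun in isolation.

## Known limitations

* The Wald test's normal reference underestimates tail mass slightly at
  2–3 replicates (null p < 0.05 fraction ≈ 0.056, not 0.050); the
  stringent calling threshold plus the effect-size filter make the
  practical sDMC false-call rate ≤ 1e-4 per CpG, which is what matters
  downstream and what the suite asserts.
* The tile caller's BH adjustment is not SLIM; q-values are comparable in
  spirit, not numerically. More importantly, its q < 0.05 contract is an
  FDR target, not a precision guarantee: when strong regions are present,
  BH's adaptive threshold admits borderline one-to-three-CpG tiles whose
  overdispersion is underestimated, so the union list carries a visible
  false fraction that the scan list does not. Recovery precision is
  therefore a scan-caller property; the union trades precision for the
  sensitivity of tiling into regions the scan misses.
* Gene models synthesized by the generator are single-exon and fully
  coding; UTR/intron annotation paths are exercised by hand-built
  fixtures in the test suite instead.
* Cross-species tests treat human gene lists as plain sets; probe-level
  processing of the underlying methylation arrays is out of scope.
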