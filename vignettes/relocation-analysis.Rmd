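---
title: "Quantifying transcription-factor complex relocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-factor complex relocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfreloc)
```

## The model

`tfreloc` analyses a specific regulatory phenomenon: an inducible
transcription factor appears, and a pre-bound pioneer factor *relocates* —
it abandons a fraction of the distal sites it occupied before induction
and reappears at sites bound by the induced factor, together with
co-factors of the elongation machinery. The package measures this from
three kinds of evidence:

1. **Binding**: pairwise peak comparisons between conditions, classified
   by the two-fold rule. With pseudocounted CPM values $a$ and $b$, the
   fold difference is $f = (a + c)/(b + c)$ with $c = 0.5$; a union peak
   is A-specific when $f > t$, B-specific when $f < 1/t$, shared
   otherwise, with $t = 2$ by default. The pseudocount exists so that
   peaks entirely absent in one condition — biologically the most
   interesting class — receive a finite, extreme fold rather than a
   division by zero, and it is deliberately small relative to typical
   occupied-site CPM so it never flips a genuine call. Ranking is by
   descending fold with ties broken by total signal and then genomic
   position; this ranked order is the contract shared by every heatmap
   and motif-density profile built afterwards ("along the same
   coordinates").
2. **Sequence**: PWM scanning of both strands. Scores are log2 odds
   against a uniform background; the reporting threshold sits at a fixed
   fraction (default 0.8) of the attainable score *range*, which keeps
   the stringency comparable across matrices of different lengths and
   information content. Overlapping same-strand hits within one PWM
   length collapse to the best-scoring one so that low-complexity
   sequence cannot inflate densities.
3. **Expression**: FPKM-based two-fold calling and the two-character
   0/1/2 response code over the (induced vs control, inhibitor vs
   induced) comparisons. Differential genes fall into the $3^2 - 1 = 8$
   codes other than "22"; the grouping itself excludes "22" by
   definition.

The relocation fraction is estimated from a three-set overlap of distal
peaks — pioneer before induction (A), pioneer after induction (B),
induced factor (C) — on merged union loci, so a locus counts once however
many raw peaks cover it. The Venn regions map onto groups 1–5
(1 = A only, 2 = AB without C, 3 = ABC, 4 = BC without A, 5 = C only; the
AC-only and B-only residuals are reported unlabeled, and the mapping is
configurable). Under the relocation model, abandoned sites populate
group 1, retained sites away from the induced factor populate group 2,
and the destinations populate group 4, so

$$\hat{r} = \frac{|G_4|}{|G_4| + |G_2|}.$$

This estimator is deliberately built from the *destination* side
(groups 4 and 2) rather than the origin side (groups 1 and 2): both are
consistent when relocation is one-to-one, but group 4 is robust to
origin-site peaks that drop below the peak-calling floor for reasons
other than relocation.

## The synthetic scenario

The generator builds the study conditions end to end: a two-chromosome
toy genome (10 Mb by default) with 2,000 regulatory sites in five classes
(ETS/GATA enhancers, ETS/RUNX composite sites, RUNX-only sites, TEAD
sites, promoters), 600 genes, four conditions crossing induction with an
inhibitor, and a planted relocation fraction of 0.6. Key design choices:

- **Layout.** Chromosome 1 is a row of per-gene blocks (12 kb): the gene
  body, its TSS, and — for linked genes — one regulatory site either at
  the TSS (promoter class) or 2.8–4.5 kb away (distal classes). The
  geometry guarantees that every distal site is beyond the ±2 kb promoter
  window of its own gene yet unambiguous under nearest-TSS assignment,
  and at least 5 kb from every *other* TSS. Unlinked sites live on
  chromosome 2, away from all genes. Infeasible sizings fail with
  explicit errors rather than silently overlapping.
- **Occupancy** is binary per site, factor and condition, scaled by a
  per-site strength in {0.5, 1, 2}; the strength continuum is what gives
  the fold-difference ranking something to rank. Upon induction the
  pioneer factor leaves 60% of its ETS/GATA sites (chosen at random) and
  appears at an equal number of composite sites; the inhibitor blocks the
  move and instead gains TEAD sites, and removes the induced factor from
  30% of its sites. The co-factor follows pioneer+induced co-occupancy.
- **Coverage** piles Poisson fragment counts (mean = depth x occupancy,
  default depth 30) with uniform midpoints over each occupied site, plus
  uniform background (0.1 fragments/kb), into run-length-encoded
  base-resolution tracks; peak sets are the occupied-site intervals. The
  generator emits no input/control track and the pipeline models none.
- **Motifs** are planted as exact consensus sequences of the bundled
  9-bp matrices (RUNX, ETS, GATA, AP1, TEAD) and the 20-bp ETS::RUNX
  composite (ETS core, 2-bp spacer, RUNX core on one strand, shipped as a
  single matrix) at recorded offsets near each site's summit, so the
  scanner must recover them perfectly at consensus threshold. The
  matrices are sharp (97:1 counts) on purpose: with a range-relative
  scan threshold of 0.8, a 9-mer of this sharpness tolerates exactly one
  mismatch, giving a low and predictable background hit rate; softer or
  shorter matrices make the same threshold far more permissive.
- **Expression** couples each site subclass to a response code
  (relocation origin "01", destination "10", primed composite "12",
  repressed sites "02"/"01" by inhibitor sensitivity, TEAD "21"; promoter
  and unlinked genes "22"). Six of the eight differential codes arise
  naturally from this occupancy logic; "00" and "20" have no generator
  mechanism, though the coder supports and is tested on all eight. Counts
  are negative binomial (dispersion 0.05, a standard bulk RNA-seq value)
  with three replicates around a lognormal baseline
  (meanlog = log 500, sdlog = 0.5). Crucially, condition multipliers are
  *peak-anchored*: the sampled baseline is the gene's expression in its
  most active condition and coded folds (default 5) step down from
  there. Because FPKM is share-based, a small gene universe would
  otherwise let strongly induced genes inflate a condition's library mass
  by 25–40% and bias every fold call; peak anchoring keeps composition
  stable by construction and matches the biology being emulated
  (the endothelial program is on and switched off, the haematopoietic
  program is off and switched on). The same multipliers drive the
  elongation-mark coverage over gene bodies.

What the generator does **not** emulate: read-level sequencing artefacts,
mappability and GC bias, irregular gene density, peak-calling noise
(peaks are truth intervals, not called from coverage), diploid genomes,
or batch effects in expression. Tests passing on this scenario therefore
validate the *analysis machinery* — counting, classification, ranking,
overlap logic, scanning, coding — not robustness to upstream artefacts
real data would add.

## Numerical choices

- Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only at file boundaries (BED and bedGraph are
  native; gene tables store the strand-aware TSS explicitly).
- PFM regularisation adds 0.25 to every count cell before normalisation,
  so log-odds scores are always finite; background is uniform.
- Tag counting uses summit ± 200 bp; anchored matrices default to 10-bp
  bins and report mean per-bp CPM; bins clipped at chromosome ends read
  as zero. Display smoothing of heatmaps (rolling mean over 50 ranked
  rows in `autoplot()`) is never applied to stored matrices.
- Metagene profiles rescale each body onto 100 bins with 2 kb flanks in
  20 fixed-bp bins; genes shorter than the bin count are skipped with a
  warning; minus-strand genes are reversed.
- Hierarchical clustering uses 1 − Pearson distance with average
  linkage; zero-variance genes sit at distance 1 from everything
  (documented degenerate case), while zero-variance *samples* are an
  error.
- The two-sided hypergeometric p-value uses the minimum-likelihood rule
  (every outcome at most as probable as the observed one contributes),
  which matches exhaustive subset enumeration exactly.
- Ties: fold ranking breaks ties by total CPM then genomic position;
  nearest-TSS assignment breaks exact distance ties toward the
  lexicographically smaller gene id; hit collapsing keeps the leftmost of
  equal-scoring overlapping hits. All tie rules are deterministic, which
  is what makes full-pipeline runs bit-reproducible.
- Seeding: every stage derives its RNG stream from the configuration
  seed plus a fixed per-stage offset, so stages can be re-run or skipped
  independently without perturbing one another's draws.

## Problem sizes used in validation

The packaged tests exercise the estimator at the default scale (10 Mb,
2,000 sites, ten seed replicates for the relocation recovery; one
default-scale realisation for expression-code recovery) and use reduced
scenarios (1.5–2 Mb, 200–400 sites) where the property under test does
not depend on scale — determinism, occupancy logic, oracle agreement.
Brute-force oracles (per-base binning, all-pairs interval logic,
exhaustive 6-mer scoring, full subset enumeration of the hypergeometric
null) are implemented independently in the test helpers and share no
code with the package internals.

## Interfaces and orchestration

The package is tidyverse-native: peaks, gene models, comparison records,
codes and cross-tabulations are tibbles; result objects provide
`tidy()`, `glance()` and `autoplot()` methods. `run_pipeline()`
orchestrates all stages from one `scenario_config()` (or its YAML form,
validated against the documented argument set) and returns a flat,
JSON-ready summary — group sizes, proximal/distal fractions, motif
fractions, the relocation estimate and the response-code histogram —
that reproduces exactly under a fixed seed. The orchestrator runs on
simulated scenarios; analyses of external files go through the reader
functions (`read_bed()`, `read_bedgraph()`, `read_fasta()`,
`read_gene_table()`, `read_pfm()`) and the same stage functions.

## Known limitations

- No replicate-aware statistical test for differential binding: the
  two-fold CPM rule is the classification criterion, matching the
  analysis being reproduced; it has no error model.
- FPKM-based coding inherits FPKM's compositionality; the generator is
  parameterised to keep this bias negligible (see above), but on real
  data with massive global shifts a spike-in or median-of-ratios
  normalisation would be needed upstream.
- The scanner's zeroth-order uniform background is simplistic for real
  genomes (no CpG or repeat modelling).
- `estimate_relocation()` assumes one-to-one relocation between distal
  site populations; many-to-one movement would bias it downward.
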