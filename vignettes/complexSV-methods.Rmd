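---
title: "complexSV methods: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{complexSV methods: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexSV)
```

This vignette documents the statistical models behind each analysis
stage, the numerical conventions, and the reasoning for the main design
choices. The README shows usage; this document explains *why* the
methods look the way they do.

## 1. Hi-C evidence for complex structural variants

### The signal

A candidate cSV from WGS amplicon reconstruction describes a set of
amplified genomic segments. Hi-C sees amplification in two distinct
ways:

- an **ecDNA** is a circle physically detached from its chromosome. Its
  bins contact *each other* far more than expected, but contact between
  the event and its chromosomal flanks does **not** scale with the
  amplification. After iterative correction (which divides each bin's
  row by its marginal), the inflated marginals of event bins *depress*
  the balanced event-to-flank values below the flank-to-flank baseline:
  the `event_lower` cis signature.
- a **multi-chromosome amplicon** joins pieces of different chromosomes
  on one molecule, producing cross-chromosome contact far above the flat
  trans background: the `event_higher` trans signature.

### Regions and contact sets

For each candidate segment we collect four sets of balanced contact
values at 10 kb resolution:

- `EVENT_PROJECTION`: event bins × flank bins,
- `FLANK_PROJECTION`: upstream flank × downstream flank,
- `WITHIN_EVENT` and `WITHIN_FLANK`: pairs inside each set.

Flanks are the same length as the segment, immediately up/downstream,
*skipping past* bins claimed by any other candidate event of the sample
(otherwise a neighboring amplicon contaminates the baseline). Truncation
at chromosome ends is flagged; segments without usable flank or with too
few pairs are reported untestable with a reason, never silently dropped.

Because cis contact decays with genomic distance, the event projection
and flank projection are **distance-matched**: both sets are restricted
to the separation range they share. Without this, the null comparison
would be confounded by decay; with it, the null calibration test in the
suite passes at the nominal level.

The decisive cis comparison is `EVENT_PROJECTION` vs `FLANK_PROJECTION`
(Wilcoxon rank-sum); `WITHIN_EVENT` vs `WITHIN_FLANK` is reported as a
secondary p-value. For trans candidates the decisive comparison is
cross-chromosome contact inside the event vs non-overlapping
cross-chromosome background. P-values are Benjamini-Hochberg adjusted
within an event; support requires at least one adjusted p below 0.05
*in the expected direction* (direction is computed from medians; a
significant result in the wrong direction is not support).

### The generative model used for validation

`simulate_hic` implements the model described in the README. Three
points matter methodologically:

1. The ecDNA uplift term is added *only* to intra-event bin pairs. The
   event-lower signature is therefore **emergent**: it appears because
   ICE deflates event-bin rows, not because the simulator writes low
   values into the projection. This makes the power tests a genuine
   end-to-end check of the balancing + testing chain.
2. Purity mixes the tumor signal linearly: at `purity -> 0` the event
   terms vanish and the simulator reduces to the null model, so null
   calibration and power curves live on one continuum.
3. Counts are Poisson, so low-coverage sparsity and ties occur naturally
   and the Wilcoxon tie correction is exercised.

Realism limits: the model has a single decay exponent, no
TAD/compartment structure, no mappability bias, and BFB fold-back
hotspots are a one-bin caricature. These do not affect what the tests
certify — calibration and power of the decision rule under a model where
ground truth is known.

## 2. Chromothripsis calling

Windows of 2.5 Mb slide at 10 kb steps. A window is called when it
contains at least 15 inversion breakend pairs, at least 15 copy-number
switches (adjacent segment boundaries with |ΔCN| > 0.5), and at least 10
deletion pairs — with *both* breakends inside the window, so a
rearrangement wider than the window never counts. Overlapping called
windows merge into regions. The thresholds are deliberately hard-coded
defaults of `chromothripsis_config()`; the boundary behavior (exactly at
threshold calls positive, any decrement calls negative) is pinned by
tests. Association between cSV-bearing chromosomes and chromothriptic
chromosomes uses the package's Fisher exact test on the per-(sample,
chromosome) 2×2 table.

## 3. Copy-number annotation

Gene-level CN is the overlap-weighted mean of segment CN, renormalized
over covered base pairs (partial coverage does not dilute toward zero;
zero coverage is `NA`, not 0). Status thresholds are strict
inequalities relative to sample ploidy ψ: biallelic loss CN < 0.5 takes
precedence; autosomes call gain above 1.95 ψ and loss below 0.5 ψ;
single-copy sex chromosomes use 0.8 ψ and 0.3 ψ. Values exactly at a
boundary are neutral — pinned bit-exactly by tests, because downstream
cohort fractions are sensitive to boundary conventions.

## 4. Convergent versus shared amplicons

Two samples amplifying the same locus may share one ancestral event or
have converged independently. Interval Jaccard cannot distinguish these
(both overlap heavily), but junction breakpoints are near-exact
replicates only under shared origin. `breakpoint_jaccard` matches
breakpoints one-to-one (greedy by distance, deterministic tie order)
requiring equal chromosomes, strands, and both positions within 100 bp.
Verdicts: `shared` above 0.25, `independent` below 0.05, `ambiguous`
between. The generators build both ground truths: shared pairs reuse
byte-identical junctions; independent samples draw junctions at least
5 kb apart.

## 5. Permutation enrichment and the discreteness caveat

Null placements keep each query interval's chromosome and length and
draw its start uniformly from the mask-free gaps of that chromosome.
Instead of rejection sampling (propose anywhere, reject mask hits —
which can loop forever on dense masks), the sampler draws a gap with
probability proportional to its number of feasible starts, then a
uniform offset: the same distribution, exact, and it fails fast with an
informative error when an interval is longer than every gap.

The reported `empirical_p = (1 + #{null >= obs}) / (n_perm + 1)` is the
standard conservative estimator. Two consequences matter for testing:

- its support is discrete (multiples of 1/(n_perm+1)), and the overlap
  count statistic itself takes few values, so a Kolmogorov-Smirnov
  uniformity test on the reported p fails *by construction* even for a
  perfect implementation;
- the correct exchangeability check is on the **tie-randomized p**,
  `(#{null > obs} + U * (1 + #{null = obs})) / (n_perm + 1)` with
  `U ~ Uniform(0,1)`, which is exactly uniform if and only if the
  observed statistic is exchangeable with the null statistics. The test
  suite asserts uniformity of the tie-randomized p and conservativeness
  of the reported p. For the check to be valid the observed queries must
  be drawn from the same continuous placement distribution the sampler
  uses — grid-aligned fixtures would break exchangeability spuriously.

Annotation overlap ("does this event touch a regulatory peak?") is a
separate rule: at least 100 bp of overlap by any event segment.

## 6. Expression: ecDNA effect beyond copy number

ecDNA-positive genes are more highly expressed, but they also have
higher copy number, so the relevant question is conditional. The nested
F-test compares `expr ~ 1 + cn` against `expr ~ 1 + cn + ecDNA` (one
added degree of freedom). Degenerate cases are sentinels, not errors in
the scan: a perfect full-model fit reports F = Inf, p = 0; both models
perfect reports F = 0, p = 1; genes with < 4 samples, a single ecDNA
group, or a collinear design are reported untested with a reason and
excluded from BH adjustment. The expression generator draws CN with a
heavier tail in ecDNA-positive samples precisely so the two covariates
are confounded and marginal tests would overstate the ecDNA effect.

## 7. Neighbor-joining phylogenetics

Distances are Hamming distances between binary mutation profiles
(optionally with an all-zero germline root). NJ is implemented in the
package rather than delegated so that ties in the Q-criterion break
deterministically (lexicographically by node label pair) and negative
branch lengths are clamped to zero with a warning — both needed for
reproducible Newick output. `ape` provides the tree container, Newick
I/O, and an independent oracle (`ape::nj`) in the tests. On additive
distances NJ is exact: the suite verifies topology *and* path-length
recovery on random trees, and end-to-end recovery from perfect-phylogeny
mutation matrices (each branch owns disjoint variants; leaves inherit
their root path, making Hamming distances exactly additive).

## 8. Statistical primitives

Implemented in-package with explicit conventions, each cross-checked
against an independent oracle in the tests:

- **Wilcoxon rank-sum**: statistic is the Mann-Whitney U of the first
  sample; exact p by full enumeration when both n ≤ 12 and no ties,
  otherwise normal approximation with tie and continuity corrections.
  Exactness is verified against brute-force enumeration over all
  combinations.
- **BH**: step-up with the cumulative-minimum formulation, verified
  against the direct definition and `p.adjust`.
- **Fisher 2×2**: two-sided by the probability-mass convention (sum of
  table masses ≤ observed mass × (1 + 1e-7), the same tolerance
  `fisher.test` uses, so both routes agree bit-for-bit on integer
  tables).
- **Kruskal-Wallis** with tie correction; **nested F** via least squares
  with a rank check (collinear designs error rather than silently
  dropping a term).

## 9. Reproducibility conventions

Every generator takes an explicit `seed`, saves and restores the
caller's RNG state, and is a pure function of (parameters, seed).
`run_all` derives all stage seeds from one integer and writes only
plain-text outputs, so reruns are byte-identical — asserted by tests and
by the acceptance script. Problem sizes in the tests (500 null events,
200 power replicates, 100 random trees, 200 enrichment datasets) were
chosen to keep the full suite within a few minutes on one CPU while
making the binomial bounds used in the assertions meaningful.
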