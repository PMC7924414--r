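---
title: "Matched background models for genomic position enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched background models for genomic position enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitematch)
```

## The model

`sitematch` treats a dataset of integration (or binding) events as a
multiset of single-base positions on a genome assembly.  Enrichment of
the signal set $S$ in an annotation track $T$ relative to a control set
$B$ is measured on the $2\times2$ table of membership counts:

$$\mathrm{FC}(T) \;=\; \frac{s_{in}/|S|}{b_{in}/|B|},$$

tested with the uncorrected Pearson $\chi^2$ statistic (one degree of
freedom) and Bonferroni-corrected over the $m$ tracks of the current
run.  The reported $\log_2$ fold change adds a Haldane–Anscombe
pseudocount of $0.5$ to all four counts so it stays finite when a cell
is empty; the raw fold change is reported as $\infty$ when the
background cell alone is empty, and as $1$ when both "inside" cells are
empty (no evidence either way).  For scored tracks, the score values at
signal and control positions are additionally compared with the
two-sample Kolmogorov–Smirnov statistic, using the asymptotic p-value
at effective size $|a||b|/(|a|+|b|)$.  Tracks are ranked by effect
strength, defined here as $|\log_2 \mathrm{FC}|$ with ties broken by
adjusted p-value and then label; "effect strength" has no canonical
definition, and this one makes depletion and enrichment comparable.

The central inferential idea is the *matched background*.  Any covariate
of the experiment — membership in a track, distance to restriction
sites, a score stratum, a sequence motif — that also influences the
annotation under test will masquerade as enrichment when controls are
uniform.  Matching the controls to the signal's distribution over that
covariate removes its contribution, in the spirit of stratified
case–control sampling.

## Matching strategies

**Stratified track covariates.**  Membership, distance and score
covariates discretize every position into a label; the joint label over
all covariates defines a stratum.  Control sites are allocated to strata
by largest-remainder (Hamilton) apportionment on the signal's stratum
counts — exact up to integer rounding, with remainder ties broken by
lexicographic stratum label so allocations are deterministic.  The
residual mismatch of any matched covariate is therefore bounded by
(number of strata)/$n$ on every stratum fraction.

Within a stratum, constraints that are plain base sets (inside/outside
a track, a score stratum, the feature-less-contig level of a distance
covariate) are intersected and sampled uniformly — no rejection needed.
A finite distance bin has no closed-form base set, so those strata are
proposed by feature-offset placement (an offset resampled from the
signal's distances in the bin, a feature and a side chosen uniformly)
and accepted only if the proposal realizes the full joint label.  The
attempt cap is 10,000 proposals per needed site; exhausting it raises
an error naming the stratum, because silently under-filling a stratum
would bias every downstream test.

**Distance matching.**  The dedicated distance matcher reproduces the
signal's empirical distance-to-feature distribution: offsets are drawn
from the signal's distance multiset (resampled with replacement, or
copied exactly in no-resample mode, in which case the control distance
multiset equals the signal's verbatim).  Each placement is verified
against the realized nearest distance — a placement that lands closer
to another feature, or outside the contig, is retried — so drawn and
realized distances agree exactly.  Distances are unsigned and measured
to the nearest covered base; sites on contigs without features carry an
infinite sentinel and are reproduced on feature-less contigs.  Which
side of a feature a control lands on is irrelevant to the
restriction-site use case, hence unsigned.

**Motif matching.**  A position frequency matrix is built from the
sequence window around each signal site (window width $2f{+}1$ for
flank $f$, or explicit; the site base sits at column
$\lfloor(w-1)/2\rfloor+1$, so a width-4 window puts the site on the
second base — the second T of a TTAA).  Column frequencies are
pseudocounted, $(c+\alpha)/(n+4\alpha)$ with $\alpha = 0.1$ by default;
bases that are N or beyond a contig edge are excluded per column.  A
control candidate's weight is the plain likelihood of its window under
the PFM (windows containing N get weight zero), and controls are drawn
with replacement from a uniform candidate pool with probability
proportional to that weight.  Likelihood rather than log-odds keeps a
zero-pseudocount PFM a hard constraint: controls then sit only in exact
motif occurrences.  A motif covariate does not stratify — a continuous
weight has no natural joint stratum — so when combined with track
covariates the stratified sample itself becomes the candidate pool; the
weighting then perturbs the exact stratum shares, which is the accepted
cost of combining both kinds.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| background size `n` | 10,000 | a common control-set size for integration-site studies; large enough that rounding error per stratum is negligible |
| distance/score bins | 10 equal-frequency | quantile bins computed on the signal keep every stratum populated regardless of the distance scale |
| PFM pseudocount α | 0.1 | keeps entries positive without washing out strong motifs; α = 0 turns the PFM into a hard constraint |
| motif pool size | max(100·n, 10⁵) | large enough that weighted resampling rarely repeats a candidate |
| rejection caps | 10,000/site | failure is loud, not silent under-filling |
| significance α | 0.05 on adjusted p | conventional |
| hotspot window / positional bin | 1 Mb | chromosome-scale summaries on mammalian-sized genomes |
| CLI seed | 42 | reproducibility by default, never wall-clock |

Every sampling operation derives its RNG stream from (seed,
operation-name), so adding a covariate to an analysis does not perturb
draws made by other operations, and identical invocations are
byte-identical.

## Coordinate and input conventions

Coordinates are 0-based half-open (BED native) everywhere.  Multi-base
signal BED records collapse to their floor midpoint — sites are treated
as points, and the midpoint is the least-biased single-base proxy; this
is a convention of this package, not a property of the data.  Strand is
ignored throughout.  Plain tracks are merged (overlaps and adjacency)
on load and clipped to contig bounds; scored tracks must be
non-overlapping, since a base with two scores is ambiguous.  Records on
contigs absent from the assembly are a hard error unless explicitly
downgraded to a logged drop — silent loss of records is the classic
genomics pitfall.  Scored BED dialects are auto-detected (5+ columns
with numeric column 5 → BED5; exactly 4 with numeric column 4 →
bedGraph) with an explicit format flag for ambiguous files.

## Degenerate inputs and numerical choices

A contingency table with a zero row or column has no association to
test: the $\chi^2$ statistic is defined as 0 with p-value 1.  No Yates
continuity correction is applied; the uncorrected statistic is the
contract verified against an independent expected-counts oracle.
Infinite distances and missing scores are excluded pairwise from KS
comparisons with a logged count.  Bonferroni's $m$ is the number of
tracks in the run — not a global library size — except in batch mode,
where the correction conservatively spans the whole matrix (rows ×
columns).  Quantile bin edges use type-1 (inverse-ECDF) quantiles, so
with distinct values every bin holds an equal share exactly;
out-of-range background values clamp into the end bins.

## What the synthetic generator emulates — and what it does not

The fixture generator produces i.i.d. random genomes with a chosen GC
fraction, annotation tracks with target coverage, k-mer occurrence
tracks (overlapping occurrences included, so EcoRI-style GAATTC and
piggyBac-style TTAA tracks are exact), and site sets drawn by rejection
sampling with per-track rate multipliers and optional hard motif
constraints.  Rejection sampling is used instead of inverse-CDF
because it is exact under arbitrary multiplier stacks and trivially
auditable.  For a single track of coverage $f$ and multiplier $r$ the
expected in-fraction has the closed form $fr/(fr+1-f)$, which the
generator records as ground truth next to every fixture so tests never
re-derive expectations from the generator's own internals.  The
confounded-pair generator emits two overlapping tracks (Jaccard ≥ 0.3)
with sites preferring only one, the canonical scenario in which
covariate matching must attenuate the induced enrichment of the other.

These fixtures have no chromatin structure, mappability gaps, copy
number, repeat families, or read-level noise.  Passing tests therefore
demonstrate correctness of the counting, testing and matching
machinery under known ground truth — not that any particular biological
conclusion on real data is right.  The test and acceptance scenarios
use a 2 Mb single-contig genome with 10,000-site signal and background
sets (50,000 controls for motif matching), sizes at which binomial
fluctuations are small relative to the tested tolerances.

## Known limitations

* Backgrounds are sampled with replacement; duplicate control sites are
  allowed, mirroring duplicate-tolerant signal multisets.
* Score matching assumes per-interval constant scores; continuous
  signal (bigWig-style) must be discretized into a scored BED first.
* Combining a motif covariate with stratified covariates biases the
  realized stratum shares toward motif-dense strata (see above).
* No FDR control is offered — Bonferroni only, matching the package's
  conservative reporting; no Fisher exact test for very small counts.
* bigBed/bigWig, GFF/VCF and remote track databases are out of scope;
  inputs are plain BED, chrom.sizes and FASTA.
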