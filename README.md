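# sitematch

Enrichment analysis of genomic position sets against annotation tracks,
with background models matched to the signal's covariates.

## The problem

High-throughput profiling produces large sets of single-base genomic
positions: virus and transposon integration sites, protein binding
sites, methylation calls.  The standard way to characterize such a set
is to ask, annotation track by annotation track, whether the sites fall
inside the annotated intervals more or less often than random control
sites do.  The catch is the choice of the control sites.  A plain
uniform background confounds every comparison with the known biases of
the experiment: a protocol that only detects integrations near EcoRI
restriction sites (GAATTC) makes every annotation that correlates with
GAATTC density look enriched, and piggyBac's strict TTAA target motif
does the same for every CpG-poor annotation.

`sitematch` builds control sets that are *matched* to the signal sites'
distribution over user-chosen covariates, so those effects cancel:

* **membership** — controls reproduce the signal's in/out fractions for
  a track;
* **distance** — controls reproduce the signal's distribution of
  distances to track features (e.g. restriction sites);
* **score** — controls reproduce the signal's distribution over the
  score strata of a scored track;
* **motif** — controls are drawn with probability proportional to the
  likelihood of their surrounding sequence under a position frequency
  matrix built from the signal.

Covariates combine: control sites are allocated across the joint strata
of all covariates in the signal's proportions (largest-remainder
apportionment, exact up to integer rounding).

## Statistics

For signal set S and background B on track T, membership counts form a
2×2 contingency table.  The package reports

* fold change `FC = (s_in/|S|) / (b_in/|B|)` and a Haldane–Anscombe
  pseudocounted `log2 FC` (0.5 added to all four counts, always finite),
* the uncorrected Pearson χ² statistic (df = 1) with its p-value,
* Bonferroni-adjusted p-values (m = number of tracks in the run),
* a two-sample Kolmogorov–Smirnov test on score distributions for
  scored tracks,

and ranks tracks by effect strength `|log2 FC|`.  Batch mode compares
several site sets against one shared background as a log2-FC matrix
with significance flags; further tools include hotspot windows,
per-chromosome positional enrichment, and a synthetic-fixture generator
(genomes, tracks, motif-constrained site sets with known ground truth).

## Worked example

```r
library(sitematch)

# synthetic scenario: 2 Mb genome, 10%-coverage track, 3x preference
g     <- gen_genome(c(chr1 = 2e6), gc = 0.5, seed = 1)
track <- gen_track(g$assembly, coverage = 0.10, mean_len = 1000,
                   seed = 2, label = "enriched")
sites <- gen_sites(g$assembly, 10000,
                   prefs = list(list(track = track, r = 3)), seed = 3)$sites

bg  <- sample_uniform(g$assembly, 10000, seed = 4)
res <- analyze(sites, bg, list(track))
res[, c("track", "s_in", "b_in", "fold_change", "log2_fc", "p_adj")]
#>      track s_in b_in fold_change  log2_fc         p_adj
#> 1 enriched 2357  943     2.49947 1.321163 8.101148e-160
```

The signal lands in the track 2357/10000 times against 943/10000 for
uniform controls — fold change 2.5, matching the analytic in-fraction
`f·r/(f·r+1−f) = 0.25` at coverage f ≈ 0.1.  Matching the background
on that track instead neutralizes it:

```r
bgm <- sample_matched(sites, covariate("membership", track = track),
                      g$assembly, n = 10000, seed = 4)
analyze(sites, bgm, list(track))$fold_change
#> [1] 1
```

The same works from the shell via the bundled CLI
(`inst/cli/sitematch`): subcommands `analyze`, `background`, `batch`,
`compare-bg`, `hotspots`, `posenrich`, `motif`, `synth`, all seeded and
byte-reproducible.

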