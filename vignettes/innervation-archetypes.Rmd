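---
title: "Innervation-density archetypes of mouse limb muscles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Innervation-density archetypes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervatlas)
```

## The problem

Retrograde tracing labels the sensory (dorsal root ganglion),
sympathetic (chain ganglion) and motor (ventral horn) neurons that
innervate an individual muscle. Counting labeled somata per muscle and
dividing by the muscle's wet weight gives an innervation *density*
(neurons per gram) that is comparable across muscles of very different
size. This package implements the downstream analysis of such a
density atlas for mouse limb muscles: clustering muscles into
innervation archetypes, relating density to muscle architecture,
relating it to the muscle transcriptome across heterogeneous public
datasets, testing gene lists for term over-representation, and
validating expression differences by relative qPCR. A bundled
reference atlas (25 muscles, three neuron classes, with companion
architecture phenotypes) provides the worked example throughout, and
seeded generators produce synthetic inputs with planted ground truth
for every stage.

## Segment vocabulary and spatial summaries

Ganglia are indexed by spinal segment in the fixed rostro-caudal order
C1–C8, T1–T13, L1–L6, S1–S4 (31 positions; mouse anatomy). Two scalar
summaries describe where a muscle's neurons of one class sit:

* the **centroid**, the proportion-weighted mean global index — lower
  is more rostral; and
* the **concentration index**, `1 - H(p)/log(n)` over the `n` occupied
  segments, where `H` is Shannon entropy: 1 for a single-segment point
  mass, 0 for a uniform spread over two or more segments,
  permutation-invariant over segments. Entropy was chosen because
  "more concentrated" needs a formula that is insensitive to which
  segments are occupied; a max-share alternative (`method =
  "max_share"`) is provided since the choice is a convention.

## Mass normalization

`normalize_density()` computes `density(muscle, class) = sum of counts
over segments / wet weight`, in neurons per gram (no unit
auto-detection; weights are grams). Muscles present in the weight
table but absent from the counts keep zero densities so the clustering
input has stable dimensions.

## Consensus clustering

`consensus_run()` follows the Monti resampling scheme. For each
candidate `k` (default 2–10) and each of `n_resamples` (default 1000)
resamples, `ceiling(p_item * n)` muscles (default 80%) are drawn
without replacement and partitioned by k-means. The consensus matrix
entry for a pair is the fraction of resamples in which the pair
co-clustered among those where both were drawn.

Design choices that the procedure's name alone does not fix:

* **Base learner.** k-means with the squared-Euclidean objective, 10
  restarts per resample, greatest-distance ("farthest point") seeding
  from a random first item. The inner loop is compiled (Rcpp) and
  draws from R's RNG stream, so a run is bit-reproducible from its
  seed.
* **No feature standardization by default.** The atlas is clustered on
  its per-gram scale; a z-score option exists (`standardize = TRUE`)
  but changes results and is off by default.
* **k selection.** The area under the empirical CDF of off-diagonal
  consensus values is computed on a fixed grid of 100 bins. With
  `A(k)` that area, the relative gain is `delta(2) = A(2)` and
  `delta(k) = (A(k) - A(k-1))/A(k-1)`; the chosen `k` is the smallest
  whose next gain drops below `tau = 0.1` — an explicit, reproducible
  form of the usual visual "where the CDF stops moving" judgement. The
  proportion of ambiguous clustering (PAC, share of entries in
  (0.1, 0.9)) is reported alongside and can be selected as the rule.
  On the bundled atlas both agree on `k = 4`.
* **Final partition.** Average-linkage agglomeration of `1 - M`, cut
  at the chosen `k`; `stats::hclust` resolves merge-height ties
  deterministically by item order.
* **Archetype naming.** A cluster below the grand mean in every class
  is "neuron-sparse muscle"; otherwise the class with the largest
  cluster-mean/grand-mean ratio names it, ties falling to the fixed
  order sensory, sympathetic, motor.
* **Cluster phenotype means** are available-case: each mean uses the
  non-missing values only and reports how many were used. This is the
  convention that reproduces the published per-cluster means, where
  one archetype's pennation mean is taken over three of four muscles.
  One published cell (the neuron-sparse cluster's mean pennation)
  divides six printed angles by five; because that denominator
  convention is ambiguous, the package does not assert that cell.

A note on CDF areas as a "stability" reading: the area equals roughly
one minus the mean consensus value, so its absolute level mixes
cluster balance with stability. It is the *relative change* across `k`
that carries the elbow signal; for a direct stability statistic at
fixed `k`, use PAC, which goes to zero as two archetypes separate.

## Correlation screens

`pearson_r()` is the sample Pearson coefficient over pairwise-complete
observations with the two-sided p-value from
`t = r*sqrt((n-2)/(1-r^2))` on `n - 2` df; at least 3 complete pairs
and non-constant vectors are required. `phenotype_screen()` crosses
the three density columns with six phenotypes; `gene_neuron_screen()`
crosses every gene's expression index with the three density columns.
Conventions:

* **Relevance** is `|r| >= 0.7` — a deliberately blunt effect-size
  rule; significance stars (`*` p < 0.05, `**` p < 0.01) are on raw
  p-values. Benjamini–Hochberg q-values are always reported alongside
  but never gate relevance, mirroring the effect-size-first reading of
  the screen.
* **Pairwise-complete deletion**, because eight of the 25 atlas
  muscles have no published mechanics beyond weight and fiber
  composition and discarding them entirely would waste the complete
  columns.
* With only seven transcriptome muscles, classes whose density
  profiles are collinear over those muscles (sympathetic and motor in
  the bundled atlas, r = 0.92) receive overlapping gene lists; the
  screen flags association, not unique attribution.

## Cross-platform expression integration

Public expression datasets for the same tissue differ in platform,
unit (FPKM vs counts) and depth; only the within-sample ordering of
genes is comparable. The integration therefore (1) intersects gene
symbols across datasets (upper-cased), (2) averages replicate columns,
(3) ranks genes by abundance within each dataset (rank 1 = most
abundant, ties averaged) and maps them to the index `1 - rank/N` in
[0, 1), and (4) merges muscles profiled by more than one dataset by
the per-gene mean of their dataset indices, recording provenance. Any
strictly increasing per-dataset distortion of abundances leaves the
index matrix unchanged — the property the tests assert exactly.
Averaging ties keeps every column's mean at `(N-1)/(2N)`; merging
after ranking (rather than pooling raw values) keeps a twice-profiled
muscle from being dominated by its deeper dataset.

## Over-representation analysis

`ora_test()` is the upper-tail hypergeometric probability
`P[X >= overlap]` for a list drawn from a background universe, which
defaults in the pipeline to the intersected transcriptome gene list —
the set of genes the screen could actually have selected. The raw
`p < 0.05` call is the default gate; BH q-values are always emitted.
An EASE-style conservative variant (overlap minus one) is available.
Term-clustering of enriched terms (as annotation servers do with kappa
statistics) is out of scope: the report ranks single terms by p-value.

## Relative quantification (2^-ddCt)

Technical replicates are averaged per (sample, gene); `dCt = Ct_target
- Ct_reference` cancels per-sample loading; `ddCt` subtracts the
control group's mean `dCt`; the fold change is `2^-ddCt`, so the
control mean maps to fold 1 by construction and any per-sample plate
offset cancels exactly. Group comparisons use the equal-variance
two-sided Student t-test on the fold scale by default (matching how
such bar plots are usually tested); a log2-scale option exists because
folds are log-normal rather than normal and the choice is not
universal.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of (config, seed); substreams are
drawn at fixed offsets so adding a stage never perturbs earlier draws.

**Atlas generator** (`simulate_muscle_atlas`). Archetype log-mean
density triples sit at a neuron-sparse baseline (1000 neurons/g, which
with milligram-scale weights yields raw totals in the tens, like real
tracing yields) plus class-elevated directions. Spacing is
`separation` within-archetype SDs, where the SD is that of the
archetype's isotropic 3-D log-scale scatter (`sqrt(3) * noise_sd`);
noise is lognormal (densities are positive and right-skewed). The
default `noise_sd = 0.1` keeps the nominal separation the dominant
determinant of raw-scale geometry; real atlas scatter is larger
(within-archetype log-SD up to ~0.9), but real between-archetype
contrasts are also far larger (10–30x), so the generator should be
read as a controlled geometry for parameter-recovery studies, not a
calibrated imitation of the published table. Wet weight falls and
pennation angle rises linearly in centered log total density
(slopes −3 and +25 with noise SD 0.2 log-units and 2 degrees), the
slow-fiber share couples weakly (+10, SD 8), and lengths/PCSA fall;
segment counts are multinomial draws from Gaussian kernels on the
global index with class-specific centers (motor most rostral, then
sensory, then sympathetic) and spreads (sympathetic tightest).

**Expression generator** (`simulate_expression`). Module genes (5% per
class) have latent abundance affine in their class's rescaled density
(amplitude 1 on the [0,1] baseline scale) plus Gaussian noise
(`noise_sd = 0.05`, the same scale as the resulting indices).
Background genes are stably expressed: constant latent level across
muscles. This is deliberate: with seven muscles, a background gene
carrying independent between-muscle variation of *any* magnitude has a
~7.6% chance of exceeding |r| = 0.7 by luck alone, which would swamp
any planted module with false calls; the planted-recovery study is
informative only if background variation stays below the rank
resolution. Consequently the recovery metrics are computed on the
positively associated lists (where modules are planted), and passing
them shows the pipeline separates signal from *rank-level* noise — it
says nothing about screens against transcriptomes whose background
genes genuinely covary with innervation. Each dataset applies its own
random strictly increasing piecewise-linear distortion (six knots)
onto an FPKM-like scale, and replicate noise (SD 0.01) is added on the
latent scale *before* the distortion: noise added after a distortion
with flat regions would shuffle ranks heavily in some muscles and not
others, creating artifactual muscle-specific signatures.

**Ct generator** (`simulate_ct`). `Ct = baseline - log2 fold +
per-sample plate offset + noise`, with the reference gene at fold 0,
so the Livak estimator inverts the construction exactly at zero noise.

## Numerical and degenerate-input conventions

* CDF areas use a fixed 100-bin grid, so the two degenerate anchors
  (all-zero consensus: area 1; all-one: area 0.01) are reproducible.
* `expression_index` accepts all-equal abundances (every index
  `1 - (N+1)/(2N)`) but a constant index profile is excluded from the
  gene screen with a recorded reason, since its correlation is
  undefined.
* Zero is a legal pennation angle and is never conflated with a
  missing value: blank cells on disk are NA in memory.
* Counts must be non-negative integers with at most one row per
  (muscle, class, segment); segment labels outside C1–S4 are parse
  errors, not warnings.
* `group_compare` returns p = 1 for two groups with equal means and
  zero variance (zero t) but refuses unequal means with zero pooled
  variance.

## Problem sizes used by the packaged studies

The bundled studies and tests use: the full 25 x 3 atlas with 500–1000
resamples for k selection (one seeded run plus a 20-seed sweep);
planted-atlas recovery over 50 seeds at 28 muscles, k in 2–8, 500
resamples; gene-module recovery over 20 seeds at 2000 genes and seven
muscles; and small-universe enumeration (background <= 12) for the
exact hypergeometric oracle. These sizes were chosen so the whole
suite runs comfortably on a laptop while keeping the Monte Carlo
margins well away from the pass thresholds.

## Known limitations

* The consensus procedure clusters a 25 x 3 matrix; with three
  features, k-means partitions are driven almost entirely by the motor
  and sympathetic axes, and small atlases make the CDF-area elbow
  noisier than the published figure suggests.
* DAVID-style functional annotation *clustering* of enriched terms is
  not reproduced; only ranked single-term ORA is.
* Probe-level microarray handling is out of scope: array datasets are
  emulated at gene level.
* The |r| >= 0.7 rule with n = 7 muscles has essentially no
  specificity against genuinely varying background genes (see above);
  conclusions at that design size rest on effect size, not error
  control.
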