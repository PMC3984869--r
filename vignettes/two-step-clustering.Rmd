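---
title: "Two-step time-series clustering: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step time-series clustering: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ttclust)
library(dplyr)
```

## The problem

Clustering whole time series by *shape* wants an elastic distance such as
dynamic time warping (DTW), which matches common trends even when they are
out of phase. But DTW over all `N(N-1)/2` pairs costs `O(N^2 n^2)` and
dominates everything else in a clustering run. The pipeline implemented here
splits the work in two:

1. **Reduction.** Group series that are already similar *in time*
   (pointwise, Euclidean) into `M` fine-grained subclusters using an
   affinity search (CAST), and summarise each subcluster by one prototype.
   This needs only the cheap Euclidean matrix.
2. **Merge.** Compute DTW only between the `M` prototypes (`M << N`),
   partition the prototypes with k-medoids into the `k` clusters sought,
   and let every series inherit the cluster of its prototype.

The expensive elastic comparisons happen `M(M-1)/2` times instead of
`N(N-1)/2`: with a reduction factor `M/N` of 0.23, roughly 95% of the DTW
work disappears. `instruction_count(N, n)` gives the instruction cost of the
full pairwise matrix this step avoids.

## Step 0: normalization

Every series is z-normalized (mean 0, standard deviation 1) so that both
distances are invariant to scale and offset. The population denominator
(`/n`) is the default; a `sample_sd` flag switches to `/(n-1)` — the two
differ only by a constant factor per series, which the normalization
cancels, so nothing downstream changes. A constant series has no scale; it
maps to all-zeros with a warning rather than an error so that degenerate
fixtures do not abort a pipeline.

## Step 1: affinity subclustering

CAST grows one subcluster at a time from a similarity matrix `A` with
entries in `[0, 1]`. The *affinity* of a series with a subcluster is its
mean similarity to the current members. A subcluster is seeded with the
unassigned series of largest similarity row-sum over the unassigned pool,
then alternates an ADD phase (admit the best unassigned candidate while its
affinity is at least the threshold `alpha`) and a REMOVE phase (expel the
worst member while its affinity is below `alpha`, re-evaluating after each
expulsion) until a full sweep changes nothing. Members' affinities at
closing time become their weights in the prototype.

Choices a user should know about:

* **Similarity conversion.** The threshold only means something once
  distances are mapped to `[0, 1]`. The default `"cor"` conversion,
  `max(0, 1 - d^2 / (2n))`, equals the Pearson correlation for z-normalized
  series, so `alpha = 0.8` reads "mean correlation at least 0.8" on any
  dataset — an absolute scale, and the scale on which the useful operating
  range of the threshold (roughly 0.7–0.9 on the bundled benchmark) lies.
  The alternative `"minmax"` (`1 - d / max(d)`) is dataset-relative: its
  scale is set by the single most distant pair, which on z-normalized
  benchmark data compresses all similarities well below 0.75 and leaves
  high thresholds producing only singletons. `"inverse"` (`1 / (1 + d)`)
  is provided for completeness.
* **Tie-breaking.** Seed choice, best-addition, and worst-removal ties all
  resolve to the lowest series index, making the subclustering a
  deterministic function of `A` and `alpha`.
* **Singletons.** A lone member's affinity is its self-similarity (1), so a
  singleton never expels itself; every series is assigned exactly once.
* **`max_sweeps`** (default 100) caps the add/remove alternation per
  subcluster. The alternation converges in a handful of sweeps in practice;
  the cap only guards against pathological similarity matrices, closing the
  subcluster as-is with a warning.
* **`alpha` vs `M`.** The subcluster count rises with the threshold
  (singletons at `alpha -> 1`, one subcluster at `alpha -> 0`).
  `find_alpha()` exploits this to hit a requested subcluster budget by
  bisection, and `ttc_cluster(target_m = ...)` exposes it.

## Prototypes

The prototype value at each time point is the affinity-weighted sum of the
members' values divided by the member count. Because weights are at most 1,
this shrinks prototypes of loose subclusters toward zero; the
`divisor = "affinity"` option divides by the total affinity mass instead,
giving a convex combination with no shrinkage. The count divisor is the
default for fidelity to the method's published form; on the bundled
benchmark the choice moves final quality by little, since the merge step
compares prototypes of similar looseness.

## Step 2: DTW + k-medoids merge

DTW here is the standard cumulative-cost dynamic program with local cost
`|x_i - y_j|`, unit moves (diagonal, down, right), and endpoints pinned to
`(1,1)` and `(n,n)`. Two options:

* `normalize_by_path = TRUE` minimises the *mean* step cost over admissible
  paths instead of the sum (an exact, path-length-indexed dynamic program,
  `O(n^3)` instead of `O(n^2)`). The sum is the default and the semantics
  used by the pipeline; the normalized form is the literal reading of the
  path-average formulation and is provided as an option.
* `window` adds a Sakoe-Chiba band for speed; no band by default, since the
  method's point is that only `M x M` DTW distances are ever computed.

k-medoids runs on the precomputed prototype DTW matrix: greedy BUILD
initialisation (deterministic) followed by alternating
nearest-medoid assignment and per-cluster medoid recomputation until a
fixed point; the objective never increases, and `init = "random"` with a
seed supports stochastic restarts. By default the pipeline weights each
prototype by its subcluster size: the weighted objective is exactly the
one-step k-medoids objective over the original series with each series
replaced by its prototype, and it stops a handful of outlier singleton
prototypes from dominating medoid selection when subcluster sizes are
skewed. Final cluster labels are inherited: a series belongs to the cluster
of its subcluster's prototype, with no post-hoc reassignment.

`k` is a user parameter, set to the number of ground-truth classes in all
reproduction experiments. If `k` exceeds the number of subclusters the fit
aborts with instructions to raise `alpha` (more subclusters) or lower `k`.

## Evaluation

With ground-truth labels available, `evaluate_clustering()` (and
`glance()` on a fit) reports:

* **Rand index** — pair-counting agreement, 1 for identical partitions;
* **conditional entropy score** — 1 minus the size-weighted normalized
  entropy of class distributions within clusters (1 when every cluster is
  pure); the entropy base cancels in the `log h` normalization, natural
  logs are used, and a single-class ground truth defines entropy 0;
* **reduction factor** `M/N` and the **majority-class error rate** of the
  subclustering — each subcluster is assigned its most frequent class (ties
  to the lowest class id) and the misclassified fraction is size-weighted.
  The error rate is 0 exactly when every subcluster is pure.

The "accuracy" reported for clustering runs is the Rand index throughout;
where the CLI writes reports it records that convention explicitly.

## The synthetic benchmark

`generate_cbf()` draws the classic three-class cylinder/bell/funnel data:
an event of amplitude `6 + N(0,1)` on a random integer support (onset
uniform on 16–32, duration uniform on 32–96, series length 128), shaped as
a boxcar, rising ramp, or falling ramp, plus unit Gaussian noise at every
point. The classes overlap heavily in time support and differ in shape,
which is exactly the regime where elastic comparison beats pointwise
comparison. The generator is bit-reproducible given a seed.

What it does *not* emulate: unequal series lengths, autocorrelated or
heteroscedastic noise, amplitude differences between classes, multiple
events per series, and class imbalance (unless configured). Passing the
bundled tests therefore demonstrates correct mechanics and the published
qualitative behaviour on this benchmark family, not performance on any
particular real dataset.

`generate_blocks()` is a second, simpler fixture — noisy copies of `k`
sinusoidal templates — whose similarity matrix is exactly block-structured
when noise is off, used to pin down CAST's boundary behaviour.

## Reproduction experiments and problem sizes

`cbf_quality_experiment()` runs the full benchmark comparison for one
generation seed: 900 series (300 per class, length 128), an affinity
threshold sweep over 0.70–0.90 with the best Rand index reported for the
two-step pipeline, and a raw-Euclidean k-medoids baseline (BUILD plus ten
seeded random restarts, best cost kept). `cbf_scaling_experiment()` checks
behaviour at larger sizes (1,000 and 2,000 series) with the threshold
chosen by bisection to yield roughly 30 subclusters. The acceptance script
(`scripts/acceptance.R`) averages the first experiment over ten seeds and
the second over five, which keeps a full run in the tens of minutes on one
core while leaving the per-seed sampling error on the Rand index near one
point.

```{r quality, eval = FALSE}
# one seed of the headline comparison (about half a minute)
run <- cbf_quality_experiment(seed = 11)
run$sweep
c(ttc = run$best_rand_index, baseline = run$baseline_rand_index)
```

Two honest limitations surface in these experiments, both visible in the
numbers the acceptance script prints rather than hidden behind defaults:

* **The reduction/error trade-off depends on dataset size.** At 900 series
  the subcluster error rate crosses 0.05 near threshold 0.76–0.78, where
  the reduction is around 65–70%; the often-quoted operating point of
  roughly 77% reduction at error 0.05 materialises on this generator at
  around 2,000 series, where same-class neighbourhoods are denser.
* **A hard subcluster budget of ~30 is too coarse for this benchmark.**
  Forcing `M ≈ 30` on 1,000–2,000 series drives the threshold to ~0.55–0.6,
  where CAST's greedy growth produces a few large mixed subclusters; their
  majority-class error (~0.2) caps any downstream merge, and the measured
  Rand index lands near 0.5–0.6 rather than 0.9. The pipeline's strong
  regime on this data keeps the error rate small (thresholds of 0.8 and
  above), at reduction factors nearer 0.3–0.5.

## Numerical and degenerate-input conventions

* Squared Euclidean distances from the Gram-matrix identity are clipped at
  0 before the square root to absorb negative float dust.
* An all-zero distance matrix (identical series) converts to an all-ones
  similarity matrix; the diagonal is always exactly 1.
* `0 log 0` is treated as 0 in entropies; `h < 2` classes define entropy 0.
* Empty k-medoids clusters (possible only with adversarial ties) keep
  their medoid rather than erroring.
* All reported partitions number clusters by ascending medoid index, so
  repeated runs are comparable label-for-label.
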