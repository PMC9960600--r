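---
title: "Multi-objective evolutionary clustering of single-cell data: methods and design"
author: "mogaclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective evolutionary clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clustering model

Given $n$ cells embedded in $d$ dimensions (by default $d = 2$, the output
of the preprocessing workflow), a clustering solution is a set of $k$
prototypes $z_1,\dots,z_k \in \mathbb{R}^d$, encoded as one flat chromosome
of length $k \times d$: positions $1..d$ are $z_1$, positions $d+1..2d$ are
$z_2$, and so on. Cells are assigned to the prototype minimizing the
Euclidean distance; ties go to the lowest prototype index so that
assignment is deterministic.

Two objectives are optimized jointly:

$$f_1 = \sum_{i=1}^{k} n_i\, d(z_i, \bar z) \quad (\text{maximize}), \qquad
  f_2 = \sum_{i=1}^{k} \sum_{x \in c_i} d(x, z_i) \quad (\text{minimize}),$$

where $n_i$ is the occupancy of cluster $i$ and $\bar z$ is the
*unweighted* mean of the $k$ prototypes (not the cell-weighted centroid —
the index describes the prototype configuration, not the data density).
$f_1$ rewards prototype configurations that are spread out *and* used:
an empty cluster contributes $n_i = 0$ and therefore nothing, so
degenerate solutions self-penalize under maximization without any repair
operator. $f_2$ is plain within-cluster dispersion; empty clusters
contribute zero. With $k = 1$, $f_1 \equiv 0$ and the problem degenerates
to compactness only.

Because the two objectives conflict, no single optimum exists; the
optimizer maintains a population and returns the Pareto front of mutually
non-dominated solutions. Solution $a$ dominates $b$ when
$f_1(a) \ge f_1(b)$, $f_2(a) \le f_2(b)$, and at least one inequality is
strict.

### Final-solution selection

Every front member is scored by the Davies–Bouldin index over its
*populated* clusters:

$$\mathrm{DBI} = \frac{1}{k'} \sum_{i} \max_{j \ne i}
  \frac{S_i + S_j}{d(z_i, z_j)}, \qquad
  S_i = \frac{1}{n_i} \sum_{x \in c_i} d(z_i, x),$$

with $S_i = 0$ for singletons. When fewer than two clusters are populated
the index is $+\infty$, so such solutions are never preferred; ties are
broken toward lower $f_2$ (the more compact solution), and if every front
member has infinite index the minimum-$f_2$ member is returned. The index
is not clamped: although often below 1 for good clusterings, the quantity
is unbounded above.

## The evolutionary engine

One generation comprises:

1. **Tournament selection.** Each tournament draws
   $\lceil 0.2 \cdot P\rceil$ distinct entrants uniformly; the winner has
   the lowest non-domination rank, then the largest crowding distance,
   with remaining ties broken uniformly at random. Tournaments repeat
   (with replacement across tournaments) until $P$ parents are drawn.
   The source material specifies "best fitness" tournaments without
   saying how two objectives are compared; rank-then-crowding is the
   standard NSGA-II comparator and is consistent with the sorting
   machinery used for survival, so that is the design adopted here.
2. **Variation.** Parents are paired consecutively; with probability 0.8
   a pair undergoes one-point crossover (cut index drawn from $[0, l)$;
   the parts strictly after the cut are exchanged, so the maximal cut
   clones the parents). Every offspring then passes through bounded
   polynomial mutation: eligible with probability 1.0 (the individual
   mutation rate), each gene mutating independently with probability 0.07
   under distribution index $\eta = 0.3$. These four values are the
   result of the grid search reported for the optimizer being
   re-implemented, taken as configuration defaults. $\eta = 0.3$ is an
   unusually small distribution index: mutations can land far from the
   parent, which keeps the search explorative.
3. **(μ+λ) survival.** Parents and offspring are merged; fast
   non-dominated sorting admits whole fronts in rank order and the
   overflowing front is truncated by descending crowding distance (ties
   broken by original index for determinism). Boundary members of a
   front carry infinite crowding and thus always survive truncation,
   which makes the best observed $f_1$ and best observed $f_2$ monotone
   across generations. The hypervolume of the rank-0 front is monotone
   as long as the front fits inside the population budget; once it
   overflows, crowding truncation may discard interior members, so only
   the conditional property is asserted by the tests.

Defaults are a population of 800 for 350 generations (the optimizer
typically converges in about 50); the tests and the acceptance protocol
use population 100 and 50 generations, which on the simulated benchmarks
below is sufficient for exact recovery at small $k$ while keeping a full
test run around two minutes.

**Determinism.** A run owns a single seeded RNG stream. Fitness
evaluation consumes no randomness, so evaluating chromosomes in parallel
(`workers > 1`) cannot perturb the stream: results are bit-identical to a
serial run, which the tests assert for 1 vs 4 workers.

### The single-objective baseline

`runSOGA()` uses the same encoding, operators and hyperparameters but a
scalar fitness — $f_2$ alone, minimized — with plain best-fitness
tournaments and no non-dominated sorting or DBI selection. Survivor
selection is not specified by the source material for the baseline; the
implementation keeps the best $P$ of the merged parent–offspring pool,
which makes the best $f_2$ monotonically non-increasing and hence
testable, and returns the fittest chromosome of the final generation.

## Preprocessing workflow

Five steps, in this order:

1. **Filtering.** Genes expressed in fewer than 3 cells; then cells with
   fewer than 200 expressed genes; then cells with mitochondrial content
   above 10% (gene ids starting `MT-`, case-insensitive, configurable —
   "mitochondrial content" has no operational definition beyond the id
   prefix convention); then cells whose total mRNA count or total
   expressed-gene count falls outside
   $10^{\,\mathrm{mean}(\log_{10} x)\pm 2\,\mathrm{sd}(\log_{10} x)}$.
   The moments are taken over the cells retained after the mito filter —
   the alternative (before) is equally defensible but has to be fixed;
   recomputing them after each removal would iterate to a fixed point,
   which no standard workflow does. Consequently the outlier step is a
   one-shot trim: re-applying the whole filter can remove a further few
   percent of cells because the survivors' spread is smaller. The
   structural steps are exactly idempotent. A $10^{-12}$ relative
   tolerance on the bounds keeps cells that sit exactly on a degenerate
   (zero-variance) bound.
2. **Highly variable genes.** The mean–variance relationship of raw
   counts is modeled by a loess trend of $\log_{10}$ variance on
   $\log_{10}$ mean (span 0.3, degree 2, positive-variance genes only);
   each gene's counts are standardized by the trend-expected sd, clipped
   at $\sqrt{n}$, and the variance of the clipped values ranks the genes.
   The top 2000 are kept. Ties are broken by gene id so that the
   selection is invariant to gene ordering. This is the "vst" convention
   of the standard single-cell toolchain, chosen because the workflow
   being mirrored names only "modeling the mean–variance relationship".
3. **Transformation.** Counts are library-size normalized to the median
   library, then `log1p`-transformed. The pseudo-count of 1 is
   zero-safe; the median target keeps values on a counts-like scale.
4. **Scaling.** Per-gene z-scoring to mean 0, variance 1 across cells;
   zero-variance genes map to zero rows.
5. **Reduction.** Exact PCA via SVD to 10 components, with the sign
   convention that each component's largest-magnitude loading is
   positive (SVD signs are otherwise arbitrary, which would break
   reproducibility). Then a pluggable 2-D reducer: the default is a
   seeded, single-threaded UMAP (15 neighbors, min_dist 0.1); the
   alternative `"pca"` simply keeps the first two components. The PCA
   fallback is exactly deterministic and permutation-equivariant, which
   the metamorphic exact-invariance tests rely on; UMAP is deterministic
   for a fixed seed and thread count but not exactly equivariant under
   input reordering.

## Cluster validity

- **Silhouette**: $s_i = (b_i - a_i)/\max(a_i, b_i)$ with $a_i$ the mean
  distance to the cell's own cluster and $b_i$ the smallest mean distance
  to another populated cluster; a cell alone in its cluster contributes
  exactly 0 (the convention for singletons), and coincident points
  ($a = b = 0$) also score 0. At least two populated clusters are
  required.
- **NMI**: $2 I(A;B)/(H(A)+H(B))$ with entropies in bits. Two
  zero-entropy partitions score 1 (they agree perfectly); exactly one
  zero-entropy partition scores 0 (it shares no information). NMI is
  base-invariant, so the bit convention only fixes intermediate values.
- **ARI**: pair-counting index from the contingency table, corrected for
  chance; 1 iff the partitions are identical up to renaming, expected 0
  under independence, *not* clamped below (worse-than-chance partitions
  can score slightly negative).
- **DBI** as above.

Each metric is verified against a literal loop-based transcription of its
definition, and silhouette/ARI additionally against independent
implementations (`cluster`, `mclust`).

## Metamorphic stability

Six perturbations with known expected effect:

| relation | action | carrier |
|---|---|---|
| MR1 | permute cell order | counts |
| MR2 | multiply one gene's counts by a factor (default 2) | counts |
| MR3 | duplicate one cell under a fresh id | counts |
| MR4 | permute gene order | counts |
| MR5 | append a constant pseudo-gene | counts |
| MR6 | negate all coordinates | embedding |

MR2's "modification" is multiplicative because that preserves integrality
and sparsity; MR6 acts on the embedding because negated raw counts are
incompatible with the log transform, whereas coordinate negation is a
Euclidean isometry under which assignment, $f_1$, $f_2$, DBI and
silhouette of any fixed labeling are provably unchanged (and tested to
be). Under the PCA fallback reducer, MR1/MR4/MR5 leave the seed-fixed
pipeline's labels exactly invariant (up to the applied permutation) — a
stronger guarantee than the statistical test.

The statistical harness runs the clusterer repeatedly (default 30 paired
repeats, run $r$ seeded `seed + r`) on original and perturbed data,
collects per-repeat silhouettes, and applies a paired t-test; a relation
is *stable* when $p > \alpha$ (default 0.05). Zero-variance paired
differences (identical distributions) are flagged degenerate with $p$
reported as 1 — under the exactly invariant combinations above this is
the expected outcome, not a failure. The original distribution is
computed once and shared across relations, which does not alter the
paired design.

## The count simulator

A deliberately reduced gamma–Poisson hierarchy in the style of the
Splatter simulator: gene base means $\sim$ Gamma(0.6, 0.3); each group
independently flags 10% of genes as differentially expressed and applies
LogNormal(1.2, 0.3) multipliers, inverted (down-regulated) with
probability 1/2; cell library sizes $\sim$ LogNormal($\ln 10^4$, 0.25);
counts are Poisson around the library-scaled, per-group normalized
profile. The gamma magnitudes are the Splatter defaults; the library
scale is a typical droplet-data order of magnitude; the DE settings (10%
of genes at a median ~3.3-fold change) were chosen once so that up to ~16
groups of 1000 cells remain separable after preprocessing — the
"strong-DE, known-truth" benchmark regime the engine is evaluated in.
Dropout, batch effects, per-gene overdispersion beyond the gamma mixing,
and mean–variance coupling of the real platform are *not* modeled:
passing benchmarks on these data demonstrates correct optimization and
recovery of planted structure, not robustness to every artifact of real
scRNA-seq chemistry. A second generator (`simulateEmbedded()`) produces
Gaussian blobs directly in embedding space for fast engine tests.

## Run-time estimation

A random-forest regressor maps (`nCells`, `k`, `cpus`, `tasksPerNode`,
`cpusPerTask`) to elapsed seconds, evaluated by mean absolute error.
Two numerical choices matter: features that never vary in the collected
logs are dropped before fitting (constant columns stall tree splits when
the per-split feature sample draws only them), and the per-split sample
is 2/3 of the remaining features rather than the regression default of
1/3, which with five features would be a single candidate. Predictions
are deterministic under the fit seed.

## Problem sizes and degenerate inputs

The acceptance protocol simulates one 1000-cell, 2000-gene dataset per
group count $k \in \{2, 4, 8, 16\}$, preprocesses with the defaults
(UMAP reducer), and runs MOGA at population 100 for 50 generations with
five seeds per dataset — about a minute end to end on one CPU. The unit
tests use smaller instances (tens to hundreds of cells, populations of
30–100) chosen to finish in a couple of minutes while still exercising
exact recovery, determinism and all oracle comparisons.

Degenerate inputs are handled explicitly rather than by error where a
convention exists: empty clusters (allowed throughout; see above),
$k = 1$ (valid; $f_1 \equiv 0$, DBI infinite, selection falls back to
$f_2$), singleton silhouettes (0), zero-variance genes (scaled to zero,
never selected as variable), zero-variance outlier bounds (no cell
removed), fewer genes than requested variable genes (keep all, warn).

## Known limitations

- Euclidean distances and hard memberships only; no fuzzy clustering.
- $k$ must be supplied (or derived via the `0.3 k_{ph}` helper from an
  external community-detection estimate, rounded half-up with a floor of
  2); the algorithm does not estimate the number of clusters.
- The UMAP path is reproducible only for a fixed seed and single-threaded
  layout; exact permutation equivariance requires the PCA fallback.
- The simulator's separability at large $k$ (32–64) depends on DE
  settings that real benchmarks pin down only loosely; behavior there is
  checked qualitatively (validity degrades as $k$ grows), not against
  fixed values.
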