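# mogaclust

Multi-objective evolutionary clustering of single-cell transcriptomes.

Identifying cell types from scRNA-seq data is usually framed as clustering,
and most tools optimize a single criterion — compactness (k-means-style) or
modularity (Louvain/Leiden community detection). But cluster analysis is
inherently multi-objective: highly compact clusters need not be well
separated, and vice versa. `mogaclust` implements a multi-objective genetic
algorithm (MOGA) that searches for *k* cluster prototypes
z<sub>1</sub>…z<sub>k</sub> in a 2-D embedding of the transcriptomes,
optimizing two conflicting objectives simultaneously:

- **separation** (maximized): f<sub>1</sub> = Σ<sub>i</sub> n<sub>i</sub> ·
  d(z<sub>i</sub>, z̄), the occupancy-weighted distance of each prototype
  from the prototype mean z̄;
- **compactness** (minimized): f<sub>2</sub> = Σ<sub>i</sub>
  Σ<sub>x∈c<sub>i</sub></sub> d(x, z<sub>i</sub>), the total distance of
  cells to their nearest prototype,

where d is the Euclidean distance and n<sub>i</sub> the size of cluster i.
Candidate solutions are real-valued chromosomes of length k×d (the
concatenated prototypes), evolved by tournament selection, one-point
crossover and bounded polynomial mutation, with NSGA-II-style fast
non-dominated sorting plus crowding distance for (μ+λ) survivor selection.
The run returns the Pareto front of non-dominated solutions; the final
clustering is the front member minimizing the Davies–Bouldin index

DBI = (1/k) Σ<sub>i</sub> max<sub>j≠i</sub> (S<sub>i</sub> + S<sub>j</sub>) /
d(z<sub>i</sub>, z<sub>j</sub>),  S<sub>i</sub> = (1/n<sub>i</sub>)
Σ<sub>x∈c<sub>i</sub></sub> d(z<sub>i</sub>, x).

The package also provides:

- the standard scRNA-seq preprocessing workflow (QC filtering, highly
  variable gene selection, log-normalization and scaling, PCA, seeded UMAP
  or deterministic PCA 2-D embedding);
- internal and external cluster-validity metrics (silhouette, NMI, ARI,
  DBI) with singleton-aware silhouette;
- a single-objective baseline GA (SOGA) optimizing compactness only;
- a metamorphic stability harness (six input perturbations MR1–MR6,
  paired-t comparison of silhouette distributions across repeated runs);
- a grouped gamma–Poisson count simulator with known cell memberships;
- a random-forest run-time estimator for budgeting large runs;
- an end-to-end pipeline (`runPipeline()`) and a thin CLI
  (`inst/cli/mogaclust`).

## Worked example

Simulate 1000 cells in 4 groups, preprocess, cluster with MOGA, and
validate against the known memberships:

```r
library(mogaclust)

sce <- simulateCounts(simulationConfig(nCells = 1000, nGenes = 2000,
                                       nGroups = 4, seed = 3))
ed  <- preprocessCounts(sce, preprocessConfig(seed = 3))
res <- runMOGA(ed, gaConfig(k = 4, populationSize = 100,
                            generations = 50, seed = 3))
validityReport(ed, res@assignment, truth = trueLabels(sce, ed),
               prototypes = prototypes(res))
```

which prints

```
ValidityReport:
   sil = 0.9325
   nmi = 1.0000
   ari = 1.0000
   dbi = 0.1012
```

A silhouette of 0.93 means cells sit much closer to their own cluster than
to any other; NMI and ARI of 1.0 mean the recovered partition is identical
to the simulated ground truth (up to label names); the low Davies–Bouldin
index (0.10) confirms tight, well-separated clusters. The cross-tabulation
of labels against truth is a perfect permutation matrix:

```
       truth
cluster Group1 Group2 Group3 Group4
      1      0    225      0      0
      2      0      0      0    216
      3    268      0      0      0
      4      0      0    234      0
```

(943 of the 1000 simulated cells survive quality filtering.)

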