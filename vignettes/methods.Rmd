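---
title: "Models and methods behind phenarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenarch)
```

`phenarch` takes a raw droplet scRNA-seq UMI matrix through quality
control, normalization, diffusion imputation, per-cell prognostic
classification, a covariance-based heterogeneity statistic, diffusion
geometry, and archetypal analysis. This vignette explains each model,
its assumptions, the parameters that matter, and the numerical choices
made where the procedure was genuinely open. Everything stated here
about behaviour on data is a property the test suite or the acceptance
script computes; nothing is an empirical claim beyond them.

## Quality control

**Knee filter.** Droplet runs produce an order of magnitude more
ambient-only barcodes than cells, at a small fraction of a cell's
library size. On the log10 total-count axis this yields a large ambient
mode and a smaller cell mode. We evaluate the empirical CDF on a
100-point grid, smooth it with a Gaussian kernel (sigma = 2 grid
steps), differentiate, and place the cutoff at the density minimum
between the main (ambient) mode and the next mode above it — the point
where the second difference of the smoothed ECDF crosses zero as the
curve turns from the ambient shoulder into the cell mode. Retention is
strict: a barcode is kept iff its total exceeds the cutoff. We
deliberately use the inter-mode valley rather than a curvature extremum
of the ECDF: the extremum sits on the flank of the ambient peak and
either keeps everything or leaks a substantial tail of ambient barcodes
into the retained set, while the valley cleanly separates the planted
mixture in our recovery tests (1000 cells at ~2000 UMIs against 10000
ambient barcodes at ~50 UMIs are recovered within 5%). Degenerate
inputs (near-constant totals, unimodal distributions) fall back to
keeping everything, with a warning.

**Complexity filter.** Barcodes whose detected-gene count falls far
below the trend of genes detected versus total counts (both logged) are
flagged: OLS residuals below −3 robust (MAD-based) standard deviations.
Two guards matter. First, the trend is fit only on barcodes passing the
knee — ambient barcodes would otherwise dominate the regression and
bend the line away from real cells. Second, a floor of 0.3 on the
log-scale shortfall (≈25% fewer genes than predicted) prevents
near-saturated libraries, where the residual spread collapses to almost
nothing, from being flagged for trivial deviations. The quantitative
rule is our operationalization of an intent ("low-complexity libraries
are removed"); it is recorded per barcode in the QC report so it can be
audited or disabled.

**Mitochondrial filter.** Cells with strictly more than 25% of
transcripts from `MT-`-prefixed genes are treated as apoptotic. The
boundary is exact: 25/100 is kept, 26/100 is removed.

**Gene filters.** Genes detected in fewer than 10 cells are removed.
Additionally, a two-Gaussian least-squares fit to the histogram of
per-gene log10 totals (50 bins, initialized at the 25th/75th
percentiles, several width initializations) identifies the upper
"expressed" mode; genes below `mu2 − 5·sd2` are removed. A fit is only
accepted when both components carry mass and the means are separated by
at least twice the summed widths — on unimodal data one component
collapses onto a shoulder of the other and the rule would otherwise cut
into the bulk, so in that case only the detection rule applies (with a
warning). The same bimodal machinery drives variable-gene selection
(`sd > mu2 − 1.5·sd2` on per-gene SDs, falling back to the top quartile).
We fit the low-expression rule on log gene totals; a rank-plot reading
of the same rule is possible but changes nothing for well-separated
modes.

## Normalization, PCA, imputation

Counts are divided by the cell total and rescaled by the median total,
so every normalized row sums to the median library size — the operation
is idempotent. PCA uses a seeded randomized SVD (range finder with
power iterations; exact SVD on small problems), after which each score
column is replaced by its OLS residual against (intercept, library
size): library size is treated as a nuisance that partially correlates
with some components. Explained-variance ratios are recorded before the
regression. The number of components is chosen at the knee of the
cumulative explained-variance curve (maximum perpendicular distance to
the chord, with the origin prepended so a dominant first component
registers), with the smallest number reaching 90% of variance as the
fallback for chord-degenerate curves.

Imputation diffuses expression over the cell graph: an adaptive
Gaussian kernel (`sigma_i` = distance to the `ka`-th neighbour, k-NN
edge set, symmetrized), row-normalized to a Markov matrix `M`, and
`Y = M^t X` applied as `t` successive sparse multiplications. Defaults
are the conservative setting `k = 27`, `ka = 12`, `t = 3` on the first
20 library-size-regressed PCs; the kernel's `ka` is shared with the
visualization/diffusion-map kernel since nothing distinguishes them in
the procedure. Row-stochasticity gives two exact invariants that the
tests assert: constant genes are preserved for every `t`, and imputed
values never leave the input column's range. No post-hoc rescaling of
imputed values to input percentiles is applied.

## Clustering and annotation

Communities are found on a Jaccard-weighted k-NN graph by seeded
Louvain modularity optimization. The neighbourhood size is chosen by a
stability scan: cluster at every k in a grid, compute all pairwise
adjusted Rand indices, and take the smallest k whose median ARI against
all larger k exceeds 0.75. The ARI heatmap has no canonical aggregation
rule; the median-versus-larger-k reading makes "stable from here
upward" precise. Note that modularity optimization on sparse k-NN
graphs of large uniform clouds fragments them (the resolution effect);
recovery tests therefore use neighbourhood sizes comparable to the
planted cluster sizes, which is also how the stability scan behaves on
real data where k is pushed upward until assignments stop changing.

Cluster annotation correlates per-cluster median imputed expression
(centered per gene across clusters) with reference bulk profiles
(centered per gene across cell types) over shared genes; p-values use
the exact t-transform of r with n−2 degrees of freedom, and only pairs
with |r| > 0.2 and p < 0.01 are flagged for display.

## Per-cell classification and bootstrap fractions

Cells are scored by the unweighted mean imputed expression of each
signature's genes and classified with a variational Bayesian Gaussian
mixture in score space — fixed component count, Dirichlet weight prior
with concentration 1/K, Gaussian-mean priors, Gamma precision priors
(diagonal and spherical modes) or a Wishart prior (tied mode), seeded
k-means initialization. No installed R package provides the variational
variant with these covariance modes, so the VB-EM updates are
implemented here and cross-checked in the tests against an EM
implementation (mclust) on well-separated fixtures. Components carry no
intrinsic identity, so after fitting they are relabeled by ascending
mean along the class-defining axis (the aggressive-signature score, by
default the last column): the top class is the high-scoring one. Scores
enter the fit unstandardized; mean-signature scores of the same imputed
matrix share a scale, and standardizing would distort the relative
weight of the two axes.

Per-patient class fractions are estimated by subsampling: 20 rounds of
500 cells per patient, fraction per class per round, mean and 2.5/97.5
percentile CI across rounds. Patients with fewer than 500 cells are
sampled with replacement to honor the fixed draw size (logged per
patient).

## Phenotypic volume

The diversity of a cell population is measured as the log
pseudo-determinant of its gene-gene covariance, normalized by the gene
count: `sum over lambda_e > tol of 0.5*log10(lambda_e^2) / d`, with the
unbiased 1/(n−1) covariance estimator. Three numerical choices: the
"nonzero" tolerance is relative (`lambda > max(lambda)·1e-10`), since an
absolute zero test is meaningless in floating point; the normalization
divides by the total gene count `d`, not the retained rank — the
distinction matters when the subsample size is below `d` and the count
of retained eigenvalues is reported alongside; and the eigenvalues are
taken from the smaller of the gene-gene covariance and the cell-cell
Gram matrix, which share their nonzero spectrum. The statistic is
computed on normalized, un-imputed expression restricted to the
variably expressed genes: diffusion imputation mixes neighbouring
cells' profiles and inflates gene-gene covariance, so imputed data
would measure the graph, not the population. Group comparisons are made
at a fixed subsample size (100 draws of 150 cells, without replacement)
because the reachable state space grows with population size.

## Diffusion geometry

The diffusion map eigendecomposes the Markov matrix through its
symmetric conjugate `D^(-1/2) A D^(-1/2)` — a route that guarantees a
real spectrum — and converts eigenvectors back to right eigenvectors of
`M`. The trivial unit eigenvalue is dropped; a second (near-)unit
eigenvalue means the graph is disconnected and is an error listing
component sizes, since diffusion distances between components are
meaningless. The embedding dimension is chosen at the largest eigengap
among the top eigenvalues, capped at 5 by default.

Distances between cells sum component differences with
eigenvalue-derived weights. The default multi-scale form weights
component `l` by `lambda_l/(1−lambda_l)`, which is the closed form of
summing the fixed-`t` diffusion distance over all walk lengths — it
avoids committing to any particular `t` and damps outlier sensitivity.
The fixed-`t` form (`lambda_l^t` weights, default `t = 3`) is provided
as an explicit mode. Both are Euclidean metrics in a weighted
eigenvector embedding, which the tests verify exhaustively on a small
fixture.

## Archetypal analysis

PCHA factorizes `X ≈ XCS` with `C` (cells × K) and `S` (K × cells)
non-negative and column-stochastic, so archetypes `Z = XᵀC` lie in the
convex hull of the data and every cell is a convex mixture of
archetypes. The optimizer alternates projected-gradient blocks on `S`
and `C` (10 sub-iterations per block, exact simplex projection,
per-block adaptive step sizes with backtracking), which makes the
objective trace non-increasing by construction. `C` is seeded by greedy
farthest-first (max-min) traversal from a seeded random start; max-min
cannot select two coincident points, which matters when many cells sit
exactly on a hull corner. The column-sum relaxation `delta` defaults to
0 (exact hull). Convergence is declared on relative objective change
below 1e-7 or an effectively exact fit; the iteration cap returns the
best iterate with a flag.

The number of archetypes is chosen at the knee of explained variance
versus K, fitted over a grid with each fit warm-started from the
previous solution plus one fresh archetype placed at the point farthest
from the current archetype set. Warm starting nests the models, so
explained variance is non-decreasing in K by construction rather than
up to optimizer noise. On planted 4-vertex simplex data (n = 2000, 1%
noise) the knee lands on K = 4 and vertices are recovered within a few
percent of the simplex diameter; both are asserted by the acceptance
checks.

Each archetype is anchored at its Euclidean-nearest cell in PC space;
its neighbourhood is the set of cells within half the multi-scale
distance to the nearest other anchor, so neighbourhoods span comparable
manifold ranges and cannot collide; every cell is also assigned to its
multi-scale-nearest anchor. Marker genes are ranked per archetype by
the mean 1-D Wasserstein-1 (earth mover's) distance between
neighbourhood expression and 100 equally sized backgrounds resampled
from the non-members, computed on imputed expression over the variably
expressed genes. The EMD is implemented as the area between empirical
CDFs (general sample sizes) and tested against the sorted-matching
closed form.

## The synthetic atlas

`simulate_atlas()` emulates exactly the structure the pipeline assumes:
tumor cells whose gene rates are Dirichlet-weighted convex combinations
of K archetypal programs; an optional minority population with private
markers; lognormal library sizes (default meanlog = log 2000, sdlog
0.35); Beta-distributed mitochondrial fractions with a designated
apoptotic subpopulation around 40%; ambient barcodes drawn from the
mean cell profile at 2.5% of a typical library; Poisson counts (an
optional negative-binomial size parameter adds overdispersion). Default
compartment sizes (1000 tumor cells, 10000 empties) mirror a typical
droplet run of a small biopsy. `simulate_simplex()` draws Dirichlet
points on a planted simplex (concentration 0.5 by default, pushing
points toward the corners so the hull is identifiable — the standard
regime for archetype benchmarks).

`simulate_two_class()` plants a low-risk/high-risk cohort. Its
`separation` parameter is a **per-gene** effect size: the rate lift
gamma is calibrated under the Poisson model so each signature gene's
normalized expression separates between classes by `separation` pooled
within-class SDs. The per-cell score (mean over the m = 10 signature
genes) then separates by `separation·sqrt(m)` score SDs — the same
noise-averaging that makes multi-gene prognostic panels far more
reliable than single markers. Consequences the tests exercise: at
separation 0 classification is at chance; at 2 and above, recovery of
planted per-patient fractions is essentially exact; at 3 (the
acceptance setting) even pure 0%/100% patients are recovered with
degenerate confidence intervals.

What the generator does *not* emulate — ambient-RNA contamination of
real cells, doublets, batch effects, gene-length or capture biases —
bounds what passing tests show: they demonstrate that each algorithm
recovers the structure it assumes, not that the assumptions hold in any
particular tissue.

## Problem sizes and determinism

The test and acceptance workloads were sized for a desk-scale run:
two-class recovery at 6 patients × 2000 cells, archetype recovery at
n = 2000 over five seeds, the end-to-end atlas at 3000 cells × 500
genes with 8000 ambient barcodes. Every stochastic step draws its seed
from a single configuration seed via a per-stage hash, and each
operation restores the caller's RNG state, so identical configurations
give byte-identical pipelines — asserted end-to-end in the suite.

## Known limitations

- Louvain's resolution behaviour makes cluster *counts* sensitive to k;
  the stability scan addresses assignment stability, not the count.
- The VB mixture reports posterior means of parameters, not full
  posterior uncertainty over K; component count is fixed by design.
- PCHA is non-convex; seeding and warm starts make it reproducible and
  empirically accurate on planted data, but global optimality is not
  guaranteed.
- The knee filter assumes a bimodal library-size distribution; nuclei
  preps or very shallow runs with merged modes trigger the degenerate
  fallback rather than a cutoff.
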