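---
title: "Distance-based cluster counting and typicality testing with incaclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based cluster counting and typicality testing with incaclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(incaclust)
```

## The problem

Unsupervised classification of genes or samples raises two questions that a
clustering algorithm by itself cannot answer. First, how many clusters does
the data actually support -- and is there any cluster structure at all?
Every partitioning algorithm returns *some* partition even on structureless
noise. Second, when a new unit arrives (a new gene expression profile, a
new tumour sample), does it belong to one of the established groups, or
does it represent a class not seen before? Discriminant-style classifiers
force the new unit into one of the known groups; detecting novelty requires
a test, not just a rule.

`incaclust` answers both questions from a **distance matrix alone**. No
coordinates, no distributional model: any dissimilarity works, which
matters for biomedical data where variables are routinely a mixture of
continuous measurements, presence/absence flags and multi-state categories,
often with missing entries.

## The geometric machinery

Let $\delta(g, g')$ be a distance between units and let $C_1, \dots, C_k$
be a partition with sizes $n_1, \dots, n_k$. Three quantities, all
computable from distances only, set the stage:

* **Geometric variability** of a group, a distance-based within-group
  variance:
  $$\hat V_\delta(C_j) = \frac{1}{2 n_j^2} \sum_{l, m}
    \delta^2\!\left(g^j_l, g^j_m\right).$$
  For Euclidean $\delta$ it equals the mean squared distance of the members
  to their centroid.

* **Squared between-group distance**, the cross-group mean squared distance
  with both variabilities removed:
  $$\hat\Delta^2_{ij} = \frac{1}{n_i n_j} \sum_{l, m}
    \delta^2\!\left(g^i_l, g^j_m\right) - \hat V_\delta(C_i)
    - \hat V_\delta(C_j).$$
  For Euclidean $\delta$ this is the squared distance between the group
  centroids.

* **Proximity function** of a unit $g_0$ to a group, the squared distance
  from $g_0$ to the group's centre:
  $$\hat\phi^2(g_0, C_j) = \frac{1}{n_j} \sum_l
    \delta^2\!\left(g_0, g^j_l\right) - \hat V_\delta(C_j).$$

The central statistic trades proximity to the clusters against the
separation between them:
$$W(g_0) = \min_{\alpha,\, \sum_i \alpha_i = 1}
  \left\{ \sum_{i=1}^k \alpha_i\, \hat\phi^2_i(g_0)
  - \sum_{i < j} \alpha_i \alpha_j\, \hat\Delta^2_{ij} \right\}.$$
Geometrically, $W(g_0)$ is the squared orthogonal **height** of $g_0$ above
the hyperplane through the cluster centres; the projections
$U_j(g_0) = \hat\phi^2_j(g_0) - W(g_0)$ measure the in-hyperplane squared
distance towards each centre. A unit close to the structure has a small
height; a unit from a novel group stands above the hyperplane.

On the affine constraint the objective is convex for Euclidean-embeddable
distances, so the minimum is the stationary point of the Lagrangian:
`inca_statistic()` solves the $(k{+}1)$-dimensional linear system
$[\hat\Delta^2 \alpha + \lambda \mathbf 1 = \hat\phi^2,\
\mathbf 1^\top \alpha = 1]$. The weights $\alpha_i$ are deliberately *not*
sign-constrained -- the hyperplane through the centres is their affine
hull, and the numeric minimiser used as an independent oracle in the test
suite explores the same set.

```{r}
pts <- rbind(c(0, 0), c(2, 0))          # two singleton clusters
inca_w(dist(pts), c(sqrt(2), sqrt(2)), c(1, 2))  # probe at (1, 1): W = 1
```

### Numerical choices

* **Singular systems.** When the solve fails, a Moore--Penrose
  pseudo-inverse is tried; if even that cannot reproduce the right-hand
  side, the configuration is degenerate (see *k $\ge$ p* below), the result
  carries `degenerate = TRUE` and $W = 0$.
* **Floors.** $W$ within $-10^{-8} \cdot \max \hat\phi^2$ of zero is
  clamped to 0 (floating-point noise). Larger negative values can be
  produced by non-Euclidean dissimilarities; they are kept and flagged
  (`negative = TRUE`) rather than hidden, and `between_group_distances()`
  warns when $\hat\Delta^2$ itself goes negative. How to treat such
  dissimilarities is the user's call; truncation would silently change the
  ordering of units.
* **$k = 1$ convention.** With a single reference group the objective
  collapses to $\alpha_1 \hat\phi^2_1$ with $\alpha_1 = 1$, so
  $W = \hat\phi^2_1$ and $U = 0$.
* **Self-inclusion.** When a scored unit belongs to a reference cluster its
  distance row is used as-is, zero self-distance included. The statistics
  are functions of `(d, labels)` only -- no unit identity is tracked. The
  one observable side effect is a knife-edge bias: on *exactly* exchangeable
  configurations (all units mutually equidistant) reference units look
  minutely closer to their own group than outside probes do, and the index
  below reaches 1 instead of 0. Any realistic jitter removes the effect
  (i.i.d. noise units give an index of 0.00--0.03), but exact symmetric
  ties are resolved in favour of the partition.

### The k $\ge$ p degeneracy

If the distance matrix embeds in a Euclidean space of dimension $p$ and
$k > p$ cluster centres affinely span that space, the centre hyperplane
*is* the space and every height is zero: $W \equiv 0$ and the test below
loses all power. This is intrinsic to the method, not an implementation
artifact. It is the reason the time-course analysis in this package uses
the Gower distance on profiles: raw 6-timepoint profiles under Euclidean
distance embed in $p = 6$ dimensions, so testing against $k = 7$ reference
classes would be blind, while the Gower distance embeds generic $n$-unit
data in up to $n - 1$ dimensions and keeps the heights informative. Any
profile-shape dissimilarity with a high embedding dimension serves the same
purpose.

## Counting clusters: the INCA index

For a candidate partition, fix cluster $C_j$ and compute the height
$W_{C_j}(g)$ of *every* unit with respect to the remaining clusters
$\{C_i : i \ne j\}$. Members of $C_j$ should stand high above that
hyperplane; units of the other clusters should sit near it. With
$\bar W_{C_j}$ the maximum height among units outside $C_j$, a member
$g \in C_j$ is **well classified** when $W_{C_j}(g) > \bar W_{C_j}$
(strictly -- a unit exactly at the cutoff is not credited), and
$$INCA_k = \frac{1}{k} \sum_{j=1}^k \frac{N_j}{n_j}$$
is the average fraction of well-classified members. Values near 1 support
the partition; low flat curves over $k$ mean no structure. For $k = 2$ the
reduced reference has a single cluster and the height collapses to the
proximity $\hat\phi^2$.

`inca_curve()` scans $k = 2, \dots, K$ with partitions from PAM or
agglomerative linkage (both delegated to the `cluster` package, whose
`pam()` and `agnes()` are the implementations practitioners use; `"ward"`
is `agnes`' Ward criterion), or with user-supplied partitions.

```{r}
sim <- simulate_modules(n_samples = 60, module_sizes = c(40, 30, 30), seed = 4)
d <- dist(t(sim$values))
curve <- inca_curve(d, K = 6, method = "pam")
round(curve$index_all, 3)
estimate_k(curve)
```

### Reading the curve

`estimate_k()` declares **no structure** when the whole curve stays below
`structure_threshold` (default 0.2 -- one unit in five well classified is
indistinguishable from background; the value is configurable and the curve
itself is always returned for inspection). Otherwise it looks for the
decisive fall of the index. The obvious rule -- the $k$ with the largest
drop $INCA_k - INCA_{k+1}$ -- misreads bumpy curves: incidental descents in
the low tail can out-drop the true fall. The implemented rule therefore
evaluates drops at $k$ that the curve *rose into* ($INCA_k \ge
INCA_{k-1}$) and whose index clears the structure threshold; when the curve
is monotonically falling (no rises at all), every positive drop from a
value above the threshold competes, and the first maximal drop wins. On
clean, well-separated data the index stays high for every coarsening of
the true partition (merging two clean clusters still classifies well), so
the curve typically saturates up to the true $k$ and collapses beyond it.

### Noise units

A handful of stray units can hide an otherwise clear structure: linkage
methods isolate them into tiny clusters, and the index stays low for every
$k$. With `L` set, any unit falling into a cluster of size $\le L$ in
*any* of the scanned partitions is flagged as a noise unit, the remaining
units are re-clustered, and a second curve is reported. The "any
partition" reading is the inclusive interpretation of the small-cluster
rule; with `L = "custom"` the user supplies the flags directly. Flagging
is a screen, not a verdict -- diffuse noise that never isolates into tiny
clusters is not caught, and the denoised curve should be read with the
same care as the original.

## The typicality test

Is a new unit $g_0$ typical of the partition? Its height $W(g_0)$ is
compared against the empirical null distribution obtained by resampling:
draw `np` units with replacement from the pooled reference units, look up
their heights, and compute the empirical p-value
$p = \#\{W_b \ge W(g_0)\}/np$; a repetition rejects when $p < \alpha$.
The whole procedure runs $10 P$ times and `pct_under_alpha` reports the
percentage of rejecting repetitions. The verdict is **atypical** when at
least half the repetitions reject (the 50% cutoff is a reporting
convention, configurable via `atypical_threshold`; both the percentage and
the verdict are returned so any rule can be applied downstream). A typical
unit is allocated to the cluster with the smallest projection $U_j$, ties
to the lowest cluster index.

Two details are deliberate. The plain proportion $\#/np$ is the default
p-value estimator, with the positively biased $(1+\#)/(np+1)$ available as
an option. And the resampling pool is all $n$ reference units, including
any unit identical to the probe: with `np` of the order of $n$ or larger
the probe's own height is then almost surely in the null sample, so a unit
duplicating a reference unit can never be rejected with full confidence --
the conservative behaviour one wants from a typicality test.

Reproducibility: with a `seed`, repetition $r$ draws from a substream
derived from `(seed, r)`, so results are bit-identical across runs and
independent of how many repetitions precede.

```{r}
probe <- which(sim$labels == 2)[1]
dmat <- as.matrix(d)
inca_test(dmat, sim$labels, dmat[, probe], np = 500, seed = 9)
```

## Distances for mixed data

Four constructors cover the common cases; any precomputed dissimilarity is
accepted everywhere else.

* `dist_gower()` -- mixed continuous / binary / qualitative variables with
  missing values, via Gower's similarity
  $s_{ij}$ and $d_{ij} = \sqrt{2(1 - s_{ij})}$ (the square-root transform
  keeps the distance Euclidean-embeddable, hence the heights
  non-negative). Terms involving a missing value drop out of numerator and
  denominator alike, so incomplete records stay comparable; a pair sharing
  no observed variable is an error, not a guess. A constant continuous
  variable contributes a full match -- the limit of $1 - |\Delta x|/R$ as
  $R \to 0$ for identical values. Binary variables code 1 = presence;
  absence--absence matches drop from the denominator, the classic
  asymmetric treatment.
* `dist_bhattacharyya()` -- frequency profiles,
  $d = \arccos \sum_l \sqrt{p_{il} p_{jl}}$, the spherical angle between
  square-root profiles.
* `dist_mahalanobis()` -- pairwise Mahalanobis distances under the pooled
  covariance, with a pseudo-inverse (eigenvalue cutoff $10^{-10}
  \lambda_{\max}$) for singular covariances, so collinear variables are
  projected out instead of crashing the computation.
* `dist_correlation()` -- $\sqrt{2(1 - r)}$ between unit profiles by
  default. The simpler $1 - r$ is available as an option, but it is not
  Euclidean-embeddable and can produce (flagged) negative heights; the
  square-root form is the default for exactly that reason.

## What the simulators emulate -- and what they do not

The generators exist so that every statistic has a testable input of known
structure, without any external download.

`simulate_modules()` emulates module-structured expression data: one
latent standard-normal profile per module across samples, member genes
$r \cdot \text{profile} + \sqrt{1 - r^2} \cdot \text{noise}$ with $r$
uniform in `[cor_lo, cor_hi]`, positive correlations only (the signed
coexpression convention), plus unstructured noise genes. The defaults
`cor_lo = 0.5`, `cor_hi = 0.9` span typical hub-to-peripheral membership
correlations and produce well-separated modules (the index at a true
three-module partition sits above 0.9); widening the range down to
$r \approx 0.3$ drowns the weakest members in noise and is a useful stress
test, but not a useful default. What the generator does *not* reproduce:
gene-gene correlations beyond the shared latent profile, mean/variance
heterogeneity, heavy tails, batch structure -- a test passing on this
generator says the statistics behave as designed, not that any particular
real data set has three modules.

`simulate_time_course()` draws 6-timepoint profiles around eight fixed
class templates (`time_course_templates()`): constant (G1), shallow
monotone rise (G2, deliberately adjacent to G1 -- separating them is meant
to be hard), flat-then-rising (G3), peaked at timepoint 2 (G4), peaked at
5 (G5), dipped at 3 (G6), cyclic with a peak at 2 and dip at 5 (G7), and a
dip at 2 followed by a plateau (G8), with i.i.d. Gaussian noise per
timepoint. The default `noise_sd = 0.1` is calibrated so that constant
profiles tested against the seven other classes are unambiguously novel
(15/15 across probe seeds in the test suite) while G1/G2 remain adjacent;
at `noise_sd` around 0.2 the G1-vs-rest decision starts to blur, which is
itself a useful regime for power studies.

`simplex_fixture()` is the analytic oracle: clusters at the vertices of a
regular simplex and a probe at a known orthogonal height $h$, so the exact
statistic $W = h^2$ is known in closed form at zero spread, and the
$k = \dim + 1$ case realises the degeneracy exactly.

## Problem sizes and reproducibility

The test suite validates the solver against a brute-force constrained
minimiser on hundreds of random small instances ($k \le 4$, points in
$\mathbb R^3$), checks the bootstrap's per-repetition rejection rate over
150 leave-one-out probes (within three Monte-Carlo standard errors of the
nominal level), and exercises the full pipeline on simulations of 60--120
units; `scripts/acceptance.R` reruns the headline analyses at the sizes of
the worked examples (1080--1200 genes, 100 samples). These sizes make the
whole suite run in seconds while leaving the statistics' sampling noise
well below the assertion tolerances. All randomness flows from explicit
seeds.

## Known limitations

* The index compares members against the **maximum** outsider height, an
  extreme statistic: a single aberrant outsider suppresses a cluster's
  count. This is faithful to the definition, but it makes the index
  sensitive to heavy-tailed noise -- the noise-unit screen exists for
  precisely that reason.
* On clean data the index saturates for every $k$ up to the true one and
  occasionally lingers for refinements of true clusters; the drop rule can
  then be knife-edged between candidates (the curve, not just the
  estimate, should be inspected). Partition-based back-ends (PAM) produce
  sharper peaks than linkage methods in this regime because they re-mix
  clusters rather than refine them.
* The typicality test inherits the resolution of the empirical null: with
  `np` draws, p-values below $1/np$ are unreachable, so `np` should be at
  least an order of magnitude above $1/\alpha$.
* For $k$ near the embedding dimension the heights collapse (see the
  degeneracy above); with few variables and many clusters, choose a
  dissimilarity with a higher embedding dimension.
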