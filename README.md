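# incaclust

Distance-based answers to the two questions clustering algorithms cannot
answer by themselves:

1. **How many clusters does the data support — if any?** Every algorithm
   returns a partition, even on pure noise; `incaclust` scores candidate
   partitions and can declare that *no* cluster structure exists.
2. **Is a new unit typical of the known groups, or does it come from a
   novel one?** Discriminant-style rules force every new unit into an
   existing group; `incaclust` tests novelty first and allocates only the
   typical units.

Everything runs on a dissimilarity matrix alone, so mixed continuous /
binary / qualitative variables (with missing values), correlation-based
profile distances, or any user-supplied dissimilarity are all first-class
inputs — the situation routinely faced with gene expression and clinical
data.

## The statistic

For a partition $C_1,\dots,C_k$ of $n$ units with distance
$\delta(g, g')$, three distance-only quantities are built: the geometric
variability (a distance-based within-group variance)

$$\hat V_\delta(C_j) = \frac{1}{2 n_j^2} \sum_{l,m} \delta^2(g^j_l, g^j_m),$$

the squared between-group distance
$\hat\Delta^2_{ij} = \tfrac{1}{n_i n_j}\sum_{l,m}\delta^2(g^i_l, g^j_m) -
\hat V_\delta(C_i) - \hat V_\delta(C_j)$, and the proximity of a unit to
a group, $\hat\phi^2(g_0, C_j) = \tfrac{1}{n_j}\sum_l \delta^2(g_0, g^j_l)
- \hat V_\delta(C_j)$. The central statistic

$$W(g_0) \;=\; \min_{\alpha,\ \sum_i \alpha_i = 1}
\Big\{ \textstyle\sum_i \alpha_i \hat\phi^2_i(g_0)
- \sum_{i<j} \alpha_i\alpha_j \hat\Delta^2_{ij} \Big\}$$

is the squared orthogonal **height** of $g_0$ above the hyperplane through
the cluster centres. Members of a real cluster stand high above the
hyperplane of the *other* clusters; units from a novel group stand high
above all of them. From this one quantity the package derives:

* the **index** $INCA_k = \frac1k \sum_j N_j / n_j$ (fraction of members
  whose height strictly exceeds every outsider's) — `inca_index()`,
  scanned over $k$ with PAM / agglomerative back-ends by `inca_curve()`,
  read by `estimate_k()`, with small-cluster **noise-unit screening**;
* the **bootstrap typicality test** — `inca_test()` compares $W(g_0)$
  against resampled reference heights over $10P$ repetitions and, for
  typical units, allocates to the cluster with the smallest projection
  $U_j = \hat\phi^2_j - W$;
* the distance constructors `dist_gower()` (mixed variables, missing
  values), `dist_bhattacharyya()`, `dist_mahalanobis()` (pairwise, pooled
  covariance, pseudo-inverse), `dist_correlation()`;
* simulators for module-structured expression data and 6-timepoint
  time-course profiles — `simulate_modules()`, `simulate_time_course()`,
  `simplex_fixture()`.

## Worked example

Sixty samples, three simulated coexpression modules of 40/30/30 genes,
Euclidean distance between gene profiles:

```r
library(incaclust)
sim <- simulate_modules(n_samples = 60, module_sizes = c(40, 30, 30), seed = 4)
d <- dist(t(sim$values))

inca_index(as.matrix(d), sim$labels)
#> INCA index for a partition into 3 clusters
#>  cluster size well_classified percent
#>        1   40              40  100.00
#>        2   30              30  100.00
#>        3   30              28   93.33
#> Total well classified (INCA index): 97.78%
```

97.8% of genes sit further from the hyperplane of the other modules than
any outside gene does — the partition is strongly supported. Scanning k
confirms three clusters:

```r
curve <- inca_curve(d, K = 6, method = "pam")
round(curve$index_all, 3)
#> [1] 0.833 0.978 0.530 0.413 0.356
estimate_k(curve)
#> Estimated number of clusters: k = 3
```

The index peaks at k = 3 and collapses beyond it; the decision rule picks
the k before the decisive fall. A member gene tested for typicality is
never rejected and is allocated to its home module; a probe equidistant
(and far) from everything is flagged as a novel group:

```r
dmat <- as.matrix(d)
probe <- which(sim$labels == 2)[1]
inca_test(dmat, sim$labels, dmat[, probe], np = 500, seed = 9)
#> INCA test
#> INCA statistic value = 30.38775
#> U projections values:
#> U1 = 72.12891
#> U2 = 1.598396
#> U3 = 87.07939
#> significative tests for alpha= 0.05: 0 (of 10 repetitions, 0%)
#> Verdict: typical; allocated to cluster 2

inca_test(dmat, sim$labels, rep(50, ncol(dmat)), np = 500, seed = 9)
#> INCA test
#> INCA statistic value = 2451.502
#> ...
#> significative tests for alpha= 0.05: 10 (of 10 repetitions, 100%)
#> Verdict: atypical (candidate for a new cluster)
```

The small `U2` in the first test is the in-hyperplane squared distance to
module 2 — the probe's home. The methods vignette
(`vignettes/inca-methodology.Rmd`) documents the model, the numerical
choices and the known limitations (notably the $k \ge p$ degeneracy: with
as many clusters as embedding dimensions, all heights vanish).

## Command line

A thin wrapper is installed as `exec/inca`:

```sh
inca simulate --generator timecourse --seed 3 --out-dir run/
inca dist     --data run/timecourse_values.csv --distance gower --out-dir run/ --out D.csv
inca numclu   --dist run/D.csv --K 10 --method pam --out-dir run/
inca test     --dist run/D.csv --partition run/timecourse_labels.csv \
              --d-test probe.csv --np 1000 --alpha 0.05 --out-dir run/
```

Each run writes its results and a JSON provenance record (configuration,
package version, seed) to the output directory.

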