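---
title: "Network-based structural validation of ordinal questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based structural validation of ordinal questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multidimensional self-report questionnaires (the motivating case is the
Eating Disorder Inventory 3: 91 items on a 0--4 Likert scale, 12 subscales,
6 composite scores) are conventionally validated with latent factor models,
which assume that items are locally independent indicators of underlying
factors. Network psychometrics takes the complementary view: items are
mutually interacting components, and a dimension is a densely connected set
of items in an estimated conditional-association network. Under that view,
structural validation asks three questions:

1. **Redundancy** -- are any items near-duplicates that should be merged
   before the network is interpreted? (A redundant pair violates the
   "unique causal component" reading of a node and distorts centrality.)
2. **Dimensionality** -- do the topological communities of the network
   reproduce the questionnaire's subscales or composite scores, and how
   stable are they under resampling?
3. **Importance** -- which items are most central, and does centrality
   replicate across clinically defined cohorts?

`netpsy` implements this pipeline end to end for ordinal response matrices,
with a synthetic-data generator so every stage is testable without any
clinical download.

## Correlation layer

Likert codes 0--4 are ordinal, so the default association measure is the
**two-step polychoric correlation**: thresholds are set to inverse-normal
cumulative marginal proportions, then each pair's $\rho$ maximizes the
bivariate-normal likelihood of the observed contingency table (Brent search
on $[-0.999, 0.999]$; the bivariate normal CDF uses Gauss--Legendre
quadrature on the Drezner--Wesolowsky single-integral form, accurate to
about $10^{-15}$). Pearson correlations are available as a config option
(`method = "pearson"`), and every downstream object records which was used,
because the choice is a genuine degree of freedom when reproducing ordinal
network analyses. The pairwise matrix is smoothed to the nearest
positive-semidefinite correlation matrix (eigenvalues clipped at $10^{-8}$,
rescaled to unit diagonal) before model fitting.

Two-step rather than full-ML estimation is a deliberate trade: at the
sample sizes where network estimation is sensible ($n \ge 500$) the
efficiency loss is negligible, and the two-step estimator is fast enough to
sit inside a bootstrap.

## Network estimation

The network is a regularized partial-correlation network: a Gaussian
graphical model estimated by the **graphical lasso**, maximizing

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \ne j} |\theta_{ij}|$$

by blockwise coordinate descent (note the diagonal is *not* penalized).
Model selection minimizes the **extended BIC**

$$\mathrm{EBIC}_\gamma = -n\left[\log\det\Theta - \mathrm{tr}(S\Theta)\right] + E\log n + 4E\gamma\log p$$

over a log-spaced grid of 100 penalties from $\lambda_{\max}$ (the largest
absolute off-diagonal correlation, the smallest penalty that empties the
graph) down to $0.01\,\lambda_{\max}$, with $\gamma = 0.5$ -- the
conservative convention of psychometric GLASSO tooling. Edge weights are
partial correlations $\rho_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$.

Numerical contract: convergence when the largest elementwise change of the
working covariance in a sweep falls below $10^{-6}$, at most 10,000 sweeps,
entries below $10^{-10}$ treated as structural zeros when counting $E$. The
solver is verified in the test suite against an independent
proximal-gradient optimizer of the same objective (agreement to about
$10^{-6}$ across random problems).

One caveat discovered during that verification: the edge count along the
penalty path is *not* strictly monotone. A borderline edge can genuinely
enter and then leave the active set as $\lambda$ decreases (both solvers
agree on this), so the monotonicity property is asserted only up to
single-edge fluctuations.

## Redundancy analysis (UVA)

Unique Variable Analysis scores each pair by the **weighted topological
overlap** of the estimated network,

$$\omega_{ij} = \frac{\sum_u |w_{iu}||w_{ju}| + |w_{ij}|}{\min(k_i, k_j) + 1 - |w_{ij}|}, \qquad k_i = \sum_u |w_{iu}|,$$

which combines the direct edge with shared-neighbor connectivity and equals
1 for fully overlapping neighborhoods. Nonzero overlaps are given
upper-tail p-values under a fitted null family -- gamma by method of
moments by default (positive-supported and flexible; lognormal and
empirical are config options) -- and compared against an **adaptive alpha**

$$\alpha_{\mathrm{adapt}} = \alpha\,\frac{\sqrt{n_{\mathrm{ref}}(\log n_{\mathrm{ref}} + q)}}{\sqrt{n(\log n + q)}},
\qquad q = \chi^2_{1,\,1-\alpha},$$

which equals the base $\alpha = 0.05$ at $n_{\mathrm{ref}} = 10$ tests and
shrinks as the number of tested pairs grows.

Significant pairs form chains (connected components). Within a chain the
*target* is the item with the largest summed overlap (the most redundant
hub -- the rule is our choice; nothing in the construct dictates it), and
the merge set is the target plus its direct neighbors plus any member of a
clique containing the target; remaining chain members wait for the next
round. Merging fits a one-factor model per set and replaces the sources
with the regression-method factor score (sets of two items use the
equal-loading closed form, since a 2-indicator one-factor model is
under-identified; Heywood cases fall back to the mean score with a
warning). Composites are named by underscore-joined sources (`"72_81"`),
and rounds repeat until nothing is significant (at most 10). Composites
are continuous, so rounds after the first correlate with Pearson.

## Dimension analysis

Communities are found by the **spinglass** algorithm for signed weighted
networks (igraph's negative-weight implementation), which minimizes the
signed Potts Hamiltonian

$$H(\sigma) = -\sum_{i<j}\left(w^+_{ij} - \gamma^+ p^+_{ij}\right)\delta(\sigma_i,\sigma_j)
 + \sum_{i<j}\left(w^-_{ij} - \gamma^- p^-_{ij}\right)\delta(\sigma_i,\sigma_j)$$

with configuration-model null expectations
$p^\pm_{ij} = k^\pm_i k^\pm_j / 2m^\pm$ on the positive and negative
subgraphs, $\gamma^+ = \gamma^- = 1$, 25 spins, annealing from temperature
1 to 0.01 with cooling factor 0.99. The optimizer is stochastic, so the
pipeline runs 10 seeded restarts (config) and keeps the lowest-energy
solution; the package evaluates $H$ itself, which also allows the test
suite to compare annealed solutions against exhaustive enumeration on small
graphs. Isolated nodes get singleton communities (the null model is
undefined at degree zero) and disconnected blocks are partitioned
separately.

Partition agreement uses **NMI** with arithmetic normalization
$2I/(H_1 + H_2)$ and **AMI** $(I - E[I])/(\bar H - E[I])$ with the exact
hypergeometric expected mutual information. Arithmetic normalization is the
dominant convention but not the only one; if a reproduction attempt with
external partitions disagrees systematically, max- and sqrt-normalizations
are the first things to try. Two all-in-one-cluster partitions compare as
identical (value 1).

## Bootstrap stability

`bootstrap_ega()` replicates correlate--estimate--partition over $B$
nonparametric row resamples (child seed = seed + replicate index;
degenerate resamples are redrawn deterministically and counted, with a hard
failure above 10%). From the ensemble:

- the **median network** takes elementwise medians of the replicate
  partial-correlation matrices;
- **item stability** aligns every replicate partition to the empirical one
  by maximum-overlap assignment (Hungarian method on the contingency table
  -- stability is undefined without alignment, and assignment is the
  standard choice; surplus replicate labels stay fresh) and reports the
  proportion of replicates in which each item keeps its empirical label;
- **structural consistency** is exact-set recovery: the proportion of
  replicates in which a dimension's item set recurs as one community
  (a `min_share` option relaxes it, e.g. to 90% of members);
- the **community-count distribution** reports mode, median, mean, sd and
  a 95% normal-approximation interval $\bar k \pm 1.96\,\mathrm{sd}$. The
  normal approximation (rather than order statistics) is used deliberately:
  replicate counts are integers concentrated on two or three values, so
  quantile intervals collapse to integers and hide dispersion.

`case_drop_stability()` implements the correlation-stability coefficient
for centrality metrics: the largest case-drop fraction at which at least
95% of subsample--full Spearman correlations stay at or above 0.7.

## Node metrics

Raw **network loadings** $NL_{ic} = \sum_{j \in c} |w_{ij}|$ decompose node
strength exactly ($\sum_c NL_{ic} = s_i$, a test invariant); each column is
standardized by $\sqrt{\sum_{j\in c} NL_{jc}}$, the network analogue of a
factor loading. Absolute weights are the default (signs are reported
separately via expected influence); a signed variant is a config flag, and
the standardization constant is recorded in the object because loading
conventions vary. **Strength** is $s_i = \sum_j |w_{ij}|$; **expected
influence** keeps signs, $EI^{(1)}_i = \sum_j w_{ij}$ and
$EI^{(2)}_i = EI^{(1)}_i + \sum_j w_{ij}\,EI^{(1)}_j$ (the standard
two-step form). Top/bottom-$k$ rankings break ties by item id so reports
are deterministic.

`subscale_agreement()` compares a partition with an item key: each subscale
is matched to the community holding the plurality of its items (Jaccard
similarity breaks ties), and the table reports matched subscales, missing
items, foreign items, and the composite score the matched subscales belong
to -- the layout validation papers tabulate. Items the key leaves unscored
are listed separately.

## The synthetic generator

`synth_spec()` + `generate_factor_data()` draw latent rows from
$N(0, \Lambda\Phi\Lambda^\top + \Theta)$ with unit total variance per item
and cut them at thresholds $(-1.5, -0.5, 0.5, 1.5)$ into five categories --
a unimodal, symmetric Likert distribution. Defaults (4 factors $\times$ 5
items, main loading 0.7, factor correlation 0.2, $n = 1000$) describe a
moderately strong, realistically correlated multidimensional scale: 0.7 is
a conventionally "good" standardized loading, and 0.2 keeps factors
related but separable. `inject_redundancy()` plants near-duplicates by
re-discretizing a source item's latent value plus Gaussian noise;
`generate_cohorts()` regenerates with a modified $\Lambda$ (an item
swapped to another factor) to emulate cohort-specific item migration.

What the generator does *not* emulate: real marginal skew (clinical Likert
items are often heavily skewed), non-normal latents, method factors,
reverse-keyed wording effects, or local dependence beyond the planted
clones. Passing the recovery suites therefore shows the pipeline is
correct and well-calibrated on its own model; it does not by itself
guarantee behavior on skewed clinical data, which is why the correlation
method and null-family choices stay configurable.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the pipeline at desk
scale, chosen so the full suite completes in a couple of minutes: oracle
checks at $p \le 4$ over 50 random problems; dimension recovery at
$4\times5$ items, $n = 1000$, 10 seeds, one $B = 100$ bootstrap;
redundancy recovery at $n = 500$ over 20 seeds; determinism on a
$3\times4$, $n = 400$ run with $B = 5$. A full 91-item, $B = 500$
validation of a real dataset is an hours-scale computation and is run
through `run_validation()` / the CLI, not the test suite.

## Known limitations

- Spinglass is stochastic; identical results require identical seeds *and*
  restart counts. Best-of-restarts stabilizes but does not guarantee the
  global optimum on large graphs.
- The polychoric layer assumes an underlying bivariate normal per pair;
  gross violations (strong floor effects) bias $\rho$ upward or downward
  and propagate to the network.
- Overlapping communities are out of scope: every item gets exactly one
  label, so genuinely multidimensional items surface only indirectly, as
  low item stability split across two dimensions.
- EBIC with $\gamma = 0.5$ is conservative; on small samples it can prune
  real cross-dimension edges, inflating apparent structural consistency.
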