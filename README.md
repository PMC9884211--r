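# netpsy

Network-based structural validation of ordinal psychometric
questionnaires, for psychometricians and clinical researchers who want to
complement factor-analytic validation with the network view: items as
mutually interacting components, dimensions as topological communities of
a conditional-association network.

Given a respondent × item matrix of Likert responses (the motivating
instrument is the Eating Disorder Inventory 3: 91 items coded 0–4, 12
subscales, 6 composite scores), the pipeline runs:

1. **Redundancy analysis (UVA)** — weighted topological overlap
   ω<sub>ij</sub> = (Σ<sub>u</sub>|w<sub>iu</sub>||w<sub>ju</sub>| + |w<sub>ij</sub>|) / (min(k<sub>i</sub>,k<sub>j</sub>) + 1 − |w<sub>ij</sub>|)
   on an estimated network, upper-tail p-values from a fitted null
   (gamma by method of moments), an adaptive significance threshold, and
   chain/clique-guided merging of redundant items into one-factor
   composite scores.
2. **Network estimation** — Gaussian graphical model with lasso penalty
   (GLASSO, off-diagonal penalty only) on polychoric (default) or Pearson
   correlations; penalty selected by the extended BIC
   (−n·loglik + E·log n + 4Eγ·log p, γ = 0.5) over a 100-point log-spaced
   λ grid; edges are partial correlations
   ρ<sub>ij</sub> = −θ<sub>ij</sub>/√(θ<sub>ii</sub>θ<sub>jj</sub>).
3. **Dimension analysis** — spinglass community detection for signed
   weighted networks (Potts Hamiltonian with configuration nulls on the
   positive/negative subgraphs, simulated annealing, best of seeded
   restarts), compared against the questionnaire's subscale/composite key.
4. **Bootstrap EGA** — the estimate-and-partition pipeline replicated
   over row resamples: median network, per-item stability, per-dimension
   structural consistency, community-count distribution.
5. **Node metrics and cohort comparison** — strength, one/two-step
   expected influence, standardized network loadings; cross-cohort
   partition agreement via normalized and adjusted mutual information on
   the original item set.

A seeded synthetic generator (multi-factor ordinal data with planted
communities, redundant clones, and cohort-specific item migration) makes
every stage testable offline.

## Worked example

```r
library(netpsy)

spec <- synth_spec(n_respondents = 800, n_factors = 3, items_per_factor = 5,
                   loading = 0.7, factor_corr = 0.2, seed = 42)
sim  <- generate_factor_data(spec)
data <- inject_redundancy(sim$data, c("4" = 0.15), seed = 43)  # plant a near-duplicate

red <- run_uva(data)                       # detect + merge redundant items
uva_merge_table(red$report)
#> # A tibble: 1 × 3
#>   composite sources n_sources
#>   <chr>     <chr>       <int>
#> 1 4_4r      4, 4r           2

net <- network_from_data(red$data)         # polychoric + GLASSO + EBIC
glance(net)
#> # A tibble: 1 × 7
#>   n_nodes n_edges density lambda gamma     n correlation
#>     <int>   <int>   <dbl>  <dbl> <dbl> <int> <chr>
#> 1      15      65   0.619 0.0327   0.5   800 polychoric

part <- spinglass_partition(net, seed = 1) # signed communities, best of 10 restarts
glance(part)
#> # A tibble: 1 × 5
#>   n_nodes n_communities energy method     seed
#>     <int>         <int>  <dbl> <chr>     <dbl>
#> 1      15             3  -3.96 spinglass      1

expanded <- expand_partition(part, red$report$merge_map)
planted  <- sim$partition$assignment
nmi(expanded$assignment[names(planted)], planted)
#> [1] 1

ens <- bootstrap_ega(red$data, B = 50, seed = 2, spinglass = list(restarts = 2))
glance(ens)
#> # A tibble: 1 × 9
#>       B n_items n_redrawn  mode median  mean    sd ci95_low ci95_high
#>   <dbl>   <int>     <int> <int>  <dbl> <dbl> <dbl>    <dbl>     <dbl>
#> 1    50      15         0     3      3     3     0        3         3

head(dplyr::arrange(centrality_table(median_network(ens)), -strength), 3)
#> # A tibble: 3 × 7
#>   item  strength   ei1   ei2 rank_strength rank_ei1 rank_ei2
#>   <chr>    <dbl> <dbl> <dbl>         <int>    <int>    <int>
#> 1 9        0.873 0.873  1.50             1        1        1
#> 2 2        0.793 0.793  1.35             2        2        2
#> 3 11       0.782 0.782  1.35             3        3        3
```

Reading the output: the planted clone `4r` is the only merge (`4_4r`); the
EBIC-selected network keeps 65 of 105 possible edges at λ ≈ 0.033; the
spinglass partition finds exactly the 3 planted dimensions (NMI = 1
against the planted item–factor map after expanding the composite back to
its sources); all 50 bootstrap replicates agree on 3 communities; and the
strongest nodes carry positive expected influence (here EI1 = strength
because all their edges are positive).

For a multi-cohort run, give `run_validation()` a `diagnosis` column and
cohort labels; `run_comparison()` then reports pairwise NMI/AMI on the
original item set plus a per-item table of migrating items.
`autoplot()` methods draw the network and the item-stability profile;
`plot_centrality()` mirrors the usual centrality figure. A thin CLI with
`simulate`/`validate`/`compare` subcommands ships in `inst/cli/netpsy.R`.

A synthetic 12-subscale item key (EDI-3-shaped codes and sizes, invented
item allocation) and a fill-in template ship under `inst/extdata/`; real
scoring requires the user's own key, loaded with `load_item_key()`.

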