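# netdiff

Differential clustering of paired weighted networks via the Generalized
Singular Value Decomposition (GSVD).

## The problem

Given two symmetric weight matrices `A` and `B` on the same `N` nodes —
typically within-group correlation networks for two experimental conditions —
`netdiff` finds *exclusive clusters*: node subsets that are densely,
positively connected in one network but not in the other, and attaches
Monte-Carlo significance to them. The motivating use case is two-group
metabolomics: within-group metabolite correlation networks built from LC-MS
peak intensities, where a condition-exclusive cluster points at a disrupted
region of metabolism, quantified by KEGG pathway over-representation.

## The method

The pair is factorized jointly as

    A = U C X⁻¹,   B = V S X⁻¹

with `U`, `V` orthogonal, `C = diag(c)`, `S = diag(s)` nonnegative
(`c² + s² = 1` componentwise, `c` nondecreasing, `s` nonincreasing). The
generalized singular values `λᵢ = cᵢ/sᵢ` are the stationary values of
`‖Ax‖/‖Bx‖`, so the extreme columns of `X⁻ᵀ` point along directions whose
structure is much stronger in one network than the other. Sorting a column's
components reorders both networks at once: clusters exclusive to `B` collect
at the head of the orderings from the first columns, clusters exclusive to
`A` at the ends of the orderings from the last columns.

A candidate cluster `s` of size τ (a contiguous run of a sorted column) is
scored by within-block edge density `f(s) = |E(s)|/|s|`,
`|s| = τ(τ−1)/2` (binary), or mean within-block weight (weighted), compared
between the two networks as a ratio or difference `c(A, B)`. Its p-value is
the proportion of `M` random node permutations whose first τ nodes score at
least as high. Clusters passing 0.05 are tested for KEGG pathway
over-representation with the upper-tail hypergeometric probability
`P(X ≥ k)` for `k` of the pathway's `m` detected members falling in a
cluster of `n` out of `N` detected metabolites.

The factorization is computed by QR of `rbind(A, B)` plus a CS
decomposition, never forming an inverse, and stays defined for singular
inputs (numerically tied end blocks are aligned deterministically; see the
methods vignette in `vignettes/`).

## Worked example

Twenty nodes; both networks share a cluster on nodes 1–5, `A` additionally
has a cluster on 6–15, `B` one on 15–20:

```r
library(netdiff)

pair <- generate_binary_pair(seed = 1)          # planted benchmark pair
fact <- compute_gsvd(pair)
ord  <- reordering_vector(fact, column = 1, end = "last")
head(ord$permutation, 10)
#>  [1]  8  9 14 12 15 10  6  7 11 13

cl   <- candidate_clusters(ord, taus = 10, ends = "head")$candidate[[1]]
test <- permutation_pvalue(pair, cl, M = 1000, seed = 1)
test
#> <perm_test> tau = 10, target A, scheme permutation, M = 1000
#>   c(A,B) = 19.5 (f_target 0.8667, f_other 0.04444; binary/ratio)
#>   p = 0.004 (corrected 0.004995)
```

The head of the final-column ordering is exactly the planted `A`-exclusive
cluster {6–15}: its block density is 0.87 in `A` against 0.04 in `B`, a
quality only 4 of 1000 random 10-node subsets reach.

Pathway over-representation uses the upper-tail hypergeometric probability;
for example, 7 of a pathway's 10 detected metabolites inside a 22-metabolite
cluster out of 98 detected:

```r
hypergeometric_tail(N = 98, n = 22, m = 10, k = 7)
#> [1] 0.001
```

End to end on a two-group intensity table with a planted group-specific
correlated block annotated to one pathway:

```r
tab   <- simulate_intensity_table(n_per_group = 12, n_metabolites = 20,
                                  block = 1:8, block_strength = 2, seed = 1)
annot <- tibble::tibble(metabolite = paste0("m", 1:20),
                        pathway = c(rep("ko_demo", 8), rep(NA, 12)))
report <- run_pipeline(tab, annotation = annot, taus = 8, M = 1000, seed = 1)
dplyr::filter(tidy(report), significant)
#>   ordering end   column run     tau target f_target f_other c_value p_value
#> 1 last_1   last      20 head      8 A          1.61 -0.0628    1.67       0
report$enrichment[1, c("pathway", "k", "m", "n", "N", "p_value")]
#>   pathway     k     m     n     N    p_value
#> 1 ko_demo     8     8     8    20 0.00000794
```

The planted block surfaces as the head run of the final-column ordering of
the Fisher-z correlation pair (mean within-block z of 1.61 in the first
group vs −0.06 in the second, no null exceedance in 1000 permutations), and
its pathway is maximally over-represented.

A command-line wrapper is installed as `exec/netdiff`, with subcommands
`simulate`, `reorder`, `validate`, `metabolomics` and `enrich`
(`netdiff --help`).

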