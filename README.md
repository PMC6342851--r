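# streambeta

Pairwise beta-diversity decomposition for presence/absence community data,
built for stream-fish surveys (sites nested in streams, streams in regions)
but usable with any binary site-by-species matrix. It answers the question
conservation planners ask of beta diversity: is compositional difference
between communities driven by **species turnover** (one species replaced by
another — favouring many dispersed protected areas) or by **nestedness /
richness difference** (poor communities being subsets of rich ones —
favouring one large species-rich reserve)?

## The statistics

For a pair of communities let `a` be the number of shared species, `b` and
`c` the numbers unique to each side. Two complementary decompositions are
computed for every pair:

**Sørensen-based (BAS):**

    β_sor = (b+c)/(2a+b+c)            total dissimilarity
    β_sim = min(b,c)/(a+min(b,c))     spatial turnover
    β_sne = β_sor − β_sim             nestedness-resultant

**Jaccard-based (POD):**

    β_jac  = (b+c)/(a+b+c)            total dissimilarity
    β_-3   = 2·min(b,c)/(a+b+c)       species replacement
    β_rich = |b−c|/(a+b+c)            richness difference

Both partitions are exactly additive, and `β_jac = 2β_sor/(1+β_sor)` links
the frameworks. Degenerate pairs follow documented conventions: one empty
community gives turnover 0 (pure richness difference, the 0/0 → 0 rule);
two empty communities give an undefined pair that is excluded from
summaries, never zeroed silently.

Around the core sit: per-stream / per-region / total and per-family
mean ± SD summary tables; PCA of dissimilarity profiles (with a PCoA
alternative); seeded Mantel permutation tests of each component against
environmental-difference matrices; checklist composition statistics by
order and IUCN-style threat category; and a synthetic community generator
(nested, replacement and mixed gradients with matched taxonomy, threat,
grouping and environmental tables) so the whole pipeline is testable
without field data.

## Worked example

```r
library(streambeta)

mc <- matching_components(c(1,1,0,1,0), c(1,0,1,1,1))
mc
#> a b c
#> 2 1 2
bas_partition(mc)
#>    beta_sor  beta_sim  beta_sne
#> 1 0.4285714 0.3333333 0.0952381
pod_partition(mc)
#>   beta_jac beta_m3 beta_rich
#> 1      0.6     0.4       0.2
```

Of the total Sørensen dissimilarity 0.43 between these two 3-species
communities, 0.33 is turnover (one species swapped for another) and only
0.10 comes from the richness difference.

An end-to-end run on a synthetic 11-stream / 42-site / 113-species study
with 70% replacement structure:

```r
res <- run_study(list(input = list(synthetic = list(phi = 0.7)),
                      mantel = list(n_perm = 999), seed = 42))
format_beta_table(res$stream_table)[c("ST01", "ES", "WS", "Total"), 1:3]
#>       beta_sor    beta_sim    beta_sne
#> ST01  "0.51±0.28" "0.47±0.27" "0.05±0.01"
#> ES    "0.22±0.12" "0.18±0.11" "0.04±0.02"
#> WS    "0.23±0.12" "0.18±0.10" "0.05±0.02"
#> Total "0.41±0.24" "0.36±0.24" "0.05±0.02"

subset(res$drivers, variable == "altitude" &
         component %in% c("beta_sim", "beta_sne"))[c("component", "r", "p")]
#>    component         r     p
#> 14  beta_sim 0.8717765 0.001
#> 21  beta_sne 0.3765419 0.017
```

As built in, turnover (`beta_sim`, 0.36 of a 0.41 total) dominates
nestedness, and the altitude gradient that drives the species replacement
is recovered by the Mantel screen (r = 0.87, P = 0.001 with 999
permutations).

The package also ships two plain-text data sets: the published
hydrology/environment table of the 11 Luoxiao Mountains streams
(`luoxiao_env()`) and a *synthetic* stand-in checklist
(`luoxiao_checklist()`) whose marginal counts match the published fauna
(113 species, 17 families, 68.1% Cypriniformes, 77.9% LC, 8 threatened
species = 7.1%); see `?luoxiao_checklist` for what it can and cannot be
used for.

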