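---
title: "Decomposing beta diversity in stream communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing beta diversity in stream communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streambeta)
```

## The model

Beta diversity — variation in species composition among communities — is
measured here on strictly presence/absence data. For a pair of communities
the matching components are `a` (shared species), `b` and `c` (unique to
either side). Total pairwise dissimilarity is split in two complementary
ways.

The Sørensen-based partition separates **spatial turnover** from
**nestedness-resultant dissimilarity**:

$$\beta_{sor} = \frac{b+c}{2a+b+c},\qquad
  \beta_{sim} = \frac{\min(b,c)}{a+\min(b,c)},\qquad
  \beta_{sne} = \beta_{sor}-\beta_{sim}.$$

The Jaccard-based partition separates **species replacement** from
**richness difference**:

$$\beta_{jac} = \frac{b+c}{a+b+c},\qquad
  \beta_{-3} = \frac{2\min(b,c)}{a+b+c},\qquad
  \beta_{rich} = \frac{|b-c|}{a+b+c}.$$

Both partitions are exactly additive, every component lies in $[0,1]$, and
$\beta_{jac} = 2\beta_{sor}/(1+\beta_{sor})$ whenever both totals are
defined. The two frameworks answer the same question on different scales:
$\beta_{-3}$ counts each replaced species pair twice relative to the
Jaccard denominator, so replacement and richness-difference shares are not
numerically comparable across frameworks, only within one.

The decomposition assumes the incidence matrix is a faithful
presence/absence record: detection is not modelled, and abundance
information, if present in the raw export, must be binarized *explicitly*
(`coerce = TRUE`); silent binarization is refused because a non-binary cell
usually signals a wrong input file.

## Degenerate pairs

Two conventions are needed once family-level subsets are taken, because a
unit can then host none of the focal family:

* **One empty unit** (`a = 0`, `min(b,c) = 0`, `b+c > 0`): the turnover
  ratio is 0/0. We define $\beta_{sim} = \beta_{-3} = 0$: turnover means
  replacement of some species by others, and a unit with nothing to replace
  is a pure richness difference, so $\beta_{sne} = \beta_{sor} = 1$. This
  convention is also the only one under which a family represented by a
  single species has a defined, exactly zero, mean turnover — the pattern
  single-species families show in published family tables.
* **Two empty units** (`a=b=c=0`): all six components are 0/0 and no
  convention is defensible; the pair is *excluded* — masked `NA`, counted,
  reported — rather than set to 0 or 1. Because published analyses rarely
  state their choice, `double_empty = "zero"` is available as a sensitivity
  alternative that treats two empty communities as identical.

All pair arithmetic stays in integers until the final division, so the
additivity identities hold to machine precision (the test suite checks
$10^4$ random triples at $10^{-12}$).

## Summary tables and their grain

Summaries are mean ± SD over a set of pairs. Three set constructions
cover the standard report layouts:

* a **unit row**: all non-excluded pairs between one stream and the
  others (`summarize_unit`);
* a **scope row**: all pairs within a member set — a region such as the
  eastern or western slope, or the Total row (`summarize_scope`);
* a **family row**: all pairs after restriction to one family's species
  (`family_table`), empty units kept.

The analysis grain matters and is an explicit choice. Stream-level rows use
the union of each stream's site incidences (`aggregate_to_streams`);
family tables are typically computed at site grain, which yields many more
pairs and higher dissimilarities. Published per-stream and per-family
tables from the same survey can therefore sit at different grains without
contradiction; the run configuration has one key per table (`grain`,
`family_grain`) with defaults `stream` and `site` respectively.

SD uses the sample (n−1) denominator by default; `sd_denominator = "n"` is
available because printed tables rarely say which was used. Report
rendering rounds half-up at two decimals, matching how such tables are
printed; machine-readable outputs keep full precision.

## Ordination

"PCA of compositional similarity" is ambiguous between at least three
procedures. The default here, `method = "profiles"`, runs a column-centered,
unscaled PCA on the rows of the dissimilarity matrix — each unit's profile
of dissimilarities to all units — which ordinates units by *whom they
differ from*. `method = "pcoa"` (classical metric MDS of the
dissimilarities themselves) is provided as the main alternative reading.
Axes are deterministically oriented (largest-magnitude loading positive) so
results are reproducible across platforms; explained-variance fractions are
non-increasing and the scores of duplicate profiles coincide.

## Environmental drivers

Each beta component matrix is screened against the absolute pairwise
difference matrix of one environmental variable (length, area, gradient,
precipitation, temperature, runoff, altitude; raw differences by default,
z-scored with `standardize = TRUE`). The statistic is the Pearson
correlation of the lower triangles; significance comes from a Mantel
permutation test that relabels the units of the environmental matrix.

Conventions, each an explicit argument because published tables rarely
state them:

* **Tail:** one-tailed `greater` by default — screens of dissimilarity
  matrices conventionally ask whether compositional difference *increases*
  with environmental difference, and published tables showing negative r
  with P near 1 are consistent with that convention. `two-sided` and
  `less` are available.
* **P definition:** with `n_perm` random permutations,
  $P = (1 + \#\{r^* \ge r\})/(n_\text{perm}+1)$, so $P \ge 1/(n_\text{perm}+1)$;
  with `exact = TRUE` all $n!$ relabelings are enumerated (identity
  included) and $P$ is the exact proportion — feasible to $n = 8$ and
  verified against independent enumeration at $n = 4$.
* **Seed:** mandatory for random permutations; results are reproducible
  and the seed is echoed into the output table.
* A component with zero variance across pairs (pure-replacement data have
  $\beta_{sne} \equiv 0$) has no defined correlation; the screening table
  records `NA` with a warning instead of aborting.

The suite checks null calibration directly: on 200 independent random
matrix pairs (11 units, 999 permutations each) the fraction of P < 0.05
must lie in [0.01, 0.10].

## Checklist composition

`composition_report` tabulates a checklist by order, family and threat
category (CR/EN/VU/NT/LC/DD/NE), reporting counts and half-up one-decimal
percentages plus the grouped "threatened" share (CR ∪ EN ∪ VU ∪ NT).
Species missing from the threat table become NE with a warning. The
package ships a **synthetic** stand-in checklist whose marginal totals
match a published mountain-stream fish fauna (113 species, 17 families,
77/16/16/1/1/2 by order, 88 LC, 8 named threatened species); it exercises
the report layout at realistic scale but carries no occurrence
information. One published order percentage ("0.1%" for a single
beloniform among 113 species) is arithmetically impossible — 1/113 rounds
to 0.9% — and is treated as a typo, not a check value.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, at
the default scale of the motivating survey type: 11 streams, 42 sites, 113
species, 17 families (one of them a singleton).

* `generate_nested`: sites along a gradient hold prefix subsets of the
  pool with richness interpolating `richness_max` → `richness_min`
  (defaults scale with the pool: about a quarter down to a twentieth of
  `n_species`). Every pair is nested by construction, so mean
  $\beta_{sim}$ is *exactly* zero.
* `generate_replacement`: every site holds exactly `k` species in a
  sliding window shifted `step` species per site, no wrap-around. Equal
  richness forces $b = c$, so $\beta_{sne}$ and $\beta_{rich}$ are
  *exactly* zero. The window is deterministic precisely so these purity
  properties are exact; stochasticity enters only through the optional
  occupancy-flip noise (`flip_prob`, default 0).
* `generate_mixed`: the pool is split into a replacement block (fraction
  `phi`) and a nested block (the rest); the richest site holds the whole
  nested block so every species occurs somewhere, as in a real checklist.
  The bundle adds a taxonomy, an LC-dominated threat table, a contiguous
  site-to-stream grouping with an east/west region split, and an
  environmental table in which altitude tracks the gradient with Gaussian
  noise (`env_noise_sd`, default 0.1 of the altitude range — enough that
  recovery is a real test, not a tautology) while the other six variables
  are pure noise in realistic positive ranges.

What the generator does **not** emulate: dispersal or niche mechanisms,
detection error, spatial autocorrelation beyond the single gradient,
correlated environmental variables, or abundance structure. Passing tests
therefore demonstrate algorithmic correctness and recoverability of a
clean signal, not performance on noisy field data.

## Test problem sizes

The suite favours exact small cases plus moderate Monte-Carlo checks:
brute-force pair oracles at 5 units × 12 species; exhaustive Mantel
enumeration at 4 units; identity sweeps over $10^4$ random triples; purity
checks across 20 seeded replicates per scenario at 10 sites × 50 species;
mixture monotonicity over `phi` ∈ {0, 0.25, 0.5, 0.75, 1} × 20 replicates
at full default scale with `flip_prob = 0.05` (so replicates differ);
driver recovery at `phi = 1` with 999 permutations across 20 seeds
(expected significant in at least 16); and the 200-replicate null
calibration described above. These sizes make the whole suite run in well
under a minute while keeping every probabilistic bound comfortably away
from its threshold.

## Known limitations

* Pairwise only: multi-site beta diversity, abundance-weighted and
  phylogenetic/functional decompositions are out of scope.
* The Mantel screen is marginal per variable — no partial Mantel or
  distance-based regression, so correlated drivers are confounded.
* Region membership (e.g. which streams drain east vs west) must be
  supplied; the bundled default for the Luoxiao streams is a documented
  drainage-based assumption, configurable, with the Yangtze-draining FS
  stream unassigned unless placed explicitly.
* The bundled checklist is synthetic (marginals only); per-species
  occurrence analyses require real data files.
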