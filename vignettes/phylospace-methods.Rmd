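---
title: "Methods: spatial-phylogenetic structure of stem-mapped plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-phylogenetic structure of stem-mapped plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the data

Community phylogenetics usually works at the plot level: a plot is a species
list, and structure means that the list is a non-random sample of a regional
pool. A fully stem-mapped plot carries strictly more information — the x-y
position of every individual plant — and lets one ask a finer question: *are
plants that grow physically close to each other more (or less) closely
related than chance would have it?* A positive association between physical
and phylogenetic distance says related plants track shared habitat
("birds of a feather"); a negative one is the classic signature of
competitive exclusion among close relatives, the mechanism behind Darwin's
naturalization hypothesis for alien plants.

phylospace implements that analysis for data of the form

* an **ultrametric phylogeny** (newick, branch lengths in millions of years,
  Ma) whose tips cover the species — or, commonly, the genera — observed;
* **stem maps**: one row per individual with plot id, species, regional
  status (indigenous/alien), optional family, and x-y coordinates in metres
  inside a plot (5 × 5 m by default);
* **plot metadata**: vegetation type (forest or grassland) per plot.

# The pipeline

## Distances

Phylogenetic distance between two species is the **patristic distance**: the
sum of branch lengths along the tree path between their tips
(`patristic_matrix()`). It is computed from an edge-by-tip incidence matrix
(shared root-path length via a cross-product), which the test-suite checks
against per-pair brute-force path enumeration. On a genus-exemplar tree,
species fall back to their genus tip, so congeneric species sit at patristic
distance zero; this matters little in practice when congenerics rarely
co-occur in a plot.

Physical distance between two individuals is the plain 2-D Euclidean
distance between their mapped coordinates (`physical_distances()`). No edge
correction is applied: the analysis treats the plot as the universe, and
every within-plot pair enters once. The field-mapping error of a few
centimetres is ignored — coordinates are taken at face value.

`build_pair_distances()` matches the two: for every unordered pair of
individuals in a plot, the physical distance and the patristic distance
between their species. Many physical values therefore map to one
phylogenetic value. **Conspecific pairs are kept by default** with
phylogenetic distance 0: those zero-distance pairs are exactly what couples
conspecific spatial aggregation into the statistic. Because the literature
is not unanimous, `include_conspecific = FALSE` masks them, and the Mantel
stage then works on heterospecific pairs only.

## The per-plot Mantel test

`mantel_test()` correlates the two distance vectors (Pearson r over the
upper triangles) and builds the null by jointly permuting rows and columns
of the phylogenetic matrix — i.e. by relabelling *individuals*, which is the
exchangeable unit once distances are taken at the individual level. Defaults:
999 permutations, one-sided "greater" alternative (spatial aggregation of
relatives is the signal of interest; a two-sided option exists because
negative associations are biologically meaningful too), add-one p-value
`p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` so p is never 0 and never
below `1/(n_perm+1)`. A plot with a single species (zero variance in the
phylogenetic vector) is reported as degenerate, not silently given r = 0.

## The PD null model

`faith_pd()` is Faith's phylogenetic diversity: the total branch length of
the minimal subtree spanning a species set, *including the path to the
root* (the convention of the widely used Phylocom `pd`); an unrooted
MRCA-spanning variant is available via `rooted = FALSE`.

`pd_null_test()` asks whether a plot's PD is lower (clustered) or higher
(overdispersed) than expected from its richness: null replicates draw the
same number of species uniformly, without replacement and without abundance
weighting, from the species pool (10,000 replicates by default). The pool
defaults to **all species observed across all plots of both vegetation
types** — a grassland plot is judged against the grassland-forest mix —
with a per-vegetation pool as an option. Tail probabilities are rank-based,
ties counted inclusively, add-one smoothed; the two-sided decision at
overall alpha = 0.05 calls a plot clustered when `p_low <= 0.025` and
overdispersed when `p_high <= 0.025`. The inclusive-tie convention makes
degenerate nulls (a star tree, or an assemblage equal to the pool) land on
"neither" rather than on both tails. The standardized effect size
`ses = (PD_obs - mean_null) / sd_null` is reported alongside and is `NA`
when the null is degenerate.

`run_pd_suite()` repeats the classification for three configurations — full
data, aliens removed, graminoids removed — recomputing the pool within each
configuration. "Graminoids" default to Poaceae only, the family people mean
by "grasses"; pass `c("Poaceae", "Cyperaceae")` to drop sedges as well.

## Plot-level comparisons

`plot_summaries()` condenses each plot to richness, PD, stem density,
percentage of alien individuals (plus `ln(pct + 1)`, so a plot without
aliens is representable at 0; the offset is configurable), Mantel r/p and
the PD classification. On that table:

* `vegetation_anovas()` — classical one-way fixed-effects ANOVA between
  vegetation types for each response;
* `fit_mantel_glms()` — one Gaussian identity-link GLM per covariate,
  `mantel_r ~ vegetation * covariate`, over the four default covariates
  (richness, PD, density, log-percent-alien). That is four models with
  three non-intercept terms each — twelve substantive p-values. A single
  full model with every covariate is deliberately **not** the default:
  twenty plots cannot support a 9-term design; it is available behind
  `full_model = TRUE`. Covariates are fit on their raw scales; with
  identity link and Gaussian errors the fits are ordinary least squares
  with classical standard errors, and the tests verify that identity
  numerically.

# The synthetic-data generator

Real stem maps with a matching dated phylogeny are rarely public, so every
stage is verified against `simulate_study()`, which produces data with
*known* spatial-phylogenetic coupling:

1. **Tree** — pure-birth (Yule) topology with exponential waiting times
   (`ape::rphylo`, birth 1, death 0), branch lengths rescaled so the root
   age is exactly `root_age` (default 150 Ma, a crown age in the right
   range for an angiosperm-wide genus tree).
2. **Niche centres** — two independent Brownian-motion traits evolved along
   the tree, affinely rescaled to the plot square. Brownian motion is a
   choice, not a claim about nature: any mechanism making patristic and
   spatial distance positively associated would serve; BM is the standard,
   analytically tractable one.
3. **Plots** — per plot: richness and total abundance drawn uniformly from
   the vegetation type's ranges, abundances allocated by a geometric
   rank-abundance series (every drawn species gets at least one
   individual), and each individual placed, with probability `kappa`, at
   its species' centre plus isotropic Gaussian noise (sd `sigma`,
   *resampled* until inside the plot — resampling rather than clipping
   keeps density smooth at the edges), otherwise uniformly at random.
   `kappa = 0` gives exchangeable labels (the null of the Mantel test
   holds exactly); `kappa = 1` gives the strongest coupling the geometry
   of the centres allows.

Defaults emulate a twenty-plot survey: 10 forest + 10 grassland plots of
5 × 5 m, a 200-species pool, per-plot richness 10–40 in both vegetation
types (richness did not differ between them in the motivating system),
100–200 individuals per forest plot and 200–400 per grassland plot
(grassland swards are denser; totals land near 4,000–4,500 individuals),
and 9% of pool species alien — aliens phylogenetically unconstrained by
default, matching the observation that alien plants integrate into the
local spatial-phylogenetic fabric, with `alien_clade = TRUE` to simulate
the opposite. `grassland_clade = TRUE` draws grassland species from the
shallowest sufficiently large clade of the pool, reproducing the
graminoid-dominated, low-PD sward situation; it is off by default because
it is a scenario switch, not part of the neutral generator.

The default placement scatter is `sigma = 0.6` m. The value was fixed once,
while calibrating the generator so that full coupling produces a clear
majority of significant per-plot Mantel tests; the assertable property —
mean per-plot r strictly increasing in `kappa`, with near-nominal rejection
at `kappa = 0` — does not depend on the particular value.

What the generator does **not** emulate: real rank-abundance shapes beyond
the geometric series, within-species clumping mechanisms other than the
shared centre (no Thomas/Neyman-Scott offspring processes), canopy
layering, terrain, or measurement error. Passing tests therefore show the
*statistics* behave as designed — size, power direction, classification
logic — not that any particular field system satisfies the generator's
assumptions.

# Numerical and design choices

* **Ultrametricity** is validated with a relative root-to-tip spread
  tolerance of 1e-6; violations warn rather than error (dated empirical
  trees carry rounding), with `strict = TRUE` to escalate. Polytomies are
  accepted as-is; path sums are well defined regardless.
* **Patristic computation** clamps tiny negative round-off to 0 and forces
  an exact zero diagonal.
* **Tie handling**: both the Mantel and the PD null count ties inclusively
  and use add-one smoothing, so no p-value is ever 0 and degenerate nulls
  classify as "neither".
* **Seeding**: every stochastic function takes a `seed`; multi-plot
  drivers derive one independent sub-seed per plot from it, so results do
  not depend on plot order and a fixed seed reproduces every number
  bit-for-bit.
* **Problem sizes in the shipped checks**: oracle equivalence runs over
  200 random trees of up to 16 tips; Mantel exactness over n = 4–6
  individuals against the full factorial of label permutations; test size
  over 1,000 uncoupled plots (199 permutations each — the type-I rate of a
  permutation test does not depend on the permutation count); PD null
  calibration over 500 random assemblages at 1,000 replicates; coupling
  recovery over 50 studies per `kappa` in {0, 0.5, 1}. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted bands.
* **Failure containment**: per-plot degeneracies (single species, too few
  individuals, emptied-by-filter) are flagged rows, not run failures;
  stages whose design the data cannot support (ANOVA with one vegetation
  type, singular GLMs) are skipped with a warning.

# Known limitations

* Plots are analysed independently; no correction for spatial
  autocorrelation *between* plots, and no cross-plot pairs.
* The Mantel test's permutation unit is the individual; if one wanted a
  species-level null holding the spatial point pattern fixed, that is a
  different (and not implemented) randomization.
* The PD null draws species with uniform probability; abundance-weighted
  nulls are out of scope.
* Genus-level trees collapse congeneric distances to zero, slightly
  deflating r in plots with co-occurring congenerics.
* The comparative GLMs treat plot summaries as independent observations —
  with ten plots per vegetation type, that is a deliberate parsimony, not
  a hierarchical model.
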