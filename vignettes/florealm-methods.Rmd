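---
title: "Methods: phylogenetic regionalization, realm chronology, and divergence drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic regionalization, realm chronology, and divergence drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florealm)
```

## Scope and data model

`florealm` turns two inputs — a dated, ultrametric genus-level phylogeny
(newick, branch lengths in Ma) and a binary genus × GSU occurrence matrix
(long-format CSV of `genus_id, gsu_id` records) — into a nested floristic
regionalization, a divergence chronology for the identified realms, a
time-resolved attribution of realm boundaries to geographic isolation versus
climate, and per-clade contribution scores. A geographic standard unit (GSU)
is any polygonal land unit used as the site of assemblage comparison;
everything in the package treats GSUs via their ids and centroids, so any
polygon scheme upstream works. Taxonomic standardization, occurrence
filtering and phylogeny inference are upstream concerns: the matrix and the
tree are the interface.

## Beta diversity

Turnover between two GSUs is Simpson dissimilarity
`1 - a / (a + min(b, c))`. Using `min(b, c)` rather than `b + c` makes the
index blind to nestedness and richness gradients: a flora that is a strict
subset of another has zero turnover against it. In phylogenetic mode the
components are branch lengths of the shared phylogeny: a branch counts as
present in a GSU when at least one of its descendant tips occurs there. Two
numerical conventions matter:

* **The root stem is excluded.** A stem above the root would be shared by
  every pair and only inflate `a` uniformly; the edge table of an `ape`
  tree does not contain it, and we never add one.
* **Zero-length branches are harmless.** Branches from resolved polytomies
  contribute zero length to whichever component they fall in.

Consequences we rely on (and test): the index is invariant to global
rescaling of branch lengths (only length ratios enter), and duplicating
every genus as a zero-length-separated twin changes nothing.

The full matrix is computed by tabulating branch presence per GSU once
(`edges × GSUs`) and forming one cross-product, so the 420-GSU, ~25k-branch
scale of a global genus-level analysis takes seconds. The contract is exact
agreement (≤ 1e-12) with the explicit per-pair branch walk
(`phylogenetic_components()`), which is kept as an independent code path for
that purpose.

Assemblages must be non-empty — Simpson beta has no value when
`a + min(b, c) = 0` — so empty genera and empty GSUs are rejected at I/O
time rather than patched downstream.

## Regionalization

`P_beta` of a partition is the sum of beta over between-cluster GSU pairs
divided by the sum over all pairs. Along the nested cut sequence of one
dendrogram it is nondecreasing in the number of clusters `k` (refining a
partition can only move pairs into the between set), which makes
"the smallest `k` reaching a threshold" well defined; `cut_at_pbeta()`
scans `k = 1..n` via `stats::cutree`, with ties in merge heights resolved by
merge order. Defaults: realms at `P_beta = 0.80`, sub-realms at `0.95`. The
two cuts come from the same dendrogram, so sub-realms always refine realms.
The two-cluster cut is exposed as `super_realms` as a descriptive overview;
no `P_beta` level is claimed for that rank.

Linkage selection (`evaluate_linkages()`) compares seven classical
agglomerative methods on two axes: *performance* — the minimum `k` whose
nested cut reaches `P_beta = 0.99`, fewer being better — and *accuracy* —
the Pearson correlation between input dissimilarities and cophenetic
distances. Best performance wins, ties broken by accuracy. On block-
structured beta matrices this selects average linkage (UPGMA), which is also
the package default when a method is named directly.

Supporting views of the same structure:

* **NMDS** (`nmds_embed()`): 2-D by default, Kruskal stress-1 with monotone
  regression, best of `n_starts` random starts (via `vegan::metaMDS`),
  coordinates centered; a fixed seed reproduces coordinates exactly. A
  matrix with no variation yields a deterministic circular layout with a
  warning rather than an error, so degenerate deep time-slices do not abort
  a chronology.
* **Fuzzy memberships** (`fuzzy_membership()`): the FANNY objective on the
  beta matrix, membership exponent 1.5 by default. The exponent is the
  classic fuzziness dial (2 is very soft for well-separated blocks; values
  near 1 approach hard assignment); 1.5 keeps sharp blocks sharp while
  leaving boundary GSUs visibly mixed.
* **Silhouettes** (`silhouette_widths()`): standard widths on the beta
  matrix; singleton clusters get width 0 by convention.
* **Confinement** (`boundary_confinement()`): the fraction of genera whose
  occupied GSUs all carry one realm label.

## Chronology by time-slicing

`slice_tree(tree, t)` collapses every branch whose age interval spans `t`
(parent older than `t`, child at or younger) into one lineage; the sliced
tree is the original truncated below `t`, with terminal branch lengths
`parent age − t`. Collapsed assemblages use the union rule: a lineage is
present wherever any member tip is. Beta at a slice uses only the truncated
tree's branch lengths — the post-`t` tree is the unit of comparison. At or
beyond the crown age no branch spans `t`; the slice degenerates onto the
root's children with a warning and the chronology records a single realm.

Slice clusters are matched to the present-day realms by maximizing total
shared-GSU overlap (an exact assignment solved by dynamic programming over
realm subsets); a matched cluster whose Jaccard overlap with its realm falls
below 0.5 is relabelled "ancestral", making the otherwise hand-assigned
coloring of such maps deterministic. Per-slice NMDS configurations are
Procrustes-aligned (rotation, reflection, scale) to the `t = 0`
configuration over shared GSUs. We re-run NMDS per slice and then align,
rather than embedding all slices jointly; this is an interpretation choice,
flagged as such.

`separation_time()` reports, for two GSU sets, the oldest slice depth from
which their majority clusters remain distinct at every younger slice. With a
10-Ma grid, a split at `s` is expected to register at the first grid point
strictly below `s` (a node at exactly `s` still sits on the crossing parent
branch), i.e. within one grid step.

## Drivers

Contemporary climate distance is the Euclidean norm in the (annual mean
temperature °C, annual precipitation mm) plane, z-scored by default because
the units are incommensurable; within-realm and between-realm OLS fits are
on raw scales. The geological-time model is
`ln(beta) ~ ln(climate isolation) + ln(geographic isolation)`, per 1-Ma (or
user-chosen) step, with the response fixed at present-day beta and the
predictors varying by step.

Geographic isolation is the minimum accumulated route cost between GSU
centroids over a land/ocean/elevation grid: 8-neighbor moves, edge cost =
great-circle length between cell centers (mean-radius sphere, 111.195 km
per equatorial degree) × the mean of the two cells' frictions, friction
`1 + k_elev · elevation/1000 m` on land and `k_ocean` on ocean. There is no
field-standard value for either constant — landscape-connectivity studies
vary them by organism — so `k_ocean = 10` and `k_elev = 1` are package
defaults, fully configurable; `k_ocean = Inf`
makes ocean impassable and flags disconnected pairs. Centroids on ocean
cells snap to the nearest land cell with a logged note.

Hierarchical partitioning of the two-predictor model is closed-form:
`I1 = (R²(x1) + R²(full) − R²(x2)) / 2`, symmetrically for `I2`; the pair
always sums to the full R², both are nonnegative, and the formula equals
the average of incremental R² over both entry orders (asserted in-code).
Collinear predictors split the R² evenly with a warning. Before taking
logs, each pairwise vector is offset by 1e-6 of its positive maximum so
occasional zeros are defined without distorting the scale. Binning uses
`[0,5), [5,10), …` with SE = SD/√n over the steps in a bin.

## Node-based clade contributions

For each internal node with two descendant clades (polytomies reduce to the
two largest children, logged), the geographic node divergence (GND) score is
the Simpson-type mismatch of the clades' occupied-GSU sets — 0 for identical
ranges, 1 for disjoint — with the metric slot pluggable for users who want a
different range-mismatch definition; the 0.65 screening threshold is a
strict inequality. SOS scores standardize each GSU's clade-A tip count
against a null that reshuffles the A/B labels across the node's tips
(preserving clade sizes and every tip's range; 200 shuffles by default,
seeded per node): positive values mark predominance of clade A. The
contribution of a node to a realm pair is the one-way ANOVA R² of its SOS
across the two realms' GSUs, which for two groups equals the squared
point-biserial correlation; constant SOS gives 0 and realms with fewer than
two scored GSUs are flagged rather than fitted.

## The synthetic world: what it emulates and what it does not

The generator plants every structure the analyses assume, with one master
seed feeding named substreams (tree / world / ranges / climate / paleo /
NMDS / SOS), so each stage reproduces in isolation.

**Geometry.** `gen_world()` tiles a `rows × cols` lattice of 4°-GSUs into
contiguous, axis-aligned, size-balanced realm blocks (the divisor pair of
`n_realms` best matching the lattice aspect), each halved along its longer
side into two planted sub-realms. Contiguity and balance are the only
geometric properties downstream stages need.

**Phylogeny.** `gen_realm_tree()` hangs one clade per realm off a
caterpillar backbone whose splits sit at the chosen ages (defaults
90/60/30 Ma for four realms). Every realm clade crowns just below the
youngest backbone split and consists of four parallel "guild" subtrees,
each recursively bisecting the realm block in space with block-resident
tips attached at every level (30% per node). This multi-scale structure —
widespread clades, regional clades, local radiations coexisting in every
GSU — is what real floras show, and it is load-bearing: time-slicing can
only separate two realms at the `P_beta = 0.80` cut if within-realm
turnover persists at that phylogenetic depth. A flat model in which every
tip ranges over its whole realm has no deep within-realm turnover, and
recently split realms then stay merged in slices regardless of their true
split time. Realm crowns are capped below the youngest backbone split so
that the "oldest k disjoint clades" rule recovers exactly the realm clades.

**Occupancy.** Each tip occurs in its home block with probability
`affinity` (0.8) and elsewhere with a leakage probability that decays
exponentially with distance beyond the adjacent GSU (`leakage = 0.02` at
the boundary, e-folding scale 6°). The decay is a dispersal kernel: it
produces the distance decay of floristic similarity that any driver
analysis needs as signal, and it keeps *collapsed lineages* mostly
confined. That last point sets the leakage scale for depth-resolved
analyses: a per-tip leakage ε compounds to `1 − (1 − ε)^m` for an m-tip
lineage, so scenarios that slice deeply (chronology, node screening) use
ε = 0.001, keeping whole-clade foreign presence below ~7%, while the
present-day regionalization scenario uses the softer 0.02.

**Climate and paleo-landscapes.** Contemporary climate mixes a latitudinal
gradient with per-realm offsets in proportion `gradient_align`, plus noise.
`gen_paleo()` builds per-step 1° land/ocean + elevation grids and per-GSU
paleoclimate tables under two scenarios. *Isolation*: an ocean strip opens
along the boundary of two adjacent realm blocks at every time younger than
their planted split (so route costs rise after the split), and paleoclimate
is spatial noise. *Climate*: the landmass stays whole; realm climates
drift apart after their splits — each backbone split event displaces its
two daughter realm sets along a fixed, golden-angle-spaced direction of the
temperature/precipitation plane, with magnitude growing as √(elapsed time),
i.e. Brownian-style divergence — on top of a smooth spatial gradient.
The directions are fixed constants of the geometry (like the block layout
itself): a per-seed random rotation can place two split events on
cancelling axes, which tests the geometry, not the method.
`gen_driver_world()` closes the loop by routing the occupancy kernel
through the planted driver (route distance or climate distance), so the
flora is genuinely structured by the driver the attribution is asked to
recover.

**What passing tests do not show.** The generator does not simulate
continental drift trajectories, speciation/extinction geography, niche
evolution, sampling effort, or taxonomic error. Recovery of planted
structure therefore demonstrates that the pipeline's statistics measure
what they claim on data satisfying their assumptions — block-structured
turnover, clade-realm association, driver-kernel exchange — not that any
real flora satisfies those assumptions.

## Problem sizes and numerical choices

The reference study system is 4 realms on a 6 × 6 lattice with 200 genera
(three realms, 150 genera, splits 60/30 Ma for chronology scenarios); rate
criteria use 10–20 replicate seeds, 100–200 label randomizations for SOS,
and 20–100 NMDS starts. These sizes make every planted signal comfortably
recoverable while a full test run stays in the tens of seconds.

Node ages are rounded to 1e-6 Ma (one year) when read off a tree, so newick
round-off accumulated across nested subtree assembly cannot leave a tip
infinitesimally above the present and break slice coverage. Beta values are
clamped at 0 against −1e-17-scale round-off. The assignment matcher is
exact up to 20 present-day realms (dynamic programming over subsets), far
above any realistic realm count.

## Known limitations

* Tip shuffling degrades but does not destroy a regionalization: genus-level
  co-occurrence survives any tree permutation, so phylogenetic Simpson beta
  retains most block structure. Sensitivity analyses over alternative trees
  should therefore be read as testing *phylogenetic* robustness only.
* The NMDS chronology trajectory (aligned centroid separations) grows toward
  the present but need not be strictly monotone slice-to-slice; local NMDS
  structure introduces bumps.
* `P_beta`-threshold cutting is scale-coarse: whether a recently diverged
  realm pair is separated at a slice depends on the turnover budget of the
  whole matrix, not only on that pair. This is a property of the method, and
  the reason the chronology reports separation within one grid step rather
  than exactly at the split age.
* File-based driver runs need per-step paleoclimate tables supplied by the
  user; `run_pipeline()` wires drivers automatically only for simulated
  worlds.
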