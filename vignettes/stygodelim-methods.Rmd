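---
title: "Models and methods behind stygodelim"
author: "stygodelim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stygodelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stygodelim)
```

stygodelim packages the integrative workflow for splitting a complex of
morphologically cryptic species — exemplified by the groundwater amphipod
*Niphargus stygius* complex — into delimited, diagnosed and
conservation-ranked species. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical decisions, in
enough detail that a user can judge what the package's results do and do
not show.

## Distance-based delimitation

Pairwise divergence is measured with the Kimura two-parameter (K2P)
correction,

$$ d = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q), $$

where $P$ and $Q$ are the proportions of transition (A–G, C–T) and
transversion differences among compared sites. Comparison uses *pairwise
deletion*: a column is dropped for a pair only when either member carries
a gap, an `N`, or an ambiguity code there. This maximises data use and is
the standard choice in barcode-gap analyses; ambiguity codes are never
partially matched (a `Y` is not half a `C`), which keeps the estimator
simple and exactly testable. When $1-2P-Q \le 0$ or $1-2Q \le 0$ the pair
is *saturated*: the distance is returned as `Inf`, which downstream
clustering treats as "above any threshold" — a conservative splitting
rule.

`threshold_clusters()` turns a distance matrix into putative species.
Default thresholds follow the empirically calibrated crustacean species
boundaries: 4% K2P and 16% patristic divergence. With single linkage
(the default), blocks are connected components of the graph with an edge
wherever $d < t$ — the "no pair below threshold across species" reading
of a divergence threshold. Complete linkage (optional) agglomerates while
the maximum intra-block distance stays below $t$, with a deterministic
smallest-index-first merge order. The edge condition is strictly `<`, so
a pair at exactly the threshold is split.

Patristic distances are path sums over a tree with branch lengths in
substitutions per site. Any supplied Newick tree is accepted; when none
is given, a neighbor-joining tree is built from the K2P matrix
(`neighbor_joining()`, classic Q-criterion via ape), with negative
estimated branch lengths clamped to zero and the total deficit reported.
Midpoint rooting (`midpoint_root()`) places the root halfway along the
longest tip-to-tip path and leaves all patristic distances unchanged.

## Poisson tree processes (ML-PTP)

PTP assumes that the number of substitutions on a branch — hence its
length — follows one of two exponential regimes: a *between-species*
(speciation) class on the branches connecting the root to each species'
stem, and a *within-species* (coalescent) class inside species subtrees.
For a branch class with $n$ branches of total length $S$, the rate MLE is
$\hat\lambda = n/S$ and the profiled log-likelihood contribution is
$n\log(n/S) - n$. A delimitation is a partition of the tips into
rooted subtrees; its log-likelihood is the sum over the two induced
classes.

`ptp_fit()` maximises this over all rooted-subtree partitions:

* **Exact search** (automatic when the tree admits at most 20 000 such
  partitions): every partition is enumerated and scored incrementally.
* **Heuristic search** otherwise: a beam-search descent that repeatedly
  applies the best frontier splits all the way down to the all-singleton
  state — walking the full path means likelihood plateaus between the
  one-species state and the optimum cannot trap the search — followed by
  best-improvement hill climbing with both split and merge moves from the
  best states visited. On 200 random trees with up to 8 tips the
  heuristic matched an independent brute-force enumeration exactly (this
  is a standing test).

Numerical choices worth knowing:

* **Branch-length floor.** Zero-length branches would give an infinite
  rate MLE; inside `ptp_loglik()` they are floored at $10^{-9}$. On
  *estimated* trees this floor is dangerous: a within class consisting
  only of floored zeros attains rate $10^9$ and a spuriously enormous
  likelihood, which rewards "purifying" the within class by splitting
  everything else off. `ptp_delimit()` therefore preprocesses estimated
  trees at the data's resolution instead (below).
* **Tie handling.** Among (near-)equal-likelihood optima the coarsest
  partition (fewest species) is returned, via a zero-gain merge pass.
  Ties arise in practice when a species is not recovered as monophyletic
  on an estimated tree, making several partitions score identically.
* **Determinism.** All remaining ties break on the lexicographically
  smallest tip label, so results are reproducible without a seed; the
  optional random restarts (which also yield per-block agreement support,
  a nonparametric stand-in for Bayesian support values) are seeded.

`ptp_delimit()` implements the standard single-locus route: identical
haplotypes are collapsed to one representative (ambiguity-insensitive
identity), a neighbor-joining tree of unique haplotypes is midpoint
rooted, internal branches below one substitution ($1/L$ for an alignment
of $L$ columns) are collapsed to multifurcations and remaining branches
floored at $1/L$ — estimated lengths below the data's resolution carry no
information about rate classes — and the fitted blocks are expanded back
to all specimens. PTP needs a rooted tree; collapsing may leave a basal
multifurcation, which the fitter is told to accept as rooted.

## Consensus and the haplotype-sharing screen

The pipeline's headline species hypothesis is the *meet* of the
single-method partitions: two specimens are conspecific only when every
method agrees. Retaining the single-method partitions for audit, this
matches the integrative-taxonomy requirement that independent evidence
concur before a split is accepted.

`lineage_sharing_screen()` asks whether any haplotype, at any locus, is
observed in two delimited species. Haplotype classes are connected
components of the pairwise relation "identical after excluding columns
where either sequence has a non-ACGT character"; the relation is not
transitive (an `N` can mask a difference), so the component closure is
the honest equivalence. An empty report is the "all haplotypes
species-specific" verdict — no sign of gene flow; restricting to
co-occurring species pairs (syntopic mode) focuses the screen on the
natural crossing experiments where introgression would be detectable.

## Molecular diagnoses (pure character attributes)

A position $p$ with state $s$ diagnoses species $B$ iff (i) every member
of $B$ with data carries exactly $s$ at $p$, and (ii) no member of any
other compared species *can* carry $s$ there. Ambiguity codes resolve to
their IUPAC sets: an outside `R` blocks an `A` diagnosis, an outside `N`
blocks any base (but not a gap), and a gap is a legal diagnostic state
blocked only by outside gaps. Inside the focal species, any ambiguity
(including `N`) breaks fixation. Comparison is flat — each focal species
against all other focal species — which matches how published per-species
diagnoses within a complex are read; species outside the declared focal
set are omitted from the comparison entirely. The implementation is
verified in the test suite against an exhaustive
position-by-state-by-species scan.

Formatted output follows the classical table layout (`28 S`, `COI`,
`ITS` in that order, further loci appended only when informative, `na`
for loci without data or without diagnostic sites). The bundled
transcription of the published diagnosis table is stored verbatim —
including its typographic anomalies (a position with a missing state, an
implausible out-of-order position) — and `parse_diagnosis()` flags these
in validation mode rather than silently correcting them.

## Evolutionary distinctness and group comparison

Fair-proportion ED splits every branch equally among the tips it
supports: $ED(i) = \sum_{e \in \text{path}(root,i)} len(e)/n(e)$. This
matches the verbal definition "terminal branch length corrected for the
species richness of the containing clade" and has the conservation
identity $\sum_i ED(i) = $ total tree length, which the tests assert on
500 random trees. Units follow the tree (substitutions/site here; Myr on
a chronogram). The Mann–Whitney rank-sum comparison between species
groups is implemented internally so that small samples get an exact
enumeration (both $n \le 8$; ties handled by permutation) and larger ones
a tie- and continuity-corrected normal approximation; both routes are
cross-checked against the standard implementation in the tests.

## Range metrics, richness and conservation ranks

Coordinates are WGS84 decimal degrees; no datum transformations are
attempted. Range area is the convex hull of a species' sites, projected
with a Lambert azimuthal equal-area projection about the sites' centroid
(equal-area being the defensible projection for areas; results are then
reproducible bit for bit), with the hull by Andrew's monotone chain and
the area by the shoelace formula; fewer than three non-collinear points
give 0 km². Maximum range diameter is the greatest haversine distance
(Earth radius 6371.0 km — site-scale precision far below the 1 km
reporting granularity). Endemism classes are single-site and two-site by
count, then area bins with left-inclusive edges (<500, 500–5000,
>5000 km²; 5000 km² is the range size below which a species qualifies as
range-restricted in Red List criterion B thinking).

Conservation ranks combine endemism and ED in a quadrant rule — (1) high
endemism and ED, (2a) low endemism/high ED, (2b) high endemism/low ED,
(3) both low. Defaults: endemism is high at ≤2 sites or <500 km²; ED is
high above 0.075, low below 0.045 (the observed tertiles of the genus-
wide distribution), and intermediate values resolve at 0.060. All
thresholds are configurable, deliberately: the published ranks are not
reproducible under any single cutoff rule (the printed table contains
mutually inconsistent borderline calls), so the package states its rule
explicitly and reproduces the unambiguous rows rather than force-fitting
the rest.

Richness accounting maps every revised species back to its nominal name
and compares alpha diversity per site and species counts per country and
drainage basin under both taxonomies. The accounting identity — the
summed per-site increase equals the number of syntopy increments — is a
standing test.

## The synthetic-data generator

`simulate_truth_bundle()` generates the benchmark the delimitation claims
are tested on. A pure-birth species topology gets branch lengths from
Exp(rate 12.5) (mean 0.08 substitutions/site — deep enough for clear
species boundaries, shallow enough that genus-scale path sums stay below
K2P saturation); each species tip is replaced by a subtree over its
sampled individuals with lengths from Exp(rate 8000) (mean
1.25 × 10⁻⁴ — species are tight clusters of near-identical haplotypes).
Sequences evolve site-independently under the K80 transition matrix
(default κ = 4 for the barcode locus), so the K2P estimator is correctly
specified and parameter-recovery tests have an analytic target. Defaults
(16 species × 4 individuals, COI 658 bp + three nuclear loci) mirror a
realistic barcoding design for a sampled species complex.

After generation, the bundle asserts its own divergence structure on the
barcode alignment: all pairs below saturation, maximum intra-specific K2P
< 1%, minimum inter-specific > 4%. Draws failing the assertion are
regenerated from the next derived seed (drawn from the seed's own RNG
stream) with the retry count reported — the benchmark *is* the stated
divergence regime, not the unconditional model. Geography places each
species' sites uniformly in disjoint geodesic discs; syntopy is planted
by merging one site of one species into a site of another, so detection
has a known truth.

What the generator does not emulate — and hence what passing tests do not
show about real data: alignment error and indel placement, rate variation
across sites and lineages (no Γ heterogeneity, no codon structure),
introgression and incomplete lineage sorting, uneven sampling effort, and
real karst geography (countries and basins are labels, not spatial
joins). Delimitation performance on the benchmark is therefore an upper
bound, not a field guarantee; on real data the multi-evidence consensus
and the sharing screen carry the weight.

## Benchmark scales and observed behaviour

The standing tests run the 16-species benchmark over 20 seeds (threshold
clustering recovers the true partition in 20/20; the end-to-end PTP route
lands within ±1 species in ≥90%), the brute-force PTP oracle over 200
random ≤8-tip trees, and the ED identity over 500 random trees — sizes
chosen so the full suite completes in about a minute while every claim
retains a margin. Exact ML-PTP on estimated haplotype trees does
occasionally return 17 rather than 16 species (a single haplotype on an
inflated terminal branch gets expelled from its species), and a species
that is non-monophyletic on the estimated tree can only be recovered as a
likelihood tie — both are properties of the model on estimated trees, not
of the search, which provably attains the optimum on the tested scales.

## Known limitations

* PTP is fitted in its single-tree ML form; Bayesian support is replaced
  by multi-restart agreement.
* The multilocus coalescent (BPP-style) is out of scope; the
  haplotype-sharing screen is the package's operational multilocus check.
* Diagnoses implement pure character attributes only (no majority-rule
  "private" attributes), against a flat comparison set.
* Threshold clustering with single linkage can chain through
  intermediates; the complete-linkage option is provided for that case.
* Published alignment-specific diagnosis coordinates cannot be
  regenerated without the original alignments; the packaged table is a
  format/parse fixture, not a recomputation target.
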