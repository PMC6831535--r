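---
title: "Gridded fern and lycophyte diversity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gridded fern and lycophyte diversity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pteridodiv)
```

## The problem

Japan's fern and lycophyte flora — on the order of 700 native taxa plus
several hundred named interspecific hybrids — is one of the most densely
collected pteridophyte floras in the world. Decades of specimen vouchering
make it possible to map presence at a 10-km resolution across the whole
archipelago, and to ask quantitative questions: where are richness and
phylogenetic diversity concentrated, are apomictic (asexually reproducing)
taxa more narrowly distributed than sexual ones, and how do phenology and
ploidy relate to range size?

`pteridodiv` implements that analysis as a reusable pipeline over three
inputs: a trait-annotated checklist, a presence-only occurrence table keyed
by grid-cell code, and a rooted reference phylogeny with branch lengths
(an rbcL tree in the motivating use). A synthetic-data generator produces
all three with the same statistical structure, so every stage of the
pipeline is testable without the original deposited files.

## The 10-km mesh

Occurrences are georeferenced only by Japan's standard area mesh. A 6-digit
secondary mesh code `PPQQRC` addresses a cell of exactly 1/12 degree of
latitude by 1/8 degree of longitude (5' x 7.5', roughly 10 km x 10 km):

* south-west corner latitude = `PP / 1.5 + R / 12` degrees north,
* south-west corner longitude = `100 + QQ + C / 8` degrees east.

The arithmetic was validated against named localities of printed codes
(Yakushima Island, the Nachi Falls area in southern Wakayama, northern
Okinawa, Iriomote), all four of which decode into their localities'
bounding boxes. Codes are carried as strings so leading zeros survive, and
only the 6-digit level is accepted — every code in the motivating dataset
is secondary mesh.

Cell **centroids** are the canonical per-cell coordinate. For latitudinal
breadth (max minus min occupied latitude) the choice is immaterial — a
constant half-cell offset cancels — which is exactly why centroids are safe
to standardise on.

## Checklist conventions

All denominators trace back to the checklist:

* *native taxa* = non-hybrid species + subspecies + varieties; hybrids
  (nothotaxa) are counted separately and excluded from every trait
  comparison;
* trait values may be `"unknown"`; unknown values are excluded from any
  denominator described as "whose ... is known" and are never imputed;
* percentages are printed at one decimal using round-half-away-from-zero,
  the convention that reproduces every published one-decimal figure from
  its printed counts.

The apomixis rate is the share of apomicts among known-mode native taxa.
Taxa capable of *either* reproductive mode form their own small group in
range comparisons; whether they belong in the apomixis-rate numerator is
genuinely ambiguous, so both conventions are exposed
(`apomixis_rate(table, include_both = )`). The default excludes them: with
the flora's published group sizes (79 strictly apomictic among ~721
known-mode natives) that convention reproduces the published 11.0% rate,
while including either-mode taxa gives 12.1%.

## Faith's PD and the root

PD of a cell is the total branch length of the minimal subtree connecting
the cell's taxa on the reference tree. Two conventions exist for "excluding
the root" when the cell's taxa sit on one side of the tree:

* **default**: root the pruned subtree at the retained tips' most recent
  common ancestor and discard the residual edge above it (the common
  unrooted-PD convention);
* `keep_root_path = TRUE`: keep the path from the MRCA up to the tree's
  original root (the root edge itself is never summed).

Both are implemented because the verbal description "trimming the tree and
summing the branch lengths, excluding the root" does not distinguish them;
real data can arbitrate. PD is *undefined* — a value, not an error — for
cells with fewer than two in-tree taxa. Taxa without a tip (incomplete
rbcL sampling, about 2% in the motivating data) count toward richness but
are dropped from PD, with per-cell dropped counts reported in the layer
metadata.

The implementation marks each edge with the number of retained tips below
it in one postorder pass; edges with count strictly between zero and the
number of retained tips are exactly the spanning subtree below the MRCA.
The per-cell map vectorises this as a sparse edge-by-tip incidence matrix
multiplied against the presence matrix in blocks of 1024 cells. Tests
verify exact agreement with an independent brute-force oracle that marks
tip-to-MRCA paths via `ape`'s `nodepath`, on 1,000 random tree/subset
instances, and with `picante::pd` on pruned subtrees.

## Group comparisons

Range metrics (occupied cells; latitudinal breadth in degrees) are compared
across reproductive mode, phenology, and ploidy. Exclusion rules: hybrids
out everywhere; unknown trait values out; the ploidy comparison restricted
to sexual taxa, because apomicts are dominated by triploids and would
confound it. Groups reduced below two members are dropped with a warning.

Two groups are compared with **Student's pooled-variance t** — named
explicitly in the motivating analysis — with Welch's form behind
`pooled = FALSE`, since the observed group spreads are very unequal. Three
or more groups get one-way ANOVA plus **Tukey's HSD** (Tukey–Kramer
standard errors for unequal n). All three statistics are implemented from
the classical formulas rather than wrapped, because the package treats them
as part of its tested surface; unit tests require agreement with
`stats::aov`, `stats::TukeyHSD` and `stats::t.test` to 1e-6 and a type-I
error rate inside the 95% binomial band of nominal 0.05 over 2,000 null
simulations each.

The studentized-range CDF — the one ingredient without a simple closed
form — is integrated numerically: the inner integral (CDF of the range of
k standard normals) and the outer mixture over the scaled-chi distribution
of the standard-deviation estimate are both evaluated with fixed
Gauss–Legendre rules (160 and 120 nodes). Agreement with independent
implementations is ~1e-12 across k = 2–8 and 2–1000 degrees of freedom,
tighter than `stats::ptukey` itself in small-df tails.

Compact letter displays use the insert-and-absorb algorithm at a family
level of 0.05. The motivating figure caption prints the threshold as
"P < 0.5", which we treat as a typo for 0.05; the level is configurable
(`alpha`) rather than silently corrected.

## The synthetic generator

`sim_config()` defaults *are* the study conditions: 721 native taxa plus
371 hybrids; 11% apomicts and 1.1% either-mode taxa (reproductive mode
known for all natives, so the realised apomict count of ~79 reproduces the
published 11.0% rate); 45% polyploids among sexual taxa; 75% evergreen;
17.3% endemism; a 35.4% red-list fraction split 7:2:82:59:67:37:1 across
EX:EW:CR:EN:VU:NT:DD; 2.1% of natives missing from the tree; and group
latitudinal-breadth distributions of 7.62 ± 5.02 degrees (sexual and
either-mode) versus 5.93 ± 3.77 (apomictic). Values not fixed by the
motivating study were chosen once as field-plausible: an 8% lycophyte
share, range centers normal around 33°N (sd 4°), apomict centers shifted 2°
south and seasonal-green taxa 4° north (the directions the flora shows),
exponential rbcL-like branch lengths with mean 0.02 expected substitutions
per site, and a within-band occupancy density of 0.02, which yields mean
range sizes of a few hundred cells, the observed order of magnitude.

The frame is a rectangular band of secondary mesh cells spanning 24–46°N x
123–146°E (48,576 cells) — the archipelago's latitude span without its
coastline. Occupancy is sampled independently per cell within each taxon's
latitude band. Two consequences matter for interpreting green tests:

* there is **no spatial autocorrelation**, so synthetic richness peaks are
  far flatter than real ones (tens of taxa per cell rather than the real
  maximum of 216) — passing tests show the *accounting* is right, not that
  the generator reproduces Japan's diversity hotspots;
* the band has no coastline mask, so occupancy percentages run higher than
  the real frame's 89.5%.

Everything is deterministic given `seed`: the checklist, tree and
occurrence generators draw from seed, seed+1 and seed+2 respectively, so
each stage is individually reproducible.

## Numerical and degenerate-input choices

* Mesh codes must be exactly six digits; anything else is a malformed-code
  error naming the offending value. Encoding clamps floating-point edge
  hits into the correct cell.
* Deduplication of occurrence records is idempotent; the pre-deduplication
  row count is preserved as provenance. Unknown taxon ids are an error that
  lists the offenders — never a silent drop.
* `top_cells` breaks ties by ascending cell code so rankings are
  deterministic.
* Proportion layers are undefined (NA), not zero, over empty denominators;
  a numerator exceeding its denominator is a consistency error.
* Zero-variance statistical inputs take their limiting values (F = 0 and
  p = 1 for identical groups; pairwise Tukey p exactly 1) rather than NaN.
* The total-cell denominator for occupancy is configuration, never
  inferred: presence-only data cannot reveal never-visited cells.

## Problem sizes used by the test suite

The suite exercises full study-scale conditions where the check needs them
(mesh round trips over all 48,576 frame cells; 1,000 random PD instances;
2,000 null simulations per test statistic; 200 replicates of the
breadth-effect detection at group sizes 413/79/8, plus a dozen end-to-end
pipeline replicates at the full 721 + 371-taxon default; parameter recovery
at 2,000 taxa) and reduced frames (80 taxa over a 6° x 5° band) for unit
tests where only correctness of the accounting is at stake.

## Limitations

* No geodesic areas, datum transforms, or 1-km mesh; the mesh module is
  deliberately limited to the 6-digit level the data use.
* No spatial autocorrelation or environmental covariates in the generator.
* PD is the only phylogenetic diversity metric; MPD/MNTD/endemism-weighted
  variants are out of scope.
* Latitudes are cell-based; specimen-level coordinates (which would break
  the centroid/corner equivalence) are not supported.
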