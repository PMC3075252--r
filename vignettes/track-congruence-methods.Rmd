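---
title: "Track congruence: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track congruence: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geotracks)
```

## The model

A species' distribution is summarised as its **individual track**: the
minimum spanning tree (MST) of its occurrence points under planar
Euclidean distance in decimal-degree space. Several individual tracks
that run along the same spatial corridor are summarised as a
**generalized track**, the panbiogeographic proxy for an ancestral
biota's range. The analytical core is therefore (a) a deterministic MST
construction, (b) a geometric decision procedure for whether two MST
segments are spatially congruent, and (c) a length-based similarity
index that collapses redundant tracks.

Two modelling assumptions deserve emphasis:

* **Planar, not geodesic.** Latitude and longitude are treated as plain
  Cartesian coordinates, and every distance — the cut value, the
  congruence bounds, track lengths — is Euclidean in degrees. The
  distance thresholds only make sense on that scale. This is adequate
  for regional analyses away from the poles; at high latitudes a degree
  of longitude shrinks, and the analysis inherits that distortion.
  Great-circle distances and antimeridian wrap-around are out of scope.
* **Congruence is pairwise and segment-based.** Tracks interact only
  through their edges; single-vertex tracks (a species whose points all
  collapse under the cut value) can never be congruent with anything.

## Parameters

All five parameters are set by the user; there are deliberately **no
default distance values**, because sensible magnitudes depend entirely
on the spatial scale of the data (a 2° cut value is coarse for a single
valley and fine for a continent). The constraining rule
`cut_value ≤ lmin ≤ lmax ≤ lmax.line` is enforced before any data is
read, and violations name the violated inequality.

| parameter | unit | role |
|---|---|---|
| `cut_value` | degrees | radius below which a species' points collapse to one |
| `lmin` | degrees | rule 1 bound on the minimum endpoint-projection distance |
| `lmax` | degrees | rule 1 bound on the maximum endpoint-projection distance |
| `lmax_line` | degrees | rule 2 bound on the foot distances under full overlap |
| `min_si` | fraction | similarity threshold at which two tracks merge |

Rule 2 exists to admit laterally offset but fully aligned segments:
two parallel segments 3.5° apart fail rule 1 whenever `lmin < 3.5`,
yet pass rule 2 as long as `lmax_line ≥ 3.5`, because each endpoint of
one projects perpendicularly onto the other. The ordering constraint
makes rule 2 the *looser* criterion, which is why it is evaluated
first; the congruent/non-congruent outcome does not depend on the
evaluation order, only the reported rule label does.

## Geometric conventions

Several small decisions fix behaviour where the geometry is ambiguous;
they are all centralised in the kernel:

* `dmin`/`dmax` are taken over the **four endpoint projections** (each
  endpoint of each segment onto the other), symmetrically. For
  non-crossing segments the true minimum set distance is attained at an
  endpoint projection anyway; for properly crossing segments `dmin` as
  defined stays positive even though the segments touch — congruence of
  crossing segments is then carried by rule 2, as the full-overlap
  pattern holds.
* A projection parameter in `[0, 1]` within a tolerance of **1e-9
  degrees** counts as a perpendicular foot, so segments sharing a
  vertex are "touching" rather than knife-edge non-congruent. The same
  tolerance pads the comparisons against `lmin`/`lmax`/`lmax_line`.
* Under full overlap, `dmax_line` is the larger of the two foot
  distances on the side that achieves full overlap; when **both**
  directions achieve it, the smaller of the two side-maxima is used —
  the most permissive reading consistent with the either-direction
  definition of full overlap.
* Zero-length segments are treated as points: they can satisfy rule 1
  through their point projections but can never produce full overlap,
  which requires two distinct endpoint feet.

## Determinism

The analysis is bit-reproducible for a given input order:

* The MST is Kruskal's algorithm with ties between equal-length edges
  broken in favour of the lexicographically smaller vertex-index pair.
  Tie-broken *edge sets* may differ between permutations of the input,
  but total length may not (it is the spanning-tree minimum, verified
  against exhaustive enumeration in the tests).
* Point thinning is a greedy single pass in input order: a point is
  dropped iff it lies within the cut value of an already-retained
  point, and the retained point is always the cluster's first original
  coordinate (no centroid averaging). This makes thinning idempotent
  and order-deterministic. One counterintuitive consequence, pinned by
  a regression test: raising the cut value does not *guarantee* fewer
  retained points, because removing an early "blocker" can free
  several later points.
* Candidate generalized tracks are generated over species pairs in
  input order; similarity reduction always merges the currently most
  similar pair (ties by lexicographic taxa label) and terminates
  because every merge reduces the candidate count by one. Merging
  additionally requires a strictly positive similarity, so with
  `min_si = 0` the candidates collapse exactly to the connected
  components of the pairwise-congruence graph rather than to one blob.
* After the fixed point, any candidate whose taxa are a subset of
  another survivor's and whose directed similarity toward it still
  reaches `min_si` is discarded as redundant; with the fixed-point
  reduction in place this cleanup is rarely triggered, but it keeps the
  output free of a track plus its own sub-track.

A performance note: a track pair whose bounding boxes are separated by
more than `lmax_line` is skipped without comparing segments. This is
exact, not heuristic — both rules imply `dmin ≤ lmax_line`, and `dmin`
is bounded below by the bounding-box gap — so the shortcut cannot
change any result.

## The synthetic corridor generator

`simulate_corridors()` builds datasets whose generalized-track
structure is known by construction: each corridor is a polyline, each
of its species samples points uniformly by arc length (optionally over
a sub-range, to exercise the asymmetry of the similarity index), and
isotropic Gaussian jitter with a standard deviation in degrees is
added. Gaussian noise was chosen over uniform as the conventional model
of coordinate error; the default benchmark uses 3 straight corridors
50° apart, 10 species per corridor, 30 points per species and jitter
0.1°, with the reference parameter set (cut 2, lmin 2.5, lmax 3,
lmax.line 4, min-SI 0.8). At 50° separation against a 4° `lmax_line`,
cross-corridor congruence is geometrically impossible, so exact
recovery (three tracks, pure taxa partitions) is the expected outcome
and is what the acceptance checks assert.

What the generator does **not** emulate: spatial autocorrelation,
sampling bias along roads and rivers, taxonomic misidentification, and
curved corridor geometry interacting with coastline constraints.
Passing the recovery tests therefore shows the machinery is correct on
clean corridor structure, not that any particular empirical dataset
will yield clean generalized tracks.

## Problem sizes and numerical checks

The test suite verifies the MST against exhaustive enumeration of all
labelled spanning trees (Prüfer sequences) for point sets of 3–8
points, the point–segment distance against the analytic
perpendicular/endpoint formula on 10,000 random pairs at 1e-9, the
congruence rules against a hand-derived truth table of 14 segment
configurations, and the full pipeline on the corridor benchmark above.
The acceptance script re-runs the corridor benchmark at 900 records and
the kernel oracles at 60 and 10,000 cases — sizes chosen so the whole
cycle completes in about a minute on a single core while still
exercising every branch of the geometry.

## Known limitations

* Planar degrees only (see above); no map projections.
* Node detection — the intersections *between* generalized tracks —
  is not implemented; the output stops at the generalized tracks
  themselves.
* The similarity numerator counts a whole edge once it is congruent
  with any edge of the other track; no partial-length proration is
  attempted.
* Taxon names are matched as exact strings. Near-identical names
  (case or underscore variants) produce a warning, never a silent
  merge.
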