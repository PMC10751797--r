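---
title: "Classifying molecular transition pathways by string matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying molecular transition pathways by string matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathstrings)
```

## The problem

A molecular process — a conformational change, a binding event — usually
proceeds from a source metastable state to a target state along more than
one mechanistic route. Trajectories sampling these transitions (from
conventional MD or from weighted-ensemble path sampling) are diverse and of
highly variable length, which defeats naive geometric clustering.

`pathstrings` takes a linguistics view. Configuration space is discretized
into a small set of states; each successful transition (from the **last**
exit of the source to the **first** entry of the target) becomes a text
string of visited states; strings are compared with a length-corrected
Gestalt similarity; and the resulting distance matrix is clustered with
Ward-linkage hierarchical agglomeration. Classes, their probabilities
(summed pathway weights), event-duration distributions, and a directed
state-transition network summarise the mechanism.

## The similarity score

For pathway strings $A$ and $B$ with lengths $L_A$, $L_B$ and longest
common subsequence of length $LCS$:

$$\mathrm{similarity}_{AB} = \frac{2\,LCS}{L_A + L_B}$$

is the raw Gestalt-style score (maximum 1, attained only for identical
strings). Molecular pathways can differ in length by an order of magnitude,
and then the raw score is dominated by the length mismatch rather than by
the shared state sequence. The corrected score shrinks the denominator by
half the length difference:

$$\mathrm{similarity}_{AB} = \frac{2\,LCS}{L_A + L_B - |L_A - L_B|/2}$$

so a long string sharing a rich common subsequence with a short query can
outrank a same-length string sharing almost nothing. The correction term
vanishes for equal lengths. Distances are $d = 1 - \mathrm{similarity}$.

```{r similarity}
gestalt_similarity("ABCDEFGHIJ", "ABCDEFGHIXY")$value   # 2*9/20.5
round(gestalt_similarity("ABCDEFGHIJ", "ABCDEFGHIXY")$value, 2)
```

Two matching notions are available: the true longest common subsequence
(dynamic programming; the default) and the classical Ratcliff–Obershelp
recursive matching-blocks count (`method = "matching-blocks"`). Both agree
on the worked example above; they differ when common symbols are
interleaved, and LCS is the documented default because the score's
definition speaks of a common *subsequence*. Scores are kept at full
floating precision; rounding (e.g. the 0.88 above) happens only at
reporting time.

## Condensation

Dwell times inflate strings with repeats (`112211122211` …) that mask the
route. `condense(s, k)` collapses immediate repetitions of blocks of length
$1 \dots k$, smallest block first, each size to a fixed point, repeating
the sweep until the whole string is a fixed point — so the result is
idempotent by construction:

```{r condense}
condense("11221112221122", 1)
condense("11221112221122", 2)
```

Level 2 (`condense_level = 2` in `pairwise_distances()` and
`class_report()`) yields the fundamental sequence of states with dwell
times disregarded. Condensation affects matching only: extraction filters
(below) and event durations always see the uncondensed frames.

## Discretization

Three assignment routes:

* **Rectilinear bins + points** (`state_map_rectilinear()`,
  `assign_rectilinear()`): per-dimension bin edges plus one representative
  point per state; the bin containing the point *is* the state, all other
  bins are unassigned (sentinel `-1`). Two points in one bin are rejected
  at map construction.
* **User hook** (`assign_hook()`): any function from a frame batch to
  integer labels, validated against the declared state set.
* **Two-stage cluster-then-classify** (`fit_two_stage()`,
  `predict_two_stage()`): average-linkage agglomerative clustering of a
  *subset* of conformations, cut at a distance threshold, then a
  k-nearest-neighbour classifier (default $N = 5$) labels the remainder.
  This sidesteps the memory cost of clustering every frame of a large
  simulation. The threshold is scale-dependent (75 suits torsion angles in
  degrees with well-separated basins) and is deliberately exposed as a
  parameter rather than defaulted. The agglomerative dissimilarity is
  Euclidean — unstated upstream, assumed and documented here. Ties in the
  neighbour vote break toward the smallest cluster id, and equidistant
  neighbours toward the lowest training-row index, so labelling is
  deterministic.

Periodic torsion coordinates should be remapped before any Euclidean step
so the branch cut avoids populated regions, e.g. ϕ from $[-180, 180)$ to
$[-210, 150)$:

```{r remap}
remap_periodic(160, 360, -210)
```

## Extraction

`extract_cmd()` scans a label series for every successful transition with
**last-exit / first-passage** semantics: re-entering the source restarts
the clock, recrossings after the first target entry are ignored. The
pathway string excludes the source dwell but includes the single arrival
symbol, so at stride 1 the string length equals the event duration in
frames. `--stride`-style subsampling keeps every *n*-th frame anchored at
the arrival frame (the target symbol is always retained), giving
$\lceil L/s \rceil$ symbols.

For weighted-ensemble trees (`trajectory_tree()`, `extract_we()`), each
segment in whose own frames a target entry occurs emits one pathway: its
lineage is traced to the root, the last source exit located, and the
pathway weighted by the arriving segment's weight at the arrival
iteration. Arrivals sharing history are each counted once (standard WE
accounting); lineages recycled through the source can arrive repeatedly.
This convention makes WE extraction on a one-walker tree agree
string-for-string with `extract_cmd` on the flattened labels — an identity
the test suite asserts. Ancestor-sharing pathways are *not* deduplicated
before matching; each arriving segment is one pathway, documented here
because the alternative (deduplication) would change class probabilities.

Pathways shorter than 10 frames trigger an alert (and a second alert when
they exceed 25% of the ensemble); `exclude_length` drops pathways with
fewer symbols than the threshold. Filtering never sees condensed strings.

## Clustering and class summaries

Ward linkage is applied directly to the $1 - \mathrm{similarity}$ matrix.
These distances are not a Euclidean embedding, so merge heights are
ordinal, not geometric — exactly the prescribed procedure, documented as
such. `suggest_cut()` places the dendrogram cut at the midpoint of the
largest gap between consecutive merge heights (ties toward fewer classes,
since cutting too low yields classes with redundant features); the cut is
advisory and any `cut_height`/`n_classes` override is honoured. Classes
are numbered by decreasing total pathway weight so "class 1" is stable
across reruns. Guardrails are warnings, not errors: fewer than 3 states,
fewer than 50 pathways, any class under 10 members.

`class_report()` bundles the distance matrix, linkage, cut, per-class
probabilities (summed weights), full event-duration lists, and the
directed network of condensed transitions with edge/node weights.

## The synthetic world

The generators state a small, fixed validation world; they are first-class
tested code, not throwaway fixtures.

* `default_route_spec()`: six states, source 0, target 5, an upper route
  0–3–4–5 with probability 0.875 and a lower route 0–1–2–5 with 0.125 —
  the scale (6 states, 2 routes, 80 pathways) of a small-peptide
  conformational-transition benchmark. Dwell times are geometric with mean
  3 frames (the simplest memoryless model consistent with Markovian state
  dynamics; mean 3 makes dwell repeats common enough that condensation
  matters). With probability 0.05 per frame a trajectory takes a one-frame
  excursion to an off-route state — enough noise that strings within a
  route differ, small enough that condensed strings remain
  route-discriminating; excursions are single-step by design so they can
  never fabricate the other route's discriminating transition.
* `generate_blobs()`: isotropic Gaussian clouds around six centroids in a
  remapped angle plane (σ = 15° in the tests, a realistic torsional
  fluctuation), for the two-stage discretizer.
* `generate_we_tree()`: walkers of the same route dynamics with a
  deterministic split-heaviest / merge-two-lightest resampler, so weights
  sum to exactly 1 every iteration and the segment table forms a genuine
  tree. The target is absorbing.

What a green test establishes: that the machinery recovers route counts,
route probabilities (within binomial error) and memberships on a Markovian,
noise-perturbed world whose ground truth is known. What it does not: real
trajectories are not Markovian in the projected coordinates, state
boundaries blur transitions, and route probabilities from path sampling
carry correlated-weight error none of which the generator emulates.

## Numerical choices

* Degenerate inputs: empty-vs-empty string comparison is an error; a
  length-1 pathway scores but is flagged by the extraction alerts; an
  all-equal-heights dendrogram returns one class with a warning.
* `-1` (unassigned) labels inside a transition are an error naming the
  frames; outside transitions they are tolerated.
* Determinism: every stochastic step is seeded; identical config + seed
  gives byte-identical artifacts (asserted in the pipeline tests).
* State ids map to a 94-character printable alphabet for display, spilling
  into higher Unicode code points beyond 94 states, so string operations
  stay per-symbol correct for any state count.

## Known limitations

* Ward heights on non-Euclidean distances have no variance interpretation;
  compare cuts, not heights, across data sets.
* The max-gap cut is a heuristic; inspect the merge table (exported as
  CSV) before trusting an automated class count.
* CSV/JSON are the only interchange formats (no NPY/HDF5 here); trees
  beyond ~10^5 segments will be slow to parse as CSV.
* No plotting: summaries are emitted as data for standard graph/plot
  tools.
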