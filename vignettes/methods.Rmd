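---
title: "Drawing accurate area-proportional 3-Venn diagrams with ellipses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drawing accurate area-proportional 3-Venn diagrams with ellipses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apvenn)
```

## The problem

A 3-Venn diagram represents three sets by three closed curves whose
overlaps realise all seven non-empty intersection regions. In an
*area-proportional* diagram the area of each region is directly
proportional to a quantity attached to its set relation — a gene count, a
patient number, a proteome overlap. Such diagrams cannot in general be
constructed analytically for a prescribed quantity vector, and circles
(three degrees of freedom per curve) provably cannot realise most 3-set
quantity vectors. Ellipses add two degrees of freedom per curve (a second
semi-axis and a rotation) while staying smooth and easy to tell apart.
`apvenn` fits three ellipses to a seven-component quantity vector
`w = (w_a, w_b, w_c, w_ab, w_ac, w_bc, w_abc)`, all components strictly
positive, by deterministic local search.

Quantities are first scaled by `100 / min(w)` (`scale_quantities()`), so
proportional inputs give identical diagrams and the scaled quantity of a
region is its required area in squared canvas units. All default step
sizes below are expressed in these units, which keeps them commensurate
with diagram size for any input magnitude.

## Exact region areas

The geometric core computes the seven region areas of three overlapping
ellipses analytically.

*Intersection points.* Each ellipse is an implicit conic. To intersect a
pair, the first ellipse is mapped to the unit circle (translate, rotate,
anisotropic scale); the second becomes a general conic
`AAx² + BBxy + CCy² + DDx + EEy + FF = 0`, and eliminating `y` against
`x² + y² = 1` yields a quartic whose real roots in [−1, 1] are the
intersection abscissae. Roots are taken from the eigenvalues of the
companion matrix — far more robust than closed-form quartic formulas —
then polished by 2-D Newton iteration on the two implicit equations and
deduplicated at `1e-9` in the normalised frame. Candidate eigenvalues with
imaginary parts up to `1e-4` are kept: a repeated real root (two circles
always produce one) perturbs into a conjugate pair with imaginary part of
order √ε, and the Newton/residual stage discards any spurious candidate.
A contact point is classified *tangential* when the two conic gradients
are parallel to within `1e-8`; tangential contacts never count as
crossings.

*Areas.* By Green's theorem the area enclosed by a piecewise boundary is
`½∮(x dy − y dx)`. For an elliptical arc from parameter `t₁` to `t₂` this
integral has the closed form `½[s₁s₂(t₂−t₁) + cx·Δy − cy·Δx]`. A pairwise
overlap is bounded by the arcs of each ellipse interior to the other; the
triple overlap by the arcs of each ellipse interior to both others. Arc
selection tests the arc midpoint against the partner conics; containment
and disjointness fall out naturally (a curve with no boundary crossings
contributes either its full area or nothing, decided by a tolerant
boundary-point test so the coincident limit counts as containment). The
seven region areas follow by inclusion–exclusion, e.g.
`A(a) = area(a) − I_ab − I_ac + T`. Round-off can leave tiny negative
region values; anything above `−1e-9` of the total is clamped to zero,
anything worse marks the result numerically inconsistent (and the diagram
invalid).

## Topology validation without an arrangement graph

`validate_topology()` accepts a diagram iff (i) every ellipse pair crosses
transversally in exactly two points and (ii) all seven region areas exceed
`1e-12` of the total diagram area. Condition (ii)'s floor is deliberately
far below the smallest region share the optimizer must handle (a few
1e-5 of the total).

These two conditions also rule out split zones, which a sampling or
arrangement-graph check would otherwise have to find: with three curves
and exactly two transversal crossings per pair the curve arrangement has
`V = 6` vertices and `E = 12` edges (each boundary is cut into four arcs),
and since pairwise-crossing curves make the arrangement connected, Euler's
formula gives exactly `F = E − V + 2 = 8` faces. Inclusion–exclusion areas
are exact indicator-function identities, so a positive area for each of
the seven interior signatures means each signature owns at least one face;
with only eight faces (one being the unbounded exterior) each signature
owns exactly one — no region can consist of two zones. This makes the
check O(1) on top of the area computation, which matters because the
optimizer validates every candidate move.

## The goodness measure and the cost

`regionError(r) = |A(r)/ΣA − w(r)/Σw|` compares area *shares*, not
absolute areas, so an error in one region does not masquerade as errors in
the others; `diagError` aggregates by the maximum over the seven regions
and always lies in [0, 1]. A diagram is *good* when it is a valid 3-Venn
topology and `diagError ≤ 1e-6` — the same epsilon other drawing tools use
as their numerical zero. The maximum (rather than mean) aggregation is a
design choice: it bounds every region's share error by the acceptance
threshold, which is the semantics the goodness definition needs.

The search itself minimises a different quantity, `cost_F6`: the mean over
regions of `(w'(r) − A(r))²/A(r)` against the scaled quantities. Working
on absolute scaled areas (not shares) keeps early, coarse moves
productive, and the `1/A(r)` factor makes the cost of a vanishing region
blow up, closing off the classic local-minimum path in which total error
is reduced by squeezing one region towards zero. Any move that produces a
non-positive region or an invalid topology scores `+Inf` and is never
accepted — one sentinel implements both the anti-collapse behaviour and
topology safety. The dimensionless variants `cost_F7` (`/A²`) and
`cost_F8` (absolute difference, `/A`) are provided for comparison;
both down-weight large errors when areas exceed one and are known to be
less effective, so the optimizer does not use them. `stress()` — the
normalised residual sum of squares about a through-origin regression of
areas on quantities — is included as a reporting metric for comparisons
with circle-based statistical fitting, with
`β = ΣA·w / Σw²` (the through-origin least-squares convention).

## The starting diagram

Local search needs a good start. Arbitrary random starts would make the
tool non-deterministic; symmetric invariant starts ignore the data. The
rational start uses three circles (so every later rotation is meaningful,
the circles get rotations 0, π/3, 2π/3):

1. The two curves with the largest required totals
   (`total(x) = w(x) + w(xy) + w(xz) + w(xyz)`, ties broken `a < b < c`)
   are drawn as an *exact* two-set area-proportional diagram: radii
   `r = √(total/π)`, separation found by bisection of the circular-lens
   area, which decreases strictly and continuously in the separation
   (tolerance `1e-10` relative, 200 iterations).
2. The third circle's centre lies on the line `L` bisecting the angle
   between the tangents to the first two circles at their upper
   intersection point, directed into the lens. Marching along `L` in steps
   of `r₃/50` and bisecting each topology change (40 steps) brackets the
   interval on which the third circle crosses both circles twice and all
   seven regions exist; within it, a golden-section search places the
   centre to minimise `|A(abc) − w'(abc)|` (relative tolerance `1e-6`).
   Golden-section is used rather than sign bisection because the
   discrepancy is an absolute value — unimodal but unsigned — and it
   reduces to the same answer whenever a sign change exists. If no
   feasible interval exists the centre falls back to the lens midpoint
   with a warning.

Changes to any ellipse later affect the triple region, so starting with
`A(abc)` on target measurably shortens the search. In practice the line
search hits its target to ~1e-7 relative whenever the target is attainable
along `L`.

## The optimizer

One hill-climbing run (`hill_climb()`) repeats, until termination:

* for each curve `a`, `b`, `c` in order: try the eight centre moves
  (`±pγ` on one or both coordinates, order E, W, N, S, NE, NW, SE, SW),
  then the eight semi-axis moves (`±pαβ` on one or both axes, same-sign
  and opposite-sign), then the two rotations (`±pθ`); each candidate that
  strictly reduces `cost_F6` is applied immediately, so later candidates
  see the updated diagram;
* after the sweep, halve every step parameter whose move class saw no
  accepted change on any curve (the halving cooling schedule: coarse
  exploration first, refinement later);
* stop *accurate* as soon as the diagram is good, *inaccurate* once
  `pγ, pαβ, pθ ≤ 1e-6`.

Defaults `pγ = 10` canvas units, `pαβ = 5 %`, `pθ = 2π/3`. The enumeration
orders and the curve order are fixed so the search is fully deterministic;
there is no randomness anywhere in the fit. In circle mode only the two
uniform semi-axis scalings are tried and rotations are skipped; `pθ` still
halves every iteration so termination behaves identically. A safety cap of
20 000 iterations per run exists but is unreachable in practice (the cost
strictly decreases over an acceptance-bounded move set).

`fit_venn3()` wraps the runs: if a run ends inaccurate (a local minimum)
and reruns are enabled, the search restarts from a fresh starting diagram
with all three *starting* step parameters multiplied by 1.2 relative to
the previous run — compounding, i.e. run `k` starts at defaults × 1.2^k —
up to 10 reruns; the first accurate diagram, or failing that the
minimum-`diagError` diagram of all runs, is returned. An audit log of
accepted moves (iteration, curve, move class, cost before/after) is
available at `audit = TRUE`; the accepted-cost sequence is strictly
decreasing by construction and the tests assert it.

## Synthetic data generators

Two generators emulate the evaluation libraries used to validate this
style of drawing method:

* **L1 (drawable)** — sample three ellipses with centres uniform on
  [0, 100]², semi-axes uniform on [10, 50] and rotations uniform on
  [0, π); reject until the triple is a valid 3-Venn topology; read off the
  seven region areas, scale them to a total of 1e5 and round to integers
  (resampling if a region rounds to zero). Every item is drawable by
  construction and the generating diagram is retained as a certificate
  (its `diagError` against the rounded item is below 1e-4, the rounding
  slack at total 1e5).
* **L2 (uniform)** — seven independent integers uniform on [1, 10000];
  drawability is unknown a priori.

Per-item seeds derive from the library seed through a fixed linear
congruential mix, exact in double precision, so libraries reproduce
across platforms. The original evaluation libraries' sampling
distributions are unpublished; the L1 ranges above were chosen once to
span thin and fat regions (region shares from ~3e-5 to ~0.5 of the
diagram, matching the spread of drawable items reported for this kind of
data). Consequences of this choice are discussed under *Limitations*.

The generators emulate the *construction principle* of those libraries,
not real biological data: real gene-list overlaps are heavy-tailed and
often nearly degenerate (regions of zero size), which neither library
produces. Passing the evaluation therefore demonstrates correctness of
the optimizer on drawable and uniform-random inputs, not fitness of any
particular biological dataset.

## Evaluation harness and problem sizes

`evaluate_library()` runs the fitter over a library and reports the
fraction of good diagrams, `diagError` statistics over the non-good ones,
iteration statistics and a rerun histogram. `scripts/acceptance.R`
recomputes the four headline statistics from scratch at desk scale —
200 L1 items (first run only), 150 L2 items (reruns enabled), 100 L2
items in circle mode, 1000 starting diagrams — sizes chosen so the whole
script completes in a few minutes on one CPU while keeping binomial
sampling error a few percentage points.

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| goodness threshold on diagError | 1e-6 | `is_good()` |
| optimizer termination on steps | 1e-6 | `hill_climb()` |
| intersection dedup / Newton target | 1e-9 (unit frame) | geometry core |
| tangency: gradient cross product | 1e-8 | geometry core |
| region positivity floor | 1e-12 × total area | `validate_topology()` |
| negative-area clamp tolerance | 1e-9 × total area | `region_areas()` |
| lens bisection tolerance | 1e-10 relative, ≤ 200 iter | `two_circle_layout()` |
| third-circle line search | 1e-6 relative, ≤ 200 iter | `place_third()` |
| interval march / boundary refine | r₃/50 steps, 40 bisections | `place_third()` |

Ties and orders: curves are always processed `a, b, c`; candidate moves in
the fixed orders listed above; two equal curve totals resolve by label
order. Rotations are stored canonically in [0, π).

## Limitations

* Quantities must be strictly positive; data with empty regions (zero
  quantities) is out of scope, though very small positive quantities are
  handled (regions down to ~3e-5 of the total area fit accurately).
* Exactly three curves; the cost function's mean (rather than sum) over
  regions anticipates generalisation, but no n > 3 geometry is
  implemented.
* The analytic geometry is floating-point, not exact arithmetic; diagrams
  are validated conservatively (tangencies and 4-point pair crossings are
  rejected rather than resolved).
* The starting-diagram quality statistic (fraction of starts with
  `diagError ≤ 0.05`) is sensitive to the L1 generator's property
  distributions, which are a package choice (the original libraries'
  distributions being unpublished). Under the ranges above the measured
  fraction sits around the low 50 %s — the optimizer's end-to-end recovery
  rates are unaffected, as the tests and the acceptance script compute
  directly.
* For quantity vectors that are not drawable with ellipses the returned
  best diagram is still topologically valid with the lowest `diagError`
  found, but there is no certificate of optimality.
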