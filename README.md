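# apvenn — accurate area-proportional 3-Venn diagrams with ellipses

Three-set Venn diagrams annotated with quantities (gene counts, patient
numbers, proteome overlaps, …) are ubiquitous in the life sciences, and they
are routinely drawn with three circles. Circles, however, have too few
degrees of freedom: for most 3-set data no circle diagram exists whose seven
region areas are proportional to the quantities, so the published figures
are often quantitatively misleading. Polygons can always achieve exact
areas but produce hard-to-read curves. Ellipses sit in between — smooth and
symmetric like circles, but with five degrees of freedom per curve — and
admit an accurate diagram for the large majority of 3-set data.

`apvenn` is an independent, from-scratch R implementation of the
ellipse-based drawing approach introduced by the eulerAPE method. Given
seven strictly positive quantities

```
omega = (w_a, w_b, w_c, w_ab, w_ac, w_bc, w_abc)
```

one per region interior to the curves, it searches for three ellipses whose
region areas `A(r)` satisfy `A(r) ∝ w(r)` for all seven regions.

## Method in brief

* **Exact region areas.** The seven region areas of three overlapping
  ellipses are computed analytically: boundary intersection points come
  from the resultant quartic of each conic pair (companion-matrix
  eigenvalues + Newton refinement), overlap areas from the arc-segment
  integral ½∮(x dy − y dx) over the region boundary, and the seven regions
  by inclusion–exclusion. A Monte-Carlo sampler is included purely as an
  independent testing oracle.
* **Goodness measure.** For each region,
  `regionError(r) = |A(r)/ΣA − w(r)/Σw|`; the diagram error `diagError` is
  the maximum over the seven regions, always in [0, 1]. A diagram is *good*
  (accurate) when it has a valid 3-Venn topology and `diagError ≤ 1e-6`.
* **Cost function.** The optimizer minimises
  `F6 = mean_r (w'(r) − A(r))² / A(r)`, where `w'` are the quantities
  scaled so the smallest is 100. The `A(r)` denominator makes the cost of a
  collapsing region explode, which steers the search away from the classic
  local minimum in which a region is shrunk to near non-existence.
* **Rational starting diagram.** Three circles: the two curves with the
  largest required totals are placed exactly by bisection of the
  circular-lens area (a two-set area-proportional diagram is always
  exact), and the third circle's centre is located along the tangent-angle
  bisector through their upper intersection point so that the triple
  overlap matches its requirement as closely as possible.
* **Hill climbing with cooling and reruns.** Each iteration perturbs every
  ellipse's centre (8 moves), semi-axes (8 moves) and rotation (2 moves) by
  step parameters `pγ = 10` canvas units, `pαβ = 5 %`, `pθ = 2π/3`,
  greedily accepting each strict cost reduction; any step class with no
  accepted move is halved, and the run stops accurate as soon as the
  diagram is good, or inaccurate when all three steps reach `1e-6`. On an
  inaccurate run the optimization is rerun with 20 % larger starting steps,
  up to 10 times, and the lowest-`diagError` diagram is kept. The whole
  pipeline is deterministic and invariant to rescaling of the input.
* **Circle-restricted mode** (`mode = "circles"`) constrains the semi-axes
  to stay equal and skips rotations — useful to demonstrate why circles are
  not enough.

## Worked example

The quantities below summarise a published medical survey on chronic
kidney disease awareness (three overlapping groups of trainees):

```r
library(apvenn)
w <- c(a = 0.25, b = 0.01, c = 0.11, ab = 0.10, ac = 0.29,
       bc = 0.03, abc = 0.15)
fit <- fit_venn3(w)
print(fit)
#> 3-Venn fit (ellipses): accurate, diagError = 7.59e-07, 40 iterations, 0 reruns
#> 3-Venn diagram (ellipses):
#>         cx       cy       s1       s2    theta
#> a  5.11673 13.34869 46.06958 54.58361 3.092441
#> b 26.89175 32.58609 24.51265 37.65792 1.025626
#> c 25.56369  0.00000 38.51067 47.93986 2.258211
```

The fit is *accurate*: every region's share of the diagram is within
`1e-6` of its required share. Compare achieved shares against `w/sum(w)`:

```r
round(region_areas(fit$diagram)$areas / sum(region_areas(fit$diagram)$areas), 4)
#>      a      b      c     ab     ac     bc    abc
#> 0.2660 0.0106 0.1170 0.1064 0.3085 0.0319 0.1596
write_diagram(fit, "ckd.svg")   # also: .png, .txt (round-trippable)
```

No circle diagram achieves this: `fit_venn3(w, mode = "circles")` bottoms
out at `diagError ≈ 0.03`.

From a shell, the same fit is

```sh
Rscript exec/apvenn fit --values 0.25,0.01,0.11,0.10,0.29,0.03,0.15 --out ckd.svg
```

and `apvenn datagen` / `apvenn eval` generate and batch-evaluate random
quantity libraries.

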