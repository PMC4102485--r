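test_that("ellipse area is closed form and invariant to pose", {
  expect_equal(ellipse_area(ellipse(0, 0, 1, 1)), pi)
  expect_equal(ellipse_area(ellipse(3, -2, 2, 1, 0.7)), 2 * pi)
  expect_equal(ellipse_area(ellipse(0, 0, 3, 1, 0)),
               ellipse_area(ellipse(5, 5, 3, 1, 1.2)))
})

test_that("boundary intersection points are found and lie on both conics", {
  # symmetric circle pair: closed-form points
  ip <- intersect_ellipses(ellipse(0, 0, 1, 1), ellipse(1, 0, 1, 1))
  pts <- ip$points[order(ip$points[, "y"]), , drop = FALSE]
  expect_equal(nrow(pts), 2L)
  expect_equal(unname(pts[, "x"]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(pts[, "y"]), c(-sqrt(3) / 2, sqrt(3) / 2), tolerance = 1e-9)
  expect_false(any(ip$tangential))

  # disjoint circles: no points
  expect_equal(nrow(intersect_ellipses(ellipse(0, 0, 1, 1),
                                       ellipse(5, 0, 1, 1))$points), 0L)

  # crossed axis-aligned ellipses: 4 points, symmetric under x <-> y
  e1 <- ellipse(0, 0, 2, 1, 0)
  e2 <- ellipse(0, 0, 1, 2, 0)
  ip <- intersect_ellipses(e1, e2)
  expect_equal(nrow(ip$points), 4L)
  on_boundary <- function(p, e) {
    v <- as.numeric(e)
    u <- cos(v[5]) * (p[1] - v[1]) + sin(v[5]) * (p[2] - v[2])
    w <- -sin(v[5]) * (p[1] - v[1]) + cos(v[5]) * (p[2] - v[2])
    abs((u / v[3])^2 + (w / v[4])^2 - 1)
  }
  for (i in 1:4) {
    expect_lt(on_boundary(ip$points[i, ], e1), 1e-9)
    expect_lt(on_boundary(ip$points[i, ], e2), 1e-9)
    # x <-> y symmetry: the swapped point is also an intersection point
    swapped <- rev(ip$points[i, ])
    dists <- apply(ip$points, 1, function(q) max(abs(q - swapped)))
    expect_lt(min(dists), 1e-8)
  }

  expect_error(intersect_ellipses(ellipse(0, 0, 2, 1, 0.3),
                                  ellipse(0, 0, 2, 1, 0.3)),
               "coincident")
})

test_that("pairwise overlap area matches closed forms", {
  # containment limit: coincident ellipses
  expect_equal(pair_intersection_area(ellipse(0, 0, 2, 1), ellipse(0, 0, 2, 1)),
               2 * pi, tolerance = 1e-12)
  # disjoint
  expect_equal(pair_intersection_area(ellipse(0, 0, 1, 1), ellipse(5, 0, 1, 1)), 0)
  # circular lens, unit circles at distance 1
  expect_equal(pair_intersection_area(ellipse(0, 0, 1, 1), ellipse(1, 0, 1, 1)),
               2 * pi / 3 - sqrt(3) / 2, tolerance = 1e-10)
  # strict containment
  expect_equal(pair_intersection_area(ellipse(0, 0, 5, 5), ellipse(1, 0, 1, 2)),
               2 * pi, tolerance = 1e-10)
  # general pair vs the circular-lens value after rigid motion
  a <- pair_intersection_area(ellipse(2, 3, 1, 1, 0.5), ellipse(2 + cos(1), 3 + sin(1), 1, 1, 2))
  expect_equal(a, 2 * pi / 3 - sqrt(3) / 2, tolerance = 1e-10)
})

test_that("triple overlap area matches closed forms and the MC oracle", {
  expect_equal(triple_intersection_area(ellipse(0, 0, 1, 1), ellipse(0, 0, 1, 1),
                                        ellipse(0, 0, 1, 1)), pi, tolerance = 1e-12)
  expect_equal(triple_intersection_area(ellipse(0, 0, 1, 1), ellipse(5, 0, 1, 1),
                                        ellipse(0, 5, 1, 1)), 0)
  # unit circles at the vertices of an equilateral triangle with side 1:
  # the triple overlap is the Reuleaux triangle of width 1, area (pi - sqrt(3))/2
  d <- classic_venn()
  expect_equal(triple_intersection_area(ellipse(0, 0, 1, 1), ellipse(1, 0, 1, 1),
                                        ellipse(0.5, sqrt(3) / 2, 1, 1)),
               (pi - sqrt(3)) / 2, tolerance = 1e-10)
  mc <- monte_carlo_region_areas(d, n = 2e5, seed = 42)
  expect_lt(abs(region_areas(d)$areas[["abc"]] - mc$areas[["abc"]]),
            3 * mc$se[["abc"]])
})

test_that("region areas satisfy inclusion-exclusion and the reconstruction identity", {
  # disjoint circles: singles only, invalid topology
  d <- venn3_diagram(ellipse(0, 0, 1, 1), ellipse(5, 0, 2, 2), ellipse(0, 5, 1, 1))
  r <- region_areas(d)
  expect_false(r$valid)
  expect_equal(unname(r$areas[c("a", "b", "c")]), c(pi, 4 * pi, pi))
  expect_equal(unname(r$areas[c("ab", "ac", "bc", "abc")]), rep(0, 4))

  # 3-fold symmetric triple: equal singles, equal pairs
  r <- region_areas(classic_venn())
  expect_true(r$valid)
  expect_equal(r$areas[["a"]], r$areas[["b"]], tolerance = 1e-10)
  expect_equal(r$areas[["a"]], r$areas[["c"]], tolerance = 1e-10)
  expect_equal(r$areas[["ab"]], r$areas[["ac"]], tolerance = 1e-10)
  expect_equal(r$areas[["ab"]], r$areas[["bc"]], tolerance = 1e-10)

  # per-curve reconstruction identity on random valid diagrams
  for (seed in 1:20) {
    d <- random_valid_diagram(seed)
    A <- region_areas(d)$areas
    E <- unclass(d)
    rec <- c(A[["a"]] + A[["ab"]] + A[["ac"]] + A[["abc"]],
             A[["b"]] + A[["ab"]] + A[["bc"]] + A[["abc"]],
             A[["c"]] + A[["ac"]] + A[["bc"]] + A[["abc"]])
    truth <- pi * E[, "s1"] * E[, "s2"]
    expect_lt(max(abs(rec - truth) / truth), 1e-9)
  }
})

test_that("topology validation accepts the Venn layout and names failures", {
  v <- validate_topology(classic_venn())
  expect_true(v$valid)
  expect_identical(v$diagnostic, "valid")

  v <- validate_topology(venn3_diagram(ellipse(0, 0, 1, 1), ellipse(5, 0, 1, 1),
                                       ellipse(0, 5, 1, 1)))
  expect_false(v$valid)
  expect_match(v$diagnostic, "intersection count")

  # two elongated crossed ellipses (4 intersection points) + a circle:
  # a split-zone risk, rejected via the pair-crossing count
  d <- venn3_diagram(ellipse(0, 0, 8, 1, 0), ellipse(0, 0, 1, 8, 0),
                     ellipse(0.5, 0.5, 3, 3, 0))
  expect_false(validate_topology(d)$valid)
})

test_that("region areas are rigid-motion invariant and scale quadratically", {
  d <- random_valid_diagram(99)
  A <- region_areas(d)$areas
  A2 <- region_areas(transform_diagram(d, dx = -37.5, dy = 12.25, rot = 0.83))$areas
  expect_lt(max(abs(A - A2) / A), 1e-9)
  k <- 2.5
  A3 <- region_areas(transform_diagram(d, scale = k))$areas
  expect_lt(max(abs(A3 - k^2 * A) / (k^2 * A)), 1e-9)
})

test_that("the Monte-Carlo oracle is deterministic, conservative, and agrees", {
  d <- random_valid_diagram(7)
  mc1 <- monte_carlo_region_areas(d, n = 1e5, seed = 3)
  mc2 <- monte_carlo_region_areas(d, n = 1e5, seed = 3)
  expect_identical(mc1$areas, mc2$areas)
  expect_error(monte_carlo_region_areas(d, n = 0), "n >= 1")
  # conservation: region estimates sum to the union estimate
  expect_lt(abs(sum(mc1$areas) - mc1$union_area), 3 * mc1$union_se)
  # oracle equivalence on a few random diagrams (the acceptance suite
  # repeats this at n = 1e6 over 50 diagrams)
  for (seed in 11:15) {
    d <- random_valid_diagram(seed)
    A <- region_areas(d)$areas
    mc <- monte_carlo_region_areas(d, n = 2e5, seed = seed)
    se <- pmax(mc$se, 3 * sum(A) / 2e5) # floor tiny-count standard errors
    expect_true(all(abs(A - mc$areas) <= 3.5 * se))
  }
})
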