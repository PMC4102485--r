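test_that("candidate enumerations match the fixed move set", {
  e <- ellipse(0, 0, 100, 50, 0.4)
  cc <- candidate_centres(e, 10)
  expect_length(cc, 8L)
  got <- t(vapply(cc, function(x) as.numeric(x)[1:2], numeric(2)))
  expect_equal(got, rbind(c(10, 0), c(-10, 0), c(0, 10), c(0, -10),
                          c(10, 10), c(-10, 10), c(10, -10), c(-10, -10)))
  # centre moves keep the axes and rotation
  expect_true(all(vapply(cc, function(x) all(as.numeric(x)[3:5] == c(100, 50, 0.4)),
                         logical(1))))

  cs <- candidate_semiaxes(e, 0.05)
  expect_length(cs, 8L)
  axes <- t(vapply(cs, function(x) as.numeric(x)[3:4], numeric(2)))
  expect_equal(axes, rbind(c(105, 50), c(95, 50), c(100, 52.5), c(100, 47.5),
                           c(105, 52.5), c(95, 47.5), c(105, 47.5), c(95, 52.5)))
  expect_true(all(vapply(cs, function(x)
    all(as.numeric(x)[c(1, 2, 5)] == c(0, 0, 0.4)), logical(1))))
  # positive axes for any p < 1
  expect_true(all(axes > 0))

  cr <- candidate_rotations(ellipse(0, 0, 2, 1, 0), 2 * pi / 3)
  expect_length(cr, 2L)
  expect_equal(sort(vapply(cr, function(x) as.numeric(x)[5], numeric(1))),
               c(pi / 3, 2 * pi / 3), tolerance = 1e-12)
  # rotating a circle never changes its region areas
  d <- classic_venn()
  A <- region_areas(d)$areas
  rotated <- venn3_diagram(candidate_rotations(ellipse(0, 0, 1, 1), 1.1)[[1]],
                           ellipse(1, 0, 1, 1), ellipse(0.5, sqrt(3) / 2, 1, 1))
  expect_equal(region_areas(rotated)$areas, A, tolerance = 1e-12)
})

test_that("a good starting diagram returns immediately", {
  d <- random_valid_diagram(5)
  w <- region_areas(d)$areas
  res <- hill_climb(w, d)
  expect_true(res$accurate)
  expect_identical(res$iterations, 0L)
  expect_equal(unclass(res$diagram), unclass(d))
})

test_that("an invalid starting diagram is rejected", {
  bad <- venn3_diagram(ellipse(0, 0, 1, 1), ellipse(5, 0, 1, 1), ellipse(0, 5, 1, 1))
  expect_error(hill_climb(w_drawable, bad), "valid 3-Venn topology")
})

test_that("the optimizer reaches a good diagram for a known-drawable item", {
  f <- fit_venn3(w_drawable)
  expect_true(f$accurate)
  expect_lte(f$diag_error, 1e-6)
  expect_true(validate_topology(f$diagram)$valid)
})

test_that("accepted moves strictly decrease the cost", {
  f <- fit_venn3(w_drawable, audit = TRUE)
  aud <- f$runs[[1]]$audit
  expect_gt(nrow(aud), 0)
  expect_true(all(aud[, "cost_after"] < aud[, "cost_before"]))
  # the accepted-cost sequence is globally decreasing within the run
  expect_true(all(diff(aud[, "cost_after"]) < 0))
})

test_that("fits are deterministic and invariant to proportional quantities", {
  f1 <- fit_venn3(w_medical)
  f2 <- fit_venn3(w_medical)
  expect_identical(unclass(f1$diagram), unclass(f2$diagram))
  expect_identical(f1$iterations, f2$iterations)
  f3 <- fit_venn3(w_medical * 40)
  expect_equal(unclass(f1$diagram), unclass(f3$diagram), tolerance = 1e-12)
  expect_equal(f1$diag_error, f3$diag_error, tolerance = 1e-9)
})

test_that("circle mode keeps the curves circular and never beats ellipses by much", {
  f <- fit_venn3(w_medical, mode = "circles")
  E <- unclass(f$diagram)
  expect_true(all(E[, "s1"] == E[, "s2"]))
  # circles are a constrained subset: on a small L2 sample their final
  # diagError should not beat the ellipse fits beyond tolerance
  lib <- generate_library(5, "L2", seed = 77)
  des <- vapply(seq_len(5), function(i) {
    w <- quantities7(as.numeric(lib$quantities[i, ]))
    c(ell = fit_venn3(w, rerun = FALSE)$diag_error,
      cir = fit_venn3(w, rerun = FALSE, mode = "circles")$diag_error)
  }, numeric(2))
  expect_true(mean(des["cir", ] - des["ell", ]) > -1e-6)
})

test_that("the rerun escape grows the start parameters and returns the best diagram", {
  # the thin-region item that the first run alone does not always crack
  f <- fit_venn3(w_thin_region, rerun = TRUE)
  expect_true(f$accurate)
  expect_lte(f$diag_error, 1e-6)
  f1 <- fit_venn3(w_thin_region, rerun = FALSE)
  expect_lte(length(f1$runs), 1L)
  # with rerun disabled the result is the single first run
  expect_equal(f1$reruns_used, 0L)
})
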