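test_that("quantity scaling sets the minimum to 100 and is proportion-invariant", {
  expect_equal(unname(scale_quantities(rep(5, 7))), rep(100, 7))
  s <- scale_quantities(w_thin_region)
  expect_equal(s[["bc"]], 100)
  expect_equal(s[["a"]], 10018 * 100 / 3)
  expect_equal(min(s), 100)
  expect_equal(scale_quantities(w_drawable), scale_quantities(7 * w_drawable))
  expect_error(quantities7(c(a = 1, b = 1, c = 1, ab = 1, ac = 1, bc = 0, abc = 1)),
               "strictly positive")
  expect_error(quantities7(c(a = 1, b = 1)), "seven region labels")
})

test_that("regionError and diagError follow the proportion-difference definition", {
  w <- rep(1, 7)
  A <- c(a = 2, b = 1, c = 1, ab = 1, ac = 1, bc = 1, abc = 1)
  expect_equal(region_error("a", A, w), 3 / 28) # |2/8 - 1/7| = 6/56
  expect_equal(diag_error(A, w), 3 / 28)        # the doubled region attains the max
  # proportional areas give zero error everywhere
  expect_equal(unname(region_error(NULL, 3 * w_drawable, w_drawable)), rep(0, 7))
  expect_equal(diag_error(3 * w_drawable, w_drawable), 0)
  # bounded in [0, 1] for arbitrary positive inputs
  set.seed(1)
  for (i in 1:50) {
    A <- stats::runif(7, 1e-6, 1e6)
    w <- stats::runif(7, 1e-6, 1e6)
    names(A) <- names(w) <- names(w_drawable)
    errs <- region_error(NULL, A, w)
    expect_true(all(errs >= 0 & errs <= 1))
    expect_true(diag_error(A, w) >= 0 && diag_error(A, w) <= 1)
  }
})

test_that("diagError is invariant to quantity rescaling and rigid motion", {
  d <- random_valid_diagram(21)
  A <- region_areas(d)
  w <- w_drawable
  expect_equal(diag_error(A, w), diag_error(A, 0.001 * w))
  d2 <- transform_diagram(d, dx = 11, dy = -4, rot = 1.1, scale = 3)
  expect_equal(diag_error(region_areas(d2), w), diag_error(A, w), tolerance = 1e-9)
})

test_that("cost functions match hand-computed values and the collapse sentinel", {
  seven <- function(x) stats::setNames(rep(x, 7), names(w_drawable))
  expect_equal(cost_F6(seven(2), seven(2)), 0)
  expect_equal(cost_F7(seven(2), seven(2)), 0)
  expect_equal(cost_F8(seven(2), seven(2)), 0)
  expect_equal(cost_F6(seven(1), seven(2)), 1)
  expect_equal(cost_F7(seven(1), seven(2)), 1)
  expect_equal(cost_F8(seven(1), seven(2)), 1)
  expect_equal(cost_F6(seven(2), seven(3)), 0.5)
  expect_equal(cost_F7(seven(2), seven(3)), 0.25)
  expect_equal(cost_F8(seven(2), seven(3)), 0.5)
  # cost explodes as a region collapses (anti-local-minimum design)
  A <- seven(1)
  costs <- sapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    A[["bc"]] <- eps
    cost_F6(A, seven(2))
  })
  expect_true(all(diff(costs) > 0))
  A[["bc"]] <- 0
  expect_identical(cost_F6(A, seven(2)), Inf)
})

test_that("stress matches the regression-through-origin definition", {
  w <- stats::setNames(rep(1, 7), names(w_drawable))
  A <- w; A[["a"]] <- 2
  # beta = 8/7, RSS = (6/7)^2 + 6 * (1/7)^2 = 6/7, TSS = 10
  expect_equal(stress(A, w), (6 / 7) / 10)
  expect_equal(stress(5 * w_drawable, w_drawable), 0, tolerance = 1e-28)
  set.seed(2)
  for (i in 1:50) {
    A <- stats::setNames(stats::runif(7, 0.01, 100), names(w_drawable))
    w2 <- stats::setNames(stats::runif(7, 0.01, 100), names(w_drawable))
    s <- stress(A, w2)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("goodness requires topology and a 1e-6 diagError", {
  d <- random_valid_diagram(33)
  w <- region_areas(d)$areas # areas equal to quantities up to a global factor
  expect_true(is_good(d, 0.37 * w))
  bad <- venn3_diagram(ellipse(0, 0, 1, 1), ellipse(5, 0, 1, 1), ellipse(0, 5, 1, 1))
  expect_false(is_good(bad, w))
})
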