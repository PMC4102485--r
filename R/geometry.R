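#' Construct an ellipse
#'
#' An ellipse is described by its centre, two semi-axis lengths and an angle
#' of rotation, the five degrees of freedom the optimizer adjusts. The
#' rotation is stored canonically in `[0, pi)` since an ellipse is invariant
#' under a half-turn of its axes.
#'
#' @param cx,cy Centre coordinates, in canvas units.
#' @param s1,s2 Semi-axis lengths (must be positive); `s1` lies along the
#'   rotated x-axis.
#' @param theta Rotation angle in radians, counter-clockwise.
#' @return A named numeric vector of class `apvenn_ellipse` with elements
#'   `cx`, `cy`, `s1`, `s2`, `theta`.
#' @examples
#' ellipse(0, 0, 2, 1, pi / 4)
#' @export
ellipse <- function(cx, cy, s1, s2, theta = 0) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(s1), is.numeric(s2),
            is.numeric(theta), length(cx) == 1L)
  if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0)
    stop("semi-axes must be positive and finite")
  e <- c(cx = as.numeric(cx), cy = as.numeric(cy), s1 = as.numeric(s1),
         s2 = as.numeric(s2), theta = canonical_angle(as.numeric(theta)))
  class(e) <- "apvenn_ellipse"
  e
}

canonical_angle <- function(theta) {
  th <- theta %% pi
  if (th < 0) th <- th + pi
  th
}

#' Construct a three-curve diagram
#'
#' Bundles three labelled ellipses (curves `a`, `b` and `c`) into a
#' candidate 3-Venn diagram.
#'
#' @param a,b,c Objects created by [ellipse()] (or length-5 numeric vectors
#'   in `cx, cy, s1, s2, theta` order).
#' @return An object of class `venn3_diagram`: a 3 x 5 numeric matrix with
#'   rows `a`, `b`, `c` and columns `cx`, `cy`, `s1`, `s2`, `theta`.
#' @examples
#' venn3_diagram(ellipse(0, 0, 1, 1), ellipse(1, 0, 1, 1), ellipse(0.5, 1, 1, 1))
#' @export
venn3_diagram <- function(a, b, c) {
  rows <- lapply(list(a = a, b = b, c = c), function(e) {
    e <- as.numeric(e)
    if (length(e) != 5L || any(!is.finite(e)) || e[3] <= 0 || e[4] <= 0)
      stop("each curve must be an ellipse with positive semi-axes")
    e[5] <- canonical_angle(e[5])
    e
  })
  d <- do.call(rbind, rows)
  dimnames(d) <- list(CURVE_LABELS, c("cx", "cy", "s1", "s2", "theta"))
  class(d) <- c("venn3_diagram", "matrix")
  d
}

as_diagram_matrix <- function(d) {
  if (inherits(d, "venn3_diagram")) return(unclass(d))
  if (is.matrix(d) && all(dim(d) == c(3L, 5L))) return(d)
  stop("expected a venn3_diagram")
}

#' Area enclosed by an ellipse
#'
#' @param e An [ellipse()].
#' @return `pi * s1 * s2`, independent of centre and rotation.
#' @export
ellipse_area <- function(e) {
  e <- as.numeric(e)
  pi * e[3] * e[4]
}

#' Boundary intersection points of two ellipses
#'
#' Solves the resultant quartic of the two implicit conics (roots from the
#' companion-matrix eigenvalues, refined by Newton iteration on both
#' implicit equations) and returns the deduplicated real intersection
#' points of the two boundaries.
#'
#' @param e1,e2 Ellipses.
#' @return A list with `points` (k x 2 matrix, k in 0..4, columns `x`, `y`)
#'   and `tangential` (logical per point: `TRUE` where the two boundaries
#'   touch without crossing). Coincident ellipses are an error.
#' @examples
#' intersect_ellipses(ellipse(0, 0, 1, 1), ellipse(1, 0, 1, 1))$points
#' @export
intersect_ellipses <- function(e1, e2) {
  v1 <- as.numeric(e1); v2 <- as.numeric(e2)
  if (isTRUE(all.equal(v1, v2, tolerance = 1e-12)))
    stop("coincident ellipses: intersection is degenerate")
  res <- .ell_intersect_cpp(v1, v2)
  colnames(res$points) <- c("x", "y")
  res
}

#' Overlap area of two ellipses
#'
#' The overlap boundary is decomposed into elliptical arcs (the portions of
#' each boundary interior to the other ellipse) and the enclosed area is
#' the sum of the arc-segment integrals `1/2 * integral(x dy - y dx)` along
#' the closed boundary. Disjoint ellipses give 0 and containment gives the
#' smaller ellipse area; neither is an error.
#'
#' @param e1,e2 Ellipses.
#' @return The overlap area (non-negative scalar).
#' @export
pair_intersection_area <- function(e1, e2) {
  .pair_area_cpp(as.numeric(e1), as.numeric(e2))
}

#' Common overlap area of three ellipses
#'
#' @param e1,e2,e3 Ellipses.
#' @return The area of the triple overlap (non-negative scalar).
#' @export
triple_intersection_area <- function(e1, e2, e3) {
  .triple_area_cpp(as.numeric(e1), as.numeric(e2), as.numeric(e3))
}

REASON_LABELS <- c("valid", "pair intersection count != 2 (or tangential)",
                   "missing or degenerate region", "numerical inconsistency")

#' Areas of the seven interior regions of a diagram
#'
#' Computes the three pairwise and the triple overlap areas analytically
#' and derives the seven region areas by inclusion-exclusion:
#' `A(abc) = T`, `A(ab) = I_ab - T`, `A(a) = area(a) - I_ab - I_ac + T`,
#' and cyclically. Negative round-off values within tolerance are clamped
#' to zero; larger negatives mark the result numerically inconsistent.
#'
#' @param d A [venn3_diagram()].
#' @return A list of class `region_areas` with `areas` (named numeric,
#'   labels `a, b, c, ab, ac, bc, abc`), `valid` (`TRUE` iff the diagram is
#'   a 3-Venn topology, see [validate_topology()]) and `diagnostic`.
#' @examples
#' d <- venn3_diagram(ellipse(0, 0, 1, 1), ellipse(1, 0, 1, 1),
#'                    ellipse(0.5, 0.8, 1, 1))
#' region_areas(d)$areas
#' @export
region_areas <- function(d) {
  E <- as_diagram_matrix(d)
  res <- .region_areas_cpp(E)
  areas <- as.numeric(res$areas)
  names(areas) <- REGION_LABELS
  structure(list(areas = areas, valid = res$valid,
                 diagnostic = REASON_LABELS[res$reason + 1L],
                 pair_points = res$pair_points, consistent = res$consistent),
            class = "region_areas")
}

#' Check that a diagram has the 3-Venn topology
#'
#' A candidate diagram is accepted iff every pair of ellipses crosses
#' transversally in exactly two points and all seven region areas exceed a
#' positivity floor (1e-12 of the total diagram area). For three such
#' curves the arrangement has 6 vertices and 12 edges, hence exactly 8
#' faces; with the exterior and seven positive-area signatures that forces
#' one face per region, so no region can be a split zone.
#'
#' @param d A [venn3_diagram()].
#' @return A list with `valid` (logical) and `diagnostic` (the first failed
#'   condition, or `"valid"`).
#' @export
validate_topology <- function(d) {
  r <- region_areas(d)
  list(valid = r$valid, diagnostic = r$diagnostic)
}

#' Monte-Carlo estimate of the region areas
#'
#' Rejection sampling over the bounding box of the three ellipses; each
#' sample is classified by the three interior-membership predicates. Used
#' as an independent oracle for the analytic computation.
#'
#' @param d A [venn3_diagram()].
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the sampler restores the caller's RNG state.
#' @return A list with `areas` and `se` (binomial standard errors), both
#'   named numeric over the seven region labels, plus `union_area` and
#'   `union_se`.
#' @export
monte_carlo_region_areas <- function(d, n = 1e6, seed = 1) {
  stopifnot(n >= 1)
  E <- as_diagram_matrix(d)
  # bounding box of the union
  ex <- sqrt(E[, "s1"]^2 * cos(E[, "theta"])^2 + E[, "s2"]^2 * sin(E[, "theta"])^2)
  ey <- sqrt(E[, "s1"]^2 * sin(E[, "theta"])^2 + E[, "s2"]^2 * cos(E[, "theta"])^2)
  x0 <- min(E[, "cx"] - ex); x1 <- max(E[, "cx"] + ex)
  y0 <- min(E[, "cy"] - ey); y1 <- max(E[, "cy"] + ey)
  box <- (x1 - x0) * (y1 - y0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  x <- runif(n, x0, x1)
  y <- runif(n, y0, y1)
  inside <- function(i) {
    u <- cos(E[i, "theta"]) * (x - E[i, "cx"]) + sin(E[i, "theta"]) * (y - E[i, "cy"])
    v <- -sin(E[i, "theta"]) * (x - E[i, "cx"]) + cos(E[i, "theta"]) * (y - E[i, "cy"])
    (u / E[i, "s1"])^2 + (v / E[i, "s2"])^2 < 1
  }
  m <- inside(1) + 2L * inside(2) + 4L * inside(3)
  counts <- tabulate(m, nbins = 7L) # signatures 1..7; 0 = outside all
  # signature -> label: 1=a, 2=b, 3=ab, 4=c, 5=ac, 6=bc, 7=abc
  sig_of <- c(a = 1L, b = 2L, c = 4L, ab = 3L, ac = 5L, bc = 6L, abc = 7L)
  p <- counts[sig_of] / n
  areas <- p * box
  se <- sqrt(pmax(p * (1 - p), 0) / n) * box
  names(areas) <- names(se) <- REGION_LABELS
  pu <- sum(counts) / n
  list(areas = areas, se = se, union_area = pu * box,
       union_se = sqrt(pu * (1 - pu) / n) * box)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.venn3_diagram <- function(x, ...) {
  cat("3-Venn diagram (ellipses):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.region_areas <- function(x, ...) {
  cat("Region areas (", if (x$valid) "valid 3-Venn topology"
      else paste0("invalid: ", x$diagnostic), "):\n", sep = "")
  print(x$areas, ...)
  invisible(x)
}
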