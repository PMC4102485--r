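#' Total required area per curve
#'
#' The total quantity assigned to a curve is the sum over the four regions
#' inside it, e.g. `total(a) = w(a) + w(ab) + w(ac) + w(abc)`. The two
#' curves with the largest totals are the ones placed first in the starting
#' diagram; ties break by label order `a < b < c`.
#'
#' @param w Quantities as accepted by [quantities7()].
#' @return A list with `totals` (named numeric over `a`, `b`, `c`),
#'   `largest` (the two largest curve labels) and `third`.
#' @export
curve_totals <- function(w) {
  w <- quantities7(w)
  totals <- c(a = w[["a"]] + w[["ab"]] + w[["ac"]] + w[["abc"]],
              b = w[["b"]] + w[["ab"]] + w[["bc"]] + w[["abc"]],
              c = w[["c"]] + w[["ac"]] + w[["bc"]] + w[["abc"]])
  ord <- order(-totals) # stable: ties keep label order
  list(totals = totals, largest = CURVE_LABELS[ord[1:2]],
       third = CURVE_LABELS[ord[3]])
}

# area of the lens of two circles with radii r1, r2 at centre distance d
circle_lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  x2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
  x1 <- max(-1, min(1, x1)); x2 <- max(-1, min(1, x2))
  r1^2 * acos(x1) + r2^2 * acos(x2) -
    0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
}

#' Place two circles with a prescribed overlap area
#'
#' Draws the exact two-set area-proportional sub-diagram: the circles get
#' radii `sqrt(total / pi)` and their centre separation is found by
#' bisection of the circular-lens area, which decreases strictly and
#' continuously from the smaller circle area (at containment) to zero (at
#' tangency), so any feasible overlap pins a unique separation.
#'
#' @param totalA,totalB Total required areas of the two curves.
#' @param overlapAB Required overlap area; must satisfy
#'   `0 < overlapAB < min(totalA, totalB)`.
#' @param tol Relative tolerance on the achieved lens area.
#' @param max_iter Bisection iteration cap.
#' @return A list with `e1`, `e2` (circles via [ellipse()], `e1` at the
#'   origin, `e2` on the positive x-axis) and `d`, the separation.
#' @export
two_circle_layout <- function(totalA, totalB, overlapAB,
                              tol = 1e-10, max_iter = 200L) {
  stopifnot(totalA > 0, totalB > 0)
  if (overlapAB <= 0 || overlapAB >= min(totalA, totalB))
    stop("required overlap must lie strictly between 0 and the smaller curve total")
  r1 <- sqrt(totalA / pi)
  r2 <- sqrt(totalB / pi)
  lo <- abs(r1 - r2)
  hi <- r1 + r2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (circle_lens_area(r1, r2, mid) > overlapAB) lo <- mid else hi <- mid
    if ((hi - lo) < tol * (r1 + r2)) break
  }
  d <- (lo + hi) / 2
  list(e1 = ellipse(0, 0, r1, r1, 0), e2 = ellipse(d, 0, r2, r2, 0), d = d)
}

#' Position the third circle along the tangent-angle bisector
#'
#' The centre of the third circle lies on the line `L` through the upper
#' intersection point of the first two circles, bisecting the angle between
#' their tangents there and directed into the lens. Along `L` the feasible
#' interval `(u, l)` is the range of positions at which the third circle
#' still crosses each of the first two circles twice and all seven regions
#' exist; its endpoints are located by marching in steps of `r3 / 50` and
#' refining each topology-change boundary by bisection. Within the
#' interval a golden-section line search picks the centre minimising the
#' discrepancy `|A(abc) - target_abc|`.
#'
#' @param e1,e2 The two circles from [two_circle_layout()]; they must
#'   intersect in two points.
#' @param r3 Radius of the third circle.
#' @param target_abc Required area of the region inside all three curves.
#' @param tol Relative tolerance of the line search.
#' @param max_iter Iteration cap for the line search.
#' @return A list with `e3` (the placed circle), `achieved_abc`, and
#'   `fallback` (`TRUE` when no feasible interval was found and the centre
#'   defaulted to the lens midpoint).
#' @export
place_third <- function(e1, e2, r3, target_abc, tol = 1e-6, max_iter = 200L) {
  stopifnot(r3 > 0, target_abc > 0)
  v1 <- as.numeric(e1); v2 <- as.numeric(e2)
  ip <- .ell_intersect_cpp(v1, v2)
  keep <- !ip$tangential
  if (sum(keep) < 2) stop("the first two curves must intersect in two points")
  pts <- ip$points[keep, , drop = FALSE]
  i1 <- pts[which.max(pts[, 2]), ] # upper intersection point
  i2 <- pts[which.min(pts[, 2]), ]
  dir <- bisector_direction(v1, v2, i1)

  base <- rbind(v1, v2, c(0, 0, r3, r3, 0))
  mk <- function(t) {
    base[3, 1] <- i1[1] + t * dir[1]
    base[3, 2] <- i1[2] + t * dir[2]
    base
  }
  valid_at <- function(t) .region_areas_cpp(mk(t))$valid
  abc_at <- function(t) .region_areas_cpp(mk(t))$areas[7]

  step <- r3 / 50
  tmax <- r3 + 2 * max(v1[3], v2[3]) + sqrt(sum((i1 - i2)^2))
  ts <- seq(step, tmax, by = step)
  ok <- vapply(ts, valid_at, logical(1))
  if (!any(ok)) {
    mid <- (i1 + i2) / 2
    warning("no feasible interval for the third curve; falling back to the lens midpoint")
    e3 <- ellipse(mid[1], mid[2], r3, r3, 0)
    return(list(e3 = e3, achieved_abc = region_areas(
      venn3_diagram(e1, e2, e3))$areas[["abc"]], fallback = TRUE))
  }
  runs <- valid_runs(ts, ok)
  best <- NULL
  for (run in runs) {
    lo <- refine_boundary(valid_at, run$lo_out, run$lo_in)
    hi <- refine_boundary(valid_at, run$hi_out, run$hi_in)
    if (hi <= lo) next
    pad <- 1e-9 * (hi - lo)
    opt <- golden_min(function(t) abs(abc_at(t) - target_abc),
                      lo + pad, hi - pad, tol = tol, max_iter = max_iter)
    if (is.null(best) || opt$fmin < best$fmin) best <- opt
  }
  e3 <- ellipse(i1[1] + best$tmin * dir[1], i1[2] + best$tmin * dir[2], r3, r3, 0)
  list(e3 = e3, achieved_abc = abc_at(best$tmin), fallback = FALSE)
}

# unit direction of the bisector of the tangents to two ellipses at point p,
# oriented downward into the lens (construction frame: e1 left, e2 right,
# p the upper intersection point)
bisector_direction <- function(v1, v2, p) {
  tangent_dir <- function(v) {
    e <- conic_coefficients(v)
    g <- c(2 * e[1] * p[1] + e[2] * p[2] + e[4],
           e[2] * p[1] + 2 * e[3] * p[2] + e[5])
    t <- c(-g[2], g[1]) / sqrt(sum(g^2))
    if (t[2] > 0) t <- -t
    t
  }
  t1 <- tangent_dir(v1)
  t2 <- tangent_dir(v2)
  d <- t1 + t2
  n <- sqrt(sum(d^2))
  if (n < 1e-12) c(0, -1) else d / n
}

# implicit conic coefficients (Axx, Axy, Ayy, Bx, By, C) of an ellipse
conic_coefficients <- function(v) {
  ct <- cos(v[5]); st <- sin(v[5])
  ia2 <- 1 / v[3]^2; ib2 <- 1 / v[4]^2
  A2 <- ct^2 * ia2 + st^2 * ib2
  B2 <- 2 * ct * st * (ia2 - ib2)
  C2 <- st^2 * ia2 + ct^2 * ib2
  c(A2, B2, C2,
    -2 * A2 * v[1] - B2 * v[2],
    -B2 * v[1] - 2 * C2 * v[2],
    A2 * v[1]^2 + B2 * v[1] * v[2] + C2 * v[2]^2 - 1)
}

# contiguous runs of TRUE in ok, with the flanking (outside) sample values
valid_runs <- function(ts, ok) {
  runs <- list()
  i <- 1L
  n <- length(ts)
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- list(
        lo_out = if (i == 1L) 0 else ts[i - 1L], lo_in = ts[i],
        hi_in = ts[j], hi_out = if (j == n) ts[n] + (ts[2] - ts[1]) else ts[j + 1L])
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# bisect the validity predicate between an invalid and a valid sample;
# works for either end of the interval (the arguments need not be ordered)
refine_boundary <- function(valid_at, t_invalid, t_valid, steps = 40L) {
  for (k in seq_len(steps)) {
    mid <- (t_invalid + t_valid) / 2
    if (valid_at(mid)) t_valid <- mid else t_invalid <- mid
  }
  t_valid
}

# golden-section minimisation of a unimodal |discrepancy| objective
golden_min <- function(f, lo, hi, tol = 1e-6, max_iter = 200L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  width0 <- b - a
  it <- 0L
  while ((b - a) > tol * width0 && it < max_iter) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
    it <- it + 1L
  }
  tmin <- if (f1 <= f2) x1 else x2
  list(tmin = tmin, fmin = min(f1, f2))
}

#' Build the rational starting diagram
#'
#' Three circles: the two curves with the largest required totals are laid
#' out as an exact two-set area-proportional diagram by lens-area bisection
#' ([two_circle_layout()]); the third circle's centre is found along the
#' tangent-angle bisector so the triple-overlap region comes out close to
#' its required area ([place_third()]). Rotation angles 0, pi/3 and 2*pi/3
#' are assigned to curves `a`, `b` and `c` so the whole rotation space is
#' reachable once the optimizer starts stretching the circles into
#' ellipses. Deterministic, and invariant under rescaling of `w`.
#'
#' @param w Quantities as accepted by [quantities7()].
#' @return A [venn3_diagram()] of three circles.
#' @examples
#' starting_diagram(c(a = 1, b = 1, c = 1, ab = 0.5, ac = 0.5, bc = 0.5, abc = 0.25))
#' @export
starting_diagram <- function(w) {
  wp <- scale_quantities(w)
  ct <- curve_totals(wp)
  l1 <- ct$largest[1]; l2 <- ct$largest[2]; l3 <- ct$third
  pair_label <- function(x, y) paste(sort(c(x, y), method = "radix"), collapse = "")
  overlap12 <- wp[[pair_label(l1, l2)]] + wp[["abc"]]
  two <- two_circle_layout(ct$totals[[l1]], ct$totals[[l2]], overlap12)
  r3 <- sqrt(ct$totals[[l3]] / pi)
  third <- place_third(two$e1, two$e2, r3, wp[["abc"]])
  placed <- list(two$e1, two$e2, third$e3)
  names(placed) <- c(l1, l2, l3)
  rot <- c(a = 0, b = pi / 3, c = 2 * pi / 3)
  curves <- lapply(CURVE_LABELS, function(lbl) {
    v <- as.numeric(placed[[lbl]])
    ellipse(v[1], v[2], v[3], v[4], rot[[lbl]])
  })
  venn3_diagram(curves[[1]], curves[[2]], curves[[3]])
}
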