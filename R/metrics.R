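#' Validate and order a set of seven region quantities
#'
#' @param w A named numeric vector (or coercible list) with one strictly
#'   positive value for each region label `a, b, c, ab, ac, bc, abc`, in
#'   any order.
#' @return A named numeric vector in canonical label order.
#' @examples
#' quantities7(c(abc = 0.15, a = 0.25, b = 0.01, c = 0.11,
#'               ab = 0.10, ac = 0.29, bc = 0.03))
#' @export
quantities7 <- function(w) {
  w <- unlist(w)
  if (is.null(names(w)) && length(w) == 7L) {
    names(w) <- REGION_LABELS
  }
  if (!all(REGION_LABELS %in% names(w)) || length(w) != 7L)
    stop("quantities must carry exactly the seven region labels a, b, c, ab, ac, bc, abc")
  w <- as.numeric(w[REGION_LABELS])
  names(w) <- REGION_LABELS
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all seven region quantities must be strictly positive and finite")
  w
}

#' Scale quantities so the smallest becomes 100
#'
#' Every quantity is multiplied by `100 / min(w)`, so proportional inputs
#' map to identical scaled quantities and hence to identical diagrams. The
#' scaled quantity of a region is the area, in squared canvas units, the
#' region should have in the fitted diagram.
#'
#' @param w Quantities as accepted by [quantities7()].
#' @return The scaled quantities, minimum exactly 100.
#' @export
scale_quantities <- function(w) {
  w <- quantities7(w)
  w * (100 / min(w))
}

#' Per-region area-proportion error
#'
#' `regionError(r) = | A(r)/sum(A) - w(r)/sum(w) |`: the absolute
#' difference between the share of the total diagram area taken by region
#' `r` and the share required of it. Always in `[0, 1]`.
#'
#' @param label One of the seven region labels; use `NULL` for all seven.
#' @param areas A [region_areas()] result or a named numeric of areas.
#' @param w Required quantities.
#' @return The region error(s).
#' @export
region_error <- function(label = NULL, areas, w) {
  A <- areas_vector(areas)
  w <- quantities7(w)
  if (sum(A) <= 0) stop("total diagram area must be positive")
  err <- abs(A / sum(A) - w / sum(w))
  if (is.null(label)) err else err[[match.arg(label, REGION_LABELS)]]
}

areas_vector <- function(areas) {
  if (inherits(areas, "region_areas")) areas <- areas$areas
  areas <- unlist(areas)
  if (!is.null(names(areas)) && all(REGION_LABELS %in% names(areas)))
    areas <- areas[REGION_LABELS]
  if (length(areas) != 7L || any(!is.finite(areas)) || any(areas < 0))
    stop("areas must be seven finite non-negative values")
  as.numeric(areas)
}

#' Diagram-level error
#'
#' The maximum of the seven [region_error()] values: a single number in
#' `[0, 1]` summarising how far the diagram's area proportions are from the
#' required ones. A diagram is *good* when it has the 3-Venn topology and
#' `diag_error <= 1e-6`.
#'
#' @inheritParams region_error
#' @return A scalar in `[0, 1]`.
#' @export
diag_error <- function(areas, w) {
  A <- areas_vector(areas)
  w <- quantities7(w)
  if (sum(A) <= 0) stop("total diagram area must be positive")
  .diag_error_cpp(A, w)
}

#' Is a diagram good for the required quantities?
#'
#' `TRUE` iff the diagram passes [validate_topology()] and its
#' [diag_error()] is at most `1e-6`.
#'
#' @param d A [venn3_diagram()].
#' @param w Required quantities.
#' @export
is_good <- function(d, w) {
  r <- region_areas(d)
  if (!r$valid) return(FALSE)
  diag_error(r, w) <= 1e-6
}

cost_generic <- function(areas, w_scaled, term) {
  A <- areas_vector(areas)
  wp <- quantities7(w_scaled)
  if (any(A <= 0)) return(Inf)
  mean(term(wp, A))
}

#' Optimization cost of a diagram
#'
#' `cost_F6` is the mean over the seven regions of
#' `(w'(r) - A(r))^2 / A(r)`, where `w'` are the scaled quantities
#' ([scale_quantities()]) and `A` the actual region areas. The `A(r)`
#' denominator blows the cost up as any region collapses, which steers the
#' hill climb away from the classic local minimum in which a region is
#' shrunk to (near) non-existence. Any non-positive region area scores
#' `Inf` and is therefore never accepted as a move.
#'
#' `cost_F7` and `cost_F8` are the dimensionless variants with per-region
#' terms `(w' - A)^2 / A^2` and `|w' - A| / A`; they are provided for
#' comparison but are not used by the optimizer.
#'
#' @param areas Region areas ([region_areas()] result or named numeric).
#' @param w_scaled Scaled quantities (required region areas).
#' @return A non-negative scalar (possibly `Inf`).
#' @export
cost_F6 <- function(areas, w_scaled) {
  cost_generic(areas, w_scaled, function(wp, A) (wp - A)^2 / A)
}

#' @rdname cost_F6
#' @export
cost_F7 <- function(areas, w_scaled) {
  cost_generic(areas, w_scaled, function(wp, A) (wp - A)^2 / A^2)
}

#' @rdname cost_F6
#' @export
cost_F8 <- function(areas, w_scaled) {
  cost_generic(areas, w_scaled, function(wp, A) abs(wp - A) / A)
}

#' Venneuler-style stress of a diagram
#'
#' The normalized loss used by circle-based statistical fitting: regress
#' the actual areas on the required quantities through the origin
#' (`beta = sum(A w) / sum(w^2)`) and return the residual sum of squares
#' divided by the total sum of squares of the areas,
#' `sum((A - beta w)^2) / sum(A^2)`. Zero iff the areas are exactly
#' proportional to the quantities; always in `[0, 1]`.
#'
#' @param areas Region areas.
#' @param w Required quantities (unscaled; the value is scale-invariant).
#' @return A scalar in `[0, 1]`.
#' @export
stress <- function(areas, w) {
  A <- areas_vector(areas)
  w <- quantities7(w)
  if (all(A == 0)) stop("stress undefined for an all-zero area vector")
  beta <- sum(A * w) / sum(w^2)
  sum((A - beta * w)^2) / sum(A^2)
}
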