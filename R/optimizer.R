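#' Search parameters of the hill climb
#'
#' @param p_gamma Centre step in canvas units (default 10).
#' @param p_alphabeta Semi-axis scaling fraction (default 0.05, i.e. 5%).
#' @param p_theta Rotation step in radians (default `2*pi/3`).
#' @return A named numeric vector of the three step parameters.
#' @export
search_params <- function(p_gamma = 10, p_alphabeta = 0.05, p_theta = 2 * pi / 3) {
  stopifnot(p_gamma > 0, p_alphabeta > 0, p_alphabeta < 1, p_theta > 0)
  c(p_gamma = p_gamma, p_alphabeta = p_alphabeta, p_theta = p_theta)
}

#' Candidate moves for one ellipse
#'
#' The neighbourhood explored at each step of the hill climb, in the fixed
#' enumeration order the optimizer uses (determinism requires a fixed
#' order):
#' * `candidate_centres()`: the eight centres with one or both coordinates
#'   shifted by `p_gamma` - order E, W, N, S, NE, NW, SE, SW;
#' * `candidate_semiaxes()`: the eight semi-axis variants with one or both
#'   axes scaled up or down by the fraction `p_alphabeta` - only `s1`
#'   (up, down), only `s2` (up, down), both same sign (up, down), opposite
#'   signs (`s1` up `s2` down, `s1` down `s2` up);
#' * `candidate_rotations()`: rotation increased or decreased by `p_theta`,
#'   renormalised into `[0, pi)`.
#'
#' @param e An [ellipse()].
#' @param p_gamma,p_alphabeta,p_theta Step parameters, see [search_params()].
#' @return A list of ellipses (8, 8 and 2 respectively).
#' @export
candidate_centres <- function(e, p_gamma) {
  stopifnot(p_gamma > 0)
  v <- as.numeric(e)
  dx <- c(1, -1, 0, 0, 1, -1, 1, -1) * p_gamma
  dy <- c(0, 0, 1, -1, 1, 1, -1, -1) * p_gamma
  lapply(1:8, function(k) ellipse(v[1] + dx[k], v[2] + dy[k], v[3], v[4], v[5]))
}

#' @rdname candidate_centres
#' @export
candidate_semiaxes <- function(e, p_alphabeta) {
  stopifnot(p_alphabeta > 0, p_alphabeta < 1)
  v <- as.numeric(e)
  up <- 1 + p_alphabeta
  dn <- 1 - p_alphabeta
  f1 <- c(up, dn, 1, 1, up, dn, up, dn)
  f2 <- c(1, 1, up, dn, up, dn, dn, up)
  lapply(1:8, function(k) ellipse(v[1], v[2], v[3] * f1[k], v[4] * f2[k], v[5]))
}

#' @rdname candidate_centres
#' @export
candidate_rotations <- function(e, p_theta) {
  stopifnot(p_theta > 0)
  v <- as.numeric(e)
  lapply(c(p_theta, -p_theta), function(dt)
    ellipse(v[1], v[2], v[3], v[4], canonical_angle(v[5] + dt)))
}

#' One hill-climbing run
#'
#' Greedy local search over the diagram's fifteen degrees of freedom. Each
#' iteration visits the curves in the fixed order `a`, `b`, `c`; for each
#' curve it tries the eight centre moves, then the eight semi-axis moves,
#' then the two rotation moves (see [candidate_centres()]), applying every
#' candidate that strictly reduces [cost_F6()] against the scaled
#' quantities (acceptance is immediate and cumulative, so later candidates
#' are evaluated against the already-updated diagram). A candidate that
#' breaks the 3-Venn topology scores infinite cost and is never accepted.
#' After a full iteration, any step parameter whose move class saw no
#' accepted change on any curve is halved; the run ends *accurate* as soon
#' as the diagram is good ([is_good()]) and *inaccurate* when all three
#' parameters have fallen to `1e-6`.
#'
#' In `circles` mode the semi-axis moves are restricted to the two uniform
#' scalings (both axes up, both down) and rotation moves are skipped.
#'
#' @param w Quantities as accepted by [quantities7()].
#' @param start A valid [venn3_diagram()] to start from.
#' @param params Step parameters from [search_params()].
#' @param mode `"ellipses"` or `"circles"`.
#' @param audit If `TRUE`, return the accepted-move log (iteration, curve,
#'   move class, cost before/after).
#' @param max_iter Safety cap on iterations.
#' @return A list with `diagram`, `diag_error`, `accurate`, `iterations`,
#'   `cost` and (optionally) `audit`.
#' @export
hill_climb <- function(w, start, params = search_params(),
                       mode = c("ellipses", "circles"),
                       audit = FALSE, max_iter = 20000L) {
  mode <- match.arg(mode)
  w <- quantities7(w)
  wp <- scale_quantities(w)
  E <- as_diagram_matrix(start)
  if (!.region_areas_cpp(E)$valid)
    stop("the starting diagram must have a valid 3-Venn topology")
  res <- .hill_climb_cpp(E, w, wp, params[["p_gamma"]], params[["p_alphabeta"]],
                         params[["p_theta"]], mode == "circles", audit,
                         as.integer(max_iter))
  res$diagram <- venn3_diagram(res$diagram[1, ], res$diagram[2, ], res$diagram[3, ])
  res
}

#' Fit an area-proportional 3-Venn diagram
#'
#' The package's main entry point. Scales the seven quantities so the
#' smallest becomes 100, builds the rational [starting_diagram()], and runs
#' the hill climb ([hill_climb()]) with default step parameters (centre
#' step 10 canvas units, semi-axis step 5%, rotation step `2*pi/3`). If
#' the run ends in a local minimum (inaccurate) and `rerun` is enabled, the
#' optimization is rerun from a fresh starting diagram with all three
#' starting step parameters 20% larger than in the previous run, up to
#' `max_reruns` times; if no run is accurate the diagram with the lowest
#' [diag_error()] across all runs is returned. The whole procedure is
#' deterministic and invariant to rescaling of `w`.
#'
#' @param w Quantities as accepted by [quantities7()].
#' @param rerun Enable the rerun escape (default `TRUE`).
#' @param mode `"ellipses"` (default) or `"circles"` (semi-axes constrained
#'   equal, rotations skipped).
#' @param max_reruns Maximum number of reruns (default 10).
#' @param audit Keep per-run accepted-move logs.
#' @return An object of class `venn3_fit`: a list with `diagram`
#'   (a [venn3_diagram()]), `diag_error`, `accurate` (`TRUE` iff the final
#'   diagram is good), `iterations` (total across runs), `reruns_used`,
#'   `mode`, `cost`, and `runs` (per-run summaries).
#' @examples
#' fit <- fit_venn3(c(a = 10, b = 8, c = 6, ab = 3, ac = 3, bc = 2, abc = 1))
#' fit$accurate
#' fit$diag_error
#' @export
fit_venn3 <- function(w, rerun = TRUE, mode = c("ellipses", "circles"),
                      max_reruns = 10L, audit = FALSE) {
  mode <- match.arg(mode)
  w <- quantities7(w)
  start <- starting_diagram(w)
  base <- search_params()
  n_runs <- if (rerun) max_reruns + 1L else 1L
  best <- NULL
  total_iter <- 0L
  runs <- vector("list", n_runs)
  used <- 0L
  for (k in seq_len(n_runs)) {
    params <- search_params(base[["p_gamma"]] * 1.2^(k - 1),
                            base[["p_alphabeta"]] * 1.2^(k - 1),
                            base[["p_theta"]] * 1.2^(k - 1))
    res <- hill_climb(w, start, params, mode, audit = audit)
    total_iter <- total_iter + res$iterations
    runs[[k]] <- list(iterations = res$iterations, accurate = res$accurate,
                      diag_error = res$diag_error,
                      audit = if (audit) res$audit else NULL)
    de <- if (is.finite(res$diag_error)) res$diag_error else Inf
    if (is.null(best) || de < best$de) best <- list(res = res, de = de)
    used <- k - 1L
    if (res$accurate) break
  }
  out <- list(diagram = best$res$diagram, diag_error = best$res$diag_error,
              accurate = best$res$accurate, iterations = total_iter,
              reruns_used = used, mode = mode, cost = best$res$cost,
              runs = runs[seq_len(used + 1L)])
  class(out) <- "venn3_fit"
  out
}

#' @export
print.venn3_fit <- function(x, ...) {
  cat(sprintf("3-Venn fit (%s): %s, diagError = %.3g, %d iteration%s, %d rerun%s\n",
              x$mode, if (x$accurate) "accurate" else "inaccurate",
              x$diag_error, x$iterations, if (x$iterations == 1) "" else "s",
              x$reruns_used, if (x$reruns_used == 1) "" else "s"))
  print(x$diagram, ...)
  invisible(x)
}
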