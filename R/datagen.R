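#' Random drawable quantities (region areas of a random valid diagram)
#'
#' Samples three ellipses (centres uniform in `[0, 100]^2`, semi-axes
#' uniform in `[10, 50]`, rotations uniform in `[0, pi)`) and rejects the
#' triple until it forms a valid 3-Venn topology. The seven region areas
#' are then scaled to a total of `1e5` and rounded to integers (resampling
#' if rounding kills a region), so a drawable quantity set by construction:
#' the generating diagram is kept as a certificate of drawability.
#'
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param max_attempts Rejection-loop bound.
#' @return A list with `w` (the seven integer quantities) and `diagram`
#'   (the certificate [venn3_diagram()]).
#' @export
random_drawable_item <- function(seed, max_attempts = 10000L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_attempts)) {
    E <- cbind(cx = runif(3, 0, 100), cy = runif(3, 0, 100),
               s1 = runif(3, 10, 50), s2 = runif(3, 10, 50),
               theta = runif(3, 0, pi))
    res <- .region_areas_cpp(E)
    if (!res$valid) next
    q <- round(res$areas / sum(res$areas) * 1e5)
    if (any(q < 1)) next
    w <- quantities7(stats::setNames(q, REGION_LABELS))
    d <- venn3_diagram(E[1, ], E[2, ], E[3, ])
    return(list(w = w, diagram = d))
  }
  stop("failed to sample a valid diagram within ", max_attempts, " attempts")
}

#' Random uniform quantities
#'
#' Seven independent integers drawn uniformly from `[1, 10000]`. Whether
#' such a quantity set admits an accurate ellipse diagram is unknown a
#' priori.
#'
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @return The seven quantities (named integer-valued numeric).
#' @export
random_uniform_item <- function(seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  quantities7(stats::setNames(sample.int(10000L, 7L, replace = TRUE), REGION_LABELS))
}

# stable per-item seed derivation: a linear congruential mix of the library
# seed and the item index, exact in double precision (inputs < 2^31)
derive_seed <- function(seed, index) {
  as.integer(((seed %% 2147483647) * 69069 + index * 1234567) %% 2147483647)
}

#' Generate a library of random quantity sets
#'
#' Batches [random_drawable_item()] (`kind = "L1"`) or
#' [random_uniform_item()] (`kind = "L2"`), with per-item seeds derived
#' reproducibly from the library seed, so the same call always produces
#' the same library on any platform.
#'
#' @param n Number of items (>= 1).
#' @param kind `"L1"` (drawable-by-construction) or `"L2"` (uniform random).
#' @param seed Library seed (integer).
#' @return An object of class `venn_library`: a list with `quantities`
#'   (an `n` x 7 data frame in label order), `kind`, `seed`, and for L1
#'   `certificates` (the generating diagrams).
#' @examples
#' lib <- generate_library(3, "L2", seed = 42)
#' lib$quantities
#' @export
generate_library <- function(n, kind = c("L1", "L2"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  items <- vector("list", n)
  certs <- if (kind == "L1") vector("list", n) else NULL
  for (i in seq_len(n)) {
    s <- derive_seed(seed, i)
    if (kind == "L1") {
      it <- random_drawable_item(s)
      items[[i]] <- it$w
      certs[[i]] <- it$diagram
    } else {
      items[[i]] <- random_uniform_item(s)
    }
  }
  q <- as.data.frame(do.call(rbind, items))
  names(q) <- REGION_LABELS
  structure(list(quantities = q, kind = kind, seed = as.integer(seed),
                 certificates = certs),
            class = "venn_library")
}

#' @export
print.venn_library <- function(x, ...) {
  cat(sprintf("%s library: %d quantity sets (seed %d)\n",
              x$kind, nrow(x$quantities), x$seed))
  print(utils::head(x$quantities), ...)
  invisible(x)
}

#' Write or read a library as CSV
#'
#' The CSV has the header `a,b,c,ab,ac,bc,abc`, one quantity set per row;
#' values round-trip exactly. For an L1 library a companion file
#' `<path>.certificates.csv` stores the generating ellipse parameters.
#'
#' @param library A `venn_library`.
#' @param path Output CSV path.
#' @param certificates Also write the L1 certificate diagrams.
#' @export
write_library <- function(library, path, certificates = !is.null(library$certificates)) {
  utils::write.csv(library$quantities, path, row.names = FALSE, quote = FALSE)
  if (certificates && !is.null(library$certificates)) {
    rows <- do.call(rbind, lapply(seq_along(library$certificates), function(i) {
      E <- as_diagram_matrix(library$certificates[[i]])
      data.frame(item = i, curve = rownames(E), cx = E[, 1], cy = E[, 2],
                 s1 = E[, 3], s2 = E[, 4], theta = E[, 5], row.names = NULL)
    }))
    utils::write.csv(rows, paste0(path, ".certificates.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_library
#' @param kind Library kind recorded on read.
#' @export
read_library <- function(path, kind = "L2") {
  q <- read_quantities(path)
  structure(list(quantities = q, kind = kind, seed = NA_integer_,
                 certificates = NULL),
            class = "venn_library")
}
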