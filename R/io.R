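#' Read quantity sets from CSV, TSV or JSON
#'
#' CSV/TSV files must carry a header with the seven region labels
#' `a, b, c, ab, ac, bc, abc` in any order, one quantity set per row. JSON
#' may be a single object keyed by the labels or an array of such objects.
#' All values must be strictly positive numbers.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"json"`.
#' @return A data frame with the seven columns in canonical label order,
#'   one row per quantity set.
#' @examples
#' read_quantities(system.file("extdata", "ckd_survey.csv", package = "apvenn"))
#' @export
read_quantities <- function(path, format = c("auto", "csv", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", json = "json",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (is.data.frame(x)) x else as.data.frame(as.list(unlist(x)))
    })
  missing <- setdiff(REGION_LABELS, names(df))
  if (length(missing))
    stop("missing region column(s): ", paste(missing, collapse = ", "))
  df <- df[REGION_LABELS]
  for (j in REGION_LABELS) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(sprintf("row %d, column '%s': quantities must be strictly positive numbers",
                   bad[1], j))
    df[[j]] <- v
  }
  df
}

fit_or_diagram <- function(x) {
  if (inherits(x, "venn3_fit")) x$diagram else x
}

# map a diagram into a 600x600 viewport (y still increases upward); returns
# the transformed 3x5 matrix
normalize_viewport <- function(E, size = 600, margin = 0.05) {
  ex <- sqrt(E[, "s1"]^2 * cos(E[, "theta"])^2 + E[, "s2"]^2 * sin(E[, "theta"])^2)
  ey <- sqrt(E[, "s1"]^2 * sin(E[, "theta"])^2 + E[, "s2"]^2 * cos(E[, "theta"])^2)
  x0 <- min(E[, "cx"] - ex); x1 <- max(E[, "cx"] + ex)
  y0 <- min(E[, "cy"] - ey); y1 <- max(E[, "cy"] + ey)
  span <- max(x1 - x0, y1 - y0)
  s <- size * (1 - 2 * margin) / span
  E[, "cx"] <- (E[, "cx"] - (x0 + x1) / 2) * s + size / 2
  E[, "cy"] <- (E[, "cy"] - (y0 + y1) / 2) * s + size / 2
  E[, "s1"] <- E[, "s1"] * s
  E[, "s2"] <- E[, "s2"] * s
  E
}

CURVE_COLOURS <- c(a = "#1b9e77", b = "#d95f02", c = "#7570b3")
CURVE_DASHES <- c(a = "", b = "14,6", c = "4,5")
CURVE_WIDTHS <- c(a = 3, b = 4, c = 2)

#' Export a fitted diagram
#'
#' Writes the diagram as SVG (three `<ellipse>` elements with
#' heterogeneous stroke channels - distinct colour, dash pattern and
#' width per curve - over translucent fills), as a PNG raster of the same
#' drawing, or as plain text with one full-precision line per curve
#' (`label cx cy s1 s2 theta`), which re-imports to an identical diagram
#' via [read_diagram()]. SVG and PNG are rescaled to a 600 x 600 viewport;
#' the text export keeps the model coordinates.
#'
#' @param x A `venn3_fit` or a [venn3_diagram()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"svg"`, `"png"` or `"txt"`.
#' @param size Viewport side in pixels for svg/png.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(x, path, format = c("auto", "svg", "png", "txt"),
                          size = 600) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, svg = "svg", png = "png", txt = "txt",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  d <- fit_or_diagram(x)
  E <- as_diagram_matrix(d)
  switch(format,
    txt = {
      lines <- c("# label cx cy s1 s2 theta",
                 vapply(CURVE_LABELS, function(l)
                   paste(l, paste(sprintf("%.17g", E[l, ]), collapse = " ")),
                   character(1)))
      writeLines(lines, path)
    },
    svg = writeLines(render_svg(E, size), path),
    png = render_png(E, path, size))
  invisible(path)
}

render_svg <- function(E, size) {
  V <- normalize_viewport(E, size)
  header <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                      size, size, size, size),
              sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))
  shapes <- vapply(CURVE_LABELS, function(l) {
    cx <- V[l, "cx"]
    cy <- size - V[l, "cy"] # svg y points down
    deg <- -V[l, "theta"] * 180 / pi
    dash <- if (nzchar(CURVE_DASHES[[l]]))
      sprintf(' stroke-dasharray="%s"', CURVE_DASHES[[l]]) else ""
    sprintf(paste0('<ellipse cx="%.4f" cy="%.4f" rx="%.4f" ry="%.4f" ',
                   'transform="rotate(%.4f %.4f %.4f)" fill="%s" fill-opacity="0.18" ',
                   'stroke="%s" stroke-width="%g"%s/>'),
            cx, cy, V[l, "s1"], V[l, "s2"], deg, cx, cy,
            CURVE_COLOURS[[l]], CURVE_COLOURS[[l]], CURVE_WIDTHS[[l]], dash)
  }, character(1))
  c(header, shapes, "</svg>")
}

render_png <- function(E, path, size) {
  V <- normalize_viewport(E, size)
  grDevices::png(path, width = size, height = size)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, size), ylim = c(0, size), asp = 1)
  t <- seq(0, 2 * pi, length.out = 361)
  lty <- c(a = 1, b = 2, c = 3)
  for (l in CURVE_LABELS) {
    u <- V[l, "s1"] * cos(t); v <- V[l, "s2"] * sin(t)
    x <- V[l, "cx"] + cos(V[l, "theta"]) * u - sin(V[l, "theta"]) * v
    y <- V[l, "cy"] + sin(V[l, "theta"]) * u + cos(V[l, "theta"]) * v
    graphics::polygon(x, y, border = NA,
                      col = grDevices::adjustcolor(CURVE_COLOURS[[l]], alpha.f = 0.18))
    graphics::lines(x, y, col = CURVE_COLOURS[[l]], lwd = CURVE_WIDTHS[[l]],
                    lty = lty[[l]])
  }
  invisible(path)
}

#' Re-import a text diagram export
#'
#' @param path A file written by [write_diagram()] with `format = "txt"`.
#' @return A [venn3_diagram()].
#' @export
read_diagram <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) != 3L) stop("expected three curve lines in ", path)
  rows <- lapply(lines, function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1)
  if (!setequal(labels, CURVE_LABELS)) stop("curve labels must be a, b, c")
  vals <- lapply(rows, function(r) as.numeric(r[2:6]))
  names(vals) <- labels
  venn3_diagram(vals[["a"]], vals[["b"]], vals[["c"]])
}

#' Evaluate the optimizer over a library
#'
#' Runs [fit_venn3()] on every quantity set of a library and aggregates the
#' outcome: the fraction of good diagrams, diagError statistics over the
#' non-good ones, iteration statistics and a rerun histogram. Per-item
#' records can be streamed to CSV for inspection.
#'
#' @param library A `venn_library` (see [generate_library()],
#'   [read_library()]).
#' @param mode `"ellipses"` or `"circles"`.
#' @param rerun Enable the rerun escape.
#' @param per_item_csv Optional path for the per-item record CSV.
#' @param progress Print a dot every 25 items.
#' @return A list of class `venn_eval` with `n`, `fraction_good`,
#'   `diag_error_stats` (min/median/mean/max over non-good items),
#'   `iteration_stats`, `rerun_histogram` and `records` (per-item data
#'   frame).
#' @export
evaluate_library <- function(library, mode = c("ellipses", "circles"),
                             rerun = TRUE, per_item_csv = NULL,
                             progress = FALSE) {
  mode <- match.arg(mode)
  q <- library$quantities
  n <- nrow(q)
  stopifnot(n >= 1)
  rec <- data.frame(item = seq_len(n), diag_error = NA_real_, accurate = NA,
                    iterations = NA_integer_, reruns = NA_integer_,
                    error = NA_character_)
  for (i in seq_len(n)) {
    w <- quantities7(as.numeric(q[i, ]))
    f <- tryCatch(fit_venn3(w, rerun = rerun, mode = mode), error = identity)
    if (inherits(f, "error")) {
      rec$error[i] <- conditionMessage(f)
    } else {
      rec$diag_error[i] <- f$diag_error
      rec$accurate[i] <- f$accurate
      rec$iterations[i] <- f$iterations
      rec$reruns[i] <- f$reruns_used
    }
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  if (!is.null(per_item_csv))
    utils::write.csv(rec, per_item_csv, row.names = FALSE)
  okrec <- rec[!is.na(rec$accurate), ]
  nong <- okrec[!okrec$accurate, ]
  stats_of <- function(x) if (length(x))
    c(min = min(x), median = stats::median(x), mean = mean(x), max = max(x))
  else c(min = NA_real_, median = NA_real_, mean = NA_real_, max = NA_real_)
  out <- list(
    n = n,
    fraction_good = mean(okrec$accurate),
    diag_error_stats = stats_of(nong$diag_error),
    iteration_stats = c(median = stats::median(okrec$iterations),
                        mean = mean(okrec$iterations)),
    rerun_histogram = table(okrec$reruns),
    records = rec)
  class(out) <- "venn_eval"
  out
}

#' @export
print.venn_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d quantity sets: %.1f%% good\n",
              x$n, 100 * x$fraction_good))
  if (any(!is.na(x$diag_error_stats)))
    cat("diagError of non-good diagrams:\n",
        paste(sprintf("  %s = %.3g", names(x$diag_error_stats),
                      x$diag_error_stats), collapse = "\n"), "\n", sep = "")
  cat(sprintf("iterations: median %g, mean %.1f\n",
              x$iteration_stats[["median"]], x$iteration_stats[["mean"]]))
  invisible(x)
}
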