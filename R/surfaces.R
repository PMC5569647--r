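# classifying measures for each cell shape on a plane:
# square bins both axis measures; the parallelogram shapes swap one axis
# for the derived measure (AC horizontal / CP vertical parallelograms of
# double-classified data on the Lexis plane).
.cell_measures <- function(spec, shape) {
  switch(shape,
         square = c(spec$x, spec$y),
         horizontal = c(spec$y, spec$derived),
         vertical = c(spec$x, spec$derived),
         .stop_demotime("unknown cell shape", "demotime_invalid"))
}

#' Bin a coordinate into a surface cell
#'
#' Half-open completed-year binning: a measure value v falls in cell
#' `floor(v / width) * width` on each classifying measure. The cell
#' index is reported as the lower edges of the two classifying measures
#' (e.g. TAL width 1, A = 80.3, T = 2.6 gives cell (80, 2)); an
#' observation exactly at death lands in the T = 0 row.
#'
#' @param coord a [demo_coord()] with the required measures present.
#' @param plane a [plane_spec()].
#' @param width cell width in years (> 0), default 1.
#' @param shape `"square"`, `"horizontal"` (y measure x derived), or
#'   `"vertical"` (x measure x derived) parallelogram.
#' @return named numeric of length 2: lower cell edges.
#' @export
assign_cell <- function(coord, plane, width = 1,
                        shape = c("square", "horizontal", "vertical")) {
  stopifnot(inherits(plane, "plane_spec"))
  shape <- match.arg(shape)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    .stop_demotime("`width` must be positive", "demotime_invalid")
  v <- unclass(as_demo_coord(coord))
  meas <- .cell_measures(plane, shape)
  vals <- v[meas]
  if (anyNA(vals))
    .stop_demotime(paste("missing measure(s):",
                         paste(meas[is.na(vals)], collapse = ", ")),
                   "demotime_missing")
  neg <- intersect(meas, c("A", "T", "L"))
  if (length(neg) && any(v[neg] < 0))
    .stop_demotime("negative duration measure cannot be binned",
                   "demotime_domain")
  out <- floor(vals / width) * width
  names(out) <- meas
  out
}

#' Aggregate panel observations into a surface grid
#'
#' Resolves each observation to its six-measure coordinate via the
#' lifeline join, bins on the chosen plane, and aggregates a count and
#' (optionally) a mean payload per cell. Observations on censored
#' lifelines cannot be placed on death-anchored planes; they are dropped
#' and counted in the grid's `dropped` field, so that
#' `sum(counts) + dropped + filtered` equals the input size.
#'
#' @param observations an [observations()] data frame.
#' @param lifelines a [lifelines()] data frame.
#' @param plane a [plane_spec()] (default the TAL plane).
#' @param width cell width in years.
#' @param statistic `"mean"` (per-cell average payload) or `"count"`.
#' @param shape cell shape, see [assign_cell()].
#' @param weights optional non-negative observation weights (defaults to
#'   unweighted); weighted cell means use them, counts stay raw.
#' @param age_range optional `c(lo, hi)`: keep observations with
#'   chronological age in `[lo, hi)`; removals counted in `filtered`.
#' @return object of class `surface_grid`: list with `plane`, `width`,
#'   `shape`, `statistic`, `measures`, a `cells` data frame (`x`, `y`,
#'   `count`, `value`), and bookkeeping fields `dropped`, `filtered`,
#'   `n_input`.
#' @export
aggregate_surface <- function(observations, lifelines,
                              plane = plane_spec("TAL"), width = 1,
                              statistic = c("mean", "count"),
                              shape = c("square", "horizontal", "vertical"),
                              weights = NULL, age_range = NULL) {
  statistic <- match.arg(statistic)
  shape <- match.arg(shape)
  stopifnot(inherits(plane, "plane_spec"))
  if (!is.numeric(width) || width <= 0)
    .stop_demotime("`width` must be positive", "demotime_invalid")
  n_input <- nrow(observations)
  empty <- function(dropped, filtered) {
    structure(list(plane = plane, width = width, shape = shape,
                   statistic = statistic,
                   measures = .cell_measures(plane, shape),
                   cells = data.frame(x = numeric(0), y = numeric(0),
                                      count = integer(0), value = numeric(0)),
                   dropped = dropped, filtered = filtered, n_input = n_input),
              class = "surface_grid")
  }
  if (n_input == 0L) return(empty(0L, 0L))
  mt <- measures_table(observations, lifelines)
  if (is.null(weights)) weights <- rep(1, n_input)
  if (length(weights) != n_input || any(weights < 0, na.rm = TRUE))
    .stop_demotime("`weights` must be non-negative, one per observation",
                   "demotime_invalid")
  filtered <- 0L
  if (!is.null(age_range)) {
    keep <- mt$A >= age_range[1] & mt$A < age_range[2]
    filtered <- sum(!keep)
    mt <- mt[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  meas <- .cell_measures(plane, shape)
  usable <- !Reduce(`|`, lapply(meas, function(m) is.na(mt[[m]])))
  dropped <- sum(!usable)
  mt <- mt[usable, , drop = FALSE]
  weights <- weights[usable]
  if (nrow(mt) == 0L) return(empty(dropped, filtered))
  if (statistic == "mean" && anyNA(mt$value))
    .stop_demotime("statistic = \"mean\" requires a payload value on every usable observation",
                   "demotime_invalid")
  bx <- floor(mt[[meas[1]]] / width) * width
  by <- floor(mt[[meas[2]]] / width) * width
  key <- paste(bx, by, sep = "|")
  count <- as.integer(tapply(rep(1L, length(key)), key, sum))
  ux <- tapply(bx, key, `[`, 1L)
  uy <- tapply(by, key, `[`, 1L)
  if (statistic == "mean") {
    wsum <- tapply(weights, key, sum)
    vsum <- tapply(weights * mt$value, key, sum)
    val <- as.numeric(vsum / wsum)
  } else {
    val <- as.numeric(count)
  }
  cells <- data.frame(x = as.numeric(ux), y = as.numeric(uy),
                      count = count, value = val)
  cells <- cells[order(cells$x, cells$y), , drop = FALSE]
  rownames(cells) <- NULL
  out <- empty(dropped, filtered)
  out$cells <- cells
  out
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("%s surface (%s cells of width %g, %s): %d populated cells, %d observations\n",
              x$plane$triad, x$shape, x$width, x$statistic,
              nrow(x$cells), sum(x$cells$count)))
  if (x$dropped > 0) cat("  dropped (censored):", x$dropped, "\n")
  if (x$filtered > 0) cat("  filtered (age range):", x$filtered, "\n")
  invisible(x)
}

#' @export
as.data.frame.surface_grid <- function(x, ...) {
  df <- x$cells
  names(df)[1:2] <- x$measures
  df
}

#' Dense matrix view of a surface grid
#'
#' @param grid a `surface_grid`.
#' @param what `"value"` or `"count"`.
#' @return numeric matrix, rows = y cells, columns = x cells, `NA` where
#'   no observation fell.
#' @export
surface_matrix <- function(grid, what = c("value", "count")) {
  what <- match.arg(what)
  cells <- grid$cells
  if (nrow(cells) == 0L) return(matrix(numeric(0), 0, 0))
  xs <- seq(min(cells$x), max(cells$x), by = grid$width)
  ys <- seq(min(cells$y), max(cells$y), by = grid$width)
  M <- matrix(NA_real_, length(ys), length(xs),
              dimnames = list(format(ys, trim = TRUE), format(xs, trim = TRUE)))
  M[cbind(match(cells$y, ys), match(cells$x, xs))] <- cells[[what]]
  M
}

#' One TAL surface per quinquennial (or other) birth cohort
#'
#' Partitions lifelines into half-open birth-cohort bins of
#' `cohort_width` years (an individual born in 1909.9 belongs to
#' 1905-1909) and aggregates a TAL surface per cohort, the layout used to
#' detect whether late-life prevalence varies over thanatological rather
#' than chronological age.
#'
#' @param observations an [observations()] data frame.
#' @param lifelines a [lifelines()] data frame.
#' @param cohort_width cohort bin width in years, default 5.
#' @param width cell width in years.
#' @param statistic,age_range passed to [aggregate_surface()].
#' @return named list of `surface_grid`s, names like `"1905-1909"`.
#' @export
cohort_tal_surfaces <- function(observations, lifelines, cohort_width = 5,
                                width = 1, statistic = "mean",
                                age_range = NULL) {
  if (!is.numeric(cohort_width) || cohort_width <= 0)
    .stop_demotime("`cohort_width` must be positive", "demotime_invalid")
  lo <- floor(lifelines$birth / cohort_width) * cohort_width
  bins <- sort(unique(lo))
  out <- list()
  for (b in bins) {
    ids <- lifelines$id[lo == b]
    ll <- lifelines[lo == b, , drop = FALSE]
    obs <- observations[observations$id %in% ids, , drop = FALSE]
    lab <- sprintf("%d-%d", as.integer(b), as.integer(b + cohort_width - 1))
    out[[lab]] <- aggregate_surface(obs, ll, plane = plane_spec("TAL"),
                                    width = width, statistic = statistic,
                                    age_range = age_range)
  }
  out
}

#' Direction-of-variation diagnostic for a surface
#'
#' Decomposes the count-weighted variance of cell means into the share
#' explained by grouping cells on the y measure (rows) and on the x
#' measure (columns). On a TAL surface, `share_T` near 1 with a smaller
#' `share_A` says contour lines run roughly horizontal: prevalence varies
#' over time to death, not over age. Zero total variance returns both
#' shares as 0.
#'
#' @param grid a `surface_grid` with at least two populated rows and two
#'   populated columns.
#' @return named numeric of length 2, shares in `[0, 1]`, named
#'   `share_<y measure>` and `share_<x measure>`.
#' @export
variation_direction <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  cells <- grid$cells
  if (nrow(cells) < 2L || length(unique(cells$x)) < 2L ||
      length(unique(cells$y)) < 2L)
    .stop_demotime("degenerate grid: need data in at least 2 rows and 2 columns",
                   "demotime_degenerate")
  w <- cells$count
  v <- cells$value
  gm <- weighted.mean(v, w)
  tot <- sum(w * (v - gm)^2) / sum(w)
  share_between <- function(groups) {
    if (tot == 0) return(0)
    gw <- tapply(w, groups, sum)
    gv <- tapply(w * v, groups, sum) / gw
    sum(gw * (gv - gm)^2) / sum(w) / tot
  }
  out <- c(share_between(cells$y), share_between(cells$x))
  names(out) <- paste0("share_", c(grid$measures[2], grid$measures[1]))
  out
}

#' Write a surface grid as long-format delimited text
#'
#' @param grid a `surface_grid`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_surface <- function(grid, path, sep = ",") {
  df <- data.frame(plane = grid$plane$triad, shape = grid$shape,
                   x_measure = grid$measures[1], y_measure = grid$measures[2],
                   x_bin = grid$cells$x, y_bin = grid$cells$y,
                   count = grid$cells$count, value = grid$cells$value)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quick image plot of a surface grid
#'
#' Presentation-only heat map with optional contour lines at chosen
#' prevalence breaks.
#'
#' @param x a `surface_grid`.
#' @param breaks contour levels (default `c(0.1, 0.4)`).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the dense matrix plotted.
#' @export
plot.surface_grid <- function(x, breaks = c(0.1, 0.4), ...) {
  M <- surface_matrix(x)
  xs <- as.numeric(colnames(M)); ys <- as.numeric(rownames(M))
  graphics::image(xs, ys, t(M), xlab = x$measures[1], ylab = x$measures[2],
                  col = grDevices::hcl.colors(24, "Reds", rev = TRUE), ...)
  if (length(breaks) && any(is.finite(M)))
    try(graphics::contour(xs, ys, t(M), levels = breaks, add = TRUE),
        silent = TRUE)
  invisible(M)
}
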