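# default (x, y) orientation of each triad plane
.PLANE_XY <- list(APC = c(x = "P", y = "A"), TPD = c(x = "P", y = "T"),
                  TAL = c(x = "A", y = "T"), LCD = c(x = "C", y = "L"))

#' Specify a temporal plane
#'
#' A temporal plane maps two measures of one triad identity to (x, y);
#' the third member of the triad is the derived measure, visible as the
#' plane's diagonals. Default orientations: AP(C), TP(D), TA(L), LC(D).
#' The `cartesian` mapping sends each measure directly to its axis with a
#' unity aspect ratio; the `isotropic` mapping slants the y axis by 60 so
#' that a unit step of every one of the three measures — including one
#' year travelled along the derived measure's diagonal — has spatial
#' length 1.
#'
#' @param triad one of `"APC"`, `"TPD"`, `"TAL"`, `"LCD"`
#'   (case-insensitive).
#' @param x,y measure labels from the triad; defaults follow the
#'   conventional diagrams.
#' @param mapping `"cartesian"` or `"isotropic"`.
#' @return object of class `plane_spec` with elements `triad`, `x`, `y`,
#'   `derived`, `mapping`.
#' @export
#' @examples
#' plane_spec("TAL", mapping = "isotropic")
plane_spec <- function(triad = c("APC", "TPD", "TAL", "LCD"),
                       x = NULL, y = NULL,
                       mapping = c("cartesian", "isotropic")) {
  triad <- toupper(as.character(triad)[1])
  triad <- match.arg(triad, c("APC", "TPD", "TAL", "LCD"))
  mapping <- match.arg(mapping)
  members <- .TRIADS[[triad]]
  if (is.null(x)) x <- .PLANE_XY[[triad]][["x"]]
  if (is.null(y)) y <- .PLANE_XY[[triad]][["y"]]
  x <- toupper(x); y <- toupper(y)
  if (!all(c(x, y) %in% members) || x == y)
    .stop_demotime(sprintf("x and y must be two distinct members of %s", triad),
                   "demotime_invalid")
  structure(list(triad = triad, x = x, y = y,
                 derived = setdiff(members, c(x, y)), mapping = mapping),
            class = "plane_spec")
}

#' @export
print.plane_spec <- function(x, ...) {
  cat(sprintf("%s plane: x = %s, y = %s, derived = %s (%s mapping)\n",
              x$triad, x$x, x$y, x$derived, x$mapping))
  invisible(x)
}

# Unit-step images of the two plotted measures and of one year travelled
# along the derived measure's diagonal. The triad relation always writes
# one member as the sum of the other two; whether the derived measure is
# that sum or a difference decides both the diagonal direction and (for
# the isotropic mapping) the side to which the y axis slants, so that all
# three steps come out at mutual 60 degrees with length 1.
.plane_basis <- function(spec) {
  id <- .IDENTITIES[[spec$triad]]
  sum_member <- id[["sum"]]
  if (spec$mapping == "cartesian") {
    ex <- c(1, 0); ey <- c(0, 1)
  } else {
    ex <- c(1, 0)
    ey <- if (spec$derived == sum_member) c(1 / 2, sqrt(3) / 2)
          else c(-1 / 2, sqrt(3) / 2)
  }
  # derived = x + y: its iso-lines run along ex - ey; derived = |x - y|:
  # they run along ex + ey (the classical 45-degree cohort diagonal).
  eder <- if (spec$derived == sum_member) ex - ey else ex + ey
  list(ex = ex, ey = ey, eder = eder)
}

#' Project a coordinate onto a temporal plane
#'
#' @param coord a [demo_coord()] with the plane's two measures present
#'   (run [complete_coord()] first if needed).
#' @param spec a [plane_spec()].
#' @return numeric `c(x, y)` in spatial units.
#' @export
#' @examples
#' project_plane(demo_coord(P = 1971, A = 30), plane_spec("APC"))
project_plane <- function(coord, spec) {
  stopifnot(inherits(spec, "plane_spec"))
  v <- unclass(as_demo_coord(coord))
  vx <- v[[spec$x]]; vy <- v[[spec$y]]
  if (anyNA(c(vx, vy)))
    .stop_demotime(sprintf("measures %s and %s must be present for the %s plane",
                           spec$x, spec$y, spec$triad), "demotime_missing")
  bs <- .plane_basis(spec)
  pt <- vx * bs$ex + vy * bs$ey
  c(x = pt[1], y = pt[2])
}

#' Spatial stretch of the derived measure's diagonal
#'
#' Length of the image of one year travelled along the derived measure's
#' diagonal (e.g. one year of a cohort's lifetime on the Lexis diagram).
#' Cartesian planes stretch it by sqrt(2); isotropic planes leave it at 1.
#'
#' @param spec a [plane_spec()].
#' @return a positive number.
#' @export
derived_measure_stretch <- function(spec) {
  stopifnot(inherits(spec, "plane_spec"))
  sqrt(sum(.plane_basis(spec)$eder^2))
}

#' Basis of the 3-D tetrahedral embedding
#'
#' Columns are the unit images of one-year steps in P, A, and T, at
#' mutual 60-degree angles (a regular-tetrahedron vertex fan): e_P along
#' x for reproducibility, e_A in the xy plane, e_T out of it. Under this
#' basis all six measure generators \{e_P, e_A, e_T, e_A - e_P,
#' e_T - e_P, e_T - e_A\} have unit length, so a unit step of every
#' demographic time measure is spatially equal.
#'
#' @return a 3 x 3 numeric matrix with columns `P`, `A`, `T`.
#' @export
tetra_basis <- function() {
  B <- cbind(P = c(1, 0, 0),
             A = c(1 / 2, sqrt(3) / 2, 0),
             T = c(1 / 2, sqrt(3) / 6, sqrt(6) / 3))
  rownames(B) <- c("x", "y", "z")
  B
}

#' Embed a complete coordinate in the 3-D hexad space
#'
#' Position = P e_P + A e_A + T e_T with the [tetra_basis()] vectors. The
#' four faces of the implied regular tetrahedron are the four triad
#' planes, each tessellated by equilateral triangles; a lifeline (fixed C
#' and D) maps to a straight segment.
#'
#' @param coord a [demo_coord()]; completed internally, all six measures
#'   must be derivable.
#' @param eps tolerance passed to [complete_coord()].
#' @return numeric `c(x, y, z)`.
#' @export
#' @examples
#' embed3d(demo_coord(C = 2000, P = 2050, D = 2100))
embed3d <- function(coord, eps = 1e-9) {
  v <- unclass(complete_coord(coord, eps = eps))
  if (anyNA(v))
    .stop_demotime("all six measures must be derivable for the 3-D embedding",
                   "demotime_missing")
  pt <- as.vector(tetra_basis() %*% v[c("P", "A", "T")])
  c(x = pt[1], y = pt[2], z = pt[3])
}

#' Invert the 3-D embedding
#'
#' Recovers (P, A, T) — and hence, through the identities, all six
#' measures — from a spatial point; the embedding is injective on valid
#' coordinates.
#'
#' @param point numeric `c(x, y, z)`.
#' @return named numeric `c(P, A, T)`.
#' @export
embed3d_invert <- function(point) {
  if (!is.numeric(point) || length(point) != 3L || any(!is.finite(point)))
    .stop_demotime("`point` must be three finite numbers", "demotime_invalid")
  out <- as.numeric(solve(tetra_basis(), point))
  c(P = out[1], A = out[2], T = out[3])
}

#' Trace a lifeline across a temporal plane or the 3-D space
#'
#' Samples a lifeline at `step`-year intervals from birth to death and
#' maps each sampled moment. On APC the path ascends along the cohort
#' diagonal; on TPD it descends to T = 0 at death; on TAL it descends the
#' constant-lifespan diagonal; on LCD the whole life collapses to one
#' point, which is returned once. Censored lifelines are only allowed on
#' APC (death-anchored measures being unknown) and then require `until`.
#'
#' @param lifeline a one-row [lifelines()] data frame.
#' @param spec a [plane_spec()], or `"3d"` for [embed3d()].
#' @param step sampling interval in years (> 0).
#' @param until end of the path for a censored lifeline on APC.
#' @return numeric matrix with columns `x`, `y` (and `z` for `"3d"`) and
#'   a `"times"` attribute of the sampled periods.
#' @export
lifeline_path <- function(lifeline, spec = "3d", step = 1, until = NULL) {
  if (is.data.frame(lifeline)) {
    stopifnot(nrow(lifeline) == 1L)
    lifeline <- as.list(lifeline)
  }
  if (!is.numeric(step) || step <= 0)
    .stop_demotime("`step` must be positive", "demotime_invalid")
  b <- as.numeric(lifeline$birth)
  d <- as.numeric(lifeline$death)
  if (length(d) == 0L) d <- NA_real_
  is3d <- identical(spec, "3d")
  if (!is3d) stopifnot(inherits(spec, "plane_spec"))
  death_anchored <- is3d || spec$triad != "APC"
  if (is.na(d)) {
    if (death_anchored)
      .stop_demotime("censored lifeline: T, D, L unknown, cannot draw on a death-anchored plane",
                     "demotime_censoring")
    if (is.null(until))
      .stop_demotime("censored lifeline on APC needs `until`", "demotime_invalid")
    tend <- until
  } else {
    tend <- d
  }
  if (tend < b)
    .stop_demotime("path end precedes birth", "demotime_invalid")
  times <- seq(b, tend, by = step)
  if (times[length(times)] < tend) times <- c(times, tend)
  pts <- t(vapply(times, function(tt) {
    cc <- measures_at(lifeline, tt)
    if (is3d) embed3d(cc) else project_plane(cc, spec)
  }, numeric(if (is3d) 3L else 2L)))
  colnames(pts) <- if (is3d) c("x", "y", "z") else c("x", "y")
  if (!is3d && spec$triad == "LCD") {
    keep <- !duplicated(round(pts, 12))
    times <- times[keep]
    pts <- pts[keep, , drop = FALSE]
  }
  attr(pts, "times") <- times
  pts
}
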