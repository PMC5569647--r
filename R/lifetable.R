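#' Build a single-year lifetable
#'
#' Standard period lifetable on an integer age grid with deaths placed at
#' interval midpoints: l(x+1) = l(x)(1 - q(x)), d(x) = l(x) q(x),
#' L(x) = l(x+1) + d(x)/2, e(x) = sum of L from x on, divided by l(x).
#' The final age group is closed out with q(omega) = 1.
#'
#' @param qx numeric vector of death probabilities in `[0, 1]`, one per
#'   single-year age starting at `ages[1]`; the last element is treated
#'   as 1.
#' @param hazard alternative input: piecewise-constant hazards (per
#'   year), converted as q = 1 - exp(-hazard). Give exactly one of `qx`
#'   and `hazard`.
#' @param ages integer age grid; defaults to `0:(length-1)`.
#' @param radix survivors at the first age, default 1.
#' @return data frame of class `lifetable` with columns `x`, `lx`, `dx`,
#'   `Lx`, `ex` (`ex` is `NA` once `lx` hits 0) and a `radix` attribute.
#' @export
#' @examples
#' build_lifetable(qx = c(0.2, 0.5, 1))
build_lifetable <- function(qx = NULL, hazard = NULL, ages = NULL, radix = 1) {
  if (is.null(qx) == is.null(hazard))
    .stop_demotime("give exactly one of `qx` and `hazard`", "demotime_invalid")
  if (!is.null(hazard)) {
    if (!is.numeric(hazard) || any(!is.finite(hazard)) || any(hazard < 0))
      .stop_demotime("hazards must be finite and non-negative", "demotime_invalid")
    qx <- 1 - exp(-hazard)
  }
  if (!is.numeric(qx) || length(qx) < 1L || anyNA(qx) ||
      any(qx < 0) || any(qx > 1))
    .stop_demotime("`qx` must be probabilities in [0, 1]", "demotime_invalid")
  k <- length(qx)
  qx[k] <- 1
  if (is.null(ages)) ages <- 0:(k - 1L)
  if (length(ages) != k || any(diff(ages) != 1))
    .stop_demotime("`ages` must be consecutive integers matching `qx`",
                   "demotime_invalid")
  if (!is.numeric(radix) || radix <= 0)
    .stop_demotime("`radix` must be positive", "demotime_invalid")
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- c(lx[-1L], 0) + dx / 2
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, NA_real_)
  out <- data.frame(x = as.integer(ages), lx = lx, dx = dx, Lx = Lx, ex = ex)
  attr(out, "radix") <- radix
  class(out) <- c("lifetable", "data.frame")
  out
}

#' Remaining life expectancy at an exact age
#'
#' @param lifetable a [build_lifetable()] result.
#' @param x0 an age on the grid with survivors remaining.
#' @return e(x0) in years.
#' @export
life_expectancy <- function(lifetable, x0) {
  i <- .lt_index(lifetable, x0)
  lifetable$ex[i]
}

.lt_index <- function(lifetable, x0) {
  stopifnot(inherits(lifetable, "lifetable"))
  i <- match(x0, lifetable$x)
  if (is.na(i))
    .stop_demotime(sprintf("age %s not on the lifetable grid", format(x0)),
                   "demotime_invalid")
  if (lifetable$lx[i] <= 0)
    .stop_demotime(sprintf("no survivors at age %s: expectancy undefined", format(x0)),
                   "demotime_expectancy")
  i
}

#' Read a delimited lifetable (HMD-style columns)
#'
#' Accepts comma- or tab-separated text with an `Age` column (a trailing
#' `"+"` on the open age group is stripped) and either `qx` or `lx`
#' (radix auto-detected from `lx[1]`). `dx`, `Lx`, and `ex` are rebuilt
#' under the package's midpoint convention so that all downstream
#' identities hold exactly.
#'
#' @param path file path.
#' @return a [build_lifetable()] result.
#' @export
read_lifetable <- function(path) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE, check.names = FALSE)
  nms <- names(df)
  age_col <- nms[tolower(nms) %in% c("age", "x")][1]
  if (is.na(age_col))
    .stop_demotime("lifetable file needs an Age column", "demotime_format")
  ages <- as.integer(sub("\\+$", "", as.character(df[[age_col]])))
  if ("qx" %in% nms) {
    radix <- if ("lx" %in% nms) as.numeric(df$lx[1]) else 1
    return(build_lifetable(qx = as.numeric(df$qx), ages = ages, radix = radix))
  }
  if ("lx" %in% nms) {
    lx <- as.numeric(df$lx)
    q <- 1 - c(lx[-1L], 0) / lx
    q[!is.finite(q)] <- 1
    return(build_lifetable(qx = pmin(pmax(q, 0), 1), ages = ages,
                           radix = lx[1]))
  }
  .stop_demotime("lifetable file needs a qx or lx column", "demotime_format")
}

#' Read a two-column prevalence schedule
#'
#' First column: thanatological age (or chronological age), consecutive
#' integers; second column: prevalence in `[0, 1]`.
#'
#' @param path file path.
#' @return numeric prevalence vector with a `"start"` attribute giving
#'   the first index age.
#' @export
read_prevalence <- function(path) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .stop_demotime("prevalence file needs two columns", "demotime_format")
  t0 <- as.numeric(df[[1]])
  v <- as.numeric(df[[2]])
  if (any(diff(t0) != 1))
    .stop_demotime("prevalence ages must be consecutive integers",
                   "demotime_format")
  if (anyNA(v) || any(v < 0 | v > 1))
    .stop_demotime("prevalence values must lie in [0, 1]", "demotime_format")
  structure(v, start = t0[1])
}
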