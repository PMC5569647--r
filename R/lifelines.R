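#' Construct a set of lifelines
#'
#' A lifeline records one individual's birth time and, unless censored,
#' death time (both in decimal years). Censoring is encoded by an `NA`
#' death: thanatological age, death cohort, and lifespan are then unknown
#' and every downstream operation propagates that absence.
#'
#' @param id identifiers (coerced to character, must be unique).
#' @param birth numeric birth times.
#' @param death numeric death times or `NA` when censored; recycled.
#' @return data frame of class `lifelines` with columns `id`, `birth`,
#'   `death`.
#' @export
#' @examples
#' lifelines(c("a", "b"), c(1900, 1905), c(1975, NA))
lifelines <- function(id, birth, death = NA_real_) {
  id <- as.character(id)
  birth <- as.numeric(birth)
  death <- as.numeric(death)
  if (length(death) == 1L && length(id) != 1L) death <- rep(death, length(id))
  df <- data.frame(id = id, birth = birth, death = death,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    .stop_demotime("lifeline ids must be unique", "demotime_invalid")
  if (anyNA(df$birth))
    .stop_demotime("birth times must not be NA", "demotime_invalid")
  bad <- !is.na(df$death) & df$death < df$birth
  if (any(bad))
    .stop_demotime(paste("death before birth for id(s):",
                         paste(df$id[bad], collapse = ", ")),
                   "demotime_validation")
  class(df) <- c("lifelines", "data.frame")
  df
}

#' Construct a set of dated observations
#'
#' Panel observations of individuals: each row is one dated measurement
#' (e.g. a survey interview), optionally carrying a binary or continuous
#' payload such as a poor-health indicator.
#'
#' @param id lifeline identifiers (character).
#' @param time observation times, decimal years.
#' @param value optional numeric payload (`NA` allowed).
#' @return data frame of class `observations` with columns `id`, `time`,
#'   `value`.
#' @export
observations <- function(id, time, value = NA_real_) {
  id <- as.character(id)
  value <- as.numeric(value)
  if (length(value) == 1L && length(id) != 1L) value <- rep(value, length(id))
  df <- data.frame(id = id, time = as.numeric(time),
                   value = value, stringsAsFactors = FALSE)
  if (anyNA(df$time))
    .stop_demotime("observation times must not be NA", "demotime_invalid")
  class(df) <- c("observations", "data.frame")
  df
}

#' Six-measure coordinate of a lifeline at a point in time
#'
#' Evaluates all demographic time measures for one individual observed at
#' period `time`. For an uncensored lifeline all six measures are
#' returned; for a censored one only A, P, and C are known and T, D, L
#' stay `NA`.
#'
#' @param lifeline a one-row [lifelines()] data frame (or list with
#'   `birth` and `death`).
#' @param time observation time (decimal years), within `[birth, death]`.
#' @return a [demo_coord()].
#' @export
#' @examples
#' ll <- lifelines("x", 2000, 2100)
#' measures_at(ll, 2050)  # A = T = 50, L = 100
measures_at <- function(lifeline, time) {
  if (is.data.frame(lifeline)) {
    if (nrow(lifeline) != 1L)
      .stop_demotime("`lifeline` must be a single lifeline", "demotime_invalid")
    lifeline <- as.list(lifeline)
  }
  b <- as.numeric(lifeline$birth)
  d <- as.numeric(lifeline$death)
  if (length(d) == 0L) d <- NA_real_
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time))
    .stop_demotime("`time` must be a single finite number", "demotime_invalid")
  if (time < b || (!is.na(d) && time > d))
    .stop_demotime(sprintf("time %.6g outside the lifeline [%.6g, %s]",
                           time, b, if (is.na(d)) "censored" else sprintf("%.6g", d)),
                   "demotime_range")
  demo_coord(A = time - b, P = time, C = b,
             T = if (is.na(d)) NA else d - time,
             D = d,
             L = if (is.na(d)) NA else d - b)
}

#' Measure table for a panel of observations
#'
#' Joins observations to their lifelines and evaluates all six measures
#' per row (T, D, L are `NA` on censored lifelines). This is the
#' vectorised workhorse behind surface binning.
#'
#' @param observations an [observations()] data frame.
#' @param lifelines a [lifelines()] data frame covering all observed ids.
#' @return data frame with columns `id`, `value`, and `A`, `P`, `C`, `T`,
#'   `D`, `L`.
#' @export
measures_table <- function(observations, lifelines) {
  stopifnot(is.data.frame(observations), is.data.frame(lifelines))
  i <- match(observations$id, lifelines$id)
  if (anyNA(i))
    .stop_demotime(paste("observations reference unknown lifeline id(s):",
                         paste(unique(observations$id[is.na(i)]), collapse = ", ")),
                   "demotime_invalid")
  b <- lifelines$birth[i]
  d <- lifelines$death[i]
  P <- observations$time
  bad <- P < b | (!is.na(d) & P > d)
  if (any(bad))
    .stop_demotime(paste("observation time outside lifeline for id(s):",
                         paste(unique(observations$id[bad]), collapse = ", ")),
                   "demotime_validation")
  data.frame(id = observations$id,
             value = if ("value" %in% names(observations)) observations$value else NA_real_,
             A = P - b, P = P, C = b, T = d - P, D = d, L = d - b,
             stringsAsFactors = FALSE)
}

#' Censor lifelines at an observation cutoff
#'
#' Deaths after `time` become unknown (`NA`), emulating the end of a
#' mortality follow-up window.
#'
#' @param lifelines a [lifelines()] data frame.
#' @param time cutoff, decimal years.
#' @return the lifelines with post-cutoff deaths set to `NA`.
#' @export
censor_at <- function(lifelines, time) {
  stopifnot(is.data.frame(lifelines))
  cut <- !is.na(lifelines$death) & lifelines$death > time
  lifelines$death[cut] <- NA_real_
  lifelines
}
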