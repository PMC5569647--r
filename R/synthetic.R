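#' Gompertz death probabilities
#'
#' Senescent mortality with hazard mu(x) = a exp(b x) gives single-year
#' death probabilities q(x) = 1 - exp(-(a/b) exp(b x) (exp(b) - 1)).
#'
#' @param a baseline hazard (per year, > 0).
#' @param b rate of aging (per year, > 0).
#' @param omega last age of the grid (default 110).
#' @return numeric vector of q(x) for x = 0..omega.
#' @export
gompertz_qx <- function(a = 1e-4, b = 0.1, omega = 110) {
  .check_gompertz(a, b)
  x <- 0:omega
  1 - exp(-(a / b) * exp(b * x) * expm1(b))
}

.check_gompertz <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    .stop_demotime("Gompertz parameters a and b must be positive scalars",
                   "demotime_invalid")
}

#' Lifetable under Gompertz mortality
#'
#' @inheritParams gompertz_qx
#' @param radix survivors at age 0.
#' @return a [build_lifetable()] result; its survivorship matches the
#'   closed form l(x) = exp(-(a/b)(exp(b x) - 1)) at every integer age.
#' @export
gompertz_lifetable <- function(a = 1e-4, b = 0.1, omega = 110, radix = 1) {
  build_lifetable(qx = gompertz_qx(a, b, omega), radix = radix)
}

#' Logistic time-to-death prevalence
#'
#' g(t) = g_max / (1 + exp(k (t - t50))): prevalence highest in the last
#' years of life and declining with thanatological age for k > 0, the
#' shape of late-life poor-health prevalence on a TAL surface.
#'
#' @param t thanatological ages (years).
#' @param g_max asymptotic prevalence near death, in `[0, 1]`.
#' @param k steepness (per year).
#' @param t50 thanatological age at half maximum (years).
#' @return prevalences in `[0, g_max]`.
#' @export
logistic_ttd <- function(t, g_max = 0.6, k = 0.8, t50 = 3) {
  if (!is.numeric(g_max) || g_max < 0 || g_max > 1)
    .stop_demotime("`g_max` must lie in [0, 1]", "demotime_invalid")
  g_max / (1 + exp(k * (t - t50)))
}

#' Simulate lifelines under Gompertz(-Makeham) mortality
#'
#' Birth times are uniform on `cohort_range`; lifespans are drawn by
#' inverse transform from the Gompertz survivorship
#' S(x) = exp(-(a/b)(exp(b x) - 1)), with an optional Makeham constant
#' added as an independent competing exponential risk. All randomness
#' flows from `seed`: equal seeds give identical output.
#'
#' @param n number of individuals.
#' @param cohort_range `c(first, last)` birth times, decimal years; a
#'   zero-width range puts all births at the same instant.
#' @param a,b Gompertz parameters, see [gompertz_qx()].
#' @param makeham optional age-independent hazard (per year, >= 0).
#' @param seed integer random seed (required; no implicit randomness).
#' @return a [lifelines()] data frame, all uncensored.
#' @export
#' @examples
#' simulate_lifelines(5, c(1900, 1910), seed = 1)
simulate_lifelines <- function(n = 20000, cohort_range = c(1905, 1925),
                               a = 1e-4, b = 0.1, makeham = 0, seed) {
  if (missing(seed)) .stop_demotime("`seed` is required", "demotime_invalid")
  .check_gompertz(a, b)
  if (!is.numeric(n) || n < 1) .stop_demotime("`n` must be >= 1", "demotime_invalid")
  n <- as.integer(n)
  set.seed(seed)
  birth <- runif(n, cohort_range[1], cohort_range[2])
  u <- runif(n)
  span <- log1p(-(b / a) * log(u)) / b
  if (makeham > 0) span <- pmin(span, rexp(n, rate = makeham))
  lifelines(id = sprintf("p%06d", seq_len(n)), birth = birth,
            death = birth + span)
}

#' Simulate panel interviews with a time-to-death health indicator
#'
#' Interview waves occur at fixed calendar times spaced `wave_interval`
#' years apart across `obs_window`; every individual alive at a wave is
#' observed and reports a binary indicator drawn with success
#' probability g(T), the logistic time-to-death prevalence at their
#' current thanatological age. Interviews never occur after death;
#' mortality follow-up is taken as exact (apply [censor_at()] to emulate
#' an analyst who loses deaths beyond the window).
#'
#' @param lifelines uncensored [lifelines()].
#' @param wave_interval years between waves (> 0).
#' @param obs_window `c(first, last)` calendar time of the wave range.
#' @param g_max,k,t50 prevalence parameters, see [logistic_ttd()].
#' @param seed integer random seed (required).
#' @return an [observations()] data frame with the binary indicator in
#'   `value`.
#' @export
simulate_panel <- function(lifelines, wave_interval = 2,
                           obs_window = c(1975, 2015),
                           g_max = 0.6, k = 0.8, t50 = 3, seed) {
  if (missing(seed)) .stop_demotime("`seed` is required", "demotime_invalid")
  if (!is.numeric(wave_interval) || wave_interval <= 0)
    .stop_demotime("`wave_interval` must be positive", "demotime_invalid")
  if (anyNA(lifelines$death))
    .stop_demotime("panel simulation needs uncensored lifelines",
                   "demotime_invalid")
  set.seed(seed)
  waves <- seq(obs_window[1], obs_window[2], by = wave_interval)
  pieces <- lapply(waves, function(w) {
    alive <- lifelines$birth <= w & w <= lifelines$death
    if (!any(alive)) return(NULL)
    tt <- lifelines$death[alive] - w
    data.frame(id = lifelines$id[alive], time = w,
               value = rbinom(sum(alive), 1L, logistic_ttd(tt, g_max, k, t50)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(observations(character(0), numeric(0), numeric(0)))
  observations(out$id, out$time, out$value)
}
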