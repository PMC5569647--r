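# Expand a prevalence schedule to the lifetable's full age grid.
# `prev` may be a plain vector (assumed to start at the grid's first
# age), a vector with a "start" attribute (see read_prevalence), or a
# two-column data frame (age, value). Ages outside the supplied range
# are NA.
.age_schedule <- function(prev, lifetable) {
  x <- lifetable$x
  if (is.data.frame(prev)) {
    start <- as.numeric(prev[[1]][1])
    v <- as.numeric(prev[[2]])
  } else {
    start <- attr(prev, "start")
    if (is.null(start)) start <- x[1]
    v <- as.numeric(prev)
  }
  out <- rep(NA_real_, length(x))
  idx <- match(seq(start, by = 1, length.out = length(v)), x)
  out[idx[!is.na(idx)]] <- v[!is.na(idx)]
  out
}

# Time-to-death schedule g(t), t = 0, 1, ...; extended beyond its last
# supplied value by carrying that value forward (warned once per call).
.ttd_schedule <- function(g, needed) {
  if (is.data.frame(g)) {
    if (as.numeric(g[[1]][1]) != 0)
      .stop_demotime("time-to-death schedule must start at t = 0",
                     "demotime_invalid")
    g <- as.numeric(g[[2]])
  }
  g <- as.numeric(g)
  if (length(g) < 1L || anyNA(g) || any(g < 0 | g > 1))
    .stop_demotime("`g` must be prevalences in [0, 1]", "demotime_invalid")
  if (length(g) < needed) {
    warning(sprintf("time-to-death schedule extended from t = %d to t = %d with its final value",
                    length(g) - 1L, needed - 1L), call. = FALSE)
    g <- c(g, rep(g[length(g)], needed - length(g)))
  }
  g[seq_len(needed)]
}

#' Sullivan healthy and unhealthy life expectancy
#'
#' Prevalence-weighted lifetable person-years: UHLE(x0) = sum over ages
#' a >= x0 of L(a) pi(a) / l(x0), and HLE = e(x0) - UHLE, so the two
#' always add up to total remaining life expectancy.
#'
#' @param lifetable a [build_lifetable()] result.
#' @param prevalence age-specific prevalence pi(a) in `[0, 1]`: a vector
#'   aligned to the lifetable ages, a [read_prevalence()] result, or a
#'   two-column data frame (age, value); must cover ages x0..omega.
#' @param x0 starting age (on the grid, with survivors).
#' @return named numeric `c(le, hle, uhle)` in years.
#' @export
#' @examples
#' lt <- build_lifetable(qx = c(0.2, 0.5, 1))
#' sullivan(lt, c(0.1, 0.2, 0.5), x0 = 0)
sullivan <- function(lifetable, prevalence, x0) {
  i0 <- .lt_index(lifetable, x0)
  pi_a <- .age_schedule(prevalence, lifetable)
  idx <- which(lifetable$x >= x0)
  live <- idx[lifetable$lx[idx] > 0]
  if (anyNA(pi_a[live]))
    .stop_demotime("prevalence must cover every age from x0 to the last survivor age",
                   "demotime_invalid")
  if (any(pi_a[live] < 0 | pi_a[live] > 1))
    .stop_demotime("prevalence must lie in [0, 1]", "demotime_invalid")
  uhle <- sum(lifetable$Lx[live] * pi_a[live]) / lifetable$lx[i0]
  e0 <- lifetable$ex[i0]
  c(le = e0, hle = e0 - uhle, uhle = uhle)
}

#' Health expectancy from a time-to-death prevalence schedule
#'
#' Treats morbidity prevalence as a function g(t) of completed
#' thanatological age t. A death in age interval a (at its midpoint)
#' contributes G(a - x0) unhealthy years lived since x0, where
#' G(k) = g(0) + ... + g(k-1) + g(k)/2: walking back from death, each
#' completed year of remaining life t is weighted g(t), with a half year
#' spent at t = k. Then UHLE(x0) = sum over a >= x0 of
#' d(a) G(a - x0) / l(x0) and HLE = e(x0) - UHLE. Under a constant g = p
#' this reduces exactly to UHLE = p e(x0), the closed form the framework
#' requires: when morbidity is purely time-to-death driven, longer lives
#' add healthy years one for one.
#'
#' @param lifetable a [build_lifetable()] result.
#' @param g time-to-death prevalence g(t) for t = 0, 1, ...: a vector
#'   (first element is t = 0), a [read_prevalence()] result, or a
#'   two-column data frame; values beyond the last supplied t are carried
#'   forward with a warning.
#' @param x0 starting age.
#' @return named numeric `c(le, hle, uhle)` in years.
#' @export
ttd_expectancies <- function(lifetable, g, x0) {
  i0 <- .lt_index(lifetable, x0)
  idx <- which(lifetable$x >= x0)
  K <- length(idx) - 1L
  g <- .ttd_schedule(g, K + 1L)
  cg <- c(0, cumsum(g))            # cg[k + 1] = g(0) + ... + g(k - 1)
  Gk <- cg[seq_len(K + 1L)] + g / 2
  uhle <- sum(lifetable$dx[idx] * Gk) / lifetable$lx[i0]
  e0 <- lifetable$ex[i0]
  c(le = e0, hle = e0 - uhle, uhle = uhle)
}

#' Chronological-age prevalence implied by a time-to-death schedule
#'
#' In a stationary population where prevalence follows g(t), the
#' prevalence observed among survivors at age a is the death-time
#' mixture pi(a) = sum over t >= 0 of d(a + t) g(t) / l(a). With
#' mortality shifting to older ages this marginal age curve falls at any
#' fixed age — more of the years lived at age a are far from death,
#' where prevalence is low — which is the mechanism behind the bias of
#' fixed Sullivan-curve projections.
#'
#' @param lifetable a [build_lifetable()] result.
#' @param g time-to-death prevalence schedule, see [ttd_expectancies()].
#' @return numeric vector of pi(a) aligned to the lifetable ages, `NA`
#'   beyond the last age with survivors.
#' @export
implied_age_prevalence <- function(lifetable, g) {
  nx <- nrow(lifetable)
  g <- .ttd_schedule(g, nx)
  pi_a <- rep(NA_real_, nx)
  for (i in seq_len(nx)) {
    if (lifetable$lx[i] <= 0) break
    t_max <- nx - i
    pi_a[i] <- sum(lifetable$dx[i:nx] * g[seq_len(t_max + 1L)]) /
      lifetable$lx[i]
  }
  pi_a
}

#' Compare health-expectancy projections under changing mortality
#'
#' Given a baseline and a new lifetable sharing one age grid and a fixed
#' time-to-death prevalence schedule g, contrasts two ways of carrying
#' morbidity forward: (i) the time-to-death method applied to each
#' lifetable, and (ii) the standard Sullivan method holding fixed the
#' chronological-age curve implied by g under *baseline* mortality. When
#' g declines with time to death and mortality improves, the fixed-curve
#' Sullivan projection inflates the growth of unhealthy life expectancy
#' relative to the time-to-death method.
#'
#' @param lifetable_base,lifetable_new [build_lifetable()] results on the
#'   same age grid.
#' @param g time-to-death prevalence schedule, see [ttd_expectancies()].
#' @param x0 starting age.
#' @return object of class `hle_comparison`: list with `x0`, `le`
#'   (base/new/delta), `ttd` and `sullivan_fixed` (each with hle/uhle
#'   base, new, delta), and `delta_uhle` plus `pct_uhle` summaries.
#' @export
compare_scenarios <- function(lifetable_base, lifetable_new, g, x0) {
  stopifnot(inherits(lifetable_base, "lifetable"),
            inherits(lifetable_new, "lifetable"))
  if (!identical(lifetable_base$x, lifetable_new$x))
    .stop_demotime("lifetables must share one age grid", "demotime_invalid")
  ttd_b <- ttd_expectancies(lifetable_base, g, x0)
  ttd_n <- ttd_expectancies(lifetable_new, g, x0)
  pi_base <- implied_age_prevalence(lifetable_base, g)
  # carry the last defined value past the baseline's last survivor age,
  # in case the new lifetable survives longer
  if (anyNA(pi_base)) {
    last <- max(which(!is.na(pi_base)))
    pi_base[is.na(pi_base)] <- pi_base[last]
  }
  sul_b <- sullivan(lifetable_base, pi_base, x0)
  sul_n <- sullivan(lifetable_new, pi_base, x0)
  le <- c(base = unname(ttd_b["le"]), new = unname(ttd_n["le"]))
  out <- list(
    x0 = x0,
    le = c(le, delta = unname(diff(le))),
    ttd = rbind(base = ttd_b, new = ttd_n, delta = ttd_n - ttd_b),
    sullivan_fixed = rbind(base = sul_b, new = sul_n, delta = sul_n - sul_b),
    delta_uhle = c(ttd = unname(ttd_n["uhle"] - ttd_b["uhle"]),
                   sullivan_fixed = unname(sul_n["uhle"] - sul_b["uhle"])),
    pct_uhle = c(ttd = 100 * unname((ttd_n["uhle"] - ttd_b["uhle"]) / ttd_b["uhle"]),
                 sullivan_fixed = 100 * unname((sul_n["uhle"] - sul_b["uhle"]) / sul_b["uhle"]))
  )
  class(out) <- "hle_comparison"
  out
}

#' @export
print.hle_comparison <- function(x, ...) {
  cat(sprintf("Health expectancy comparison at age %s\n", format(x$x0)))
  cat(sprintf("  life expectancy: %.3f -> %.3f (delta %+.3f)\n",
              x$le["base"], x$le["new"], x$le["delta"]))
  cat(sprintf("  UHLE delta, time-to-death method:    %+.3f (%.1f%%)\n",
              x$delta_uhle["ttd"], x$pct_uhle["ttd"]))
  cat(sprintf("  UHLE delta, fixed Sullivan curve:    %+.3f (%.1f%%)\n",
              x$delta_uhle["sullivan_fixed"], x$pct_uhle["sullivan_fixed"]))
  invisible(x)
}
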