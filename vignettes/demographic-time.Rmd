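---
title: "Six measures of demographic time: methods and conventions"
author: "demotime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six measures of demographic time: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demotime)
```

## The model

Demographic data are conventionally structured by chronological age (A),
period (P), and birth cohort (C) — the Lexis triad. Three further measures
complete the picture once death is treated as an event on the same footing
as birth: thanatological age (T, time remaining until death), death cohort
(D, calendar time of death), and lifespan (L). The six are linked by four
triad identities,

$$A = P - C, \qquad T = D - P, \qquad L = D - C, \qquad L = A + T,$$

any two members of a triad determining the third. Jointly they form a
single hexad identity with three degrees of freedom: any three independent
measures that include a calendar anchor (P, C, or D) determine all six.
The TAL triad contains no calendar measure, which is why knowing
`{T, A, L}` alone pins down nothing else — and why, for the living, T, D,
and L are unknown until death or a mortality follow-up resolves them.

The hexad is a special case of a general calculus: $n$ dated events
$p \in \mathbf{R}^n$ imply $m = n(n-1)/2$ pairwise durations
$d = X p$, where $X$ is an $m \times n$ matrix with one $-1$ and one $+1$
per row ([difference_matrix()]). $X$ annihilates constants and has rank
$n - 1$: durations are translation invariant and events are not
recoverable from durations. Arranged as a graph — one hub vertex carrying
the $n$ event edges, duration edges between event vertices — every
triangle is a triad identity, $\binom{n+1}{3}$ in all. The demographic
case is $n = 3$ (events C, P, D), giving the tetrahedral graph whose four
faces are APC, TPD, TAL, and LCD, 15 measure dyads of which 12 are
informative (LP, CT, and AD are not).

```{r hexad}
complete_coord(demo_coord(T = 30, P = 1971))   # fills the death cohort
subset(classify_dyads(demographic_graph()), !informative)
```

## Numerical and representational conventions

**Decimal years.** All times are continuous decimal years; `dec_year()`
converts ISO dates on a fixed 365.25-day year. Worked examples quoted in
completed years are treated as exact reals; completed-year inputs
therefore carry roughly a ±1-year ambiguity that the package documents
but does not model. Where a date is given at sub-annual resolution but a
lifespan in completed years (a death "in December 1995" with lifespan
96), we evaluate at annual resolution (D = 1996, so C = 1900); no
sub-annual rounding rule is defined.

**Completion.** `complete_coord()` applies the four identity equations to
a fixed point. It is idempotent, and order of rule application cannot
matter because each rule is a deterministic linear consequence of its
inputs. Residuals above `eps` (default 1e-9 years, suitable for exact
arithmetic; raise it for rounded survey data) raise an inconsistency
error naming the violated identity. Negative A, T, or L is a domain error
here — demographic semantics require $C \le P \le D$ — while the general
event module deliberately permits negative durations, since event
ordering there is a labelling convention. `check_consistency()` is the
non-throwing variant that reports violations instead.

**Censoring** is encoded by an absent death time, never a sentinel. All
operations propagate absence: `measures_at()` returns A, P, C only;
death-anchored surfaces drop such observations and report the count;
`lifeline_path()` refuses death-anchored planes for censored lives.

## Plane mappings and the 3-D embedding

A temporal plane maps two measures of a triad to (x, y). The Cartesian
mapping assigns each measure directly to its axis at unity aspect; the
third, derived measure then appears along diagonals, and one year
travelled along such a diagonal (e.g. one year of a cohort's life on the
Lexis plane) spans $\sqrt 2$ spatial units. The isotropic mapping removes
that distortion: the y-axis image is slanted so that unit steps of all
three measures, diagonal included, have length 1 at mutual 60° — the
ternary-coordinate rendering of a triad.

One subtlety is worth recording. Whether the derived measure is the *sum*
of the two plotted measures (as L = A + T on the TA plane) or their
*difference* (as C = P − A on the AP plane) decides which way its
diagonals run, so a single fixed 60° basis cannot make every plane
isotropic. The package therefore slants the y axis to $(1/2, \sqrt3/2)$
in the sum case and $(-1/2, \sqrt3/2)$ in the difference case; both
generate the same triangular lattice, and isotropy — the defining
requirement — then holds on every plane and orientation, which the test
suite verifies for all twelve orientations.

The 3-D embedding positions a complete coordinate at
$P\,e_P + A\,e_A + T\,e_T$, with the three basis vectors unit length at
mutual 60° (`tetra_basis()`): a regular-tetrahedron vertex fan, under
which all six measure generators are spatially equal and each face
restricts to an isotropic triad plane tessellated by equilateral
triangles. The embedding is parameterised by (P, A, T) because they are
an independent spanning set; it is injective, and `embed3d_invert()`
recovers them by solving the basis. Isotropy fixes the geometry only up
to rotation and handedness — no origin or orientation is canonical — so
the package pins $e_P$ along x, $e_A$ in the xy plane with positive y,
and $e_T$ with positive z, purely for reproducibility.

## Surfaces

`aggregate_surface()` bins observation coordinates into half-open
completed-year cells $[k w, (k+1) w)$ on each classifying measure —
standard single-year demographic classification; squares bin the two
axis measures, the parallelogram shapes swap one axis for the derived
measure (the AC and CP double-classifications of the Lexis plane). An
observation exactly at death falls in the T = 0 row. Counts are
conserved: cell totals plus dropped (censored) plus filtered (age
window) equal the input size. The age window (e.g. 70–100 for late-life
surfaces) is a configurable filter, never hard-coded, and optional
per-observation weights are supported but default to unweighted.

`variation_direction()` summarises a surface by a count-weighted
between-group variance decomposition of cell means, grouped by row (T)
and by column (A), each as a share of total weighted variance; zero total
variance returns 0 by the 0/0 → 0 convention. Horizontal contours — the
signature of time-to-death-driven prevalence — appear as
`share_T` near 1 with smaller `share_A`. This statistic is the package's
own diagnostic; it formalises "contours run horizontal" but is not a
substitute for proper statistical contour estimation, which is out of
scope, as is any smoothing or graduation of surfaces.

## Health expectancies

The lifetable (`build_lifetable()`) uses single-year ages, deaths at
interval midpoints ($L_x = l_{x+1} + d_x/2$), and an open age group
closed out with $q(\omega) = 1$, $\omega$ defaulting to 110; abridged
tables must be graduated upstream. The Sullivan method weights
person-years by an age prevalence curve $\pi$:

$$\mathrm{UHLE}(x_0) = \frac{\sum_{a \ge x_0} L_a \pi(a)}{l_{x_0}},
\qquad \mathrm{HLE} = e(x_0) - \mathrm{UHLE}.$$

The time-to-death method instead takes prevalence as a function $g(t)$
of completed thanatological age. A death in interval $a$ contributes
$G(k) = \sum_{t<k} g(t) + \tfrac12 g(k)$ unhealthy years ($k = a - x_0$):
walking back from a midpoint death, half a year at completed remaining
life $k$ and a full year at each smaller $t$. Then
$\mathrm{UHLE}(x_0) = \sum_a d_a G(a - x_0) / l_{x_0}$. These discrete
conventions are the package's own, fixed so that the constant-$g$ closed
form $\mathrm{UHLE} = p\,e(x_0)$ holds *exactly* — which the framework
logically requires: when morbidity is purely a function of time to
death, added life expectancy is added healthy life expectancy, year for
year. A $g$ supplied on fewer years than needed is extended by its final
value, with a warning. A completed-year schedule is read as the year's
midpoint value of any underlying continuous trajectory, consistent with
the midpoint placement of deaths.

`implied_age_prevalence()` gives the marginal age curve of a stationary
population whose morbidity follows $g$:
$\pi(a) = \sum_t d_{a+t}\, g(t) / l_a$. Applying Sullivan to this
implied curve almost reproduces the time-to-death result; the exact
discrepancy is

$$U_S - U_T = \frac{1}{2 l_{x_0}} \sum_{a \ge x_0} d_a
  \left[g(a - x_0) - \pi(a)\right],$$

a boundary effect of half-interval conventions, bounded in magnitude by
$\max_t g(t)/2$ and typically far smaller. The test suite asserts the
identity to machine precision and the bound across random lifetables.

The projection-bias comparison (`compare_scenarios()`) contrasts, under
a mortality improvement, the time-to-death method applied to both
lifetables against the Sullivan method holding the *baseline* implied
age curve fixed. With $g$ declining in $t$, the fixed curve attributes
to old age prevalence that really belongs to the last years of life, so
it over-projects the growth of unhealthy life expectancy; the
time-to-death method moves morbidity out with mortality. This direction
holds in every one of 100 random Gompertz improvement pairs in the
acceptance tests. Reproducing published empirical expectancy values is
out of scope: those require restricted survey linkages and national
lifetables, and the package deliberately replaces them with
property-based checks on synthetic inputs. Incidence-based multistate
health expectancy and confidence intervals are likewise out of scope.

## The synthetic generator and what passing tests show

`simulate_lifelines()` draws births uniformly over the cohort range and
lifespans by inverse transform from the Gompertz survivorship
$S(x) = \exp(-(a/b)(e^{bx} - 1))$; an optional Makeham constant enters
as an independent competing exponential risk (the minimum of the two
lifetimes has exactly the Gompertz–Makeham hazard).
`simulate_panel()` interviews everyone alive at fixed calendar waves and
draws a binary indicator with probability $g(T)$, the logistic
time-to-death law $g(t) = g_{\max} / (1 + e^{k(t - t_{50})})$. All
randomness flows from explicit seeds; equal seeds give identical output.

The default study conditions are 20,000 lifelines born 1905–1925,
Gompertz $a = 10^{-4}$, $b = 0.1$ (modal adult age at death near 80,
matching the cohorts the late-life surfaces describe), prevalence
$g_{\max} = 0.6$, $k = 0.8$, $t_{50} = 3$, interviews every 2 years; the
observation window 1975–2015 covers these cohorts' old age the way a
long-running retirement panel would. The generator emulates the temporal
*structure* of such a panel — dated interviews, exact birth dates, exact
mortality follow-up — and none of its frictions: no nonresponse, proxy
interviews, survey weights, or imperfect death linkage, and interviews
never occur after death. Passing recovery tests therefore show the
binning, completion, and expectancy machinery is correct under known
ground truth; they say nothing about measurement problems in real survey
data. Unknown death times of censored individuals are never imputed.

Cell-wise recovery is judged at 3 binomial standard errors per cell
(cells with at least 30 observations), with the expected cell value
computed as the within-cell mean of the true $g(T)$ so deviations are
purely binomial. Across several hundred cells roughly 0.3% exceed 3 SE
by chance, so the criterion is that at least 99% of cells conform — the
standard multiple-comparison rendering of a per-cell check. Problem
sizes in the routine tests (8,000–50,000 simulated lives, lifetables to
$\omega = 110$) were chosen as the smallest giving comfortable
Monte-Carlo margins for the properties tested.

## Known limitations

Completed-year granularity of real vital records is acknowledged but not
modelled; the package treats its inputs as exact continuous times.
Single-year lifetables only. The direction-of-variation statistic is
descriptive, not inferential. The 3-D embedding is a coordinate tool —
no interactive or perspective rendering is provided, and plot methods
are presentation-only. APC *identification* (separating age, period, and
cohort effects statistically) is explicitly not addressed: the identity
that makes the measures mutually derivable is precisely what makes such
effects non-identifiable without further assumptions.
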