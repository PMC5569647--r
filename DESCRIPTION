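Package: demotime
Title: Demographic Time Measures, Temporal Planes, and Time-to-Death
    Health Expectancy
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the six measures of demographic time - chronological
    age, period, birth cohort, thanatological age (time to death), death
    cohort, and lifespan - and the identities connecting them. Completes
    partial coordinates via the four triad identities (APC, TPD, TAL, LCD),
    provides the general event-to-duration vector-space machinery for any
    number of dated events, maps coordinates to Cartesian and isotropic
    temporal planes and to a three-dimensional tetrahedral embedding, bins
    lifelines and panel observations into surfaces on any temporal plane,
    and computes healthy life expectancy from either age-specific (Sullivan)
    or time-to-death prevalence schedules, including a comparison of the two
    methods under changing mortality. A synthetic-data module (Gompertz
    mortality, logistic time-to-death prevalence, panel interview waves)
    supports simulation studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
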