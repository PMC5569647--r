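test_that("lifetable construction follows the midpoint convention", {
  lt <- build_lifetable(qx = c(0.5, 0.5, 1))
  expect_equal(lt$lx, c(1, 0.5, 0.25))
  expect_equal(lt$dx, c(0.5, 0.25, 0.25))
  expect_equal(lt$Lx, c(0.75, 0.375, 0.125))
  expect_equal(lt$ex[1], 1.25)
  # everyone dies in the first interval: e(0) = 1/2
  expect_equal(build_lifetable(qx = 1)$ex[1], 0.5)
  # internal identities
  set.seed(31)
  lt2 <- random_lifetable()
  expect_true(all(diff(lt2$lx) <= 0))
  expect_equal(lt2$dx, lt2$lx - c(lt2$lx[-1], 0))
  expect_equal(rev(cumsum(rev(lt2$dx))), lt2$lx)
  expect_equal(lt2$ex, rev(cumsum(rev(lt2$Lx))) / lt2$lx)
  expect_error(build_lifetable(qx = c(0.5, 1.2)), class = "demotime_invalid")
  expect_error(build_lifetable(qx = c(0.5, 1), hazard = 1),
               class = "demotime_invalid")
  expect_error(life_expectancy(lt, 7), class = "demotime_invalid")
})

test_that("Gompertz lifetables match the closed-form survivorship", {
  a <- 1e-4; b <- 0.1
  lt <- gompertz_lifetable(a, b)
  x <- lt$x
  expect_equal(lt$lx, exp(-(a / b) * (exp(b * x) - 1)), tolerance = 1e-12)
  # b -> 0: exponential lifetimes, e(0) -> 1/a
  lt_exp <- build_lifetable(qx = gompertz_qx(0.02, 1e-9, omega = 2000))
  expect_equal(lt_exp$ex[1], 50, tolerance = 0.1)
  # halving the hazard lengthens life
  expect_gt(gompertz_lifetable(a / 2, b)$ex[1], lt$ex[1])
  expect_error(gompertz_qx(-1, 0.1), class = "demotime_invalid")
})

test_that("Sullivan expectancies match a brute-force oracle", {
  lt <- toy_lifetable()
  pi_a <- c(0.1, 0.2, 0.5)
  res <- sullivan(lt, pi_a, 0)
  expect_equal(unname(res["uhle"]), sullivan_oracle(lt, pi_a, 0))
  expect_equal(unname(res["uhle"]), 0.31)
  expect_equal(unname(res["hle"] + res["uhle"]), unname(res["le"]))
  # zero and constant prevalence limits
  expect_equal(unname(sullivan(lt, rep(0, 3), 0)["uhle"]), 0)
  expect_equal(unname(sullivan(lt, rep(0, 3), 0)["hle"]), lt$ex[1])
  p <- 0.37
  expect_equal(unname(sullivan(lt, rep(p, 3), 0)["uhle"]), p * lt$ex[1],
               tolerance = 1e-15)
  # from a later age, against the oracle
  expect_equal(unname(sullivan(lt, pi_a, 1)["uhle"]),
               sullivan_oracle(lt, pi_a, 1))
  expect_error(sullivan(build_lifetable(qx = c(1, 1)), pi_a, 1),
               class = "demotime_expectancy")
  expect_error(sullivan(lt, c(0.1, NA, 0.2), 0), class = "demotime_invalid")
})

test_that("time-to-death expectancies match per-death-age enumeration", {
  lt <- toy_lifetable()
  g <- c(1, 0.5, 0)
  res <- ttd_expectancies(lt, g, 0)
  expect_equal(unname(res["uhle"]), ttd_oracle(lt, g, 0))
  expect_equal(unname(res["uhle"]), 1.2)
  expect_equal(unname(res["hle"] + res["uhle"]), unname(res["le"]))
  expect_equal(unname(ttd_expectancies(lt, rep(0, 3), 0)["uhle"]), 0)
  # constant g = p gives UHLE = p e(x0) exactly, at any starting age
  set.seed(41)
  for (i in 1:20) {
    lt2 <- random_lifetable()
    p <- runif(1)
    for (x0 in c(0, 5, 12)) {
      expect_equal(unname(ttd_expectancies(lt2, rep(p, 40), x0)["uhle"]),
                   p * life_expectancy(lt2, x0), tolerance = 1e-12)
      expect_equal(unname(sullivan(lt2, rep(p, nrow(lt2)), x0)["uhle"]),
                   p * life_expectancy(lt2, x0), tolerance = 1e-12)
    }
  }
  # oracle agreement on random inputs
  for (i in 1:10) {
    lt2 <- random_lifetable()
    g2 <- runif(nrow(lt2))
    expect_equal(unname(ttd_expectancies(lt2, g2, 3)["uhle"]),
                 ttd_oracle(lt2, g2, 3), tolerance = 1e-12)
  }
  # schedule shorter than needed is carried forward, with a warning
  expect_warning(ttd_expectancies(lt, c(1, 0.5), 0), "extended")
})

test_that("pointwise larger prevalence never lowers UHLE", {
  set.seed(43)
  for (i in 1:20) {
    lt <- random_lifetable()
    g <- runif(nrow(lt), 0, 0.8)
    bump <- g + runif(nrow(lt), 0, 0.2)
    expect_gte(ttd_expectancies(lt, bump, 0)[["uhle"]],
               ttd_expectancies(lt, g, 0)[["uhle"]])
    expect_gte(sullivan(lt, bump, 0)[["uhle"]],
               sullivan(lt, g, 0)[["uhle"]])
  }
})

test_that("implied age prevalence is the death-time mixture of g", {
  lt <- toy_lifetable()
  # constant g mixes to itself
  expect_equal(implied_age_prevalence(lt, rep(0.3, 3)), rep(0.3, 3))
  # hand mixture for the toy table at age 0:
  # d = (0.2, 0.4, 0.4), g = (1, 0.5, 0) => pi(0) = 0.2*1 + 0.4*0.5 + 0.4*0
  g <- c(1, 0.5, 0)
  pi_a <- implied_age_prevalence(lt, g)
  expect_equal(pi_a[1], 0.4)
  expect_equal(pi_a[2], (0.4 * 1 + 0.4 * 0.5) / 0.8)
  expect_equal(pi_a[3], 1)
  expect_true(all(pi_a >= 0 & pi_a <= 1, na.rm = TRUE))
  # older mortality with declining g lowers prevalence at any fixed age
  g_dec <- logistic_ttd(0:110)
  lt_base <- gompertz_lifetable(1e-4, 0.1)
  lt_new <- gompertz_lifetable(0.8e-4, 0.1)
  pi_b <- implied_age_prevalence(lt_base, g_dec)
  pi_n <- implied_age_prevalence(lt_new, g_dec)
  keep <- !is.na(pi_b) & !is.na(pi_n) & lt_base$x <= 105
  expect_true(all(pi_n[keep] <= pi_b[keep] + 1e-12))
})

test_that("Sullivan with the implied curve reproduces the TTD result", {
  # exact discrepancy identity:
  # U_S - U_T = (1 / 2 l(x0)) sum_a d(a) [g(a - x0) - pi(a)],
  # bounded in magnitude by max(g) / 2
  set.seed(47)
  for (i in 1:20) {
    lt <- random_lifetable()
    g <- sort(runif(nrow(lt), 0, 0.9), decreasing = TRUE)
    x0 <- sample(c(0, 2, 5), 1)
    pi_a <- implied_age_prevalence(lt, g)
    pi_fill <- pi_a
    if (anyNA(pi_fill))
      pi_fill[is.na(pi_fill)] <- pi_fill[max(which(!is.na(pi_fill)))]
    u_s <- sullivan(lt, pi_fill, x0)[["uhle"]]
    u_t <- ttd_expectancies(lt, g, x0)[["uhle"]]
    idx <- which(lt$x >= x0)
    pred <- sum(lt$dx[idx] * (g[idx - min(idx) + 1] - pi_fill[idx])) /
      (2 * lt$lx[min(idx)])
    expect_equal(u_s - u_t, pred, tolerance = 1e-12)
    expect_lt(abs(u_s - u_t), max(g) / 2 + 1e-12)
  }
})

test_that("scenario comparison exposes the fixed-curve projection bias", {
  g <- logistic_ttd(0:110)
  lt80 <- gompertz_lifetable(1.2e-4, 0.095)
  # identical lifetables: all deltas vanish
  same <- compare_scenarios(lt80, lt80, g, 60)
  expect_equal(unname(same$le["delta"]), 0)
  expect_equal(unname(same$delta_uhle), c(0, 0))
  # mortality improvement: fixed Sullivan curve projects more growth in
  # unhealthy years than the time-to-death method
  lt10 <- gompertz_lifetable(0.8e-4, 0.095)
  cmp <- compare_scenarios(lt80, lt10, g, 60)
  expect_gt(cmp$le[["delta"]], 0)
  expect_gt(cmp$delta_uhle[["sullivan_fixed"]], cmp$delta_uhle[["ttd"]])
  # both methods' components always add to total life expectancy
  expect_equal(cmp$ttd["new", "hle"] + cmp$ttd["new", "uhle"],
               cmp$ttd["new", "le"])
  # constant g: both methods give exactly p * delta e
  p <- 0.25
  cmp_c <- compare_scenarios(lt80, lt10, rep(p, 111), 60)
  expect_equal(unname(cmp_c$delta_uhle[["ttd"]]),
               p * cmp_c$le[["delta"]], tolerance = 1e-12)
  expect_equal(unname(cmp_c$delta_uhle[["sullivan_fixed"]]),
               p * cmp_c$le[["delta"]], tolerance = 1e-12)
  expect_error(compare_scenarios(lt80, toy_lifetable(), g, 60),
               class = "demotime_invalid")
})

test_that("lifetable and prevalence files round-trip", {
  dir <- withr::local_tempdir()
  lt <- gompertz_lifetable(1e-4, 0.1, radix = 100000)
  lt_path <- file.path(dir, "lt.csv")
  write.table(data.frame(Age = c(head(lt$x, -1), "110+"), lx = lt$lx),
              lt_path, sep = ",", row.names = FALSE, quote = FALSE)
  back <- read_lifetable(lt_path)
  expect_equal(back$lx, lt$lx, tolerance = 1e-9)
  expect_equal(attr(back, "radix"), 100000)
  expect_equal(back$ex[61], lt$ex[61], tolerance = 1e-9)
  g_path <- file.path(dir, "g.csv")
  write.table(data.frame(t = 0:20, prevalence = logistic_ttd(0:20)),
              g_path, sep = ",", row.names = FALSE, quote = FALSE)
  g <- read_prevalence(g_path)
  expect_equal(as.numeric(g), logistic_ttd(0:20))
  expect_identical(attr(g, "start"), 0)
  expect_error(read_lifetable(write_tmp_csv(data.frame(foo = 1))),
               class = "demotime_format")
})
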