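test_that("cell assignment floors on half-open completed-year bins", {
  tal <- plane_spec("TAL")
  expect_equal(assign_cell(demo_coord(A = 80.3, T = 2.6), tal),
               c(A = 80, T = 2))
  ap <- plane_spec("APC")
  cc <- complete_coord(demo_coord(A = 30.0, P = 1971.0))
  expect_equal(assign_cell(cc, ap), c(P = 1971, A = 30))
  # same observation classified as an age x cohort parallelogram
  expect_equal(assign_cell(cc, ap, shape = "horizontal"), c(A = 30, C = 1941))
  expect_equal(assign_cell(cc, ap, shape = "vertical"), c(P = 1971, C = 1941))
  # width 5 bins
  expect_equal(assign_cell(demo_coord(A = 82, T = 3), tal, width = 5),
               c(A = 80, T = 0))
  # exact death lands in the T = 0 row
  expect_equal(assign_cell(demo_coord(A = 90, T = 0), tal)[["T"]], 0)
  expect_error(assign_cell(demo_coord(A = -1, T = 2), tal),
               class = "demotime_domain")
  expect_error(assign_cell(demo_coord(A = 80), tal),
               class = "demotime_missing")
  expect_error(assign_cell(demo_coord(A = 1, T = 1), tal, width = 0),
               class = "demotime_invalid")
})

test_that("aggregation counts, averages, and conserves observations", {
  ll <- lifelines(c("a", "b", "c"), c(1900, 1900.2, 1950), c(1985, 1985.4, NA))
  obs <- observations(c("a", "b", "a", "c"),
                      c(1980.5, 1980.9, 1984.2, 1980),
                      c(1, 0, 1, 1))
  g <- aggregate_surface(obs, ll, plane_spec("TAL"))
  # a@1980.5: A=80.5 T=4.5; b@1980.9: A=80.7 T=4.5 -> same (80, 4) cell
  cell <- g$cells[g$cells$x == 80 & g$cells$y == 4, ]
  expect_identical(cell$count, 2L)
  expect_equal(cell$value, 0.5)
  # censored c is dropped from the death-anchored plane
  expect_identical(g$dropped, 1L)
  expect_identical(sum(g$cells$count) + g$dropped, nrow(obs))
  # on APC nothing is dropped
  g_apc <- aggregate_surface(obs, ll, plane_spec("APC"))
  expect_identical(g_apc$dropped, 0L)
  expect_identical(sum(g_apc$cells$count), nrow(obs))
  # three values in one cell
  ll1 <- lifelines("z", 1900, 1990)
  obs3 <- observations(rep("z", 3), c(1980.1, 1980.5, 1980.9), c(1, 0, 1))
  g3 <- aggregate_surface(obs3, ll1)
  expect_identical(g3$cells$count, 3L)
  expect_equal(g3$cells$value, 2 / 3)
  # empty input is an empty grid, not an error
  g0 <- aggregate_surface(observations(character(0), numeric(0)), ll)
  expect_identical(nrow(g0$cells), 0L)
  # count statistic and weights
  gc <- aggregate_surface(obs3, ll1, statistic = "count")
  expect_equal(gc$cells$value, 3)
  gw <- aggregate_surface(obs3, ll1, weights = c(2, 1, 1))
  expect_equal(gw$cells$value, 3 / 4)
  expect_error(aggregate_surface(observations("z", 1980, NA), ll1),
               class = "demotime_invalid")
})

test_that("binning is equivariant under calendar shifts", {
  set.seed(11)
  n <- 40
  ll <- lifelines(sprintf("i%d", 1:n), runif(n, 1900, 1910),
                  runif(n, 1960, 2000))
  obs <- observations(ll$id, ll$birth + runif(n, 0, 50), rbinom(n, 1, 0.5))
  obs <- obs[obs$time <= ll$death[match(obs$id, ll$id)], ]
  w <- 4
  shift <- 8  # multiple of the width
  ll2 <- lifelines(ll$id, ll$birth + shift, ll$death + shift)
  obs2 <- observations(obs$id, obs$time + shift, obs$value)
  g1 <- aggregate_surface(obs, ll, plane_spec("APC"), width = w)
  g2 <- aggregate_surface(obs2, ll2, plane_spec("APC"), width = w)
  # calendar axis shifts by exactly `shift`, age axis unchanged
  expect_equal(g2$cells$x, g1$cells$x + shift)
  expect_equal(g2$cells$y, g1$cells$y)
  expect_equal(g2$cells$count, g1$cells$count)
  # duration-only plane is fully invariant
  t1 <- aggregate_surface(obs, ll, plane_spec("TAL"), width = w)
  t2 <- aggregate_surface(obs2, ll2, plane_spec("TAL"), width = w)
  expect_equal(t1$cells, t2$cells)
})

test_that("TAL cells respect the lifespan diagonal constraint", {
  set.seed(12)
  n <- 200
  ll <- lifelines(sprintf("i%d", 1:n), runif(n, 1900, 1905),
                  runif(n, 1905, 2000))
  tt <- runif(n)
  obs <- observations(ll$id, ll$birth + tt * (ll$death - ll$birth))
  g <- aggregate_surface(obs, ll, statistic = "count")
  mt <- measures_table(obs, ll)
  for (r in seq_len(nrow(g$cells))) {
    i <- g$cells$x[r]; j <- g$cells$y[r]
    in_cell <- floor(mt$A) == i & floor(mt$T) == j
    expect_true(all(mt$L[in_cell] >= i + j & mt$L[in_cell] < i + j + 2))
  }
})

test_that("cohort surfaces use half-open quinquennial bins", {
  ll <- lifelines(c("a", "b", "c"), c(1909.9, 1910.0, 1921.5),
                  c(1990, 1991, 1999))
  obs <- observations(c("a", "b", "c"), c(1985, 1985, 1995), c(1, 0, 1))
  out <- cohort_tal_surfaces(obs, ll)
  expect_identical(names(out), c("1905-1909", "1910-1914", "1920-1924"))
  expect_identical(sum(out[["1905-1909"]]$cells$count), 1L)
  # a cohort whose observations are all unusable gives an empty grid
  ll2 <- rbind(ll, lifelines("d", 1930, NA))
  class(ll2) <- class(ll)
  obs2 <- rbind(obs, observations("d", 1980, 1))
  out2 <- cohort_tal_surfaces(obs2, ll2)
  expect_identical(nrow(out2[["1930-1934"]]$cells), 0L)
  expect_identical(out2[["1930-1934"]]$dropped, 1L)
})

test_that("variation shares decompose the cell-mean variance", {
  mk_grid <- function(cells) {
    g <- aggregate_surface(observations(character(0), numeric(0)),
                           lifelines(character(0), numeric(0)))
    g$cells <- cells
    g
  }
  # means depend only on T (the y measure)
  cells <- expand.grid(x = 0:3, y = 0:3)
  cells$count <- 5L
  cells$value <- c(0.8, 0.5, 0.3, 0.1)[cells$y + 1]
  vs <- variation_direction(mk_grid(cells))
  expect_equal(unname(vs["share_T"]), 1)
  expect_lt(vs[["share_A"]], 1)
  # identical means everywhere: zero variance convention 0/0 -> 0
  cells$value <- 0.4
  expect_equal(unname(variation_direction(mk_grid(cells))), c(0, 0))
  # degenerate grids
  expect_error(variation_direction(mk_grid(cells[1, ])),
               class = "demotime_degenerate")
  expect_error(variation_direction(mk_grid(cells[cells$y == 0, ])),
               class = "demotime_degenerate")
})

test_that("surface matrices and serialization round the long format", {
  ll <- lifelines("a", 1900, 1990)
  obs <- observations(rep("a", 3), c(1980, 1985, 1989), c(1, 1, 0))
  g <- aggregate_surface(obs, ll)
  M <- surface_matrix(g)
  expect_equal(sum(is.finite(M)), 3)
  df <- as.data.frame(g)
  expect_identical(names(df)[1:2], c("A", "T"))
  path <- file.path(withr::local_tempdir(), "surf.csv")
  write_surface(g, path)
  back <- read.csv(path)
  expect_equal(back$value, g$cells$value)
  expect_identical(back$plane[1], "TAL")
})
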