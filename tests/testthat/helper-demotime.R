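# shared fixtures, built in code

# tiny three-age lifetable used across health-expectancy tests:
# q = (0.2, 0.5, 1) => l = (1, 0.8, 0.4), L = (0.9, 0.6, 0.2), e0 = 1.7
toy_lifetable <- function() build_lifetable(qx = c(0.2, 0.5, 1))

demographic_graph_fixture <- function() demographic_graph()

# random lifetable with qx increasing and q(omega) = 1
random_lifetable <- function(omega = 30) {
  q <- sort(runif(omega, 0.005, 0.5))
  build_lifetable(qx = c(q, 1))
}

# independent Sullivan oracle: explicit per-age loop
sullivan_oracle <- function(lt, pi_a, x0) {
  i0 <- match(x0, lt$x)
  total <- 0
  for (i in which(lt$x >= x0)) total <- total + lt$Lx[i] * pi_a[i]
  total / lt$lx[i0]
}

# independent time-to-death oracle: enumerate each death age separately.
# A death in age interval a happens at its midpoint, k + 1/2 years after
# x0 (k = a - x0): walking back from death, the deceased spends half a
# year at completed thanatological age k and a full year at each of
# k-1, ..., 0.
ttd_oracle <- function(lt, g, x0) {
  i0 <- match(x0, lt$x)
  total <- 0
  for (i in which(lt$x >= x0)) {
    k <- lt$x[i] - x0
    years <- 0.5 * g[k + 1]
    if (k >= 1) for (t in 0:(k - 1)) years <- years + g[t + 1]
    total <- total + lt$dx[i] * years
  }
  total / lt$lx[i0]
}

write_tmp_csv <- function(df, name = "tmp.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  path
}
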