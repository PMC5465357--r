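test_that("site preference is the alpha-beta difference and inverts bulk/SP", {
  expect_equal(site_preference(10, 4), 6)
  expect_equal(site_preference(3.2, 3.2), 0)
  expect_error(site_preference(NaN, 1), class = "n2osource_invalid_value")

  # reference-tank round trip: bulk -0.7, SP -5.3 implies alpha/beta from the
  # inverted definitions, and those round-trip back
  ab <- d15n_alpha_beta(-0.7, -5.3)
  expect_equal(ab$d15n_alpha, -3.35)
  expect_equal(ab$d15n_beta, 1.95)
  expect_equal(site_preference(ab$d15n_alpha, ab$d15n_beta), -5.3)
  expect_equal((ab$d15n_alpha + ab$d15n_beta) / 2, -0.7)
})

test_that("cap-delta-17O: worked points, linearity, and convention agreement", {
  expect_equal(cap_delta_17o(0, 0), 0)
  expect_equal(cap_delta_17o(5.2, 10), 0)
  expect_equal(cap_delta_17o(10, 10), 4.8)
  expect_error(cap_delta_17o(1, 1, lambda = 0.4), class = "n2osource_config_error")
  expect_error(cap_delta_17o(1, 1, lambda = 0.6), class = "n2osource_config_error")

  # linear form is exactly linear in both arguments
  set.seed(11)
  for (i in 1:20) {
    a <- runif(2, -30, 30); b <- runif(2, -30, 30); k <- runif(1, -2, 2)
    expect_equal(cap_delta_17o(a[1] + k * a[2], b[1] + k * b[2]),
                 cap_delta_17o(a[1], b[1]) + k * cap_delta_17o(a[2], b[2]))
  }

  # the conventions agree closely near the origin and diverge quadratically,
  # |log - linear| ~ lambda*(1-lambda)*d18O^2/2000: within 0.05 permil for
  # |d18O| <= 15 and within 0.35 permil out to |d18O| = 50
  d18 <- seq(-15, 15, by = 3)
  d17 <- 0.52 * d18 + runif(length(d18), -3, 3)
  expect_lt(max(abs(cap_delta_17o(d17, d18, form = "logarithmic") -
                    cap_delta_17o(d17, d18, form = "linear"))), 0.05)
  d18 <- seq(-50, 50, by = 5)
  d17 <- 0.52 * d18 + runif(length(d18), -3, 3)
  expect_lt(max(abs(cap_delta_17o(d17, d18, form = "logarithmic") -
                    cap_delta_17o(d17, d18, form = "linear"))), 0.35)
})

test_that("cap-delta-17O is conserved under mass-dependent fractionation", {
  set.seed(12)
  lambda <- 0.52
  for (i in 1:50) {
    d18 <- runif(1, -10, 40); d17 <- runif(1, -10, 30); shift <- runif(1, -20, 20)
    before <- cap_delta_17o(d17, d18, lambda = lambda)
    after <- cap_delta_17o(d17 + lambda * shift, d18 + shift, lambda = lambda)
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("conservative mixing: weighted mean, reorder/split invariance, errors", {
  expect_equal(mix_pools(c(50, 50), c(7.7, 7.7)), 7.7)
  expect_equal(mix_pools(c(120, 20), c(18.5, 0)), 120 * 18.5 / 140)
  expect_equal(mix_pools(c(30, 0), c(4, 99)), 4)       # zero-weight pool
  expect_error(mix_pools(c(0, 0), c(1, 2)), class = "n2osource_degenerate_input")
  expect_error(mix_pools(c(-1, 2), c(1, 2)), class = "n2osource_invalid_value")

  set.seed(13)
  for (i in 1:20) {
    conc <- runif(4, 0, 100); val <- runif(4, -10, 20)
    m <- mix_pools(conc, val)
    ord <- sample(4)
    expect_equal(mix_pools(conc[ord], val[ord]), m)
    # splitting the first pool into halves is conservative
    expect_equal(mix_pools(c(conc[1] / 2, conc[1] / 2, conc[-1]),
                           c(val[1], val[1], val[-1])), m)
  }
})

test_that("precursor fraction: ratio, scale invariance, informative floor", {
  expect_equal(precursor_fraction(0, 8.5), 0)
  expect_equal(precursor_fraction(8.5, 8.5), 1)
  expect_equal(precursor_fraction(6.5, 8.5), 6.5 / 8.5, tolerance = 1e-12)
  expect_error(precursor_fraction(1, 0.5),
               class = "n2osource_uninformative_tracer")

  set.seed(14)
  for (i in 1:20) {
    n2o <- runif(1, -5, 15); pre <- runif(1, 2, 20); k <- runif(1, 0.5, 3)
    expect_equal(precursor_fraction(k * n2o, k * pre), precursor_fraction(n2o, pre))
  }
})

test_that("TRN delta-15N mass balance removes the oxidised pools", {
  expect_equal(trn_d15n(100, 10, 50, 5, 10, 0), 18.75)
  expect_equal(trn_d15n(80, 12.5, 0, 99, 0, 99), 12.5)  # identity at zero NO3/NO2
  expect_error(trn_d15n(50, 10, 40, 5, 10, 0), class = "n2osource_degenerate_input")

  # round trip: rebuild TDN from the three sub-pools, re-solve, recover input
  set.seed(15)
  for (i in 1:30) {
    c3 <- runif(1, 0, 100); c2 <- runif(1, 0, 20); ctrn <- runif(1, 5, 80)
    d3 <- runif(1, -5, 20); d2 <- runif(1, -10, 10); dtrn <- runif(1, -5, 25)
    ctdn <- c3 + c2 + ctrn
    dtdn <- (d3 * c3 + d2 * c2 + dtrn * ctrn) / ctdn
    expect_equal(trn_d15n(ctdn, dtdn, c3, d3, c2, d2), dtrn, tolerance = 1e-9)
  }
})
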