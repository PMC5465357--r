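test_that("build_system assembles the four balances with the reduction shift", {
  set.seed(21)
  ems <- random_endmembers()
  sys0 <- build_system(5, 16, 0.76, ems, f_red = 0)
  sys9 <- build_system(5, 16, 0.76, ems, f_red = 0.9)
  expect_equal(dim(sys0$A), c(4, 4))
  expect_equal(qr(sys0$A)$rank, 4)
  expect_equal(unname(sys0$b["closure"]), 1)
  # reduction with sp_eps_red = -6: f_red = 0.9 shifts the SP row by -5.4
  expect_equal(unname(sys9$b["sp"] - sys0$b["sp"]), -5.4)
  # the 17O-excess row is untouched by f_red
  expect_equal(sys9$b["o_ratio"], sys0$b["o_ratio"])
  expect_equal(sys9$A[2, ], sys0$A[2, ])

  # two processes with identical signatures -> collinearity naming them
  em_df <- tibble::as_tibble(ems)
  em_df[em_df$process == "nDNF", c("dd15n", "sp", "o_transfer")] <-
    em_df[em_df$process == "bDNF", c("dd15n", "sp", "o_transfer")]
  expect_error(build_system(5, 16, 0.76, endmember_set(em_df), 0),
               regexp = "bDNF.*nDNF", class = "n2osource_collinear")
})

test_that("solve_fractions recovers vertices and exact compositions", {
  set.seed(22)
  for (i in 1:10) {
    ems <- random_endmembers()
    # vertex recovery: measurement composed as one pure endmember
    for (j in 1:4) {
      f_true <- setNames(as.numeric(seq_len(4) == j), ems$process)
      fwd <- forward_model(f_true, ems, f_red = 0)
      pf <- solve_fractions(build_system(fwd$dd15n_meas, fwd$sp_meas,
                                         fwd$o_ratio_meas, ems, 0))
      expect_equal(pf$f_raw, f_true, tolerance = 1e-9)
      expect_true(pf$feasible)
      expect_lt(pf$residual_norm, 1e-9)
    }
    # uniform composition round trip
    f_true <- setNames(rep(0.25, 4), ems$process)
    fwd <- forward_model(f_true, ems, f_red = 0.3)
    pf <- solve_fractions(build_system(fwd$dd15n_meas, fwd$sp_meas,
                                       fwd$o_ratio_meas, ems, 0.3))
    expect_equal(pf$f_raw, f_true, tolerance = 1e-10)
  }
})

test_that("clip_renormalize zeroes negatives, rescales, and is idempotent", {
  x <- c(bDNF = 0.5, fDNF = 0.6, AMO = -0.1, nDNF = 0)
  y <- clip_renormalize(x)
  expect_equal(unname(y), c(0.5 / 1.1, 0.6 / 1.1, 0, 0))
  expect_equal(sum(y), 1)
  expect_equal(clip_renormalize(y), y)
  feasible <- c(bDNF = 0.2, fDNF = 0.3, AMO = 0.4, nDNF = 0.1)
  expect_equal(clip_renormalize(feasible), feasible)
  expect_error(clip_renormalize(c(a = -1, b = -0.2, c = 0, d = 0)),
               class = "n2osource_infeasible")

  set.seed(23)
  for (i in 1:25) {
    z <- runif(4, -0.5, 1.5)
    if (all(z <= 0)) next
    expect_equal(sum(clip_renormalize(z)), 1, tolerance = 1e-12)
    expect_true(all(clip_renormalize(z) >= 0))
  }
})

test_that("forward model composes endmember signatures exactly", {
  ems <- n2osource:::inject_amo(default_endmembers(), 4.6, 11.9)
  # pure fungal denitrification with no reduction: SP equals the 37 endmember
  f <- c(bDNF = 0, fDNF = 1, AMO = 0, nDNF = 0)
  expect_equal(forward_model(f, ems, 0)$sp_meas, 37)
  # pure AMO: no O transferred from the labelled NO2- pool
  expect_equal(forward_model(c(bDNF = 0, fDNF = 0, AMO = 1, nDNF = 0), ems,
                             0.5)$o_ratio_meas, 0)
  # raising f_red strictly raises SP_meas when sp_eps_red < 0
  sp_at <- vapply(c(0, 0.3, 0.9), function(fr) forward_model(f, ems, fr)$sp_meas,
                  numeric(1))
  expect_true(all(diff(sp_at) > 0))
  expect_error(forward_model(c(bDNF = 0.7, fDNF = 0.5, AMO = -0.2, nDNF = 0),
                             ems, 0), class = "n2osource_invalid_value")
})

test_that("partition_core inverts the forward model and names missing fields", {
  # zero-noise synthetic record round trip
  set.seed(24)
  for (i in 1:10) {
    f <- setNames(random_simplex(c(4, 4, 2, 1)), c("bDNF", "fDNF", "AMO", "nDNF"))
    tr <- core_truth("rt", "HN", f = f, f_red = 0.1)
    rec <- generate_steady_record(tr, default_endmembers(), noise_scale = 0)
    pf <- partition_core(rec, default_endmembers(), f_red = 0.1)
    expect_equal(pf$f, f, tolerance = 1e-9)
  }

  rec <- hn_mean_record()
  rec$cap17o_n2o <- NULL
  err <- expect_error(partition_core(rec, default_endmembers(), 0.1),
                      class = "n2osource_missing_measurement")
  expect_match(conditionMessage(err), "cap17o_n2o")

  # an O-ratio beyond the attainable span flags infeasibility
  rec2 <- hn_mean_record()
  rec2$cap17o_n2o <- rec2$cap17o_no2 * 1.4   # o_ratio = 1.4 > max attainable 1
  pf2 <- partition_core(rec2, default_endmembers(), 0.1)
  expect_false(pf2$feasible)
})

test_that("treatment-mean high-nitrate inversion ranks fungal denitrification highly", {
  pf <- partition_core(hn_mean_record(), default_endmembers(), f_red = 0.1)
  rank_fdnf <- rank(-pf$f)["fDNF"]
  expect_lte(rank_fdnf, 2)
  expect_true(pf$feasible)
  expect_equal(sum(pf$f), 1, tolerance = 1e-9)
})

test_that("partition_n2o returns a long provenance-carrying table", {
  recs <- tibble::as_tibble(hn_mean_record())
  out <- partition_n2o(recs, f_red = c(0.1, 0.9))
  expect_s3_class(out, "n2o_partition")
  expect_equal(nrow(out), 8)
  expect_setequal(names(out), c("core_id", "f_red", "process", "f_raw", "f",
                                "residual_norm", "feasible", "config_hash"))
  sums <- dplyr::summarise(dplyr::group_by(out, f_red), s = sum(f))$s
  expect_equal(sums, c(1, 1), tolerance = 1e-9)
})

test_that("raising measured SP never lowers the clipped high-SP total", {
  set.seed(25)
  ems <- n2osource:::inject_amo(default_endmembers(), 4.6, 11.9)
  n_checked <- 0
  for (i in 1:200) {
    dd <- runif(1, -5, 15); o <- runif(1, 0.2, 1); sp <- runif(1, -5, 35)
    f1 <- try(clip_renormalize(solve_fractions(
      build_system(dd, sp, o, ems, 0.1)))$f, silent = TRUE)
    f2 <- try(clip_renormalize(solve_fractions(
      build_system(dd, sp + runif(1, 0.1, 5), o, ems, 0.1)))$f, silent = TRUE)
    if (inherits(f1, "try-error") || inherits(f2, "try-error")) next
    n_checked <- n_checked + 1
    expect_gte(f2[["fDNF"]] + f2[["AMO"]], f1[["fDNF"]] + f1[["AMO"]] - 1e-9)
  }
  expect_gt(n_checked, 100)
})
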