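test_that("exact null distribution matches hand enumeration at (1,1,1)", {
  d <- exact_null_distribution(c(1, 1, 1), "rd")
  expect_equal(d$support, c(0, 1, 3, 4))
  expect_equal(d$prob, c(1, 2, 2, 1) / 6)
  expect_equal(sum(d$prob), 1)
  expect_equal(d$mean, 2)
  expect_equal(d$variance, 2)

  d2 <- exact_null_distribution(c(1, 1), "rd")
  expect_equal(d2$support, c(0, 1))
  expect_equal(d2$prob, c(0.5, 0.5))
})

test_that("enumerated moments equal the closed forms (dual route)", {
  for (sizes in list(c(3, 3), c(2, 2, 2), c(3, 2, 1), c(2, 2, 1, 1))) {
    d <- exact_null_distribution(sizes, "rd")
    expect_equal(d$mean, rd_null_mean(sizes), tolerance = 1e-12)
    expect_equal(d$variance, rd_null_variance(sizes), tolerance = 1e-12)
  }
})

test_that("null distribution is symmetric under composition reversal", {
  for (sizes in list(c(2, 1), c(3, 2, 1), c(1, 2, 3, 2))) {
    fwd <- exact_null_distribution(sizes, "rd")
    rev <- exact_null_distribution(rev(sizes), "rd")
    expect_equal(fwd$support, rev$support)
    expect_equal(fwd$prob, rev$prob)
  }
})

test_that("enumeration cap triggers a helpful error", {
  expect_error(exact_null_distribution(c(10, 10, 10), "rd", cap = 1000),
               "permutation")
})

test_that("exact p-values come from the enumerated tail", {
  # perfectly separated increasing singleton sample: S = 4, p = 1/6
  gs <- grouped_sample(list(a = 0.3, b = 1.1, c = 2.5))
  tt <- trend_test(gs, "rd", method = "exact")
  expect_equal(tt$statistic, 4)
  expect_equal(tt$p_value, 1 / 6)

  # permutation route approaches the exact tail probability
  gs2 <- grouped_sample(list(a = c(0.1, 0.5), b = c(1.0, 1.7),
                             c = c(2.2, 3.0)))
  ex <- trend_test(gs2, "rd", method = "exact")
  pm <- trend_test(gs2, "rd", method = "permutation", n_perm = 4000,
                   seed = 3)
  expect_lt(abs(pm$p_value - ex$p_value), 0.02)
})

test_that("permutation inference follows the add-one convention", {
  gs <- grouped_sample(list(a = c(1, 1), b = c(1, 1)))
  # constant data: statistic invariant under permutation, p must be 1
  expect_warning(tt <- trend_test(gs, "rd", method = "permutation",
                                  n_perm = 200, seed = 1), "tied")
  expect_equal(tt$p_value, 1)

  # reproducibility and the (b+1)/(B+1) floor
  gs2 <- grouped_sample(list(a = c(0.1, 0.4), b = c(2.2, 3.0)))
  t1 <- trend_test(gs2, "jt", method = "permutation", n_perm = 500,
                   seed = 7)
  t2 <- trend_test(gs2, "jt", method = "permutation", n_perm = 500,
                   seed = 7)
  expect_identical(t1$p_value, t2$p_value)
  expect_gte(t1$p_value, 1 / 501)
})

test_that("permutation p-values are valid under the exchangeable null", {
  set.seed(99)
  n_data <- 150
  hits <- 0
  for (i in seq_len(n_data)) {
    gs <- grouped_sample(list(a = rnorm(3), b = rnorm(3)))
    p <- trend_test(gs, "rd", method = "permutation", n_perm = 99,
                    seed = i)$p_value
    if (p <= 0.05) hits <- hits + 1
  }
  # P(p <= 0.05) <= 0.05 + granularity; allow 3 binomial SE above that
  expect_lt(hits / n_data, 0.05 + 0.02 + 3 * sqrt(0.07 * 0.93 / n_data))
})

test_that("asymptotic method is refused where theory does not cover", {
  gs <- grouped_sample(list(a = c(1, 2), b = c(3, 4)))
  expect_error(trend_test(gs, "jt", method = "asymptotic"),
               "only for the")
  tied <- grouped_sample(list(a = c(1, 2), b = c(2, 3)))
  expect_error(trend_test(tied, "rd", method = "asymptotic"), "tied")
  expect_error(trend_test(tied, "rd", method = "exact"), "tied")
})

test_that("side = 'decreasing' reverses the group order", {
  gs <- grouped_sample(list(a = c(5, 6), b = c(3, 4), c = c(1, 2)))
  up <- trend_test(gs, "rd", method = "exact")
  dn <- trend_test(gs, "rd", method = "exact", side = "decreasing")
  expect_gt(up$p_value, 0.5)
  expect_equal(dn$p_value,
               trend_test(grouped_sample(rev(gs$values)), "rd",
                          method = "exact")$p_value)
})

test_that("cutpoint calibration shares draws across tests", {
  sp <- scenario_spec("normal", mean = c(0, 0, 0), sizes = c(5, 5, 5),
                      null = TRUE)
  c_all <- calibrate_cutpoints(sp, tests = c("jt", "rd"),
                               replicates = 400, seed = 5)
  c_jt <- calibrate_cutpoints(sp, tests = "jt", replicates = 400,
                              seed = 5)
  # identical datasets by construction: same seed, generation does not
  # depend on the test list
  expect_identical(c_all$cutpoints[["jt"]], c_jt$cutpoints[["jt"]])
  expect_named(c_all$cutpoints, c("jt", "rd"))
  expect_error(calibrate_cutpoints(sp, replicates = 50), "100")
})

test_that("cutpoint is the ceiling(0.95 B) order statistic", {
  sp <- scenario_spec("normal", mean = c(0, 0), sizes = c(3, 3),
                      null = TRUE)
  set.seed(41)
  cc <- calibrate_cutpoints(sp, tests = "jt", replicates = 200, seed = 41)
  set.seed(41)
  stats <- trendrank:::simulate_statistics(sp, 200, "jt")[, "jt"]
  expect_identical(cc$cutpoints[["jt"]], sort(stats)[ceiling(0.95 * 200)])
})
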