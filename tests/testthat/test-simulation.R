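test_that("scenario_spec validates families and parameters", {
  sp <- scenario_spec("normal", mean = c(0, 0.5, 1), sizes = c(10, 10, 10))
  expect_equal(sp$dist, rep("normal", 3))
  expect_equal(sp$sd, rep(1, 3))

  mx <- scenario_spec(c("normal", "exponential", "exponential"),
                      mean = c(1, 1, 1), sizes = c(30, 20, 10))
  expect_equal(mx$dist[2], "exponential")

  expect_error(scenario_spec("gamma", mean = c(0, 0), sizes = c(5, 5)),
               "unknown family")
  expect_error(scenario_spec("exponential", mean = c(0, 1),
                             sizes = c(5, 5)), "positive mean")
  expect_error(scenario_spec("normal", mean = c(0, 1, 2),
                             sizes = c(5, 5)), "one entry per group")
})

test_that("generate_dataset draws the stated families", {
  # law of large numbers at 3 SE for the exponential mean
  sp <- scenario_spec("exponential", mean = c(2, 2),
                      sizes = c(25000, 25000))
  gs <- generate_dataset(sp, seed = 12)
  expect_lt(abs(mean(unlist(gs$values)) - 2), 0.03)

  # normal group means and sds
  spn <- scenario_spec("normal", mean = c(0, 5), sd = c(1, 3),
                       sizes = c(20000, 20000))
  gn <- generate_dataset(spn, seed = 13)
  expect_lt(abs(mean(gn$values[[2]]) - 5), 3 * 3 / sqrt(20000))
  expect_lt(abs(sd(gn$values[[2]]) - 3), 0.1)

  # t3 is a location shift of a symmetric heavy-tailed variate
  spt <- scenario_spec("t3", mean = c(0, 4), sizes = c(20000, 20000))
  gt <- generate_dataset(spt, seed = 14)
  expect_lt(abs(median(gt$values[[2]]) - 4), 0.05)

  # determinism contract
  expect_identical(generate_dataset(sp, seed = 12)$values, gs$values)
})

test_that("power_study produces the full scenario-by-test grid", {
  ns <- scenario_spec("normal", mean = c(0, 0, 0), sizes = c(5, 5, 5),
                      null = TRUE)
  alts <- list(shift = scenario_spec("normal", mean = c(0, 1, 2),
                                     sizes = c(5, 5, 5)))
  pt <- power_study(ns, alts, b_null = 400, b_alt = 400, seed = 2)
  expect_s3_class(pt, "power_table")
  expect_equal(nrow(pt), 2 * 5)   # null + shift, five tests
  expect_setequal(unique(pt$scenario), c("null", "shift"))
  expect_true(all(pt$rate >= 0 & pt$rate <= 1))

  # monotonicity smoke test: power under a clear shift beats size
  for (tst in unique(pt$test)) {
    expect_gt(pt$rate[pt$scenario == "shift" & pt$test == tst],
              pt$rate[pt$scenario == "null" & pt$test == tst])
  }
})

test_that("common random numbers: test list never changes the draws", {
  ns <- scenario_spec("normal", mean = c(0, 0, 0), sizes = c(4, 4, 4),
                      null = TRUE)
  alts <- list(a = scenario_spec("normal", mean = c(0, 0.5, 1),
                                 sizes = c(4, 4, 4)))
  p_all <- power_study(ns, alts, tests = c("jt", "tm", "rd"),
                       b_null = 300, b_alt = 300, seed = 8)
  p_jt <- power_study(ns, alts, tests = "jt", b_null = 300,
                      b_alt = 300, seed = 8)
  a <- p_all[p_all$test == "jt", c("scenario", "rate")]
  b <- p_jt[, c("scenario", "rate")]
  expect_equal(a$rate[order(a$scenario)], b$rate[order(b$scenario)])
})

test_that("mjt and cu always reject together under shared draws", {
  ns <- scenario_spec("normal", mean = c(0, 0, 0), sizes = c(6, 5, 4),
                      null = TRUE)
  alts <- list(a = scenario_spec("normal", mean = c(0, 0.6, 1.2),
                                 sizes = c(6, 5, 4)))
  pt <- power_study(ns, alts, tests = c("mjt", "cu"), b_null = 500,
                    b_alt = 500, seed = 17)
  for (sc in unique(pt$scenario)) {
    expect_identical(pt$rate[pt$scenario == sc & pt$test == "mjt"],
                     pt$rate[pt$scenario == sc & pt$test == "cu"])
  }
})

test_that("table_report compares against reference cells", {
  pt <- data.frame(scenario = c("a", "a"), sizes = "(10,10,10)",
                   test = c("jt", "rd"), rate = c(0.66, 0.68),
                   b_null = 100, b_alt = 100, seed = 1)
  ref <- data.frame(scenario = "a", sizes = "(10,10,10)", test = "jt",
                    value = 0.662)
  rep <- table_report(pt, ref, tol = 0.02)
  expect_true(rep$pass[rep$test == "jt"])
  expect_true(is.na(rep$pass[rep$test == "rd"]))  # uncompared, not fatal
  expect_equal(rep$deviation[rep$test == "jt"], 0.002)

  ident <- table_report(pt, pt[, c("scenario", "sizes", "test",
                                   "rate")] |>
                          transform(value = rate), tol = 0)
  expect_true(all(ident$deviation == 0))
})

test_that("bundled reference cells and configs load coherently", {
  ref <- reference_cells("table1")
  expect_equal(nrow(ref), 120)   # 6 scenarios x 4 sizes x 5 tests
  expect_true(all(ref$value >= 0 & ref$value <= 1))
  expect_setequal(unique(ref$test), c("jt", "mjt", "tm", "cu", "rd"))
  expect_error(reference_cells("table99"), "unknown table")

  cfg <- load_scenario_config(system.file("extdata", "configs",
                                          "table1.json",
                                          package = "trendrank"))
  expect_s3_class(cfg$null_spec, "scenario_spec")
  expect_length(cfg$alt_specs, 5)
  expect_length(cfg$sizes_list, 4)
  expect_null(cfg$calib_spec)

  # mixed design calibrates from an exchangeable standard-normal null
  cfg4 <- load_scenario_config(system.file("extdata", "configs",
                                           "table4.json",
                                           package = "trendrank"))
  expect_s3_class(cfg4$calib_spec, "scenario_spec")
  expect_equal(unique(cfg4$calib_spec$dist), "normal")
  expect_equal(cfg4$null_spec$dist,
               c("normal", "exponential", "exponential"))
})
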