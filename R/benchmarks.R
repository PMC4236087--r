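#' Re-run the published benchmark cells
#'
#' Recomputes, from scratch, the ten headline size/power cells used to
#' validate this implementation against the published simulation study:
#' each cell runs the full shared-draw protocol (calibrate every test's
#' cutpoint on `b_null` simulated null datasets, then estimate the
#' rejection proportion over `b_alt` fresh datasets) for its scenario.
#' Cells sharing a calibration configuration share one run.
#'
#' @param seed Integer base seed; all randomness derives from it.
#' @param b_null Null replicates for cutpoint calibration (published
#'   protocol: 20,000).
#' @param b_alt Replicates per rejection-rate estimate (published
#'   protocol: 10,000).
#' @return A named list, one entry per benchmark id (`t1`..`t10`), each
#'   a list with `value` (the rejection proportion) and `n` (`b_alt`).
#' @examples
#' run_benchmarks(seed = 1, b_null = 500, b_alt = 500)$t1
#' @export
run_benchmarks <- function(seed = 1, b_null = 20000, b_alt = 10000) {
  seed <- as.integer(seed)
  k3 <- c(10, 10, 10)
  dec <- c(30, 20, 10)
  k4 <- c(8, 8, 8, 8)
  k4d <- c(20, 20, 10, 10)
  norm <- function(mu, sizes, null = FALSE) {
    scenario_spec("normal", mu, sizes = sizes, null = null)
  }
  cell <- function(pt, scenario, test) {
    pt$rate[pt$scenario == scenario & pt$test == test]
  }
  res <- list()

  # three standard-normal groups (10,10,10): size and the linear shift
  ptA <- power_study(
    norm(c(0, 0, 0), k3, null = TRUE),
    list(a = norm(c(0, 0.5, 1), k3)),
    b_null = b_null, b_alt = b_alt, seed = seed, include_null = TRUE)
  res$t1 <- cell(ptA, "null", "rd")
  res$t2 <- cell(ptA, "a", "rd")
  res$t3 <- cell(ptA, "a", "jt")

  # decreasing sizes (30,20,10), standard-normal calibration: the
  # convex normal alternative and the conservative mixed null
  ptB <- power_study(
    norm(c(0, 0, 0), dec, null = TRUE),
    list(c = norm(c(0, 0, 1), dec),
         mixed_null = scenario_spec(
           c("normal", "exponential", "exponential"), c(1, 1, 1),
           sizes = dec)),
    b_null = b_null, b_alt = b_alt, seed = seed + 1L,
    include_null = FALSE)
  res$t4 <- cell(ptB, "c", "tm")
  res$t7 <- cell(ptB, "mixed_null", "rd")

  # shifted t (3 df), non-monotone shift (0,1,0.5)
  ptC <- power_study(
    scenario_spec("t3", c(0, 0, 0), sizes = dec, null = TRUE),
    list(d = scenario_spec("t3", c(0, 1, 0.5), sizes = dec)),
    b_null = b_null, b_alt = b_alt, seed = seed + 2L,
    include_null = FALSE)
  res$t5 <- cell(ptC, "d", "rd")

  # exponential groups with means (1,2,2)
  ptD <- power_study(
    scenario_spec("exponential", c(1, 1, 1), sizes = dec, null = TRUE),
    list(b = scenario_spec("exponential", c(1, 2, 2), sizes = dec)),
    b_null = b_null, b_alt = b_alt, seed = seed + 3L,
    include_null = FALSE)
  res$t6 <- cell(ptD, "b", "rd")

  # four equal groups of 8, gradual normal shift
  ptF <- power_study(
    norm(c(0, 0, 0, 0), k4, null = TRUE),
    list(A = norm(c(0, 0.2, 0.5, 1), k4)),
    b_null = b_null, b_alt = b_alt, seed = seed + 4L,
    include_null = FALSE)
  res$t8 <- cell(ptF, "A", "rd")

  # four groups (20,20,10,10): end shift for Cuzick, and the mixed
  # normal/exponential alternative
  ptG <- power_study(
    norm(c(0, 0, 0, 0), k4d, null = TRUE),
    list(C = norm(c(0, 0, 0, 1), k4d),
         B = scenario_spec(
           c("normal", "normal", "exponential", "exponential"),
           c(1, 1.5, 1.5, 1.5), sizes = k4d)),
    b_null = b_null, b_alt = b_alt, seed = seed + 5L,
    include_null = FALSE)
  res$t9 <- cell(ptG, "C", "cu")
  res$t10 <- cell(ptG, "B", "rd")

  lapply(res, function(v) list(value = v, n = b_alt))
}
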