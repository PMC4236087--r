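#' Exact null distribution of a trend statistic
#'
#' Enumerates every equally likely assignment of the ranks 1..N to the
#' groups (N! / prod(n_i!) distinct assignments, since within-group
#' order is irrelevant) and tabulates the chosen statistic. This is the
#' verification oracle for the closed-form null moments and the route to
#' exact small-sample p-values.
#'
#' @param sizes Group sizes (n_1, ..., n_k).
#' @param test One of `"jt"`, `"mjt"`, `"tm"`, `"cu"`, `"rd"`.
#' @param cap Maximum number of arrangements to enumerate; beyond this
#'   an error suggests Monte-Carlo (permutation) inference.
#' @return An object of class `null_distribution`: a list with `test`,
#'   `sizes`, `support` (sorted distinct values), `prob` (matching
#'   probabilities, summing to one), `mean`, `variance`, and
#'   `provenance = "exact"`.
#' @examples
#' d <- exact_null_distribution(c(1, 1, 1), "rd")
#' d$support  # 0 1 3 4
#' d$prob     # 1/6 1/3 1/3 1/6
#' @export
exact_null_distribution <- function(sizes, test = "rd", cap = 200000) {
  sizes <- check_sizes(sizes)
  test <- match.arg(normalize_tests(test), TEST_NAMES)
  M <- multinomial_count(sizes)
  if (M > cap) {
    stop("exact enumeration needs ", M, " arrangements (cap ", cap,
         "); use permutation inference instead")
  }
  Rm <- enumerate_rank_assignments(sizes)
  s <- batch_statistics(Rm, sizes, test)[, test]
  tab <- table(s)
  support <- as.numeric(names(tab))
  prob <- as.numeric(tab) / length(s)
  structure(
    list(test = test, sizes = sizes, support = support, prob = prob,
         mean = sum(support * prob),
         variance = sum(support^2 * prob) - sum(support * prob)^2,
         provenance = "exact", replicates = NULL, seed = NULL),
    class = "null_distribution"
  )
}

multinomial_count <- function(sizes) {
  rem <- sum(sizes)
  m <- 1
  for (n in sizes) {
    m <- m * choose(rem, n)
    rem <- rem - n
  }
  m
}

# All assignments of ranks 1..N to groups, one per column, rows blocked
# by group. Within-group rank order is irrelevant to every statistic.
enumerate_rank_assignments <- function(sizes) {
  rec <- function(avail, sz) {
    if (length(sz) == 1L) return(matrix(avail, ncol = 1L))
    cmb <- utils::combn(length(avail), sz[1L])
    parts <- vector("list", ncol(cmb))
    for (ci in seq_len(ncol(cmb))) {
      idx <- cmb[, ci]
      sub <- rec(avail[-idx], sz[-1L])
      parts[[ci]] <- rbind(
        matrix(avail[idx], nrow = sz[1L], ncol = ncol(sub)), sub)
    }
    do.call(cbind, parts)
  }
  rec(seq_len(sum(sizes)), sizes)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution of the", toupper(x$test), "statistic (",
      x$provenance, ")\n")
  cat("  sizes: (", paste(x$sizes, collapse = ", "), ")",
      "  support points:", length(x$support), "\n")
  cat("  mean:", format(x$mean), " variance:", format(x$variance), "\n")
  invisible(x)
}

# Upper-tail probability P(stat >= observed) with a numeric fuzz that is
# safe because all five statistics live on a half-integer grid.
tail_probability <- function(dist, observed) {
  sum(dist$prob[dist$support >= observed - 1e-9])
}

#' Trend test for ordered alternatives
#'
#' Tests the null of identical distributions against the monotone
#' ordered alternative implied by the group order of `x`, using any of
#' the five trend statistics and one of three inference routes:
#'
#' * `"asymptotic"`: standard normal inference via the exact null
#'   moments; available only for the rank-difference (`"rd"`) statistic,
#'   and only for tie-free data (the variance assumes continuity).
#' * `"permutation"`: Monte-Carlo permutation of the pooled (mid)ranks
#'   with the add-one convention p = (1 + b) / (B + 1).
#' * `"exact"`: full enumeration of the null distribution (small N).
#'
#' @param x A [grouped_sample()] (or a `ranked_sample`, for rank-only
#'   input).
#' @param test Statistic name: `"rd"` (default, alias `"new"`), `"jt"`,
#'   `"mjt"`, `"tm"`, or `"cu"`.
#' @param method `"asymptotic"`, `"permutation"`, or `"exact"`.
#' @param side `"increasing"` (default) or `"decreasing"`; decreasing is
#'   tested by reversing the group order.
#' @param n_perm Permutation replicates (method `"permutation"`).
#' @param seed Integer seed for the permutation draw.
#' @param cap Arrangement cap for method `"exact"`.
#' @return An object of class `trend_test`: a list with `test`,
#'   `statistic`, `z` (asymptotic method only, otherwise `NA`),
#'   `p_value`, `method`, `side`, `replicates`, `seed`, `sizes`, and
#'   `groups`.
#' @examples
#' gs <- grouped_sample(list(a = c(0.1, 0.9), b = c(1.4, 2.0),
#'                           c = c(2.2, 3.1)))
#' trend_test(gs, test = "rd", method = "exact")
#' @export
trend_test <- function(x, test = "rd",
                       method = c("asymptotic", "permutation", "exact"),
                       side = c("increasing", "decreasing"),
                       n_perm = 10000, seed = 1, cap = 200000) {
  method <- match.arg(method)
  side <- match.arg(side)
  test <- match.arg(normalize_tests(test), TEST_NAMES)
  if (inherits(x, "grouped_sample") && side == "decreasing") {
    x <- reverse_groups(x)
  } else if (inherits(x, "ranked_sample") && side == "decreasing") {
    stop("side = 'decreasing' needs the grouped sample, not ranks")
  }
  r <- as_ranked(x)
  observed <- trend_statistics(r, test)[[test]]

  if (method == "asymptotic") {
    if (test != "rd") {
      stop("asymptotic inference is available only for the ",
           "rank-difference ('rd') test; use method = 'permutation'")
    }
    if (r$tie_flag) {
      stop("tied data: the exact null variance assumes continuous ",
           "(tie-free) data; use method = 'permutation'")
    }
    z <- rd_standardize(observed, r$n)
    p <- normal_pvalue(z)
    return(new_trend_test(test, observed, z, p, method, side, r,
                          replicates = NULL, seed = NULL))
  }

  if (method == "exact") {
    if (r$tie_flag) {
      stop("tied data: exact enumeration assigns the ranks 1..N and ",
           "assumes tie-free data; use method = 'permutation'")
    }
    dist <- exact_null_distribution(r$n, test, cap = cap)
    p <- tail_probability(dist, observed)
    return(new_trend_test(test, observed, NA_real_, p, method, side, r,
                          replicates = NULL, seed = NULL))
  }

  # permutation
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  if (r$tie_flag && test == "rd") {
    warning("tied data: rank-difference statistic computed on midranks; ",
            "permutation inference remains valid")
  }
  set.seed(as.integer(seed))
  pooled <- unlist(r$ranks, use.names = FALSE)
  N <- r$N
  Rm <- vapply(seq_len(n_perm), function(i) sample(pooled),
               numeric(N))
  perm <- batch_statistics(Rm, r$n, test)[, test]
  p <- (1 + sum(perm >= observed - 1e-9)) / (n_perm + 1)
  new_trend_test(test, observed, NA_real_, p, method, side, r,
                 replicates = n_perm, seed = as.integer(seed))
}

new_trend_test <- function(test, statistic, z, p, method, side, r,
                           replicates, seed) {
  structure(
    list(test = test, statistic = statistic, z = z, p_value = p,
         method = method, side = side, replicates = replicates,
         seed = seed, sizes = r$n, groups = r$groups),
    class = "trend_test"
  )
}

#' @export
print.trend_test <- function(x, ...) {
  lab <- c(jt = "Jonckheere-Terpstra", mjt = "Modified Jonckheere-Terpstra",
           tm = "Terpstra-Magel", cu = "Cuzick",
           rd = "Rank-difference")[x$test]
  cat(lab, "trend test (", x$method, ", side =", x$side, ")\n")
  cat("  groups:", paste(x$groups, collapse = " < "),
      "  sizes: (", paste(x$sizes, collapse = ", "), ")\n")
  cat("  statistic =", format(x$statistic), sep = " ")
  if (!is.na(x$z)) cat(", z =", format(round(x$z, 4)))
  cat(", p-value =", format.pval(x$p_value, digits = 4), "\n")
  if (!is.null(x$replicates)) {
    cat("  (", x$replicates, " permutations, seed ", x$seed, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Calibrate simulated-null cutpoints shared across tests
#'
#' Draws `replicates` null datasets once from `null_spec`, evaluates
#' every requested statistic on each dataset (common random numbers),
#' and returns each test's empirical upper-alpha cutpoint: the
#' ceiling((1 - alpha) * B)-th order statistic of its null draws. The
#' downstream rejection rule is statistic strictly greater than the
#' cutpoint, which is slightly conservative under discreteness.
#'
#' @param null_spec A [scenario_spec()] describing the null sampling
#'   family and sizes.
#' @param tests Statistics to calibrate.
#' @param replicates Number of null datasets (>= 100).
#' @param seed Integer seed.
#' @param alpha Nominal level.
#' @return An object of class `cutpoints`: a list with `cutpoints`
#'   (named numeric), `alpha`, `replicates`, `seed`, and `sizes`.
#' @examples
#' sp <- scenario_spec("normal", mean = c(0, 0, 0), sizes = c(5, 5, 5))
#' calibrate_cutpoints(sp, replicates = 500, seed = 1)
#' @export
calibrate_cutpoints <- function(null_spec, tests = TEST_NAMES,
                                replicates = 20000, seed = 1,
                                alpha = 0.05) {
  stopifnot(inherits(null_spec, "scenario_spec"))
  tests <- normalize_tests(tests)
  if (replicates < 100) stop("'replicates' must be at least 100")
  set.seed(as.integer(seed))
  stats <- simulate_statistics(null_spec, replicates, tests)
  idx <- ceiling((1 - alpha) * replicates)
  cuts <- apply(stats, 2L, function(v) sort(v)[idx])
  structure(
    list(cutpoints = cuts, alpha = alpha, replicates = replicates,
         seed = as.integer(seed), sizes = null_spec$sizes),
    class = "cutpoints"
  )
}

#' @export
print.cutpoints <- function(x, ...) {
  cat("Simulated-null cutpoints (alpha =", x$alpha, ",", x$replicates,
      "replicates, seed", x$seed, ")\n")
  print(round(x$cutpoints, 3))
  invisible(x)
}

# Draw `B` datasets from a scenario and return the B x tests statistic
# matrix. Consumes the current RNG stream; generation never depends on
# which tests are requested, so every test sees identical datasets.
simulate_statistics <- function(spec, B, tests) {
  X <- simulate_matrix(spec, B)
  Rm <- apply(X, 2L, rank)
  batch_statistics(Rm, spec$sizes, tests)
}
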