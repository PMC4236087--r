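#' Trend statistics for ordered alternatives
#'
#' Five rank statistics against the monotone (nondecreasing) ordered
#' alternative, all computed from the combined-sample ranks so that a
#' single ranking serves every test on a given dataset:
#'
#' * `jt`: Jonckheere-Terpstra, the sum over group pairs i < j of
#'   Mann-Whitney counts (cross-pairs with the later-group observation
#'   larger; tied cross-pairs count 1/2).
#' * `mjt`: modified Jonckheere-Terpstra, weighting each Mann-Whitney
#'   count by the group distance (j - i).
#' * `tm`: Terpstra-Magel, the number of k-tuplets (one observation per
#'   group) in strictly increasing order.
#' * `cu`: Cuzick, the sum over groups of group index times the group's
#'   pooled rank-sum.
#' * `rd`: the rank-difference trend statistic, accumulating the positive
#'   part of the combined-sample rank difference over every cross-group
#'   pair; it records the magnitude of each concordant comparison, not
#'   just its sign.
#'
#' @param x A [grouped_sample()] or [ranked_sample][assign_ranks()].
#' @param tests Character vector naming the statistics to compute; any of
#'   `"jt"`, `"mjt"`, `"tm"`, `"cu"`, `"rd"` (alias `"new"` for `"rd"`).
#' @return `trend_statistics()` returns a named numeric vector; the
#'   single-statistic wrappers return a length-one numeric.
#' @examples
#' gs <- grouped_sample(list(a = c(1.2, 3.4), b = c(2.2, 4.1)))
#' trend_statistics(gs)
#' rd_statistic(gs)
#' @export
trend_statistics <- function(x, tests = c("jt", "mjt", "tm", "cu", "rd")) {
  tests <- normalize_tests(tests)
  r <- as_ranked(x)
  batch_statistics(rank_matrix(r), r$n, tests)[1L, ]
}

#' @rdname trend_statistics
#' @export
jt_statistic <- function(x) trend_statistics(x, "jt")[["jt"]]

#' @rdname trend_statistics
#' @export
mjt_statistic <- function(x) trend_statistics(x, "mjt")[["mjt"]]

#' @rdname trend_statistics
#' @export
tm_statistic <- function(x) trend_statistics(x, "tm")[["tm"]]

#' @rdname trend_statistics
#' @export
cu_statistic <- function(x) trend_statistics(x, "cu")[["cu"]]

#' @rdname trend_statistics
#' @export
rd_statistic <- function(x) trend_statistics(x, "rd")[["rd"]]

TEST_NAMES <- c("jt", "mjt", "tm", "cu", "rd")

normalize_tests <- function(tests) {
  tests <- tolower(as.character(tests))
  tests[tests == "new"] <- "rd"
  if (length(tests) == 1L && tests == "all") tests <- TEST_NAMES
  bad <- setdiff(tests, TEST_NAMES)
  if (length(bad) > 0L) {
    stop("unknown test(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(TEST_NAMES, collapse = ", "), ")")
  }
  unique(tests)
}

# Batch engine: columns of Rm are pooled rank vectors (rows blocked by
# group, sizes n in hypothesis order); returns a B x length(tests) matrix.
# All five statistics are computed with column-vectorized sweeps so the
# per-dataset cost is a handful of matrix operations, which is what makes
# the 20,000-replicate calibration runs feasible in pure R.
batch_statistics <- function(Rm, n, tests = TEST_NAMES) {
  tests <- normalize_tests(tests)
  k <- length(n)
  B <- ncol(Rm)
  ends <- cumsum(n)
  starts <- ends - n + 1L
  blocks <- lapply(seq_len(k), function(g) {
    Rm[starts[g]:ends[g], , drop = FALSE]
  })
  out <- matrix(NA_real_, nrow = B, ncol = length(tests),
                dimnames = list(NULL, tests))

  if (any(c("jt", "mjt", "rd") %in% tests)) {
    jt <- mjt <- rd <- numeric(B)
    for (i in seq_len(k - 1L)) {
      Ri <- blocks[[i]]
      for (j in (i + 1L):k) {
        Rj <- blocks[[j]]
        conc <- numeric(B)
        pos <- numeric(B)
        for (u in seq_len(n[i])) {
          D <- Rj - rep(Ri[u, ], each = n[j])
          gt <- D > 0
          conc <- conc + colSums(gt) + 0.5 * colSums(D == 0)
          pos <- pos + colSums(D * gt)
        }
        jt <- jt + conc
        mjt <- mjt + (j - i) * conc
        rd <- rd + pos
      }
    }
    if ("jt" %in% tests) out[, "jt"] <- jt
    if ("mjt" %in% tests) out[, "mjt"] <- mjt
    if ("rd" %in% tests) out[, "rd"] <- rd
  }

  if ("cu" %in% tests) {
    w <- rep(seq_len(k), n)
    out[, "cu"] <- colSums(Rm * w)
  }

  if ("tm" %in% tests) {
    # chain-counting dynamic program: f_j(x) = sum of f_{j-1}(y) over
    # y < x in the previous group; strict inequality, so tied tuplets
    # never count
    f <- matrix(1, nrow = n[1L], ncol = B)
    for (j in 2L:k) {
      Rp <- blocks[[j - 1L]]
      Rj <- blocks[[j]]
      fn <- matrix(0, nrow = n[j], ncol = B)
      for (u in seq_len(n[j])) {
        lt <- Rp < rep(Rj[u, ], each = n[j - 1L])
        fn[u, ] <- colSums(f * lt)
      }
      f <- fn
    }
    out[, "tm"] <- colSums(f)
  }

  out
}
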