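# Independent brute-force oracles. Everything here is written with plain
# loops over raw ranks/values, deliberately sharing no code with the
# package's vectorized batch engine.

o_pair_stats <- function(ranks) {
  k <- length(ranks)
  jt <- mjt <- rd <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (a in ranks[[i]]) {
        for (b in ranks[[j]]) {
          if (b > a) {
            jt <- jt + 1
            mjt <- mjt + (j - i)
            rd <- rd + (b - a)
          } else if (b == a) {
            jt <- jt + 0.5
            mjt <- mjt + 0.5 * (j - i)
          }
        }
      }
    }
  }
  list(jt = jt, mjt = mjt, rd = rd)
}

o_cu <- function(ranks) {
  s <- 0
  for (l in seq_along(ranks)) s <- s + l * sum(ranks[[l]])
  s
}

# strict-increase tuplet count by full enumeration of one observation
# per group
o_tm <- function(values) {
  grid <- do.call(expand.grid, values)
  m <- as.matrix(grid)
  inc <- rep(TRUE, nrow(m))
  for (j in 2:ncol(m)) inc <- inc & (m[, j] > m[, j - 1])
  sum(inc)
}

o_abs_rank_diff <- function(ranks) {
  k <- length(ranks)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (a in ranks[[i]]) for (b in ranks[[j]]) s <- s + abs(b - a)
    }
  }
  s
}

# all distinct assignments of the ranks 1..N to groups, as a list of
# per-group rank-set lists (independent recursion from the package's
# column-matrix enumerator)
o_assignments <- function(sizes) {
  rec <- function(avail, sz) {
    if (length(sz) == 0L) return(list(list()))
    out <- list()
    # combn over positions, not values: combn(x, m) with scalar x would
    # expand to seq_len(x)
    for (idx in utils::combn(seq_along(avail), sz[1L], simplify = FALSE)) {
      for (rest in rec(avail[-idx], sz[-1L])) {
        out[[length(out) + 1L]] <- c(list(avail[idx]), rest)
      }
    }
    out
  }
  rec(seq_len(sum(sizes)), sizes)
}

o_null_moments <- function(sizes, stat_fn) {
  vals <- vapply(o_assignments(sizes), stat_fn, numeric(1))
  c(mean = mean(vals), variance = mean(vals^2) - mean(vals)^2)
}

# all compositions of N into k ordered positive parts
o_compositions <- function(N, k) {
  if (k == 1L) return(list(N))
  out <- list()
  for (first in seq_len(N - k + 1L)) {
    for (rest in o_compositions(N - first, k - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

random_grouped_sample <- function(kmin = 2, kmax = 4, nmax = 6) {
  k <- sample(seq(kmin, kmax), 1L)
  if (kmin == kmax) k <- kmin
  n <- sample(seq_len(nmax), k, replace = TRUE)
  n[n < 1] <- 1
  grouped_sample(split(stats::rnorm(sum(n)), rep(seq_len(k), n)))
}
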