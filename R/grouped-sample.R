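#' Grouped sample for ordered-alternative testing
#'
#' Bundle k independent samples together with the hypothesized ordering of
#' their groups. The group order is scientific input: it defines the
#' direction of the monotone alternative and is never inferred by sorting
#' labels.
#'
#' @param values Numeric vector of observations, or a list of per-group
#'   numeric vectors (in which case `groups` is taken from the list names,
#'   or generated as `g1..gk`).
#' @param groups Vector of group labels, one per observation (ignored when
#'   `values` is a list).
#' @param group_order Character vector giving the hypothesized ordering of
#'   the group labels (smallest location first). Defaults to the order of
#'   first appearance.
#'
#' @return An object of class `grouped_sample`: a list with components
#'   `values` (named list of per-group numeric vectors, in hypothesis
#'   order), `groups` (ordered labels), `n` (group sizes), and `N`.
#' @examples
#' gs <- grouped_sample(list(low = c(1.2, 3.4), high = c(2.2, 4.1)))
#' assign_ranks(gs)
#' @export
grouped_sample <- function(values, groups = NULL, group_order = NULL) {
  if (is.list(values)) {
    labs <- names(values)
    if (is.null(labs) || any(labs == "")) {
      labs <- paste0("g", seq_along(values))
    }
    groups <- rep(labs, lengths(values))
    values <- unlist(values, use.names = FALSE)
    if (is.null(group_order)) group_order <- labs
  }
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (is.null(groups) || length(groups) != length(values)) {
    stop("'groups' must have one label per observation")
  }
  groups <- as.character(groups)
  if (is.null(group_order)) group_order <- unique(groups)
  group_order <- as.character(group_order)
  if (anyDuplicated(group_order)) stop("duplicated labels in 'group_order'")
  if (length(group_order) < 2L) stop("at least two groups are required")
  unknown <- setdiff(unique(groups), group_order)
  if (length(unknown) > 0L) {
    stop("group label(s) not in declared order: ",
         paste(unknown, collapse = ", "))
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("all values must be finite")
  }
  split_vals <- split(values, factor(groups, levels = group_order))
  n <- vapply(split_vals, length, integer(1))
  if (any(n < 1L)) {
    stop("empty group(s): ", paste(group_order[n < 1L], collapse = ", "))
  }
  structure(
    list(values = split_vals, groups = group_order,
         n = unname(n), N = sum(n)),
    class = "grouped_sample"
  )
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat("Grouped sample: k =", length(x$n), "groups, N =", x$N, "\n")
  cat("Hypothesized order:", paste(x$groups, collapse = " < "), "\n")
  cat("Group sizes:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

# Reverse the hypothesized ordering (used for side = "decreasing").
reverse_groups <- function(x) {
  stopifnot(inherits(x, "grouped_sample"))
  k <- length(x$n)
  grouped_sample(x$values[k:1], group_order = x$groups[k:1])
}

#' Assign combined-sample ranks
#'
#' Rank all observations in the pooled sample of size N, keeping the group
#' structure. Ties receive midranks and set `tie_flag`; the sum of all
#' ranks is always N(N+1)/2.
#'
#' @param x A [grouped_sample()].
#' @return An object of class `ranked_sample` with components `ranks`
#'   (named list of per-group rank vectors), `groups`, `n`, `N`, and
#'   `tie_flag`.
#' @export
assign_ranks <- function(x) {
  stopifnot(inherits(x, "grouped_sample"))
  pooled <- unlist(x$values, use.names = FALSE)
  r <- rank(pooled)
  ranks <- split(r, rep(seq_along(x$n), x$n))
  names(ranks) <- x$groups
  structure(
    list(ranks = ranks, groups = x$groups, n = x$n, N = x$N,
         tie_flag = anyDuplicated(pooled) > 0L),
    class = "ranked_sample"
  )
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat("Ranked sample: k =", length(x$n), "groups, N =", x$N,
      if (x$tie_flag) "(midranks used)" else "(no ties)", "\n")
  for (g in x$groups) {
    cat("  ", g, ": ", paste(x$ranks[[g]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

as_ranked <- function(x) {
  if (inherits(x, "ranked_sample")) return(x)
  if (inherits(x, "grouped_sample")) return(assign_ranks(x))
  stop("expected a grouped_sample or ranked_sample")
}

# N x 1 matrix of pooled ranks, rows blocked by group in hypothesis order.
rank_matrix <- function(r) {
  matrix(unlist(r$ranks, use.names = FALSE), ncol = 1L)
}
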