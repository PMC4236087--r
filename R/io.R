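#' Read a long-format CSV into a grouped sample
#'
#' Expects a header row with a group-label column and a numeric value
#' column (names configurable). The hypothesized group ordering is
#' supplied by the caller, never inferred by sorting labels.
#'
#' @param path CSV file path.
#' @param group_order Character vector of group labels in hypothesized
#'   order; defaults to order of first appearance in the file.
#' @param group_col,value_col Column names (defaults `"group"`,
#'   `"value"`).
#' @return A [grouped_sample()].
#' @export
read_long_csv <- function(path, group_order = NULL,
                          group_col = "group", value_col = "value") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  miss <- setdiff(c(group_col, value_col), names(df))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  vals <- df[[value_col]]
  if (!is.numeric(vals)) {
    suppressWarnings(vals <- as.numeric(vals))
  }
  if (anyNA(vals) || !all(is.finite(vals))) {
    bad <- which(is.na(vals) | !is.finite(vals))
    stop("non-numeric or non-finite value(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  grouped_sample(vals, as.character(df[[group_col]]),
                 group_order = group_order)
}

#' Write and read power tables
#'
#' Lossless CSV round-trip for [power_study()] results; rates are
#' written with 17 significant digits so a written table reads back
#' identically.
#'
#' @param x A `power_table` data frame.
#' @param path Output CSV path.
#' @return `write_power_table()` returns `path` invisibly;
#'   `read_power_table()` returns a `power_table` data frame.
#' @export
write_power_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x
  out$rate <- sprintf("%.17g", out$rate)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(scenario = "character",
                                       sizes = "character",
                                       test = "character"))
  df$rate <- as.numeric(df$rate)
  class(df) <- c("power_table", "data.frame")
  df
}

# Small library-independent FNV-1a hash of a string, used to fingerprint
# configurations in run logs.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
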