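#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same observations.
#' Equals 1 for identical partitions (up to label permutation) and has
#' expectation 0 under random labeling.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 7919) %% 2147483647
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
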