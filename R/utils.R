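# Shared internals: activity binning, seed handling, numeric guards.

# Bin edges for the 5%-activity histogram: [0,5), [5,10), ..., [90,95), [95,100].
N_BINS <- 20L
BIN_WIDTH <- 5

bin_labels <- function() {
  lo <- seq(0, 95, by = BIN_WIDTH)
  sprintf("[%d,%d%s", lo, lo + BIN_WIDTH, c(rep(")", N_BINS - 1L), "]"))
}

# Map activity values in [0,100] to bin indices 1..20; 100 falls in the final
# closed bin.
activity_bin_index <- function(x) {
  pmin.int(floor(x / BIN_WIDTH) + 1L, N_BINS)
}

#' Bin activity values into the standard 20-bin probability vector
#'
#' Activity profiles and penalty distributions are compared on a common
#' support of twenty 5%-activity bins: `[0,5), [5,10), ..., [90,95), [95,100]`
#' (the last bin is closed so that 100% activity is representable).
#'
#' @param samples Numeric vector of activity values, all in `[0, 100]`.
#' @return Named numeric vector of 20 bin probabilities summing to 1.
#' @examples
#' bin_distribution(c(2.4, 97.6))
#' @export
bin_distribution <- function(samples) {
  if (length(samples) == 0L) {
    stop("cannot bin an empty sample set", call. = FALSE)
  }
  if (anyNA(samples) || any(samples < 0 | samples > 100)) {
    stop("activity samples must lie in [0, 100]", call. = FALSE)
  }
  counts <- tabulate(activity_bin_index(samples), nbins = N_BINS)
  setNames(counts / sum(counts), bin_labels())
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed leaves the global stream untouched.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results stable regardless of how many random draws intermediate
# steps consume. The result stays inside the positive 32-bit integer range.
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
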