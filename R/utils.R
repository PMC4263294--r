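# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probe midpoint
#'
#' A probe (a 60-mer in the assays this package targets) is represented
#' downstream by a single point, the integer midpoint of its interval.
#' All membership tests (bins, windows, genic spans) use this point.
#'
#' @param start,end 0-based half-open interval bounds.
#' @return Integer-valued numeric midpoint, `floor((start + end) / 2)`.
#' @export
probe_mid <- function(start, end) floor((start + end) / 2)

# Error constructors. "data" errors map to CLI exit 1, "usage" errors to 2.
oxo_data_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oxomap_data_error", "oxomap_error")))
}

oxo_usage_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oxomap_usage_error", "oxomap_error")))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    oxo_data_error("%s: missing required column(s): %s", what,
                   paste(missing, collapse = ", "))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Used so seeded operations do not
# perturb the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed for component k of a master seed; stays < 2^31.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647
  as.integer(s) + 1L
}

# Sorted-by-(chrom, start) check used by several consumers.
is_sorted_track <- function(df) {
  if (nrow(df) < 2L) return(TRUE)
  o <- order(df$chrom, df$start, method = "radix")
  all(o == seq_len(nrow(df)))
}

sort_track <- function(df) {
  df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
}

#' Toy genome assembly
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return A `data.frame` with columns `chrom`, `length`.
#' @export
genome_assembly <- function(chrom, length) {
  if (anyDuplicated(chrom)) oxo_data_error("assembly: duplicated chromosome names")
  if (any(!is.finite(length)) || any(length <= 0))
    oxo_data_error("assembly: chromosome lengths must be finite and > 0")
  data.frame(chrom = as.character(chrom), length = as.numeric(length),
             stringsAsFactors = FALSE)
}
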