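# Genic damage averaging and expression-group comparisons.
#
# Per gene, the damage level is the mean probe log-ratio over the
# transcribed span (transcription start to end site). Genes are then split
# by expression (at the median, or top vs bottom quantile) and the two
# groups compared with a two-sided pooled-variance Student's t-test.

#' Mean probe signal over each gene's transcribed span
#'
#' Probes belong to a gene when their midpoint lies in
#' `[tx_start, tx_end)`; overlapping genes each average their own probes
#' (probe reuse allowed). Genes covering no probe get `NA` and are excluded
#' from downstream group statistics.
#'
#' @param genes Gene data.frame.
#' @param probes Sorted probe data.frame.
#' @return `genes` with an added `genic_signal` column.
#' @export
genic_signal <- function(genes, probes) {
  stopifnot_cols(genes, c("chrom", "tx_start", "tx_end"), "genic_signal")
  stopifnot_cols(probes, c("chrom", "start", "end", "value"), "genic_signal")
  if (!is_sorted_track(probes))
    oxo_data_error("genic_signal: probes must be sorted by (chrom, start)")
  genes$genic_signal <- NA_real_
  for (ch in unique(genes$chrom)) {
    p <- which(probes$chrom == ch)
    g <- which(genes$chrom == ch)
    if (length(p) == 0L) next
    mid <- probe_mid(probes$start[p], probes$end[p])
    o <- order(mid)
    mid <- mid[o]
    cs <- c(0, cumsum(probes$value[p][o]))
    hi <- findInterval(genes$tx_end[g] - 0.5, mid)   # mid <= tx_end - 1
    lo <- findInterval(genes$tx_start[g] - 0.5, mid) + 1L  # mid >= tx_start
    n <- hi - lo + 1L
    has <- n >= 1L
    genes$genic_signal[g[has]] <-
      (cs[hi[has] + 1L] - cs[lo[has]]) / n[has]
  }
  genes
}

#' Split genes into expression groups
#'
#' `"median"` mode: genes with expression strictly above the median go to
#' the high group, the rest (ties included) to the low group, giving a full
#' partition. `"top_bottom"` mode: the top and bottom `q` fraction of genes
#' by expression rank (the middle discarded); `q` of 0.25 and 0.10 are the
#' preconfigured analyses.
#'
#' @param genes Genes carrying `expression` and `genic_signal`; rows with
#'   either missing are dropped first.
#' @param mode `"median"` or `"top_bottom"`.
#' @param q Tail fraction for `"top_bottom"` (default 0.25).
#' @return List with `high`, `low` (data.frames), `mode`, `n_usable`, and
#'   `threshold` (the median, for median mode).
#' @export
split_by_expression <- function(genes, mode = c("median", "top_bottom"),
                                q = 0.25) {
  mode <- match.arg(mode)
  stopifnot_cols(genes, c("expression", "genic_signal"), "split_by_expression")
  use <- genes[is.finite(genes$expression) & is.finite(genes$genic_signal), ,
               drop = FALSE]
  if (nrow(use) < 4L)
    oxo_data_error("split_by_expression: need >= 4 genes with expression and genic signal, got %d",
                   nrow(use))
  if (mode == "median") {
    med <- stats::median(use$expression)
    high <- use[use$expression > med, , drop = FALSE]
    low <- use[use$expression <= med, , drop = FALSE]
    threshold <- med
  } else {
    if (!is.numeric(q) || q <= 0 || q > 0.5)
      oxo_data_error("split_by_expression: q must be in (0, 0.5]")
    k <- floor(q * nrow(use))
    if (k < 1L)
      oxo_data_error("split_by_expression: tail fraction q=%g selects no genes (n=%d)",
                     q, nrow(use))
    o <- order(use$expression, use$gene_id %||% seq_len(nrow(use)))
    low <- use[o[seq_len(k)], , drop = FALSE]
    high <- use[o[seq(nrow(use) - k + 1L, nrow(use))], , drop = FALSE]
    threshold <- NA_real_
  }
  if (nrow(high) == 0L || nrow(low) == 0L)
    oxo_data_error("split_by_expression: empty expression group")
  list(high = high, low = low, mode = mode, q = if (mode == "median") NA else q,
       n_usable = nrow(use), threshold = threshold)
}

#' Two-group comparison (Student's t-test)
#'
#' Two-sided pooled-variance Student's t-test by default (the classical
#' test; `var_equal = FALSE` gives Welch's variant).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled variance (default `TRUE`).
#' @return Object of class `group_comparison`: list with `group_a_n`,
#'   `group_b_n`, `mean_a`, `mean_b`, `t_stat`, `df`, `p_value`, `method`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    oxo_data_error("compare_groups: each group needs >= 2 finite values")
  if (stats::var(c(values_a - mean(values_a), values_b - mean(values_b))) == 0)
    oxo_data_error("compare_groups: zero pooled variance (constant data)")
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  structure(list(group_a_n = length(values_a), group_b_n = length(values_b),
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (var_equal) "student" else "welch"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.3f, df = %.1f, p = %.3g\n",
              x$method, x$t_stat, x$df, x$p_value))
  cat(sprintf("  group A: n = %d, mean = %.4f\n", x$group_a_n, x$mean_a))
  cat(sprintf("  group B: n = %d, mean = %.4f\n", x$group_b_n, x$mean_b))
  invisible(x)
}

#' Shared-breaks histogram of two value sets
#'
#' Export helper for the paired group histograms (expression groups,
#' lamina groups): one set of bin edges spanning both groups, counts per
#' group.
#'
#' @param values_a,values_b Numeric vectors.
#' @param breaks Number of bins (default 30).
#' @return `data.frame(bin_start, bin_end, n_a, n_b)`.
#' @export
two_group_histogram <- function(values_a, values_b, breaks = 30L) {
  all <- c(values_a, values_b)
  all <- all[is.finite(all)]
  if (length(all) == 0L) oxo_data_error("two_group_histogram: no finite values")
  rng <- range(all)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = breaks + 1L)
  h <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(rep(0L, breaks))
    tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = breaks)
  }
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
             n_a = h(values_a), n_b = h(values_b))
}
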