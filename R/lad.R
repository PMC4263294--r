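# Lamina-associated domain (LAD) association statistics.
#
# The genome is tiled into fragments (default 200 kb, a scale below the
# 100 kb - 10 Mb span of LADs); per fragment we average the damage signal
# (probe midpoints) and the lamin B1 DamID value (base-pair weighted over
# covered bases). Fragments split at a lamin cutoff (default 0, the trough
# of the bimodal lamin distribution) give two groups whose mean difference
# is tested both by Student's t and by a permutation null built by randomly
# reassigning lamin values across fragments.

#' Per-fragment damage and lamin profiles
#'
#' @param assembly [genome_assembly()] data.frame.
#' @param probes Sorted probe data.frame.
#' @param lamin Non-overlapping valued intervals
#'   (`chrom,start,end,value`), e.g. a lifted-over DamID profile.
#' @param fragment_size Fragment size in bp (default 200000; 50000 and
#'   500000 are the usual robustness settings).
#' @param min_probes Minimum probes for a defined fragment mean (default 1).
#' @return Fragments (`make_bins` tiling) with `n_probes`, `mean_signal`,
#'   `lamin` (covered-base weighted mean, `NA` when no lamin coverage) and
#'   `lamin_coverage` (covered bp). Attribute `n_excluded` counts fragments
#'   missing either quantity.
#' @export
fragment_profiles <- function(assembly, probes, lamin,
                              fragment_size = 200000, min_probes = 1L) {
  stopifnot_cols(lamin, c("chrom", "start", "end", "value"),
                 "fragment_profiles")
  check_no_overlap(sort_track(lamin), "fragment_profiles lamin")
  bins <- make_bins(assembly, fragment_size)
  bins <- mean_signal_per_bin(bins, probes, min_probes = min_probes)
  wsum <- rep(0, nrow(bins))
  wlen <- rep(0, nrow(bins))
  for (ch in unique(lamin$chrom)) {
    b <- which(bins$chrom == ch)
    if (length(b) == 0L) next
    li <- which(lamin$chrom == ch)
    for (i in li) {
      s <- lamin$start[i]; e <- lamin$end[i]; v <- lamin$value[i]
      j1 <- findInterval(s, bins$start[b])
      j2 <- findInterval(e - 1, bins$start[b])
      j1 <- max(j1, 1L)
      for (j in j1:j2) {
        if (j > length(b)) break
        ov <- min(e, bins$end[b[j]]) - max(s, bins$start[b[j]])
        if (ov > 0) {
          wsum[b[j]] <- wsum[b[j]] + v * ov
          wlen[b[j]] <- wlen[b[j]] + ov
        }
      }
    }
  }
  bins$lamin <- ifelse(wlen > 0, wsum / pmax(wlen, 1), NA_real_)
  bins$lamin_coverage <- wlen
  attr(bins, "n_excluded") <- sum(is.na(bins$mean_signal) | is.na(bins$lamin))
  bins
}

complete_fragments <- function(fragments) {
  stopifnot_cols(fragments, c("mean_signal", "lamin"), "lad fragments")
  fragments[is.finite(fragments$mean_signal) & is.finite(fragments$lamin), ,
            drop = FALSE]
}

#' Split fragments at a lamin cutoff
#'
#' Fragments with lamin value strictly above `cutoff` form the positive
#' (lamina-proximal) group; values at or below `cutoff` the negative group
#' (deterministic tie rule). Fragments missing either quantity are dropped
#' first.
#'
#' @param fragments Output of [fragment_profiles()].
#' @param cutoff Lamin cutoff (default 0).
#' @return List with `positive`, `negative` data.frames.
#' @export
split_by_cutoff <- function(fragments, cutoff = 0) {
  use <- complete_fragments(fragments)
  pos <- use[use$lamin > cutoff, , drop = FALSE]
  neg <- use[use$lamin <= cutoff, , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    oxo_data_error("split_by_cutoff: empty group at cutoff %g (%d positive, %d negative)",
                   cutoff, nrow(pos), nrow(neg))
  list(positive = pos, negative = neg)
}

#' Group means and t-test for a lamin split
#'
#' @param positive,negative Fragment data.frames from [split_by_cutoff()].
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return List with `mean_positive`, `mean_negative`, `diff`
#'   (positive - negative) and `comparison` (a [compare_groups()] result).
#' @export
group_stats <- function(positive, negative, var_equal = TRUE) {
  a <- positive$mean_signal
  b <- negative$mean_signal
  cmp <- compare_groups(a, b, var_equal = var_equal)
  list(mean_positive = mean(a), mean_negative = mean(b),
       diff = mean(a) - mean(b), comparison = cmp)
}

#' Permutation z-score test for the lamin-group difference
#'
#' The observed statistic is the difference of mean damage signal between
#' lamin-positive and lamin-negative fragments. The null is built by
#' randomly reassigning the lamin values across fragments (the damage
#' signal stays put), recomputing the group difference under the same
#' cutoff each iteration. Because the multiset of lamin values is fixed,
#' the group sizes are identical in every iteration, so each draw reduces
#' to sampling which fragments are labelled positive. Reported:
#' `z = (observed - null_mean) / null_sd` and the add-one empirical p-value
#' `(1 + #{|null| >= |observed|}) / (n_iter + 1)` (never exactly 0).
#'
#' @param fragments Output of [fragment_profiles()].
#' @param cutoff Lamin cutoff (default 0).
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @param studentized Use the pooled-t statistic instead of the raw mean
#'   difference (default `FALSE`, the raw difference).
#' @return Object of class `permutation_result`: list with
#'   `observed_diff`, `null_mean`, `null_sd`, `z_score`, `empirical_p`,
#'   `n_iter`, `seed`, `n_positive`, `n_negative`, `statistic`.
#' @export
permutation_test <- function(fragments, cutoff = 0, n_iter = 1000L,
                             seed = NULL, studentized = FALSE) {
  if (n_iter < 1L) oxo_data_error("permutation_test: n_iter must be >= 1")
  use <- complete_fragments(fragments)
  if (nrow(use) < 10L)
    oxo_data_error("permutation_test: need >= 10 fragments with both values, got %d",
                   nrow(use))
  sig <- use$mean_signal
  pos <- use$lamin > cutoff
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    oxo_data_error("permutation_test: empty group at cutoff %g", cutoff)
  stat <- if (studentized) {
    function(a, b) compare_groups(a, b)$t_stat
  } else {
    function(a, b) mean(a) - mean(b)
  }
  observed <- stat(sig[pos], sig[!pos])
  n <- length(sig)
  draw <- function() {
    idx <- sample.int(n, n_pos)
    stat(sig[idx], sig[-idx])
  }
  null <- if (is.null(seed)) {
    vapply(seq_len(n_iter), function(i) draw(), numeric(1L))
  } else {
    with_seed(seed, vapply(seq_len(n_iter), function(i) draw(), numeric(1L)))
  }
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  if (!is.finite(null_sd) || null_sd == 0)
    oxo_data_error("permutation_test: degenerate null (null_sd = 0; constant signal?)")
  structure(list(observed_diff = observed, null_mean = null_mean,
                 null_sd = null_sd,
                 z_score = (observed - null_mean) / null_sd,
                 empirical_p = (1 + sum(abs(null) >= abs(observed))) /
                   (n_iter + 1),
                 n_iter = as.integer(n_iter), seed = seed,
                 n_positive = n_pos, n_negative = n_neg,
                 statistic = if (studentized) "t" else "mean_diff"),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s statistic, %d iterations%s)\n",
              x$statistic, x$n_iter,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  groups: %d positive / %d negative fragments\n",
              x$n_positive, x$n_negative))
  cat(sprintf("  observed difference = %.4f\n", x$observed_diff))
  cat(sprintf("  null mean = %.4f, null sd = %.4f\n", x$null_mean, x$null_sd))
  cat(sprintf("  z-score = %.2f, empirical p = %.3g\n", x$z_score,
              x$empirical_p))
  invisible(x)
}

#' 2-D fragment count grid (lamin x signal)
#'
#' Counts fragments over a regular grid spanning the observed ranges; the
#' underlying table of a contour plot of damage level against lamin level.
#'
#' @param fragments Output of [fragment_profiles()].
#' @param x_bins,y_bins Number of grid cells for lamin (x) and signal (y).
#' @return Integer matrix `x_bins` rows (lamin) by `y_bins` columns
#'   (signal) with attributes `x_breaks`, `y_breaks`; counts sum to the
#'   number of usable fragments.
#' @export
density_grid <- function(fragments, x_bins = 20L, y_bins = 20L) {
  use <- complete_fragments(fragments)
  if (nrow(use) < 1L) oxo_data_error("density_grid: no usable fragments")
  edges <- function(v, k) {
    r <- range(v)
    if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)
    seq(r[1L], r[2L], length.out = k + 1L)
  }
  xe <- edges(use$lamin, x_bins)
  ye <- edges(use$mean_signal, y_bins)
  xi <- findInterval(use$lamin, xe, rightmost.closed = TRUE)
  yi <- findInterval(use$mean_signal, ye, rightmost.closed = TRUE)
  m <- matrix(0L, nrow = x_bins, ncol = y_bins)
  for (i in seq_along(xi)) m[xi[i], yi[i]] <- m[xi[i], yi[i]] + 1L
  attr(m, "x_breaks") <- xe
  attr(m, "y_breaks") <- ye
  m
}
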