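# Sliding-window smoothing of per-probe signals.
#
# Chromosome-scale damage profiles are drawn by replacing each probe's
# log-ratio with the plain mean over all probes within `halfwidth` bases in
# both directions (default 500 kb, i.e. a 1 Mb total span). Windows never
# cross chromosome boundaries and always contain the probe itself. All
# distances are between probe midpoints.

#' Per-probe sliding-window smoothing
#'
#' For each probe i the smoothed value is the mean of the values of all
#' probes j on the same chromosome with |mid_j - mid_i| <= `halfwidth`
#' (window boundary inclusive, window includes the probe itself).
#'
#' @param probes Probe data.frame (`chrom,start,end,value`) sorted by
#'   (chrom, start); unsorted input is an error.
#' @param halfwidth Window half-width in bp (default 500000, a 1 Mb span).
#' @return `probes` with an added `smoothed` column, same row order.
#' @export
smooth_per_probe <- function(probes, halfwidth = 500000) {
  stopifnot_cols(probes, c("chrom", "start", "end", "value"),
                 "smooth_per_probe")
  if (!is.finite(halfwidth) || halfwidth <= 0)
    oxo_data_error("smooth_per_probe: halfwidth must be > 0")
  if (!is_sorted_track(probes))
    oxo_data_error("smooth_per_probe: probes must be sorted by (chrom, start)")
  probes$smoothed <- NA_real_
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    mid <- probe_mid(probes$start[sel], probes$end[sel])
    o <- order(mid)  # midpoints can disorder under variable probe lengths
    m <- mid[o]
    v <- probes$value[sel][o]
    cs <- c(0, cumsum(v))
    # inclusive window [m - halfwidth, m + halfwidth]; midpoints are integers
    hi <- findInterval(m + halfwidth, m)
    lo <- findInterval(m - halfwidth - 0.5, m) + 1L
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    probes$smoothed[sel[o]] <- sm
  }
  probes
}

#' Fixed-step window track
#'
#' Averages probe values over windows of `window` bp placed every `step` bp
#' from position 0 on each chromosome (probe membership by midpoint,
#' half-open `[start, start + window)`). Windows holding fewer than
#' `min_probes` probes emit no record. With `step == window` (default) the
#' output is a valid non-overlapping bedGraph track.
#'
#' @param probes Sorted probe data.frame.
#' @param window Window size in bp (default 1e6).
#' @param step Step between window starts (default `window`); must be
#'   <= `window`.
#' @param min_probes Minimum probes for a window to be reported.
#' @param assembly Optional [genome_assembly()]; if given, windows tile the
#'   full chromosome lengths (ends clipped), otherwise they stop at the last
#'   probe.
#' @return `data.frame(chrom, start, end, value, n_probes)`.
#' @export
window_track <- function(probes, window = 1e6, step = window,
                         min_probes = 1L, assembly = NULL) {
  stopifnot_cols(probes, c("chrom", "start", "end", "value"), "window_track")
  if (step > window) oxo_data_error("window_track: step must be <= window")
  if (!is_sorted_track(probes))
    oxo_data_error("window_track: probes must be sorted by (chrom, start)")
  out <- list()
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    mid <- sort(probe_mid(probes$start[sel], probes$end[sel]))
    v <- probes$value[sel][order(probe_mid(probes$start[sel],
                                           probes$end[sel]))]
    cs <- c(0, cumsum(v))
    chrom_len <- if (!is.null(assembly)) {
      i <- match(ch, assembly$chrom)
      if (is.na(i)) next
      assembly$length[i]
    } else max(mid) + 1
    starts <- seq(0, max(0, chrom_len - 1), by = step)
    ends <- pmin(starts + window, chrom_len)
    hi <- findInterval(starts + window - 0.5, mid)
    lo <- findInterval(starts - 0.5, mid) + 1L
    n <- hi - lo + 1L
    keep <- n >= min_probes
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch, start = starts[keep], end = ends[keep],
      value = (cs[hi[keep] + 1L] - cs[lo[keep]]) / n[keep],
      n_probes = n[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
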