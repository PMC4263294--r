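# Non-overlapping genomic binning, gene counting and the gene-density
# association summary.
#
# Chromosomes are tiled with fixed-size fragments (1 Mb for the gene-density
# analysis, 200 kb for the lamina analysis); per fragment we record the
# mean probe log-ratio, the number of probes, and the number of genes, and
# summarize how damage levels vary with gene density (Pearson correlation
# plus per-gene-count medians/quartiles for a box-plot export).

#' Tile an assembly with non-overlapping bins
#'
#' @param assembly [genome_assembly()] data.frame.
#' @param bin_size Bin size in bp (> 0).
#' @return `data.frame(chrom, start, end, partial)`; the final bin of each
#'   chromosome is kept even when shorter than `bin_size` and flagged
#'   `partial`.
#' @export
make_bins <- function(assembly, bin_size) {
  if (!is.finite(bin_size) || bin_size <= 0)
    oxo_data_error("make_bins: bin_size must be > 0")
  out <- lapply(seq_len(nrow(assembly)), function(i) {
    L <- assembly$length[i]
    starts <- seq(0, L - 1, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    data.frame(chrom = assembly$chrom[i], start = starts, end = ends,
               partial = (ends - starts) < bin_size, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Assign positions to bins within one chromosome's sorted tiling; returns
# the bin row index or NA.
assign_to_bins <- function(bins, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    b <- which(bins$chrom == ch)
    if (length(b) == 0L) next
    p <- which(chrom == ch)
    j <- findInterval(pos[p], bins$start[b])
    ok <- j >= 1L & pos[p] < bins$end[b][pmax(j, 1L)]
    idx[p[ok]] <- b[j[ok]]
  }
  idx
}

#' Mean probe signal per bin
#'
#' Each probe is assigned to exactly one bin by its midpoint; the bin mean
#' is the plain mean of assigned probe values. Bins with fewer than
#' `min_probes` probes get `NA` (missing, excluded downstream).
#'
#' @param bins Output of [make_bins()].
#' @param probes Sorted probe data.frame.
#' @param min_probes Minimum probe count for a defined mean (default 1).
#' @return `bins` with added `n_probes`, `mean_signal`.
#' @export
mean_signal_per_bin <- function(bins, probes, min_probes = 1L) {
  stopifnot_cols(probes, c("chrom", "start", "end", "value"),
                 "mean_signal_per_bin")
  mid <- probe_mid(probes$start, probes$end)
  idx <- assign_to_bins(bins, probes$chrom, mid)
  n <- tabulate(idx, nbins = nrow(bins))
  sums <- rep(0, nrow(bins))
  ok <- !is.na(idx)
  if (any(ok)) {
    agg <- rowsum(probes$value[ok], group = idx[ok])
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  bins$n_probes <- n
  bins$mean_signal <- ifelse(n >= min_probes, sums / pmax(n, 1L), NA_real_)
  bins
}

#' Count genes per bin
#'
#' The default `"tss"` rule counts each gene once, in the unique bin holding
#' its strand-aware 5' start (`tx_start` for `+`, `tx_end - 1` for `-`).
#' The `"overlap"` rule counts a gene in every bin its span intersects.
#' Genes on chromosomes absent from the binned assembly are skipped with a
#' warning.
#'
#' @param bins Output of [make_bins()].
#' @param genes Gene data.frame from [read_genes_bed()].
#' @param rule `"tss"` (default) or `"overlap"`.
#' @return `bins` with an added `gene_count` column.
#' @export
count_genes_per_bin <- function(bins, genes, rule = c("tss", "overlap")) {
  rule <- match.arg(rule)
  stopifnot_cols(genes, c("chrom", "strand", "tx_start", "tx_end"),
                 "count_genes_per_bin")
  known <- genes$chrom %in% unique(bins$chrom)
  if (any(!known))
    warning(sprintf("count_genes_per_bin: %d gene(s) on chromosomes absent from the assembly skipped",
                    sum(!known)))
  genes <- genes[known, , drop = FALSE]
  counts <- rep(0L, nrow(bins))
  if (nrow(genes) > 0L) {
    if (rule == "tss") {
      pos5 <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
      idx <- assign_to_bins(bins, genes$chrom, pos5)
      counts <- tabulate(idx[!is.na(idx)], nbins = nrow(bins))
    } else {
      i1 <- assign_to_bins(bins, genes$chrom, genes$tx_start)
      i2 <- assign_to_bins(bins, genes$chrom, genes$tx_end - 1)
      # spans are contiguous within a chromosome's tiling
      idx <- unlist(lapply(seq_len(nrow(genes)), function(g) {
        if (is.na(i1[g]) && is.na(i2[g])) return(integer())
        seq(if (is.na(i1[g])) i2[g] else i1[g],
            if (is.na(i2[g])) i1[g] else i2[g])
      }))
      counts <- tabulate(idx, nbins = nrow(bins))
    }
  }
  bins$gene_count <- counts
  bins
}

#' Gene-density association summary
#'
#' Relates per-bin gene counts to per-bin mean damage signal: the Pearson
#' correlation over all bins with a defined mean (uncapped counts), plus a
#' per-gene-count group summary (n, median, quartiles) for box-plot export,
#' with counts >= `cap` pooled into one group.
#'
#' @param bins Bins carrying `mean_signal` and `gene_count`.
#' @param cap Pooling cap for the group summary (default 10); the
#'   correlation always uses uncapped counts.
#' @return An object of class `density_association`: list with `groups`
#'   (data.frame `gene_count,label,n_bins,median,q1,q3`), `pearson_r`,
#'   `r_pvalue`, `n_bins_used`, `degenerate`.
#' @export
density_association <- function(bins, cap = 10L) {
  stopifnot_cols(bins, c("mean_signal", "gene_count"), "density_association")
  use <- bins[!is.na(bins$mean_signal), , drop = FALSE]
  if (nrow(use) < 3L)
    oxo_data_error("density_association: need >= 3 bins with defined mean signal")
  degenerate <- stats::sd(use$gene_count) == 0 || stats::sd(use$mean_signal) == 0
  if (degenerate) {
    pearson_r <- NA_real_
    r_pvalue <- NA_real_
  } else {
    ct <- stats::cor.test(use$gene_count, use$mean_signal, method = "pearson")
    pearson_r <- unname(ct$estimate)
    r_pvalue <- ct$p.value
  }
  gc_cap <- pmin(use$gene_count, cap)
  groups <- do.call(rbind, lapply(sort(unique(gc_cap)), function(g) {
    v <- use$mean_signal[gc_cap == g]
    data.frame(gene_count = g,
               label = if (g == cap) sprintf(">=%d", cap) else as.character(g),
               n_bins = length(v),
               median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, pearson_r = pearson_r, r_pvalue = r_pvalue,
                 n_bins_used = nrow(use), cap = cap, degenerate = degenerate),
            class = "density_association")
}

#' @export
print.density_association <- function(x, ...) {
  cat(sprintf("Gene-density association over %d bins\n", x$n_bins_used))
  if (x$degenerate) cat("  Pearson r: undefined (zero variance)\n")
  else cat(sprintf("  Pearson r = %.3f (P = %.3g)\n", x$pearson_r, x$r_pvalue))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
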