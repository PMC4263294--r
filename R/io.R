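# Readers/writers for the external formats the pipeline touches.
#
# Conventions: all coordinates are 0-based half-open (native to BED,
# bedGraph and chain files). Readers return plain data.frames and attach a
# "dropped" attribute counting records removed by validity filters; nothing
# is silently discarded. Files compressed with gzip are accepted by ".gz"
# extension.

open_text <- function(path) {
  if (!file.exists(path)) oxo_usage_error("input file not found: %s", path)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Read a whitespace/tab separated text file into a character matrix of
# fields, enforcing a constant field count and reporting 1-based file line
# numbers on malformed rows. Lines starting with "#" or "track" skipped.
read_fields <- function(path, n_fields, what, header = FALSE) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^(#|track( |$))", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) oxo_data_error("%s: empty file: %s", what, path)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (header) {
    hdr <- fields[[1L]]
    fields <- fields[-1L]
    nf <- nf[-1L]
    lineno <- lineno[-1L]
    if (length(fields) == 0L)
      oxo_data_error("%s: no data rows in %s", what, path)
  } else hdr <- NULL
  bad <- which(nf < n_fields)
  if (length(bad) > 0L)
    oxo_data_error("%s: malformed line %d in %s (%d field(s), expected >= %d)",
                   what, lineno[bad[1L]], path, nf[bad[1L]], n_fields)
  m <- t(vapply(fields, function(f) f[seq_len(n_fields)], character(n_fields)))
  list(fields = m, header = hdr, lineno = lineno)
}

num_or_die <- function(x, what, path, lineno, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  na_token <- toupper(x) %in% c("NA", "NAN", ".")
  bad <- which(is.na(v) & !(allow_na & na_token))
  if (length(bad) > 0L)
    oxo_data_error("%s: non-numeric field on line %d of %s: '%s'",
                   what, lineno[bad[1L]], path, x[bad[1L]])
  v
}

#' Read a per-probe signal table
#'
#' Reads the per-probe measurements of an immunoprecipitation microarray.
#' In `"ratio"` mode the file already carries the per-probe log2(IP/input)
#' value; in `"two_channel"` mode it carries raw IP (Cy5) and input (Cy3)
#' intensities and the log-ratio is computed here. Probes with non-finite
#' values (or non-positive intensities in two-channel mode) are dropped and
#' counted, never imputed.
#'
#' @param path TSV, either with a header line naming the columns below or
#'   headerless in positional (bedGraph-like) order. Ratio mode columns:
#'   `chrom,start,end,value`; two-channel mode: `chrom,start,end,ip,input`.
#' @param mode `"ratio"` or `"two_channel"`.
#' @return `data.frame(chrom, start, end, value)` sorted by (chrom, start),
#'   with attribute `dropped` (number of filtered rows).
#' @export
read_probe_table <- function(path, mode = c("ratio", "two_channel")) {
  mode <- match.arg(mode)
  ncol_needed <- if (mode == "ratio") 4L else 5L
  r <- read_fields(path, ncol_needed, "probe table", header = FALSE)
  want <- if (mode == "ratio") c("chrom", "start", "end", "value")
          else c("chrom", "start", "end", "ip", "input")
  first <- r$fields[1L, ]
  if (identical(tolower(first[seq_len(ncol_needed)]), want)) {
    if (nrow(r$fields) == 1L)
      oxo_data_error("probe table: no data rows in %s", path)
    r$fields <- r$fields[-1L, , drop = FALSE]
    r$lineno <- r$lineno[-1L]
  } else if (is.na(suppressWarnings(as.numeric(first[2L])))) {
    oxo_data_error("probe table: header must be '%s', got '%s'",
                   paste(want, collapse = "\t"),
                   paste(first, collapse = "\t"))
  }
  m <- r$fields
  start <- num_or_die(m[, 2L], "probe table", path, r$lineno)
  end <- num_or_die(m[, 3L], "probe table", path, r$lineno)
  bad <- which(!(start < end))
  if (length(bad) > 0L)
    oxo_data_error("probe table: start >= end on line %d of %s",
                   r$lineno[bad[1L]], path)
  if (mode == "ratio") {
    value <- num_or_die(m[, 4L], "probe table", path, r$lineno,
                        allow_na = TRUE)
    keep <- is.finite(value)
  } else {
    ip <- num_or_die(m[, 4L], "probe table", path, r$lineno, allow_na = TRUE)
    input <- num_or_die(m[, 5L], "probe table", path, r$lineno,
                        allow_na = TRUE)
    keep <- is.finite(ip) & is.finite(input) & ip > 0 & input > 0
    value <- ifelse(keep, log2(ip / input), NA_real_)
  }
  probes <- data.frame(chrom = m[, 1L], start = start, end = end,
                       value = value, stringsAsFactors = FALSE)[keep, ,
                                                                drop = FALSE]
  probes <- sort_track(probes)
  rownames(probes) <- NULL
  attr(probes, "dropped") <- sum(!keep)
  probes
}

#' Merge replicate probe tracks
#'
#' Combines biological replicates by the per-probe arithmetic mean of their
#' log-ratio values. Probes are matched on (chrom, start, end); probes
#' absent from any replicate are dropped and counted.
#'
#' @param tracks A list of one or more probe data.frames
#'   (`chrom,start,end,value`).
#' @return Merged probe data.frame sorted by (chrom, start), attribute
#'   `dropped` = number of distinct probes not shared by all replicates.
#' @export
merge_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L || is.data.frame(tracks))
    oxo_data_error("merge_replicates: need a non-empty list of probe tracks")
  for (t in tracks) stopifnot_cols(t, c("chrom", "start", "end", "value"),
                                   "merge_replicates")
  if (length(tracks) == 1L) {
    out <- sort_track(tracks[[1L]])
    rownames(out) <- NULL
    attr(out, "dropped") <- 0L
    return(out)
  }
  keys <- lapply(tracks, function(t) paste(t$chrom, t$start, t$end, sep = "\r"))
  shared <- Reduce(intersect, keys)
  union_n <- length(unique(unlist(keys)))
  base <- tracks[[1L]]
  idx <- match(shared, keys[[1L]])
  out <- base[idx, c("chrom", "start", "end"), drop = FALSE]
  vals <- vapply(seq_along(tracks), function(i)
    tracks[[i]]$value[match(shared, keys[[i]])], numeric(length(shared)))
  out$value <- if (length(shared) == 1L) mean(vals) else rowMeans(vals)
  out <- sort_track(out)
  rownames(out) <- NULL
  attr(out, "dropped") <- union_n - length(shared)
  out
}

#' Read gene annotation (BED6)
#'
#' @param path BED file, at least 6 columns
#'   (chrom, start, end, name, score, strand), no header.
#' @return `data.frame(gene_id, chrom, strand, tx_start, tx_end)`.
#' @export
read_genes_bed <- function(path) {
  r <- read_fields(path, 6L, "genes BED")
  m <- r$fields
  tx_start <- num_or_die(m[, 2L], "genes BED", path, r$lineno)
  tx_end <- num_or_die(m[, 3L], "genes BED", path, r$lineno)
  strand <- m[, 6L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L)
    oxo_data_error("genes BED: invalid strand '%s' on line %d of %s",
                   strand[bad[1L]], r$lineno[bad[1L]], path)
  bad <- which(!(tx_start < tx_end))
  if (length(bad) > 0L)
    oxo_data_error("genes BED: start >= end on line %d of %s",
                   r$lineno[bad[1L]], path)
  if (anyDuplicated(m[, 4L]))
    oxo_data_error("genes BED: duplicate gene_id '%s' in %s",
                   m[duplicated(m[, 4L]), 4L][1L], path)
  genes <- data.frame(gene_id = m[, 4L], chrom = m[, 1L], strand = strand,
                      tx_start = tx_start, tx_end = tx_end,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$tx_start, method = "radix"), ]
  rownames(genes) <- NULL
  genes
}

#' Read a normalized expression table
#'
#' @param path TSV with a header: `gene_id` plus one column per replicate of
#'   log2-scale normalized expression.
#' @return `data.frame(gene_id, expression)` where `expression` is the mean
#'   across replicate columns.
#' @export
read_expression_tsv <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) == 0L) oxo_data_error("expression table: empty file: %s", path)
  stopifnot_cols(df, "gene_id", "expression table")
  if (ncol(df) < 2L)
    oxo_data_error("expression table: need at least one replicate column")
  if (anyDuplicated(df$gene_id))
    oxo_data_error("expression table: duplicate gene_id '%s'",
                   df$gene_id[duplicated(df$gene_id)][1L])
  reps <- df[, -1L, drop = FALSE]
  if (!all(vapply(reps, is.numeric, logical(1L))))
    oxo_data_error("expression table: replicate columns must be numeric")
  data.frame(gene_id = as.character(df$gene_id),
             expression = rowMeans(as.matrix(reps)),
             stringsAsFactors = FALSE)
}

#' Attach expression values to gene records
#'
#' Left join by `gene_id`; genes without an expression entry carry `NA`
#' (counted in attribute `n_missing_expression`).
#'
#' @param genes Output of [read_genes_bed()].
#' @param expr Output of [read_expression_tsv()].
#' @return `genes` with an added `expression` column.
#' @export
attach_expression <- function(genes, expr) {
  stopifnot_cols(genes, "gene_id", "attach_expression")
  stopifnot_cols(expr, c("gene_id", "expression"), "attach_expression")
  genes$expression <- expr$expression[match(genes$gene_id, expr$gene_id)]
  attr(genes, "n_missing_expression") <- sum(is.na(genes$expression))
  genes
}

#' Read a valued interval track (bedGraph dialect)
#'
#' Four columns (chrom, start, end, value), 0-based half-open, no header;
#' `track` and `#` lines are skipped. Overlapping intervals are an error.
#'
#' @param path bedGraph file (optionally gzipped).
#' @return Sorted `data.frame(chrom, start, end, value)`, attribute
#'   `dropped` = rows removed for non-finite values.
#' @export
read_interval_values <- function(path) {
  r <- read_fields(path, 4L, "bedGraph")
  m <- r$fields
  start <- num_or_die(m[, 2L], "bedGraph", path, r$lineno)
  end <- num_or_die(m[, 3L], "bedGraph", path, r$lineno)
  value <- num_or_die(m[, 4L], "bedGraph", path, r$lineno)
  bad <- which(!(start < end))
  if (length(bad) > 0L)
    oxo_data_error("bedGraph: start >= end on line %d of %s",
                   r$lineno[bad[1L]], path)
  keep <- is.finite(value)
  df <- data.frame(chrom = m[, 1L], start = start, end = end, value = value,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- sort_track(df)
  rownames(df) <- NULL
  check_no_overlap(df, sprintf("bedGraph %s", path))
  attr(df, "dropped") <- sum(!keep)
  df
}

check_no_overlap <- function(df, what) {
  if (nrow(df) < 2L) return(invisible(df))
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  ov <- which(same & df$start[-1L] < df$end[-nrow(df)])
  if (length(ov) > 0L) {
    i <- ov[1L]
    oxo_data_error(
      "%s: overlapping intervals %s:%d-%d and %s:%d-%d", what,
      df$chrom[i], df$start[i], df$end[i],
      df$chrom[i + 1L], df$start[i + 1L], df$end[i + 1L])
  }
  invisible(df)
}

#' Write a bedGraph track
#'
#' Records are sorted before writing; values are formatted to 6 significant
#' digits. By default overlapping records are rejected (bedGraph tracks are
#' step functions); sliding-window exports may disable the check.
#'
#' @param track `data.frame(chrom, start, end, value)`.
#' @param path Output path.
#' @param check_overlap Reject overlapping records (default `TRUE`).
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path, check_overlap = TRUE) {
  stopifnot_cols(track, c("chrom", "start", "end", "value"), "write_bedgraph")
  track <- sort_track(track)
  if (check_overlap) check_no_overlap(track, "write_bedgraph")
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(track$end), formatC(track$value, digits = 6,
                                                  format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as TSV (header, no quoting, trailing newline)
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write chrom.sizes (two-column TSV: chromosome, length)
#'
#' @param path chrom.sizes file.
#' @return [genome_assembly()] data.frame.
#' @export
read_chrom_sizes <- function(path) {
  r <- read_fields(path, 2L, "chrom.sizes")
  genome_assembly(r$fields[, 1L],
                  num_or_die(r$fields[, 2L], "chrom.sizes", path, r$lineno))
}

#' @rdname read_chrom_sizes
#' @param assembly A [genome_assembly()] data.frame.
#' @export
write_chrom_sizes <- function(assembly, path) {
  writeLines(sprintf("%s\t%d", assembly$chrom, as.integer(assembly$length)),
             path)
  invisible(path)
}
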