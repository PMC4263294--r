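# Chain-file based interval remapping between genome assemblies.
#
# A UCSC chain describes one pairwise alignment between a source ("target",
# t) and a destination ("query", q) sequence as an ordered run of gapless
# blocks: each block line carries its size and the gaps (dt on the source,
# dq on the destination) before the next block; the last line carries only a
# size. t coordinates are always on the + strand; when qStrand is "-", the
# q coordinates are expressed on the reverse-complemented destination
# sequence and must be reflected (pos' = qSize - pos) to report + strand
# positions.
#
# An interval maps through a chain when enough of its bases fall in aligned
# blocks: mapped_fraction = aligned bases / interval length must reach
# `min_blocks` (the liftOver -minBlocks criterion, default 0.1). The output
# span is the envelope [min, max) of the destination positions of the
# interval's aligned bases, so insertions interior to the interval are
# spanned rather than split.

#' Parse a UCSC chain file
#'
#' @param path Chain file (optionally gzipped). Header lines have 13
#'   fields: `chain score tName tSize tStrand tStart tEnd qName qSize
#'   qStrand qStart qEnd id`.
#' @return Object of class `chain_set`: a list of chains, each a list with
#'   the header fields plus numeric vectors `size`, `dt`, `dq` and
#'   precomputed block start offsets `t_block`, `q_block`.
#' @export
parse_chain <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0L)
    oxo_data_error("parse_chain: no chain records in %s", path)
  chains <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[i]]), "[\t ]+")[[1L]]
    if (length(h) != 13L)
      oxo_data_error("parse_chain: malformed chain header (need 13 fields): '%s'",
                     lines[hdr_idx[i]])
    body <- lines[seq(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)]
    body <- trimws(body)
    body <- body[nzchar(body)]
    if (length(body) == 0L)
      oxo_data_error("parse_chain: chain %s has no alignment blocks", h[13L])
    parts <- strsplit(body, "[\t ]+")
    nf <- lengths(parts)
    if (any(nf[-length(nf)] != 3L) || nf[length(nf)] != 1L)
      oxo_data_error("parse_chain: chain %s: block lines must have 3 fields (last line 1)",
                     h[13L])
    size <- as.numeric(vapply(parts, `[`, "", 1L))
    dt <- c(as.numeric(vapply(parts[-length(parts)], `[`, "", 2L)), 0)
    dq <- c(as.numeric(vapply(parts[-length(parts)], `[`, "", 3L)), 0)
    if (any(!is.finite(size)) || any(size < 1))
      oxo_data_error("parse_chain: chain %s: block sizes must be >= 1", h[13L])
    ch <- list(score = as.numeric(h[2L]),
               t_name = h[3L], t_size = as.numeric(h[4L]), t_strand = h[5L],
               t_start = as.numeric(h[6L]), t_end = as.numeric(h[7L]),
               q_name = h[8L], q_size = as.numeric(h[9L]), q_strand = h[10L],
               q_start = as.numeric(h[11L]), q_end = as.numeric(h[12L]),
               id = h[13L], size = size, dt = dt, dq = dq)
    if (ch$t_strand != "+")
      oxo_data_error("parse_chain: chain %s: tStrand must be '+'", ch$id)
    if (!ch$q_strand %in% c("+", "-"))
      oxo_data_error("parse_chain: chain %s: invalid qStrand '%s'", ch$id,
                     ch$q_strand)
    if (sum(size) + sum(dt) != ch$t_end - ch$t_start)
      oxo_data_error("parse_chain: chain %s: block sums do not span the t range",
                     ch$id)
    if (sum(size) + sum(dq) != ch$q_end - ch$q_start)
      oxo_data_error("parse_chain: chain %s: block sums do not span the q range",
                     ch$id)
    ch$t_block <- ch$t_start + cumsum(c(0, size + dt))[seq_along(size)]
    ch$q_block <- ch$q_start + cumsum(c(0, size + dq))[seq_along(size)]
    chains[[i]] <- ch
  }
  structure(chains, class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set with %d chain(s)\n", length(x)))
  for (ch in x)
    cat(sprintf("  chain %s: %s:%d-%d -> %s:%d-%d (%s) score %g, %d block(s)\n",
                ch$id, ch$t_name, ch$t_start, ch$t_end, ch$q_name,
                ch$q_start, ch$q_end, ch$q_strand, ch$score,
                length(ch$size)))
  invisible(x)
}

# Aligned overlap of [start, end) with one chain: number of aligned bases
# and the destination-envelope (on the + strand of q).
chain_overlap <- function(ch, start, end) {
  os <- pmax(start, ch$t_block)
  oe <- pmin(end, ch$t_block + ch$size)
  w <- pmax(0, oe - os)
  aligned <- sum(w)
  if (aligned == 0)
    return(list(aligned = 0))
  hit <- which(w > 0)
  qs <- ch$q_block[hit] + (os[hit] - ch$t_block[hit])
  qe <- ch$q_block[hit] + (oe[hit] - ch$t_block[hit])
  qmin <- min(qs)
  qmax <- max(qe)
  if (ch$q_strand == "-") {
    tmp <- qmin
    qmin <- ch$q_size - qmax
    qmax <- ch$q_size - tmp
  }
  list(aligned = aligned, q_name = ch$q_name, q_start = qmin, q_end = qmax,
       q_strand = ch$q_strand)
}

#' Map one interval to the destination assembly
#'
#' Candidate chains are those with at least one aligned base inside the
#' interval; a candidate is eligible when its mapped fraction (aligned
#' bases / interval length) reaches `min_blocks`. With exactly one eligible
#' chain the interval maps to the envelope of its aligned bases'
#' destination positions. Failures are labelled `"deleted"` (no candidate),
#' `"partially_deleted"` (best fraction below `min_blocks`) or
#' `"ambiguous"` (two or more eligible chains; set `best_chain = TRUE` to
#' instead pick by score, then aligned bases, then lowest chain id).
#'
#' @param chrom,start,end Source interval (0-based half-open).
#' @param chains A [parse_chain()] `chain_set`.
#' @param min_blocks Minimum mapped fraction in (0, 1] (default 0.1).
#' @param best_chain Resolve ambiguity by best score instead of failing.
#' @return List with `status` ("mapped" or a failure reason) and, when
#'   mapped, `chrom`, `start`, `end`, `strand` (destination strand),
#'   `chain_id`, `mapped_fraction`.
#' @export
map_interval <- function(chrom, start, end, chains, min_blocks = 0.1,
                         best_chain = FALSE) {
  if (!is.finite(min_blocks) || min_blocks <= 0 || min_blocks > 1)
    oxo_data_error("map_interval: min_blocks must be in (0, 1]")
  if (!(start < end)) oxo_data_error("map_interval: start must be < end")
  len <- end - start
  cands <- list()
  for (ch in chains) {
    if (ch$t_name != chrom) next
    ov <- chain_overlap(ch, start, end)
    if (ov$aligned == 0) next
    ov$fraction <- ov$aligned / len
    ov$score <- ch$score
    ov$id <- ch$id
    cands[[length(cands) + 1L]] <- ov
  }
  if (length(cands) == 0L)
    return(list(status = "deleted"))
  fracs <- vapply(cands, `[[`, 0, "fraction")
  eligible <- which(fracs >= min_blocks)
  if (length(eligible) == 0L)
    return(list(status = "partially_deleted", best_fraction = max(fracs)))
  if (length(eligible) > 1L) {
    if (!best_chain)
      return(list(status = "ambiguous", n_eligible = length(eligible)))
    e <- cands[eligible]
    o <- order(-vapply(e, `[[`, 0, "score"),
               -vapply(e, `[[`, 0, "aligned"),
               vapply(e, `[[`, "", "id"))
    pick <- e[[o[1L]]]
  } else pick <- cands[[eligible]]
  list(status = "mapped", chrom = pick$q_name, start = pick$q_start,
       end = pick$q_end, strand = pick$q_strand, chain_id = pick$id,
       mapped_fraction = pick$fraction)
}

#' Map a valued interval track to the destination assembly
#'
#' Each interval is mapped independently with [map_interval()], its value
#' carried unchanged. Mapped intervals that collide (overlap an interval
#' already mapped earlier in input order) on the destination are dropped
#' and counted as `"collision"`. A rejection report tabulates all failure
#' reasons.
#'
#' @param track `data.frame(chrom, start, end, value)`, non-overlapping.
#' @param chains A `chain_set`.
#' @param min_blocks,best_chain See [map_interval()].
#' @return List with `mapped` (sorted destination track), `unmapped`
#'   (source intervals + failure reason), `report`
#'   (`data.frame(reason, n)` including `"mapped"`).
#' @export
map_profile <- function(track, chains, min_blocks = 0.1, best_chain = FALSE) {
  stopifnot_cols(track, c("chrom", "start", "end", "value"), "map_profile")
  check_no_overlap(sort_track(track), "map_profile input")
  n <- nrow(track)
  res_chrom <- character(n); res_start <- numeric(n); res_end <- numeric(n)
  status <- character(n)
  kept <- new.env(parent = emptyenv())  # per-chrom kept intervals
  for (i in seq_len(n)) {
    m <- map_interval(track$chrom[i], track$start[i], track$end[i], chains,
                      min_blocks = min_blocks, best_chain = best_chain)
    status[i] <- m$status
    if (m$status != "mapped") next
    ks <- get0(m$chrom, envir = kept, ifnotfound = NULL)
    if (!is.null(ks)) {
      j <- findInterval(m$start, ks$start)
      clash <- (j >= 1L && ks$end[j] > m$start) ||
        (j < length(ks$start) && ks$start[j + 1L] < m$end)
      if (clash) { status[i] <- "collision"; next }
      pos <- j + 1L
      ks$start <- append(ks$start, m$start, after = j)
      ks$end <- append(ks$end, m$end, after = j)
    } else ks <- list(start = m$start, end = m$end)
    assign(m$chrom, ks, envir = kept)
    res_chrom[i] <- m$chrom; res_start[i] <- m$start; res_end[i] <- m$end
  }
  ok <- status == "mapped"
  mapped <- data.frame(chrom = res_chrom[ok], start = res_start[ok],
                       end = res_end[ok], value = track$value[ok],
                       stringsAsFactors = FALSE)
  mapped <- sort_track(mapped)
  rownames(mapped) <- NULL
  unmapped <- data.frame(chrom = track$chrom[!ok], start = track$start[!ok],
                         end = track$end[!ok], reason = status[!ok],
                         stringsAsFactors = FALSE)
  tab <- table(factor(status, levels = c("mapped", "deleted",
                                         "partially_deleted", "ambiguous",
                                         "collision")))
  report <- data.frame(reason = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(mapped = mapped, unmapped = unmapped, report = report)
}

#' Write a chain_set back to UCSC chain format
#'
#' @param chains A `chain_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_chain <- function(chains, path) {
  out <- character()
  for (ch in chains) {
    out <- c(out, sprintf("chain %g %s %d %s %d %d %s %d %s %d %d %s",
                          ch$score, ch$t_name, as.integer(ch$t_size),
                          ch$t_strand, as.integer(ch$t_start),
                          as.integer(ch$t_end), ch$q_name,
                          as.integer(ch$q_size), ch$q_strand,
                          as.integer(ch$q_start), as.integer(ch$q_end),
                          ch$id))
    nb <- length(ch$size)
    if (nb > 1L)
      out <- c(out, sprintf("%d\t%d\t%d", as.integer(ch$size[-nb]),
                            as.integer(ch$dt[-nb]), as.integer(ch$dq[-nb])))
    out <- c(out, sprintf("%d", as.integer(ch$size[nb])), "")
  }
  writeLines(out, path)
  invisible(path)
}
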