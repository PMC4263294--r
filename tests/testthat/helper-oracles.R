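# Independent oracles and fixture builders. These deliberately use the
# slowest, most literal formulation of each operation (O(n^2) window scans,
# per-base chain walks) so they share no code path with the implementation
# they check.

# O(n^2) sliding-window mean oracle (midpoint distance, inclusive bounds).
brute_smooth <- function(probes, halfwidth) {
  mid <- floor((probes$start + probes$end) / 2)
  vapply(seq_len(nrow(probes)), function(i) {
    sel <- probes$chrom == probes$chrom[i] & abs(mid - mid[i]) <= halfwidth
    mean(probes$value[sel])
  }, numeric(1L))
}

# Literal per-window mean oracle for fixed-step window tracks.
brute_window <- function(probes, window, step, chrom_len) {
  mid <- floor((probes$start + probes$end) / 2)
  out <- list()
  for (ch in unique(probes$chrom)) {
    starts <- seq(0, chrom_len - 1, by = step)
    for (s in starts) {
      sel <- probes$chrom == ch & mid >= s & mid < s + window
      if (!any(sel)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = min(s + window, chrom_len),
        value = mean(probes$value[sel]), n_probes = sum(sel))
    }
  }
  do.call(rbind, out)
}

# Per-base chain-walk oracle for interval mapping. Walks every base of the
# interval through every chain's block arithmetic.
oracle_map_interval <- function(chrom, start, end, chains, min_blocks = 0.1,
                                best_chain = FALSE) {
  len <- end - start
  cands <- list()
  for (ch in chains) {
    if (ch$t_name != chrom) next
    qpos <- rep(NA_real_, len)
    for (b in seq_along(ch$size)) {
      for (pos in seq(start, end - 1)) {
        if (pos >= ch$t_block[b] && pos < ch$t_block[b] + ch$size[b])
          qpos[pos - start + 1L] <- ch$q_block[b] + (pos - ch$t_block[b])
      }
    }
    aligned <- sum(!is.na(qpos))
    if (aligned == 0) next
    qplus <- if (ch$q_strand == "-") ch$q_size - 1 - qpos else qpos
    cands[[length(cands) + 1L]] <- list(
      fraction = aligned / len, aligned = aligned, q_name = ch$q_name,
      qmin = min(qplus, na.rm = TRUE), qmax = max(qplus, na.rm = TRUE),
      id = ch$id, score = ch$score)
  }
  if (length(cands) == 0L) return(list(status = "deleted"))
  fr <- vapply(cands, `[[`, 0, "fraction")
  elig <- which(fr >= min_blocks)
  if (length(elig) == 0L) return(list(status = "partially_deleted"))
  if (length(elig) > 1L) {
    if (!best_chain) return(list(status = "ambiguous"))
    e <- cands[elig]
    o <- order(-vapply(e, `[[`, 0, "score"), -vapply(e, `[[`, 0, "aligned"),
               vapply(e, `[[`, "", "id"))
    pick <- e[[o[1L]]]
  } else pick <- cands[[elig]]
  list(status = "mapped", chrom = pick$q_name, start = pick$qmin,
       end = pick$qmax + 1)
}

# Directly construct a chain (bypassing the parser) from block geometry.
make_chain <- function(t_name, t_start, sizes, dts, dqs, q_name, q_size,
                       q_strand, q_start, id, score = 1000,
                       t_size = 10000000) {
  n <- length(sizes)
  dt <- c(dts, 0)[seq_len(n)]
  dq <- c(dqs, 0)[seq_len(n)]
  dt[n] <- 0; dq[n] <- 0
  ch <- list(score = score, t_name = t_name, t_size = t_size,
             t_strand = "+", t_start = t_start,
             t_end = t_start + sum(sizes) + sum(dt),
             q_name = q_name, q_size = q_size, q_strand = q_strand,
             q_start = q_start, q_end = q_start + sum(sizes) + sum(dq),
             id = as.character(id), size = sizes, dt = dt, dq = dq)
  ch$t_block <- ch$t_start + cumsum(c(0, sizes + dt))[seq_len(n)]
  ch$q_block <- ch$q_start + cumsum(c(0, sizes + dq))[seq_len(n)]
  ch
}

chain_set_of <- function(...) structure(list(...), class = "chain_set")

# Random toy chain sets over one source chromosome, including minus-strand
# chains; chains may overlap on the source so ambiguity arises.
random_chain_set <- function(n_chains = 3L, t_len = 5000L) {
  chains <- lapply(seq_len(n_chains), function(i) {
    nb <- sample(1:4, 1L)
    sizes <- sample(20:200, nb, replace = TRUE)
    dts <- sample(0:100, nb, replace = TRUE)
    dqs <- sample(0:100, nb, replace = TRUE)
    t_start <- sample(0:(t_len %/% 2), 1L)
    q_strand <- sample(c("+", "-"), 1L)
    make_chain("cA", t_start, sizes, dts, dqs,
               q_name = sample(c("cB1", "cB2"), 1L), q_size = 100000L,
               q_strand = q_strand, q_start = sample(0:50000, 1L),
               id = i, score = sample(100:10000, 1L), t_size = t_len * 2)
  })
  structure(chains, class = "chain_set")
}

# Random sorted probe track on one chromosome.
random_probes <- function(n, chrom = "chr1", span = 1e6, sd = 1) {
  start <- sort(sample.int(span, n))
  data.frame(chrom = chrom, start = start, end = start + 60,
             value = rnorm(n, 0, sd), stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
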