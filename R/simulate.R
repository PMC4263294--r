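# Synthetic data with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# probes every ~6 kb; lamina-associated domains (LADs) spanning 100 kb to
# 10 Mb with sharp borders, carrying a bimodal lamin B1 signal (Normal(+mu)
# inside, Normal(-mu) outside, per 10 kb tile); an additive damage effect
# (oxo_delta) on probes inside LADs plus Gaussian noise; genes placed with
# inter-LAD:LAD odds favouring inter-LADs; log-normal expression; and a
# paired toy assembly related by seeded indels and one inversion, described
# by a chain file, for testing coordinate transfer. All randomness flows
# from one master seed through fixed per-component child seeds, so each
# artefact is reproducible in isolation.

#' Simulation configuration
#'
#' @param seed Master seed (integer).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp);
#'   default one 20 Mb chromosome.
#' @param probe_spacing Mean probe spacing in bp (default 6000).
#' @param probe_length Probe length (default 60, a 60-mer).
#' @param lad_length_range LAD lengths are log-uniform on this range
#'   (default 100 kb - 10 Mb), truncated to fit.
#' @param lad_genome_fraction Target fraction of the genome inside LADs
#'   (default 0.4).
#' @param lamin_mu,lamin_sd Bimodal lamin signal: tile values are
#'   Normal(+mu, sd) inside LADs and Normal(-mu, sd) outside (defaults 2.0,
#'   0.5).
#' @param lamin_tile Lamin profile tile size in bp (default 10000).
#' @param oxo_delta Additive damage effect on probes inside LADs (default
#'   0.38, the implied group gap 0.25 - (-0.13)).
#' @param oxo_sd Probe noise SD (default 0.5).
#' @param gene_density_ratio Per-base inter-LAD : LAD gene placement odds
#'   (default 5).
#' @param n_genes Number of genes (default 300).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (defaults log(20000), 0.8).
#' @param expression_meanlog,expression_sdlog Log-normal raw expression
#'   parameters (defaults 5, 1.5); the table stores log2 values.
#' @param expression_rep_sd Replicate noise SD on the log2 scale (default
#'   0.1).
#' @param n_expression_reps Number of expression replicates (default 2).
#' @param chain_event_rate Indel events per Mb for the paired assembly
#'   (default 0.5).
#' @param chain_inversion Include one inversion per chromosome where it
#'   fits (default `TRUE`).
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chrS1 = 20e6),
                              probe_spacing = 6000,
                              probe_length = 60,
                              lad_length_range = c(1e5, 1e7),
                              lad_genome_fraction = 0.4,
                              lamin_mu = 2.0,
                              lamin_sd = 0.5,
                              lamin_tile = 10000,
                              oxo_delta = 0.38,
                              oxo_sd = 0.5,
                              gene_density_ratio = 5,
                              n_genes = 300L,
                              gene_length_meanlog = log(20000),
                              gene_length_sdlog = 0.8,
                              expression_meanlog = 5,
                              expression_sdlog = 1.5,
                              expression_rep_sd = 0.1,
                              n_expression_reps = 2L,
                              chain_event_rate = 0.5,
                              chain_inversion = TRUE) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              probe_spacing = probe_spacing, probe_length = probe_length,
              lad_length_range = lad_length_range,
              lad_genome_fraction = lad_genome_fraction,
              lamin_mu = lamin_mu, lamin_sd = lamin_sd,
              lamin_tile = lamin_tile, oxo_delta = oxo_delta,
              oxo_sd = oxo_sd, gene_density_ratio = gene_density_ratio,
              n_genes = as.integer(n_genes),
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              expression_rep_sd = expression_rep_sd,
              n_expression_reps = as.integer(n_expression_reps),
              chain_event_rate = chain_event_rate,
              chain_inversion = isTRUE(chain_inversion))
  if (is.null(names(cfg$chrom_lengths)))
    names(cfg$chrom_lengths) <- sprintf("chrS%d", seq_along(cfg$chrom_lengths))
  with(cfg, {
    if (any(chrom_lengths <= 0) || probe_spacing <= 0 || lamin_tile <= 0)
      oxo_data_error("simulation_config: lengths must be > 0")
    if (lad_genome_fraction <= 0 || lad_genome_fraction >= 1)
      oxo_data_error("simulation_config: lad_genome_fraction must be in (0,1)")
    if (oxo_sd <= 0) oxo_data_error("simulation_config: oxo_sd must be > 0")
    if (lad_length_range[1L] <= 0 || diff(lad_length_range) < 0)
      oxo_data_error("simulation_config: invalid lad_length_range")
    if (n_genes < 0 || n_expression_reps < 1)
      oxo_data_error("simulation_config: invalid gene/replicate counts")
  })
  structure(cfg, class = "simulation_config")
}

rloguniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# Draw one chromosome's LAD set: log-uniform lengths accumulated until the
# target coverage is reached (last domain truncated to hit it), separated
# by randomly sized inter-LAD gaps.
draw_lads <- function(L, range, fraction) {
  target <- round(fraction * L)
  lens <- numeric()
  while (sum(lens) < target) {
    l <- round(rloguniform(1L, range[1L], min(range[2L], L)))
    if (sum(lens) + l > target) l <- target - sum(lens)
    lens <- c(lens, l)
  }
  lens <- lens[lens > 0]
  k <- length(lens)
  w <- stats::runif(k + 1L)
  gaps <- floor((L - target) * w / sum(w))
  gaps[1L] <- gaps[1L] + (L - target) - sum(gaps)
  starts <- cumsum(c(0, lens)) + cumsum(gaps)
  data.frame(start = starts[seq_len(k)], end = starts[seq_len(k)] + lens,
             stringsAsFactors = FALSE)
}

pos_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  j <- findInterval(pos, starts)
  j >= 1L & pos < ends[pmax(j, 1L)]
}

#' Simulate a complete dataset
#'
#' Generates, in memory, every input the pipeline consumes: probe
#' log-ratios, a lamin B1 interval profile, gene annotations, an expression
#' table, the assembly, and a ground-truth record (LAD intervals, per-probe
#' LAD membership, true effect size, placement odds). Deterministic given
#' `config$seed`. Use [write_dataset()] to materialize files.
#'
#' @param config A [simulation_config()].
#' @return Object of class `oxomap_simulation`: list with `assembly`,
#'   `lads`, `probes`, `lamin`, `genes`, `expression`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    oxo_data_error("simulate_dataset: config must be a simulation_config")
  chroms <- names(config$chrom_lengths)
  assembly <- genome_assembly(chroms, config$chrom_lengths)

  lads <- with_seed(derive_seed(config$seed, 1L), {
    do.call(rbind, lapply(chroms, function(ch) {
      d <- draw_lads(config$chrom_lengths[[ch]], config$lad_length_range,
                     config$lad_genome_fraction)
      cbind(chrom = ch, d)
    }))
  })

  lamin <- with_seed(derive_seed(config$seed, 2L), {
    do.call(rbind, lapply(chroms, function(ch) {
      L <- config$chrom_lengths[[ch]]
      starts <- seq(0, L - 1, by = config$lamin_tile)
      ends <- pmin(starts + config$lamin_tile, L)
      ld <- lads[lads$chrom == ch, ]
      inside <- pos_in_intervals(floor((starts + ends) / 2), ld$start, ld$end)
      data.frame(chrom = ch, start = starts, end = ends,
                 value = stats::rnorm(length(starts),
                                      ifelse(inside, config$lamin_mu,
                                             -config$lamin_mu),
                                      config$lamin_sd),
                 stringsAsFactors = FALSE)
    }))
  })

  probes <- with_seed(derive_seed(config$seed, 3L), {
    do.call(rbind, lapply(chroms, function(ch) {
      L <- config$chrom_lengths[[ch]]
      base <- seq(0, L - config$probe_length, by = config$probe_spacing)
      jit <- floor(stats::runif(length(base), -config$probe_spacing / 4,
                                config$probe_spacing / 4))
      start <- pmin(pmax(base + jit, 0), L - config$probe_length)
      start <- sort(start)
      ld <- lads[lads$chrom == ch, ]
      mid <- probe_mid(start, start + config$probe_length)
      inside <- pos_in_intervals(mid, ld$start, ld$end)
      data.frame(chrom = ch, start = start,
                 end = start + config$probe_length,
                 value = config$oxo_delta * inside +
                   stats::rnorm(length(start), 0, config$oxo_sd),
                 in_lad = inside, stringsAsFactors = FALSE)
    }))
  })
  probe_in_lad <- probes$in_lad
  probes$in_lad <- NULL

  genes <- with_seed(derive_seed(config$seed, 4L), {
    if (config$n_genes == 0L) return(NULL)
    # weighted-per-base sampling segments: LAD weight 1, inter-LAD weight
    # gene_density_ratio
    segs <- do.call(rbind, lapply(chroms, function(ch) {
      L <- config$chrom_lengths[[ch]]
      ld <- lads[lads$chrom == ch, ]
      bounds <- sort(unique(c(0, ld$start, ld$end, L)))
      s <- bounds[-length(bounds)]
      e <- bounds[-1L]
      inside <- pos_in_intervals(s, ld$start, ld$end)
      data.frame(chrom = ch, start = s, end = e,
                 w = ifelse(inside, 1, config$gene_density_ratio),
                 stringsAsFactors = FALSE)
    }))
    segs <- segs[segs$end > segs$start, ]
    wtot <- cumsum(segs$w * (segs$end - segs$start))
    u <- stats::runif(config$n_genes, 0, wtot[length(wtot)])
    si <- findInterval(u, c(0, wtot[-length(wtot)]), left.open = FALSE)
    si <- pmin(pmax(si, 1L), nrow(segs))
    within <- (u - c(0, wtot)[si]) / segs$w[si]
    p5 <- floor(segs$start[si] + pmin(within, segs$end[si] - segs$start[si] - 1))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    len <- pmax(200, round(stats::rlnorm(config$n_genes,
                                         config$gene_length_meanlog,
                                         config$gene_length_sdlog)))
    chrom <- segs$chrom[si]
    Lv <- config$chrom_lengths[chrom]
    tx_start <- ifelse(strand == "+", p5, pmax(p5 + 1 - len, 0))
    tx_end <- ifelse(strand == "+", pmin(p5 + len, Lv), p5 + 1)
    tx_end <- pmax(tx_end, tx_start + 1)
    g <- data.frame(gene_id = sprintf("g%04d", seq_len(config$n_genes)),
                    chrom = chrom, strand = strand, tx_start = tx_start,
                    tx_end = tx_end, p5 = p5, stringsAsFactors = FALSE)
    g[order(g$chrom, g$tx_start, method = "radix"), ]
  })
  gene_in_lad <- NULL
  if (!is.null(genes)) {
    gene_in_lad <- vapply(seq_len(nrow(genes)), function(i) {
      ld <- lads[lads$chrom == genes$chrom[i], ]
      pos_in_intervals(genes$p5[i], ld$start, ld$end)
    }, logical(1L))
    names(gene_in_lad) <- genes$gene_id
    genes$p5 <- NULL
    rownames(genes) <- NULL
  }

  expression <- with_seed(derive_seed(config$seed, 5L), {
    if (is.null(genes)) return(NULL)
    raw <- stats::rlnorm(nrow(genes), config$expression_meanlog,
                         config$expression_sdlog)
    reps <- vapply(seq_len(config$n_expression_reps), function(r)
      log2(raw) + stats::rnorm(nrow(genes), 0, config$expression_rep_sd),
      numeric(nrow(genes)))
    df <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
    for (r in seq_len(config$n_expression_reps))
      df[[sprintf("rep_%d", r)]] <- reps[, r]
    df
  })

  truth <- list(
    lads = lads,
    lad_fraction_realized = sum(lads$end - lads$start) /
      sum(config$chrom_lengths),
    oxo_delta = config$oxo_delta,
    gene_density_ratio = config$gene_density_ratio,
    probe_in_lad = probe_in_lad,
    gene_in_lad = gene_in_lad,
    seed = config$seed)

  structure(list(assembly = assembly, lads = lads, probes = probes,
                 lamin = lamin, genes = genes, expression = expression,
                 truth = truth, config = config),
            class = "oxomap_simulation")
}

#' Write a simulated dataset to a directory
#'
#' Emits `probes.bedgraph`, `lamin.bedgraph`, `genes.bed`,
#' `expression.tsv`, `chrom.sizes` and `truth.json`. Byte-identical across
#' runs with the same config.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of paths.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "oxomap_simulation"))
    oxo_data_error("write_dataset: sim must be an oxomap_simulation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(probes = file.path(dir, "probes.bedgraph"),
             lamin = file.path(dir, "lamin.bedgraph"),
             genes = file.path(dir, "genes.bed"),
             expression = file.path(dir, "expression.tsv"),
             chrom_sizes = file.path(dir, "chrom.sizes"),
             truth = file.path(dir, "truth.json"))
  write_bedgraph(sim$probes, paths[["probes"]])
  write_bedgraph(sim$lamin, paths[["lamin"]])
  if (!is.null(sim$genes))
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", sim$genes$chrom,
                       as.integer(sim$genes$tx_start),
                       as.integer(sim$genes$tx_end), sim$genes$gene_id,
                       sim$genes$strand), paths[["genes"]])
  if (!is.null(sim$expression)) write_tsv(sim$expression, paths[["expression"]])
  write_chrom_sizes(sim$assembly, paths[["chrom_sizes"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

# ---- paired assembly + chain file ------------------------------------------

# Draw non-overlapping edit events (deletions, insertions, one optional
# inversion) for a chromosome of length L; margin bases keep events off
# each other and off the ends.
draw_events <- function(L, rate, inversion, margin = 1000) {
  ev <- data.frame(type = character(), s = numeric(), e = numeric(),
                   len = numeric(), stringsAsFactors = FALSE)
  if (inversion && L >= 2e6) {
    ilen <- round(rloguniform(1L, 2e5, min(2e6, L / 4)))
    s <- floor(stats::runif(1L, margin, L - ilen - margin))
    ev <- rbind(ev, data.frame(type = "inv", s = s, e = s + ilen,
                               len = ilen, stringsAsFactors = FALSE))
  }
  n <- stats::rpois(1L, rate * L / 1e6)
  if (n > 0L) {
    type <- sample(c("del", "ins"), n, replace = TRUE)
    len <- round(rloguniform(n, 1e3, 5e4))
    s <- floor(stats::runif(n, margin, L - margin - len))
    e <- ifelse(type == "del", s + len, s)  # insertions are points in source
    ev <- rbind(ev, data.frame(type = type, s = s, e = e, len = len,
                               stringsAsFactors = FALSE))
  }
  if (nrow(ev) == 0L) return(ev)
  ev <- ev[order(ev$s), , drop = FALSE]
  keep <- logical(nrow(ev))
  last_end <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$s[i] - margin > last_end) {
      keep[i] <- TRUE
      last_end <- max(ev$e[i], ev$s[i])
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Segment decomposition of source -> destination for one chromosome.
# Returns colinear ("co") and inverted ("inv") segments with their t
# (source) and q (destination) spans, plus the destination length.
segment_map <- function(L, events) {
  segs <- list()
  src <- 0; d <- 0
  add_co <- function(from, to) {
    if (to > from)
      segs[[length(segs) + 1L]] <<- list(type = "co", t0 = from, t1 = to,
                                         q0 = d, q1 = d + (to - from))
  }
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      add_co(src, e$s)
      d <- d + (e$s - src)
      if (e$type == "del") {
        # source bases absent from destination
      } else if (e$type == "ins") {
        d <- d + e$len
      } else {  # inversion
        segs[[length(segs) + 1L]] <- list(type = "inv", t0 = e$s, t1 = e$e,
                                          q0 = d, q1 = d + (e$e - e$s))
        d <- d + (e$e - e$s)
      }
      src <- max(e$e, e$s)
    }
  }
  add_co(src, L)
  d <- d + (L - src)
  list(segs = segs, q_size = d)
}

build_chain_from_segs <- function(segs, t_name, t_size, q_name, q_size,
                                  id_start) {
  chains <- list()
  id <- id_start
  co <- Filter(function(s) s$type == "co", segs)
  if (length(co) > 0L) {
    t0 <- vapply(co, `[[`, 0, "t0"); t1 <- vapply(co, `[[`, 0, "t1")
    q0 <- vapply(co, `[[`, 0, "q0"); q1 <- vapply(co, `[[`, 0, "q1")
    size <- t1 - t0
    nb <- length(size)
    dt <- c(t0[-1L] - t1[-nb], 0)
    dq <- c(q0[-1L] - q1[-nb], 0)
    chains[[length(chains) + 1L]] <- list(
      score = sum(size), t_name = t_name, t_size = t_size, t_strand = "+",
      t_start = t0[1L], t_end = t1[nb], q_name = q_name, q_size = q_size,
      q_strand = "+", q_start = q0[1L], q_end = q1[nb],
      id = as.character(id), size = size, dt = dt, dq = dq,
      t_block = t0, q_block = q0)
    id <- id + 1L
  }
  for (s in Filter(function(s) s$type == "inv", segs)) {
    chains[[length(chains) + 1L]] <- list(
      score = s$t1 - s$t0, t_name = t_name, t_size = t_size, t_strand = "+",
      t_start = s$t0, t_end = s$t1, q_name = q_name, q_size = q_size,
      q_strand = "-", q_start = q_size - s$q1, q_end = q_size - s$q0,
      id = as.character(id), size = s$t1 - s$t0, dt = 0, dq = 0,
      t_block = s$t0, q_block = q_size - s$q1)
    id <- id + 1L
  }
  list(chains = chains, next_id = id)
}

# Expected mapping outcome (min_blocks rule) for one source tile, computed
# directly from the event segments -- independent of the chain machinery.
tile_truth <- function(a, b, segs, min_blocks = 0.1) {
  len <- b - a
  co_qmin <- Inf; co_qmax <- -Inf; co_al <- 0
  inv_qmin <- Inf; inv_qmax <- -Inf; inv_al <- 0
  for (s in segs) {
    os <- max(a, s$t0); oe <- min(b, s$t1)
    if (oe <= os) next
    if (s$type == "co") {
      co_al <- co_al + (oe - os)
      co_qmin <- min(co_qmin, s$q0 + (os - s$t0))
      co_qmax <- max(co_qmax, s$q0 + (oe - s$t0))
    } else {
      inv_al <- inv_al + (oe - os)
      inv_qmin <- min(inv_qmin, s$q0 + (s$t1 - oe))
      inv_qmax <- max(inv_qmax, s$q0 + (s$t1 - os))
    }
  }
  fr_co <- co_al / len; fr_inv <- inv_al / len
  n_cand <- (co_al > 0) + (inv_al > 0)
  n_elig <- (fr_co >= min_blocks) + (fr_inv >= min_blocks)
  if (n_cand == 0L) return(list(status = "deleted"))
  if (n_elig == 0L) return(list(status = "partially_deleted"))
  if (n_elig == 2L) return(list(status = "ambiguous"))
  if (fr_co >= min_blocks)
    list(status = "mapped", dest_start = co_qmin, dest_end = co_qmax)
  else list(status = "mapped", dest_start = inv_qmin, dest_end = inv_qmax)
}

#' Simulate a paired assembly and its chain file
#'
#' Derives a second toy assembly from the configured one by seeded
#' deletions, insertions and (optionally) one inversion per chromosome, and
#' builds UCSC chains in both directions, plus a per-10-kb ground-truth
#' table of expected mapping outcomes computed directly from the edit
#' events (independent of the chain machinery).
#'
#' @param config A [simulation_config()] (`chain_event_rate`,
#'   `chain_inversion`, `seed`, `chrom_lengths` are used).
#' @return List with `assembly2`, `chains_fwd` (source to derived),
#'   `chains_rev` (derived to source), `events` (per-chromosome edit
#'   table), `truth` (tile table: `chrom,start,end,expected_status,
#'   dest_start,dest_end`).
#' @export
simulate_chain_pair <- function(config) {
  if (!inherits(config, "simulation_config"))
    oxo_data_error("simulate_chain_pair: config must be a simulation_config")
  chroms <- names(config$chrom_lengths)
  with_seed(derive_seed(config$seed, 6L), {
    fwd <- list(); rev <- list(); id_f <- 1L; id_r <- 1L
    events_all <- list(); truth_all <- list(); q_sizes <- numeric()
    for (ch in chroms) {
      L <- config$chrom_lengths[[ch]]
      ev <- draw_events(L, config$chain_event_rate, config$chain_inversion)
      sm <- segment_map(L, ev)
      q_sizes[[ch]] <- sm$q_size
      bf <- build_chain_from_segs(sm$segs, ch, L, ch, sm$q_size, id_f)
      fwd <- c(fwd, bf$chains); id_f <- bf$next_id
      # reverse direction: swap t and q spans of every segment
      rsegs <- lapply(sm$segs, function(s)
        list(type = s$type, t0 = s$q0, t1 = s$q1, q0 = s$t0, q1 = s$t1))
      br <- build_chain_from_segs(rsegs, ch, sm$q_size, ch, L, id_r)
      rev <- c(rev, br$chains); id_r <- br$next_id
      if (nrow(ev) > 0L) events_all[[ch]] <- cbind(chrom = ch, ev)
      starts <- seq(0, L - 1, by = 10000)
      ends <- pmin(starts + 10000, L)
      tt <- lapply(seq_along(starts), function(i)
        tile_truth(starts[i], ends[i], sm$segs))
      truth_all[[ch]] <- data.frame(
        chrom = ch, start = starts, end = ends,
        expected_status = vapply(tt, `[[`, "", "status"),
        dest_start = vapply(tt, function(x) x$dest_start %||% NA_real_, 0),
        dest_end = vapply(tt, function(x) x$dest_end %||% NA_real_, 0),
        stringsAsFactors = FALSE)
    }
    list(assembly2 = genome_assembly(chroms, q_sizes),
         chains_fwd = structure(fwd, class = "chain_set"),
         chains_rev = structure(rev, class = "chain_set"),
         events = if (length(events_all)) do.call(rbind, events_all) else
           data.frame(),
         truth = do.call(rbind, truth_all))
  })
}
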