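test_that("simulation is deterministic: same seed, byte-identical files", {
  cfg <- simulation_config(seed = 77)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempfile(), "c")
  write_dataset(simulate_dataset(simulation_config(seed = 78)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "probes.bedgraph"))),
                         unname(tools::md5sum(file.path(d3, "probes.bedgraph")))))
})

test_that("generated world matches its stated structure", {
  sim <- simulate_dataset(simulation_config(seed = 61))
  cfg <- sim$config

  # LAD lengths within the configured range; realized coverage near target
  lens <- sim$lads$end - sim$lads$start
  expect_true(all(lens <= cfg$lad_length_range[2L]))
  expect_lt(abs(sim$truth$lad_fraction_realized - cfg$lad_genome_fraction),
            0.05)

  # lamin signal is bimodal with modes separated by ~2*mu
  tile_mid <- floor((sim$lamin$start + sim$lamin$end) / 2)
  in_lad <- vapply(tile_mid, function(p)
    any(p >= sim$lads$start & p < sim$lads$end), logical(1L))
  sep <- mean(sim$lamin$value[in_lad]) - mean(sim$lamin$value[!in_lad])
  expect_lt(abs(sep - 2 * cfg$lamin_mu), 0.15)

  # probe damage effect: mean inside-LAD minus outside ~ oxo_delta
  d <- mean(sim$probes$value[sim$truth$probe_in_lad]) -
    mean(sim$probes$value[!sim$truth$probe_in_lad])
  expect_lt(abs(d - cfg$oxo_delta), 4 * cfg$oxo_sd / sqrt(1000))

  # probes roughly every probe_spacing bases
  expect_equal(nrow(sim$probes),
               length(seq(0, 20e6 - 60, by = cfg$probe_spacing)))

  # gene placement odds: P(5' in LAD) from realized lengths, binomial 99%
  lad_len <- sum(lens)
  inter_len <- sum(cfg$chrom_lengths) - lad_len
  p_lad <- lad_len / (lad_len + cfg$gene_density_ratio * inter_len)
  n_in <- sum(sim$truth$gene_in_lad)
  bounds <- stats::qbinom(c(0.005, 0.995), cfg$n_genes, p_lad)
  expect_gte(n_in, bounds[1L])
  expect_lte(n_in, bounds[2L])

  # emitted files agree with the in-memory objects
  d <- tempfile()
  paths <- write_dataset(sim, d)
  expect_equal(nrow(read_interval_values(paths[["lamin"]])),
               nrow(sim$lamin))
  genes_back <- read_genes_bed(paths[["genes"]])
  expect_setequal(genes_back$gene_id, sim$genes$gene_id)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$oxo_delta, cfg$oxo_delta)
})

test_that("a null world has no damage effect", {
  sim0 <- simulate_dataset(simulation_config(seed = 62, oxo_delta = 0))
  fr <- fragment_profiles(sim0$assembly, sim0$probes, sim0$lamin)
  sp <- split_by_cutoff(fr)
  gs <- group_stats(sp$positive, sp$negative)
  se <- abs(gs$diff / gs$comparison$t_stat)
  expect_lt(abs(gs$diff), 3 * se)
})

test_that("chain pair with no events is the identity", {
  cfg <- simulation_config(seed = 63, chrom_lengths = c(chrZ = 1e6),
                           chain_event_rate = 0, chain_inversion = FALSE)
  pair <- simulate_chain_pair(cfg)
  expect_equal(pair$assembly2$length, 1e6)
  expect_true(all(pair$truth$expected_status == "mapped"))
  m <- map_interval("chrZ", 123456, 133456, pair$chains_fwd)
  expect_equal(c(m$start, m$end), c(123456, 133456))
})

test_that("chain-pair mapping outcomes match the event-derived truth", {
  for (seed in c(64, 65)) {
    cfg <- simulation_config(seed = seed, chain_event_rate = 1)
    pair <- simulate_chain_pair(cfg)
    expect_gt(nrow(pair$events), 0L)
    tt <- pair$truth
    # spot-check every status class plus a random sample of tiles
    idx <- unique(c(vapply(unique(tt$expected_status), function(s)
      which(tt$expected_status == s)[1L], 0L),
      withr::with_seed(seed, sample.int(nrow(tt), 200))))
    for (i in idx) {
      m <- map_interval(tt$chrom[i], tt$start[i], tt$end[i],
                        pair$chains_fwd, min_blocks = 0.1)
      expect_identical(m$status, tt$expected_status[i],
                       label = sprintf("tile %d status", i))
      if (m$status == "mapped") {
        expect_equal(c(m$start, m$end),
                     c(tt$dest_start[i], tt$dest_end[i]),
                     label = sprintf("tile %d span", i))
      }
    }
    # deletions produce 'deleted' tiles somewhere when a deletion spans
    # a full tile
    dels <- pair$events[pair$events$type == "del", , drop = FALSE]
    if (any(dels$len >= 20000))
      expect_true(any(tt$expected_status == "deleted"))
  }
})

test_that("inverted segments are mapped with reflected coordinates", {
  cfg <- simulation_config(seed = 66, chain_event_rate = 0,
                           chain_inversion = TRUE)
  pair <- simulate_chain_pair(cfg)
  inv_chain <- Filter(function(ch) ch$q_strand == "-", pair$chains_fwd)
  expect_length(inv_chain, 1L)
  inv <- inv_chain[[1L]]
  # a tile strictly inside the inversion, checked against the per-base
  # walk oracle
  s <- inv$t_start + 1000
  got <- map_interval(inv$t_name, s, s + 5000, pair$chains_fwd)
  want <- oracle_map_interval(inv$t_name, s, s + 5000, pair$chains_fwd)
  expect_identical(got$status, "mapped")
  expect_equal(c(got$start, got$end), c(want$start, want$end))
  expect_equal(got$strand, "-")
  # and against the event-derived truth table
  tt <- pair$truth
  i <- which(tt$start == (s %/% 10000) * 10000)
  if (tt$expected_status[i] == "mapped") {
    m <- map_interval(tt$chrom[i], tt$start[i], tt$end[i], pair$chains_fwd)
    expect_equal(c(m$start, m$end), c(tt$dest_start[i], tt$dest_end[i]))
  }
})
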