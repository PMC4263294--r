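# Pipeline orchestration: subcommands over the analysis stages with a JSON
# config file, CLI flag overrides (precedence CLI > config > defaults),
# deterministic outputs and a run-log per command. Every record exclusion
# is counted and logged; nothing is dropped silently.

pipeline_defaults <- function() {
  list(out = ".",
       probes = NULL,          # one or more probe bedGraph/TSV paths
       probe_mode = "ratio",
       genes = NULL,
       expression = NULL,
       lamin = NULL,
       chain = NULL,
       chrom_sizes = NULL,
       halfwidth = 500000,
       window = 1e6,
       bin_size = 1e6,
       fragment_size = 200000,
       min_probes = 1,
       min_blocks = 0.1,
       best_chain = FALSE,
       cutoff = 0,
       gene_rule = "tss",
       welch = FALSE,
       n_iter = 1000,
       seed = NULL,
       cap = 10)
}

#' Build a pipeline configuration
#'
#' Merges, in increasing precedence: package defaults, a JSON config file,
#' and direct overrides.
#'
#' @param config_file Optional path to a JSON object of settings.
#' @param ... Direct overrides of individual settings.
#' @return A named list of settings (class `pipeline_config`).
#' @export
pipeline_config <- function(config_file = NULL, ...) {
  cfg <- pipeline_defaults()
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      oxo_usage_error("config file not found: %s", config_file)
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown) > 0L)
      oxo_usage_error("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1L))]
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    oxo_usage_error("unknown setting(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

require_inputs <- function(cfg, keys) {
  for (k in keys) {
    v <- cfg[[k]]
    if (is.null(v)) oxo_usage_error("required input '%s' not set", k)
    for (p in v) if (!file.exists(p))
      oxo_usage_error("input file for '%s' not found: %s", k, p)
  }
}

config_hash <- function(cfg) {
  # path-valued settings enter the hash by basename so that identical runs
  # rooted in different directories hash identically
  for (k in c("out", "probes", "genes", "expression", "lamin", "chain",
              "chrom_sizes"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- basename(cfg[[k]])
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_runlog <- function(cfg, command, counts, outputs) {
  log <- list(tool = "oxomap",
              version = as.character(utils::packageVersion("oxomap")),
              command = command,
              config_hash = config_hash(unclass(cfg)),
              seed = cfg$seed,
              counts = counts,
              outputs = basename(unname(outputs)))  # relative: keeps
              # runs in different directories byte-comparable
  path <- file.path(cfg$out, sprintf("%s_runlog.json", command))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

load_probes <- function(cfg) {
  tracks <- lapply(cfg$probes, read_probe_table, mode = cfg$probe_mode)
  merged <- merge_replicates(tracks)
  attr(merged, "read_dropped") <- sum(vapply(tracks, attr, 0L, "dropped"))
  merged
}

# ---- subcommands -----------------------------------------------------------

cmd_simulate <- function(cfg) {
  if (is.null(cfg$seed)) oxo_usage_error("cmd_simulate: --seed is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(simulation_config(seed = cfg$seed))
  paths <- write_dataset(sim, cfg$out)
  pair <- simulate_chain_pair(sim$config)
  chain_path <- file.path(cfg$out, "toy.chain")
  write_chain(pair$chains_rev, chain_path)  # derived -> native, as consumed
  write_chain(pair$chains_fwd, file.path(cfg$out, "toy_fwd.chain"))
  write_chrom_sizes(pair$assembly2, file.path(cfg$out, "chrom2.sizes"))
  # the lamin profile is delivered on the derived assembly, as a foreign
  # DamID track would be, and lifted back by cmd_liftover
  foreign <- map_profile(sim$lamin, pair$chains_fwd,
                         min_blocks = cfg$min_blocks)
  write_bedgraph(foreign$mapped, file.path(cfg$out, "lamin_foreign.bedgraph"))
  counts <- list(probes = nrow(sim$probes), genes = nrow(sim$genes),
                 lamin_tiles = nrow(sim$lamin),
                 lamin_foreign = nrow(foreign$mapped))
  outputs <- c(paths, chain = chain_path)
  write_runlog(cfg, "simulate", counts, outputs)
  outputs
}

cmd_smooth <- function(cfg) {
  require_inputs(cfg, "probes")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  probes <- load_probes(cfg)
  sm <- smooth_per_probe(probes, halfwidth = cfg$halfwidth)
  out1 <- file.path(cfg$out, "smoothed.bedgraph")
  write_bedgraph(data.frame(chrom = sm$chrom, start = sm$start,
                            end = sm$end, value = sm$smoothed), out1)
  track <- window_track(probes, window = cfg$window,
                        min_probes = cfg$min_probes,
                        assembly = if (!is.null(cfg$chrom_sizes))
                          read_chrom_sizes(cfg$chrom_sizes) else NULL)
  out2 <- file.path(cfg$out, "windows.bedgraph")
  write_bedgraph(track[, c("chrom", "start", "end", "value")], out2)
  write_runlog(cfg, "smooth",
               list(probes_used = nrow(probes),
                    probes_dropped_read = attr(probes, "read_dropped"),
                    probes_dropped_merge = attr(probes, "dropped")),
               c(out1, out2))
  c(out1, out2)
}

cmd_bins <- function(cfg) {
  require_inputs(cfg, c("probes", "genes", "chrom_sizes"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  probes <- load_probes(cfg)
  genes <- read_genes_bed(cfg$genes)
  assembly <- read_chrom_sizes(cfg$chrom_sizes)
  bins <- make_bins(assembly, cfg$bin_size)
  bins <- mean_signal_per_bin(bins, probes, min_probes = cfg$min_probes)
  bins <- count_genes_per_bin(bins, genes, rule = cfg$gene_rule)
  assoc <- density_association(bins, cap = cfg$cap)
  out1 <- file.path(cfg$out, "bins.tsv")
  write_tsv(bins[, c("chrom", "start", "end", "n_probes", "mean_signal",
                     "gene_count")], out1)
  out2 <- file.path(cfg$out, "density_groups.tsv")
  write_tsv(assoc$groups, out2)
  out3 <- file.path(cfg$out, "density_stats.tsv")
  write_tsv(data.frame(pearson_r = assoc$pearson_r,
                       r_pvalue = assoc$r_pvalue,
                       n_bins_used = assoc$n_bins_used), out3)
  write_runlog(cfg, "bins",
               list(probes_used = nrow(probes), n_bins = nrow(bins),
                    n_bins_with_signal = assoc$n_bins_used,
                    genes = nrow(genes)),
               c(out1, out2, out3))
  c(out1, out2, out3)
}

cmd_expression <- function(cfg) {
  require_inputs(cfg, c("probes", "genes", "expression"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  probes <- load_probes(cfg)
  genes <- read_genes_bed(cfg$genes)
  genes <- attach_expression(genes, read_expression_tsv(cfg$expression))
  genes <- genic_signal(genes, probes)
  var_equal <- !isTRUE(cfg$welch)
  rows <- list()
  per_gene <- NULL
  for (spec in list(list(mode = "median", q = NA),
                    list(mode = "top_bottom", q = 0.25),
                    list(mode = "top_bottom", q = 0.10))) {
    sp <- if (spec$mode == "median") split_by_expression(genes, "median")
          else split_by_expression(genes, "top_bottom", q = spec$q)
    cmp <- compare_groups(sp$high$genic_signal, sp$low$genic_signal,
                          var_equal = var_equal)
    label <- if (spec$mode == "median") "median" else
      sprintf("top_bottom_%g", spec$q)
    rows[[label]] <- data.frame(split = label, n_high = cmp$group_a_n,
                                n_low = cmp$group_b_n, mean_high = cmp$mean_a,
                                mean_low = cmp$mean_b, t_stat = cmp$t_stat,
                                df = cmp$df, p_value = cmp$p_value)
    if (spec$mode == "median") {
      per_gene <- rbind(
        data.frame(sp$high[, c("gene_id", "expression", "genic_signal")],
                   group = "high"),
        data.frame(sp$low[, c("gene_id", "expression", "genic_signal")],
                   group = "low"))
      hist_df <- two_group_histogram(sp$high$genic_signal,
                                     sp$low$genic_signal)
      names(hist_df)[3:4] <- c("n_high", "n_low")
    }
  }
  out1 <- file.path(cfg$out, "expression_genes.tsv")
  write_tsv(per_gene, out1)
  out2 <- file.path(cfg$out, "expression_tests.tsv")
  write_tsv(do.call(rbind, rows), out2)
  out3 <- file.path(cfg$out, "expression_histogram.tsv")
  write_tsv(hist_df, out3)
  write_runlog(cfg, "expression",
               list(genes = nrow(genes),
                    genes_missing_expression = attr(genes,
                                                    "n_missing_expression"),
                    genes_without_probes = sum(is.na(genes$genic_signal))),
               c(out1, out2, out3))
  c(out1, out2, out3)
}

cmd_liftover <- function(cfg) {
  require_inputs(cfg, c("lamin", "chain"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  lamin <- read_interval_values(cfg$lamin)
  chains <- parse_chain(cfg$chain)
  res <- map_profile(lamin, chains, min_blocks = cfg$min_blocks,
                     best_chain = isTRUE(cfg$best_chain))
  out1 <- file.path(cfg$out, "lamin_lifted.bedgraph")
  write_bedgraph(res$mapped, out1)
  out2 <- file.path(cfg$out, "liftover_unmapped.tsv")
  write_tsv(res$unmapped, out2)
  out3 <- file.path(cfg$out, "liftover_report.tsv")
  write_tsv(res$report, out3)
  write_runlog(cfg, "liftover",
               c(list(intervals_in = nrow(lamin)),
                 stats::setNames(as.list(res$report$n), res$report$reason)),
               c(out1, out2, out3))
  c(out1, out2, out3)
}

cmd_lads <- function(cfg) {
  require_inputs(cfg, c("probes", "lamin", "chrom_sizes"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  probes <- load_probes(cfg)
  lamin <- read_interval_values(cfg$lamin)
  assembly <- read_chrom_sizes(cfg$chrom_sizes)
  frags <- fragment_profiles(assembly, probes, lamin,
                             fragment_size = cfg$fragment_size,
                             min_probes = cfg$min_probes)
  sp <- split_by_cutoff(frags, cutoff = cfg$cutoff)
  gs <- group_stats(sp$positive, sp$negative, var_equal = !isTRUE(cfg$welch))
  out1 <- file.path(cfg$out, "fragments.tsv")
  write_tsv(frags[, c("chrom", "start", "end", "n_probes", "mean_signal",
                      "lamin", "lamin_coverage")], out1)
  out2 <- file.path(cfg$out, "lad_groups.tsv")
  write_tsv(data.frame(group = c("positive", "negative"),
                       n = c(nrow(sp$positive), nrow(sp$negative)),
                       mean_signal = c(gs$mean_positive, gs$mean_negative),
                       t_stat = gs$comparison$t_stat, df = gs$comparison$df,
                       p_value = gs$comparison$p_value), out2)
  grid <- density_grid(frags)
  gdf <- as.data.frame(grid)
  names(gdf) <- sprintf("signal_bin_%d", seq_len(ncol(gdf)))
  out3 <- file.path(cfg$out, "lad_grid.tsv")
  write_tsv(gdf, out3)
  hist_df <- two_group_histogram(sp$positive$mean_signal,
                                 sp$negative$mean_signal)
  names(hist_df)[3:4] <- c("n_positive", "n_negative")
  out4 <- file.path(cfg$out, "lad_histogram.tsv")
  write_tsv(hist_df, out4)
  write_runlog(cfg, "lads",
               list(fragments = nrow(frags),
                    fragments_excluded = attr(frags, "n_excluded"),
                    n_positive = nrow(sp$positive),
                    n_negative = nrow(sp$negative)),
               c(out1, out2, out3, out4))
  c(out1, out2, out3, out4)
}

cmd_permtest <- function(cfg) {
  require_inputs(cfg, c("probes", "lamin", "chrom_sizes"))
  if (is.null(cfg$seed)) oxo_usage_error("cmd_permtest: --seed is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  probes <- load_probes(cfg)
  lamin <- read_interval_values(cfg$lamin)
  assembly <- read_chrom_sizes(cfg$chrom_sizes)
  frags <- fragment_profiles(assembly, probes, lamin,
                             fragment_size = cfg$fragment_size,
                             min_probes = cfg$min_probes)
  pr <- permutation_test(frags, cutoff = cfg$cutoff, n_iter = cfg$n_iter,
                         seed = cfg$seed)
  out1 <- file.path(cfg$out, "permutation.tsv")
  write_tsv(data.frame(observed_diff = pr$observed_diff,
                       null_mean = pr$null_mean, null_sd = pr$null_sd,
                       z_score = pr$z_score, empirical_p = pr$empirical_p,
                       n_iter = pr$n_iter, seed = pr$seed,
                       n_positive = pr$n_positive,
                       n_negative = pr$n_negative), out1)
  write_runlog(cfg, "permtest",
               list(fragments = nrow(frags),
                    fragments_excluded = attr(frags, "n_excluded")),
               out1)
  out1
}

cmd_all <- function(cfg) {
  if (is.null(cfg$seed)) oxo_usage_error("cmd_all: --seed is required")
  root <- cfg$out
  step <- function(sub, fn, cfg) {
    cfg$out <- file.path(root, sub)
    fn(cfg)
  }
  sim_paths <- step("simulate", cmd_simulate, cfg)
  simdir <- file.path(root, "simulate")
  cfg$probes <- file.path(simdir, "probes.bedgraph")
  cfg$genes <- file.path(simdir, "genes.bed")
  cfg$expression <- file.path(simdir, "expression.tsv")
  cfg$chrom_sizes <- file.path(simdir, "chrom.sizes")
  cfg$chain <- file.path(simdir, "toy.chain")
  cfg$lamin <- file.path(simdir, "lamin_foreign.bedgraph")
  step("smooth", cmd_smooth, cfg)
  step("bins", cmd_bins, cfg)
  step("expression", cmd_expression, cfg)
  step("liftover", cmd_liftover, cfg)
  cfg$lamin <- file.path(root, "liftover", "lamin_lifted.bedgraph")
  step("lads", cmd_lads, cfg)
  step("permtest", cmd_permtest, cfg)
  invisible(root)
}

# ---- CLI -------------------------------------------------------------------

cli_help <- function() {
  cat("usage: oxomap <command> [--config file.json] [--key value ...]\n",
      "commands: simulate | smooth | bins | expression | liftover | lads |\n",
      "          permtest | all\n",
      "common flags: --out DIR --seed INT --probes FILE[,FILE] --genes FILE\n",
      "  --expression FILE --lamin FILE --chain FILE --chrom-sizes FILE\n",
      "  --halfwidth BP --window BP --bin-size BP --fragment-size BP\n",
      "  --min-blocks FRAC --cutoff X --n-iter N --gene-rule tss|overlap\n",
      "  --welch --best-chain\n", sep = "")
}

parse_cli_flags <- function(args) {
  flags <- list()
  logical_flags <- c("welch", "best_chain")
  numeric_keys <- c("halfwidth", "window", "bin_size", "fragment_size",
                    "min_probes", "min_blocks", "cutoff", "n_iter", "seed",
                    "cap")
  i <- 1L
  config_file <- NULL
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) oxo_usage_error("unexpected argument: %s", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (key == "config") {
      config_file <- args[i + 1L]
      i <- i + 2L
    } else if (key %in% logical_flags) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i + 1L > length(args))
        oxo_usage_error("flag %s needs a value", a)
      v <- args[i + 1L]
      if (key %in% numeric_keys) v <- as.numeric(v)
      if (key == "probes") v <- strsplit(v, ",")[[1L]]
      flags[[key]] <- v
      i <- i + 2L
    }
  }
  list(config_file = config_file, flags = flags)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Returns (invisibly) an exit
#' status: 0 success, 1 data error, 2 usage error; the `inst/exec/oxomap`
#' wrapper forwards it to the shell. Partial outputs of a failed command
#' are removed.
#'
#' @param args Character vector of CLI arguments (default: the process
#'   command line).
#' @return Invisibly, the integer exit status.
#' @export
oxomap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    cli_help()
    return(invisible(0L))
  }
  command <- args[1L]
  handlers <- list(simulate = cmd_simulate, smooth = cmd_smooth,
                   bins = cmd_bins, expression = cmd_expression,
                   liftover = cmd_liftover, lads = cmd_lads,
                   permtest = cmd_permtest, all = cmd_all)
  run <- function() {
    if (!command %in% names(handlers))
      oxo_usage_error("unknown command: %s", command)
    parsed <- parse_cli_flags(args[-1L])
    cfg <- do.call(pipeline_config,
                   c(list(config_file = parsed$config_file), parsed$flags))
    before <- list.files(cfg$out, recursive = TRUE, full.names = TRUE)
    tryCatch(handlers[[command]](cfg), error = function(e) {
      after <- list.files(cfg$out, recursive = TRUE, full.names = TRUE)
      unlink(setdiff(after, before))
      stop(e)
    })
  }
  status <- tryCatch({
    run()
    0L
  }, oxomap_usage_error = function(e) {
    message("oxomap: ", conditionMessage(e))
    2L
  }, error = function(e) {
    message("oxomap: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
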