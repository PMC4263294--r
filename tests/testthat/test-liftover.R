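identity_chain_file <- function(len = 1000L) {
  write_lines_tmp(c(sprintf("chain 1000 chrT %d + 0 %d chrQ %d + 0 %d 1",
                            len, len, len, len),
                    sprintf("%d", len), ""), ".chain")
}

test_that("parse_chain reads valid chains and rejects inconsistent ones", {
  cs <- parse_chain(identity_chain_file())
  expect_length(cs, 1L)
  expect_equal(cs[[1L]]$size, 1000)

  bad <- write_lines_tmp(c("chain 1000 chrT 1000 + 0 1000 chrQ 1000 + 0 1000 1",
                           "900", ""), ".chain")
  expect_error(parse_chain(bad), "chain 1.*span")

  toy <- write_lines_tmp(c(
    "chain 111 chrT 5000 + 0 250 chrQ 5000 + 0 200 7",
    "100\t50\t0", "100", "",
    "chain 222 chrT 5000 + 1000 1100 chrQ 5000 - 0 100 8",
    "100", "",
    "chain 333 chrT 5000 + 2000 2600 chrQ 9000 + 100 650 9",
    "200\t100\t50", "300", ""), ".chain")
  cs3 <- parse_chain(toy)
  expect_length(cs3, 3L)
  expect_equal(vapply(cs3, `[[`, 0, "score"), c(111, 222, 333))
  expect_equal(cs3[[2L]]$q_strand, "-")
})

test_that("map_interval implements the minimum mapped-fraction rule", {
  # two 100 bp blocks separated by a 50 bp source gap: interval [0,250)
  # has 200/250 = 0.8 aligned, envelope q [0,200)
  ch <- make_chain("chrT", 0, c(100, 100), 50, 0, "chrQ", 10000, "+", 0, 1)
  cs <- chain_set_of(ch)
  m <- map_interval("chrT", 0, 250, cs, min_blocks = 0.1)
  expect_equal(m$status, "mapped")
  expect_equal(c(m$start, m$end), c(0, 200))
  expect_equal(m$mapped_fraction, 0.8)

  # interval entirely in the source gap: no aligned base
  expect_equal(map_interval("chrT", 100, 150, cs)$status, "deleted")
  # fraction below the threshold
  expect_equal(map_interval("chrT", 99, 150, cs, min_blocks = 0.1)$status,
               "partially_deleted")
  # raising min_blocks can only lose mappings (monotonicity)
  expect_equal(map_interval("chrT", 0, 250, cs, min_blocks = 0.9)$status,
               "partially_deleted")

  idc <- parse_chain(identity_chain_file())
  mi <- map_interval("chrT", 123, 456, idc)
  expect_equal(c(mi$start, mi$end), c(123, 456))
})

test_that("minus-strand chains reflect coordinates", {
  # t [100,300) aligned to the reverse strand of a 500 bp destination;
  # with qStart 50 on the minus strand, + strand envelope is
  # [500 - 250, 500 - 50) = [250, 450)
  ch <- make_chain("chrT", 100, 200, numeric(0), numeric(0), "chrQ", 500,
                   "-", 50, 1)
  m <- map_interval("chrT", 100, 300, chain_set_of(ch))
  expect_equal(m$status, "mapped")
  expect_equal(c(m$start, m$end), c(250, 450))
  o <- oracle_map_interval("chrT", 100, 300, chain_set_of(ch))
  expect_equal(c(o$start, o$end), c(m$start, m$end))
})

test_that("ambiguity fails closed unless best-chain selection is requested", {
  ch1 <- make_chain("chrT", 0, 100, numeric(0), numeric(0), "cB1", 1000,
                    "+", 0, 1, score = 500)
  ch2 <- make_chain("chrT", 0, 100, numeric(0), numeric(0), "cB2", 1000,
                    "+", 200, 2, score = 900)
  cs <- chain_set_of(ch1, ch2)
  expect_equal(map_interval("chrT", 0, 100, cs)$status, "ambiguous")
  best <- map_interval("chrT", 0, 100, cs, best_chain = TRUE)
  expect_equal(best$status, "mapped")
  expect_equal(best$chain_id, "2")   # higher score wins
})

test_that("mapping agrees with the per-base walk oracle on random chains", {
  withr::local_seed(41)
  n_checked <- 0L
  for (rep in seq_len(30)) {
    cs <- random_chain_set(n_chains = sample(1:4, 1L))
    for (k in seq_len(5)) {
      s <- sample(0:4800, 1L)
      e <- s + sample(10:400, 1L)
      got <- map_interval("cA", s, e, cs)
      want <- oracle_map_interval("cA", s, e, cs)
      expect_identical(got$status, want$status)
      if (got$status == "mapped") {
        expect_identical(got$chrom, want$chrom)
        expect_identical(c(got$start, got$end), c(want$start, want$end))
      }
      # monotonicity in min_blocks: a hard failure never becomes a success
      # when tightening (ambiguity can resolve, so it is exempt)
      if (got$status %in% c("deleted", "partially_deleted"))
        expect_false(map_interval("cA", s, e, cs,
                                  min_blocks = 1)$status == "mapped")
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("map_profile carries values, reports failures, drops collisions", {
  idc <- parse_chain(identity_chain_file(100000L))
  track <- data.frame(chrom = "chrT", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100), value = 1:10)
  res <- map_profile(track, idc)
  expect_equal(res$mapped[, c("start", "end", "value")],
               track[, c("start", "end", "value")])
  expect_equal(res$report$n[res$report$reason == "mapped"], 10L)

  # chain with a 100 bp source deletion swallowing interval [100,200)
  ch <- make_chain("chrT", 0, c(100, 800), 100, 0, "chrQ", 10000, "+", 0, 1)
  res2 <- map_profile(track, chain_set_of(ch))
  expect_equal(nrow(res2$mapped), 9L)
  expect_equal(res2$unmapped$reason, "deleted")
  expect_equal(res2$unmapped$start, 100)

  # two source intervals landing on the same destination collide; the
  # later one is dropped and counted
  ch_a <- make_chain("chrT", 0, 100, numeric(0), numeric(0), "chrQ", 1000,
                     "+", 0, 1)
  ch_b <- make_chain("chrT", 5000, 100, numeric(0), numeric(0), "chrQ", 1000,
                     "+", 50, 2)
  twice <- data.frame(chrom = "chrT", start = c(0, 5000), end = c(100, 5100),
                      value = c(1, 2))
  res3 <- map_profile(twice, chain_set_of(ch_a, ch_b))
  expect_equal(nrow(res3$mapped), 1L)
  expect_equal(res3$mapped$value, 1)
  expect_equal(res3$report$n[res3$report$reason == "collision"], 1L)

  # strand flip: values preserved, output sorted on the destination
  flip <- make_chain("chrT", 0, 1000, numeric(0), numeric(0), "chrQ", 1000,
                     "-", 0, 1)
  res4 <- map_profile(track, chain_set_of(flip))
  expect_equal(res4$mapped$value, 10:1)
  expect_true(all(diff(res4$mapped$start) > 0))
})

test_that("write_chain / parse_chain round-trip preserves geometry", {
  withr::local_seed(42)
  cs <- random_chain_set(3L)
  p <- tempfile(fileext = ".chain")
  write_chain(cs, p)
  back <- parse_chain(p)
  for (i in seq_along(cs)) {
    for (f in c("score", "t_start", "t_end", "q_start", "q_end", "q_strand"))
      expect_equal(back[[i]][[f]], cs[[i]][[f]])
    expect_equal(back[[i]]$size, cs[[i]]$size)
    expect_equal(back[[i]]$t_block, cs[[i]]$t_block)
    expect_equal(back[[i]]$q_block, cs[[i]]$q_block)
  }
})
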