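toy_fragments <- function(lamin, signal, size = 1000) {
  n <- length(lamin)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * size,
             end = seq_len(n) * size, n_probes = 1L,
             mean_signal = signal, lamin = lamin)
}

test_that("fragment lamin averages are weighted over covered bases only", {
  a <- genome_assembly("chr1", 1000)
  probes <- data.frame(chrom = "chr1", start = 0, end = 60, value = 1)
  frag <- function(lamin) fragment_profiles(a, probes, lamin,
                                            fragment_size = 1000)
  full <- frag(data.frame(chrom = "chr1", start = 0, end = 1000, value = 4))
  expect_equal(full$lamin, 4)
  half <- frag(data.frame(chrom = "chr1", start = 0, end = 500, value = 2))
  expect_equal(half$lamin, 2)        # uncovered half carries no weight
  expect_equal(half$lamin_coverage, 500)
  split <- frag(data.frame(chrom = "chr1", start = c(0, 500),
                           end = c(500, 1000), value = c(-1, 3)))
  expect_equal(split$lamin, 1)
  none <- frag(data.frame(chrom = "chr2", start = 0, end = 100, value = 9))
  expect_true(is.na(none$lamin))
  expect_equal(attr(none, "n_excluded"), 1L)
})

test_that("cutoff split sends exact-cutoff fragments to the negative group", {
  fr <- toy_fragments(lamin = c(-1, 1), signal = c(0, 0))
  sp <- split_by_cutoff(fr)
  expect_equal(nrow(sp$positive), 1L)
  expect_equal(nrow(sp$negative), 1L)

  tie <- toy_fragments(lamin = c(0, 1), signal = c(0, 0))
  expect_equal(split_by_cutoff(tie)$negative$lamin, 0)
  expect_error(split_by_cutoff(toy_fragments(c(1, 2), c(0, 0))), "empty")

  withr::local_seed(51)
  lam <- c(rnorm(60, -2, 0.5), rnorm(40, 2, 0.5))
  sp2 <- split_by_cutoff(toy_fragments(lam, rnorm(100)))
  expect_equal(nrow(sp2$positive), sum(lam > 0))
  expect_equal(nrow(sp2$negative), sum(lam <= 0))
})

test_that("group_stats recovers a constructed group gap", {
  withr::local_seed(52)
  pos <- toy_fragments(rep(1, 500), rnorm(500, 0.38, 0.01))
  neg <- toy_fragments(rep(-1, 500), rnorm(500, 0, 0.01))
  gs <- group_stats(pos, neg)
  se <- gs$diff / gs$comparison$t_stat
  expect_lt(abs(gs$diff - 0.38), 3 * se)
  expect_error(group_stats(toy_fragments(c(1, 1), c(2, 2)),
                           toy_fragments(c(-1, -1), c(2, 2))), "variance")
  expect_error(compare_groups(1, 2), ">= 2")
})

test_that("permutation test is seeded, reproducible and exchangeable", {
  withr::local_seed(53)
  fr <- toy_fragments(lamin = c(rnorm(40, 2, 0.5), rnorm(60, -2, 0.5)),
                      signal = rnorm(100))
  p1 <- permutation_test(fr, n_iter = 500, seed = 9)
  p2 <- permutation_test(fr, n_iter = 500, seed = 9)
  expect_identical(p1$z_score, p2$z_score)
  expect_identical(p1$empirical_p, p2$empirical_p)
  # two seeds agree on the null location within Monte-Carlo error
  p3 <- permutation_test(fr, n_iter = 500, seed = 10)
  expect_lt(abs(p1$null_mean - p3$null_mean),
            4 * p1$null_sd / sqrt(p1$n_iter))
  expect_equal(p1$z_score, (p1$observed_diff - p1$null_mean) / p1$null_sd)

  expect_error(permutation_test(toy_fragments(c(-1, 1), c(0, 1)),
                                n_iter = 10), ">= 10")
  const <- toy_fragments(lamin = rnorm(20), signal = rep(2, 20))
  expect_error(permutation_test(const, n_iter = 100, seed = 1),
               "degenerate")
})

test_that("permutation null is calibrated and detects planted effects", {
  withr::local_seed(54)
  # null: lamin labels independent of signal; |z| < 3 should be the norm
  zs <- vapply(seq_len(100), function(i) {
    fr <- toy_fragments(lamin = rnorm(80), signal = rnorm(80))
    permutation_test(fr, n_iter = 200, seed = i)$z_score
  }, numeric(1L))
  expect_lte(sum(abs(zs) >= 3), 2L)

  # strong planted effect over >= 1000 fragments
  lam <- c(rnorm(400, 2, 0.3), rnorm(600, -2, 0.3))
  sig <- 0.5 * (lam > 0) + rnorm(1000, 0, 0.3)
  pr <- permutation_test(toy_fragments(lam, sig), n_iter = 1000, seed = 55)
  expect_gt(pr$z_score, 10)
  expect_equal(pr$empirical_p, 1 / 1001)
})

test_that("effect sizes are recovered across a simulation grid", {
  for (delta in c(0, 0.1, 0.38)) {
    for (sigma in c(0.3, 0.5)) {
      cfg <- simulation_config(seed = 560 + round(1000 * delta + 10 * sigma),
                               oxo_delta = delta, oxo_sd = sigma)
      sim <- simulate_dataset(cfg)
      fr <- fragment_profiles(sim$assembly, sim$probes, sim$lamin)
      sp <- split_by_cutoff(fr)
      gs <- group_stats(sp$positive, sp$negative)
      se <- abs(gs$diff / gs$comparison$t_stat)
      expect_lt(abs(gs$diff - delta), 3 * se)
    }
  }
})

test_that("density grid tallies fragments exactly", {
  one <- toy_fragments(0.5, 1.5)
  g1 <- density_grid(one, 4, 4)
  expect_equal(sum(g1), 1L)

  four <- toy_fragments(c(-1, -1, 1, 1), c(-2, 2, -2, 2))
  g2 <- density_grid(four, 2, 2)
  expect_equal(unclass(g2)[1:2, 1:2], matrix(1L, 2, 2), ignore_attr = TRUE)
  expect_equal(sum(g2), 4L)

  withr::local_seed(56)
  fr <- toy_fragments(rnorm(200), rnorm(200))
  expect_equal(sum(density_grid(fr, 5, 7)), 200L)
  expect_equal(sum(density_grid(fr, 31, 13)), 200L)  # refinement conserves
})
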