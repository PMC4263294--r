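test_that("genic signal averages probes inside the transcribed span", {
  probes <- data.frame(chrom = "chr1", start = c(100, 300, 900),
                       end = c(160, 360, 960), value = c(1, 3, 50))
  genes <- data.frame(gene_id = c("g1", "gnone", "gnested"), chrom = "chr1",
                      strand = "+", tx_start = c(50, 2000, 250),
                      tx_end = c(500, 3000, 500))
  gs <- genic_signal(genes, probes)
  expect_equal(gs$genic_signal[gs$gene_id == "g1"], 2)       # mean(1, 3)
  expect_true(is.na(gs$genic_signal[gs$gene_id == "gnone"]))
  # nested/overlapping genes each average their own probes independently
  expect_equal(gs$genic_signal[gs$gene_id == "gnested"], 3)
})

test_that("expression splits partition and discard as specified", {
  g <- function(expr) data.frame(gene_id = sprintf("g%02d", seq_along(expr)),
                                 expression = expr,
                                 genic_signal = 0.1 * seq_along(expr))
  sp <- split_by_expression(g(c(1, 2, 3, 4)), "median")
  expect_setequal(sp$high$expression, c(3, 4))
  expect_setequal(sp$low$expression, c(1, 2))

  sp10 <- split_by_expression(g(1:10), "top_bottom", q = 0.10)
  expect_equal(sp10$high$expression, 10)
  expect_equal(sp10$low$expression, 1)

  # ties at the median all go low: median of {1,2,2,3} is 2
  tie <- split_by_expression(g(c(1, 2, 2, 3)), "median")
  expect_setequal(tie$low$expression, c(1, 2, 2))
  expect_equal(tie$high$expression, 3)

  # partition properties under a larger random fixture
  withr::local_seed(31)
  gg <- g(rnorm(101))
  spm <- split_by_expression(gg, "median")
  expect_equal(sort(c(spm$high$gene_id, spm$low$gene_id)), sort(gg$gene_id))
  expect_length(intersect(spm$high$gene_id, spm$low$gene_id), 0L)
  spq <- split_by_expression(gg, "top_bottom", q = 0.25)
  expect_equal(nrow(spq$high), 25L)
  expect_equal(nrow(spq$low), 25L)
  expect_error(split_by_expression(g(c(1, 2, 3)), "median"), ">= 4")
})

test_that("compare_groups is the pooled-variance Student's t-test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  # hand-computed: means 2 and 5, pooled s^2 = 1, t = -3/sqrt(2/3)
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(cmp$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(cmp$df, 4)

  swapped <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t_stat, -cmp$t_stat)
  expect_equal(swapped$p_value, cmp$p_value)

  expect_error(compare_groups(c(1, 1), c(1, 1)), "variance")
  expect_error(compare_groups(1, c(1, 2)), ">= 2")
  welch <- compare_groups(c(1, 2, 3), c(4, 5, 9), var_equal = FALSE)
  expect_lt(welch$df, 4)
})

test_that("the t-test holds its nominal size under the null", {
  withr::local_seed(32)
  reject <- vapply(seq_len(1000), function(i) {
    compare_groups(rnorm(30), rnorm(30))$p_value < 0.05
  }, logical(1L))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("two_group_histogram shares edges and preserves counts", {
  h <- two_group_histogram(c(0, 1, 2), c(10, 11), breaks = 5)
  expect_equal(sum(h$n_a), 3L)
  expect_equal(sum(h$n_b), 2L)
  expect_equal(nrow(h), 5L)
  expect_equal(h$bin_start[1], 0)
  expect_equal(h$bin_end[5], 11)
})
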