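mk_track <- function(hdg, chrom = "chr1", span = 1000) {
  n <- length(hdg)
  structure(data.frame(
    sg_id = sprintf("SG%03d", seq_len(n)), chrom = chrom,
    start = span * (seq_len(n) - 1L), end = span * seq_len(n) - 100,
    hdg = hdg, stringsAsFactors = FALSE),
    class = c("hdg_track", "data.frame"))
}

test_that("low mask uses a strict bound and treats NA as not low", {
  tr <- mk_track(c(0.49, 0.50, NA, 0))
  expect_equal(low_hdg_mask(tr, 0.5), c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(low_hdg_mask(mk_track(rep(0, 5)))))
})

test_that("block merging enforces run length and strict adjacency", {
  tr12 <- mk_track(rep(0.1, 12))
  b <- merge_blocks(low_hdg_mask(tr12), tr12)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_sgs, 12L)
  tr9 <- mk_track(rep(0.1, 9))
  expect_equal(nrow(merge_blocks(low_hdg_mask(tr9), tr9)), 0L)
  # 10 low, 1 high, 10 low -> two blocks
  tr21 <- mk_track(c(rep(0.1, 10), 0.9, rep(0.1, 10)))
  b21 <- merge_blocks(low_hdg_mask(tr21), tr21)
  expect_equal(nrow(b21), 2L)
  expect_equal(b21$n_sgs, c(10L, 10L))
  # with a gap tolerance of 1 the same pattern is a single block
  b_gap <- merge_blocks(low_hdg_mask(tr21), tr21, max_gap = 1L)
  expect_equal(nrow(b_gap), 1L)
  expect_equal(b_gap$n_sgs, 21L)
})

test_that("block ids are ordered by descending genomic length per chrom", {
  hdgv <- c(rep(0.1, 10), rep(0.9, 3), rep(0.1, 15))
  tr <- mk_track(hdgv)
  b <- merge_blocks(low_hdg_mask(tr), tr)
  longer <- which.max(b$end - b$start)
  expect_equal(b$block_id[longer], "chr1#1")
  expect_equal(sort(b$block_id), c("chr1#1", "chr1#2"))
  # block span covers member SG anchors (half-open)
  expect_equal(b$start[b$block_id == "chr1#2"], tr$start[1])
  expect_equal(b$end[b$block_id == "chr1#2"], tr$end[10])
})

test_that("degenerate clustering tests behave at the extremes", {
  # every SG low: observed density is maximal, no replicate can exceed
  ct <- cluster_test(30L, 1:30, n_reps = 500L, seed = 1L)
  expect_true(all(ct$p == 0))
  # an empty window while low SGs exist elsewhere: almost always exceeded
  ct2 <- cluster_test(40L, 31:40, n_reps = 2000L, seed = 2L)
  expect_gt(ct2$p[1L], 0.9)
  expect_error(cluster_test(5L, 1:6), "more low SGs")
})

test_that("empirical P agrees with complete enumeration within 3 SE", {
  # 12 SGs, 3 low, all inside the first window of 10
  exact <- exact_window_p(12L, 1:3)
  ct <- cluster_test(12L, 1:3, n_reps = 20000L, seed = 5L)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_true(all(abs(ct$p - exact) <= pmax(3 * se, 1e-12)))
})

test_that("identical seeds reproduce the test bit-for-bit", {
  a <- cluster_test(50L, c(3:9, 20:24), n_reps = 3000L, seed = 99L)
  b <- cluster_test(50L, c(3:9, 20:24), n_reps = 3000L, seed = 99L)
  expect_identical(a, b)
  cc <- cluster_test(50L, c(3:9, 20:24), n_reps = 3000L, seed = 100L)
  expect_false(identical(a$p, cc$p))
})

test_that("the pseudocount mode lifts zero P values off the floor", {
  ct <- cluster_test(30L, 1:30, n_reps = 100L, seed = 1L,
                     pseudocount = TRUE)
  expect_true(all(ct$p == 1 / 101))
})

test_that("significance filtering is inclusive at alpha and annotates P", {
  tr <- mk_track(c(rep(0.1, 12), rep(0.9, 28)))
  mask <- low_hdg_mask(tr)
  blocks <- merge_blocks(mask, tr)
  tests <- cluster_test_track(tr, mask, n_reps = 1000L, seed = 3L)
  sig <- significant_blocks(blocks, tests, alpha = 0.01)
  expect_equal(nrow(sig), 1L)
  expect_true(sig$min_window_p <= 0.01)
  # inclusive boundary: alpha exactly equal to the block P keeps it
  sig2 <- significant_blocks(blocks, tests, alpha = sig$min_window_p)
  expect_equal(nrow(sig2), 1L)
  # a random scatter of low SGs yields no significant blocks
  set.seed(8)
  tr2 <- mk_track(ifelse(runif(60) < 0.2, 0.1, 0.9))
  m2 <- low_hdg_mask(tr2)
  b2 <- merge_blocks(m2, tr2)
  expect_equal(nrow(significant_blocks(
    b2, cluster_test_track(tr2, m2, n_reps = 500L, seed = 4L))), 0L)
})

test_that("block summaries report totals and framework fraction", {
  b <- data.frame(block_id = c("c1#1", "c1#2"), chrom = "c1",
                  start = c(0, 5e6), end = c(1e6, 7e6), n_sgs = c(20L, 30L),
                  mean_hdg = 0.1, stringsAsFactors = FALSE)
  s <- block_summary(b, framework_length = 1e8)
  expect_equal(s$n_blocks, 2L)
  expect_equal(s$total_bp, 3e6)
  expect_equal(s$fraction, 0.03)
  s0 <- block_summary(b[0, ], 1e8)
  expect_equal(s0$total_bp, 0)
  expect_equal(s0$fraction, 0)
})

test_that("null behaviour follows the exact window-count distribution and
           the inclusive rule is conservative", {
  # marginally, a window count is Hypergeom(n, k, window); under the strict
  # exceedance rule a window is called at P < 0.05 iff its observed count
  # reaches t = min{v : P(X > v) < 0.05}, so the expected fraction of such
  # windows is P(X >= t) -- above 0.05 by construction (discreteness)
  n <- 60L; k <- 12L; w <- 10L
  sf <- function(v) stats::phyper(v, k, n - k, w, lower.tail = FALSE)
  t <- min(which(vapply(0:w, sf, 1) < 0.05)) - 1L
  predicted <- sf(t - 1L)   # P(X >= t)
  set.seed(17)
  strict <- 0L; incl <- 0L; n_tot <- 0L
  for (r in 1:40) {
    low <- sample.int(n, k)
    ct <- cluster_test(n, low, n_reps = 2000L)
    ci <- cluster_test(n, low, n_reps = 2000L, inclusive = TRUE)
    strict <- strict + sum(ct$p < 0.05)
    incl <- incl + sum(ci$p < 0.05)
    n_tot <- n_tot + nrow(ct)
  }
  expect_lt(abs(strict / n_tot - predicted), 0.03)
  expect_lte(incl / n_tot, 0.05)
})
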