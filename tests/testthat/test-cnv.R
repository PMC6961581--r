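library(data.table)

test_that("uniform positions produce equal-width equal-count bins", {
  pos <- data.frame(chrom = "chr1", pos = seq(10, 100000, by = 10))
  bins <- build_empirical_bins(pos, B = 5, chrom_sizes = c(chr1 = 100000))
  expect_equal(nrow(bins), 5L)
  expect_equal(bin_counts(pos, bins), rep(2000L, 5))
  widths <- bins$end - bins$start + 1
  expect_true(max(widths) / min(widths) < 1.01)
})

test_that("bin widths adapt to position density (quantile construction)", {
  set.seed(4)
  # density doubled on the first half of the chromosome
  pos <- data.frame(chrom = "chr1",
                    pos = sort(c(sample.int(50000, 20000),
                                 sample.int(50000, 10000) + 50000L)))
  bins <- build_empirical_bins(pos, B = 30, chrom_sizes = c(chr1 = 100000))
  counts <- bin_counts(pos, bins)
  expect_lte(diff(range(counts)), 1L)
  w_first <- mean((bins$end - bins$start + 1)[bins$end <= 50000])
  w_second <- mean((bins$end - bins$start + 1)[bins$start > 50000])
  expect_gt(w_second / w_first, 1.6)  # half the density, about twice the width
})

test_that("rebinning the pooled reference is self-consistent across chromosomes", {
  set.seed(8)
  cs <- c(chr1 = 8e5, chr2 = 1.2e6)
  pos <- rbind(data.frame(chrom = "chr1", pos = sort(sample.int(8e5, 40000))),
               data.frame(chrom = "chr2", pos = sort(sample.int(1.2e6, 60000))))
  bins <- build_empirical_bins(pos, B = 250, chrom_sizes = cs)
  counts <- bin_counts(pos, bins)
  expect_lte(diff(range(counts)), 1L)
  expect_equal(sum(counts), 100000L)
  expect_error(build_empirical_bins(pos[1:100, ], B = 200, chrom_sizes = cs),
               "exceeds")
})

test_that("per-bin GC is computed from the reference sequence", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("AT", 500),
                                                     strrep("GC", 500))))
  pos <- data.frame(chrom = "chr1", pos = seq(2, 2000, by = 2))
  bins <- build_empirical_bins(pos, B = 2, chrom_sizes = c(chr1 = 2000),
                               genome = genome)
  expect_equal(bins$gc, c(0, 1))
})

test_that("normalization returns mean-one vectors and undoes planted GC bias", {
  # constant counts, constant GC: exactly flat
  flat <- normalize_profile(rep(50L, 400), gc = rep(0.4, 400))
  expect_equal(flat, rep(1, 400))
  expect_error(normalize_profile(rep(0L, 10)), "empty")
  # arbitrary counts: mean is exactly one
  set.seed(10)
  counts <- rpois(500, 40)
  gc <- runif(500, 0.3, 0.6)
  v <- normalize_profile(counts, gc)
  expect_equal(mean(v), 1)
  # planted smooth GC bias multiplied into flat counts is removed
  bias <- exp(0.8 * (gc - mean(gc)))
  biased <- round(200 * bias)
  corrected <- normalize_profile(biased, gc)
  expect_lt(max(abs(corrected - 1)), 0.05)
  # without correction the bias would remain far above that tolerance
  uncorrected <- normalize_profile(biased, gc = NULL)
  expect_gt(max(abs(uncorrected - 1)), 0.1)
})

test_that("segmentation leaves a flat noiseless profile unsplit", {
  s <- segment_profile(rep(1, 100))
  expect_equal(nrow(s$segments), 1L)
  expect_equal(s$segmented, rep(1, 100))
  expect_error(segment_profile(c(1, NaN, 1)), "NaN")
})

test_that("a planted single step is found at the least-squares breakpoint", {
  set.seed(21)
  x <- c(rnorm(500, 1, 0.05), rnorm(500, 1.5, 0.05))
  s <- segment_profile(x, seed = 3)
  expect_equal(length(s$breakpoints), 1L)
  k <- oracle_one_breakpoint(x)
  expect_lte(abs(s$breakpoints[1] - k), 2L)
  expect_lte(abs(k - 500L), 2L)
  # segment means equal the means of their member bins
  for (i in seq_len(nrow(s$segments))) {
    expect_equal(s$segments$mean[i],
                 mean(x[s$segments$start[i]:s$segments$end[i]]))
  }
})

test_that("a planted two-step profile matches the exhaustive two-change-point oracle", {
  set.seed(33)
  x <- c(rnorm(70, 1, 0.05), rnorm(60, 1.6, 0.05), rnorm(70, 0.9, 0.05))
  s <- segment_profile(x, seed = 5)
  ko <- oracle_two_breakpoints(x)
  expect_equal(length(s$breakpoints), 2L)
  expect_true(all(abs(sort(s$breakpoints) - ko) <= 2L))
})

test_that("ploidy grid search recovers exact constructions and documented ties", {
  seg <- rep(c(0.5, 1, 1.5), times = c(25, 50, 25))
  p <- estimate_ploidy(seg)
  expect_equal(p$ploidy, 2)
  expect_equal(sort(unique(p$integer_states)), c(1, 2, 3))
  expect_equal(p$sse, 0)
  # all-ones vector: SSE zero at 2, 3 and 4; tie resolves to 2
  expect_equal(estimate_ploidy(rep(1, 100))$ploidy, 2)
  # ploidy scaling leaves segment boundaries unchanged
  set.seed(12)
  x <- c(rnorm(60, 0.8, 0.03), rnorm(60, 1.2, 0.03))
  s <- segment_profile(x, seed = 2)
  p2 <- estimate_ploidy(s)
  expect_equal(length(p2$scaled), length(x))
  expect_equal(which(diff(p2$scaled) != 0), s$breakpoints)
})

test_that("profile clustering uses Manhattan distance and separates planted clones", {
  expect_equal(unname(as.matrix(dist(rbind(c(1, 1), c(2, 2)),
                                     method = "manhattan"))[1, 2]), 2)
  m <- cbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(5, 5, 5))
  hc <- cluster_profiles(m)
  # identical profiles merge first at height 0
  expect_equal(hc$height[1], 0)
  expect_error(cluster_profiles(m[, 1, drop = FALSE]), "at least 2")
  # three planted clones, twenty noisy replicates each
  set.seed(14)
  base <- list(rep(c(1, 2), each = 50), rep(c(2, 3), each = 50),
               rep(2, 100))
  prof <- sapply(rep(1:3, each = 20), function(k)
    base[[k]] + rnorm(100, 0, 0.1))
  hc3 <- cluster_profiles(prof)
  labels <- cutree(hc3, k = 3)
  expect_equal(adjusted_rand(labels, rep(1:3, each = 20)), 1)
})

test_that("the display transform for amplified profiles is log(y + 1)", {
  expect_equal(cn_display_transform(c(0, 1, 80)), log(c(1, 2, 81)))
})
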