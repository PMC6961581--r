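library(data.table)

test_that("source-specific SNV calling applies the variant and specificity rules", {
  site <- function(alt_count, depth)
    data.table(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
               alt_count = alt_count, depth = depth)
  # A: 3/20 (15%), B: 0/15 well covered -> A-specific
  p1 <- call_source_snvs(site(3L, 20L), site(0L, 15L))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$source, "A")
  # 3/100 = 3% < 5%: not a variant
  expect_equal(nrow(call_source_snvs(site(3L, 100L), site(0L, 15L))), 0L)
  # 2 alt reads < 3: not a variant
  expect_equal(nrow(call_source_snvs(site(2L, 10L), site(0L, 15L))), 0L)
  # variant in A but B under-covered (10 < 12 reads): not assignable
  expect_equal(nrow(call_source_snvs(site(4L, 30L), site(0L, 10L))), 0L)
  # variant in both: specific to neither
  expect_equal(nrow(call_source_snvs(site(4L, 30L), site(5L, 30L))), 0L)
  # excluded positions are never scored
  expect_equal(nrow(call_source_snvs(site(3L, 20L), site(0L, 15L),
    exclude = data.table(chrom = "chr1", pos = 100L))), 0L)
})

test_that("identity assignment computes minority ratios and the mixed band", {
  panel <- data.table(chrom = "chr1", pos = 1:200, ref = "A",
                      alt = "G", source = rep(c("A", "B"), each = 100))
  obs_for <- function(bag, n_a, n_b) rbind(
    data.table(bag = bag, chrom = "chr1", pos = seq_len(n_a), base = "G"),
    data.table(bag = bag, chrom = "chr1", pos = 100L + seq_len(n_b), base = "G"))
  calls <- assign_identity(rbind(obs_for("c1", 97L, 3L),
                                 obs_for("c2", 50L, 50L),
                                 obs_for("c3", 0L, 40L)), panel)
  expect_equal(calls[bag == "c1", label], "A")
  expect_equal(calls[bag == "c1", minority_ratio], 0.03)
  expect_equal(calls[bag == "c2", label], "MIXED")
  expect_equal(calls[bag == "c3", label], "B")
  # band edges are exclusive: exactly 15% / 85% is not mixed
  edge <- assign_identity(obs_for("e1", 85L, 15L), panel)
  expect_equal(edge$label, "A")
  # minority ratio is symmetric under source relabeling
  sw <- copy(panel)[, source := fifelse(source == "A", "B", "A")]
  calls_sw <- assign_identity(obs_for("c1", 97L, 3L), sw)
  expect_equal(calls_sw$minority_ratio, 0.03)
  expect_equal(calls_sw$label, "B")
  # reference-base observations at panel sites are uninformative
  refobs <- data.table(bag = "r1", chrom = "chr1", pos = 1:10, base = "A")
  expect_equal(assign_identity(refobs, panel)$label, "UNASSIGNED")
})

test_that("planted contamination and doublets are recovered", {
  sim <- simulate_identity_obs(n_cells_a = 60, n_cells_b = 40,
                               n_doublets = 6, obs_per_cell = 400,
                               contamination = 0.005, seed = 19)
  calls <- assign_identity(sim$observations, sim$panel)
  merged <- sim$truth[calls, on = "bag"]
  expect_true(all(merged[source == "DOUBLET", label] == "MIXED"))
  expect_true(all(merged[source == "A", label] == "A"))
  expect_true(all(merged[source == "B", label] == "B"))
  # median minority ratio of singlets within binomial error of 0.5%
  singlets <- merged[source != "DOUBLET"]
  expect_lt(abs(median(singlets$minority_ratio) - 0.005),
            3 * sqrt(0.005 * 0.995 / 400))
})

test_that("the collision expectation matches exhaustive enumeration and Monte Carlo", {
  # n=2, N=2: the 4 equally likely outcomes contain 2 collisions
  expect_equal(expected_collisions(2, 2), 0.5)
  expect_equal(expected_collisions(1, 1000), 0)
  expect_equal(expected_collisions(0, 10), 0)
  # Monte-Carlo agreement within 3 standard errors
  mc_cases <- list(c(10, 100), c(235, 9216), c(500, 4096))
  set.seed(29)
  for (case in mc_cases) {
    n <- case[1]; N <- case[2]
    trials <- 4000L
    hits <- replicate(trials, {
      draws <- sample.int(N, n, replace = TRUE)
      sum(tabulate(draws) >= 2L)
    })
    se <- sd(hits) / sqrt(trials)
    expect_lt(abs(mean(hits) - expected_collisions(n, N)), 3 * se + 1e-6)
  }
})

test_that("observed mixed-identity rate matches the analytic collision expectation", {
  # cells drawing barcodes with replacement: cells sharing a barcode merge
  # into one observed mixed barcode
  set.seed(31)
  n <- 300L; N <- 2000L
  trials <- 300L
  mixed <- replicate(trials, {
    src <- sample(c("A", "B"), n, replace = TRUE)
    bc <- sample.int(N, n, replace = TRUE)
    tab <- split(src, bc)
    sum(vapply(tab, function(s) length(s) >= 2 && length(unique(s)) == 2,
               logical(1)))
  })
  # a collided barcode is observed MIXED only when the two cells differ in
  # source (probability 1/2 for a pair)
  expected <- expected_collisions(n, N) * 0.5
  se <- sd(mixed) / sqrt(trials)
  expect_lt(abs(mean(mixed) - expected), 3 * se + 0.05)
})

test_that("the default exclusion list carries the six artifact-prone sites", {
  ex <- default_snv_exclusions()
  expect_equal(nrow(ex), 6L)
  expect_equal(ex$pos[1], 569874L)
})
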