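test_that("composite barcode lengths are fixed per protocol", {
  expect_equal(bag_layout("dna")$barcode_length, 11L)
  expect_equal(bag_layout("rna2a")$barcode_length, 12L)
  expect_equal(bag_layout("rna2b")$barcode_length, 12L)
  expect_equal(bag_layout("rna3")$barcode_length, 18L)
  expect_equal(bag_layout("dna")$tag_length, 4L)
  expect_equal(bag_layout("rna3")$tag_length, 12L)
})

test_that("DNA Read 2 validation enforces the cut-site anchor and slices", {
  lay <- bag_layout("dna")
  mk <- function(anchor) paste0("GGGGGG", strrep("A", 15), "CCCCC", "TTTT",
                                anchor, strrep("T", 30))
  exact <- extract_barcodes(mk("CATG"), lay)
  expect_true(exact$pass)
  expect_equal(exact$bag_barcode, "GGGGGGCCCCC")
  expect_equal(exact$varietal_tag, "TTTT")

  one_mm <- extract_barcodes(mk("CATC"), lay)
  expect_true(one_mm$pass)
  two_mm <- extract_barcodes(mk("CAAA"), lay)
  expect_false(two_mm$pass)
  expect_equal(two_mm$reason, "anchor")

  short <- extract_barcodes(strrep("A", 30), lay)
  expect_false(short$pass)
  expect_equal(short$reason, "too_short")
})

test_that("three-round RNA layout yields an 18-base composite barcode", {
  lay <- bag_layout("rna3")
  wl <- list(c("AAAAAA", "CCCCCC"), c("GGGGGG", "TTTTTT"), c("ACACAC"))
  read <- build_structured_reads("AAAAAAGGGGGGACACAC", "GATTACATTGCA", lay)
  res <- extract_barcodes(read, lay, whitelists = wl)
  expect_true(res$pass)
  expect_equal(nchar(res$bag_barcode), 18L)
  expect_equal(res$bag_barcode, "AAAAAAGGGGGGACACAC")
  expect_equal(res$varietal_tag, "GATTACATTGCA")
})

test_that("GGG anchor allowance boundary admits one mismatch on layout B", {
  lay <- bag_layout("rna2b")
  wl <- list("ACGTAC", "TGCATG")
  read <- build_structured_reads("ACGTACTGCATG", "AAAAAACCCCCC", lay)
  substr(read, 38, 40) <- "GGA"  # one mismatch: allowed
  expect_true(extract_barcodes(read, lay, whitelists = wl)$pass)
  substr(read, 38, 40) <- "GAA"  # two mismatches: rejected
  res <- extract_barcodes(read, lay, whitelists = wl)
  expect_false(res$pass)
  expect_equal(res$reason, "anchor")
})

test_that("whitelist gating fails corrupted barcodes at exactly the corrupted rate", {
  lay <- bag_layout("rna2b")
  wl <- list(c("AAAAAA", "CCCCCC", "GGGGGG"), c("TTTTTT", "ACACAC", "TGTGTG"))
  set.seed(42)
  n <- 400L
  bc <- paste0(sample(wl[[1]], n, replace = TRUE),
               sample(wl[[2]], n, replace = TRUE))
  tags <- replicate(n, paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                             collapse = ""))
  reads <- build_structured_reads(bc, tags, lay)
  corrupt <- seq_len(n) %% 20L == 0L  # exactly 5%
  substr(reads[corrupt], 1, 6) <- "NNNNNN"
  res <- extract_barcodes(reads, lay, whitelists = wl)
  expect_equal(sum(!res$pass), sum(corrupt))
  expect_equal(res$reason[corrupt], rep("invalid_barcode", sum(corrupt)))
  expect_equal(res$bag_barcode[!corrupt], bc[!corrupt])
  expect_equal(res$varietal_tag[!corrupt], tags[!corrupt])
})

test_that("extraction is a left inverse of the generator under anchor noise", {
  for (proto in c("dna", "rna2a")) {
    lay <- bag_layout(proto)
    set.seed(7)
    n <- 2000L
    bases <- c("A", "C", "G", "T")
    bc <- apply(matrix(sample(bases, n * lay$barcode_length, TRUE), n), 1,
                paste, collapse = "")
    tg <- apply(matrix(sample(bases, n * lay$tag_length, TRUE), n), 1,
                paste, collapse = "")
    mm <- if (proto == "dna") 1L else 0L  # plant up to the allowance
    reads <- build_structured_reads(bc, tg, lay, anchor_mismatches = mm)
    res <- extract_barcodes(reads, lay)
    expect_true(all(res$pass))
    expect_equal(res$bag_barcode, bc)
    expect_equal(res$varietal_tag, tg)
    # order independence: a permutation of reads gives the permuted result
    perm <- sample.int(n)
    res2 <- extract_barcodes(reads[perm], lay)
    expect_equal(res2$pass, res$pass[perm])
    expect_equal(res2$bag_barcode, res$bag_barcode[perm])
  }
})

test_that("adapter trimming drops pairs below the 100-base retention rule", {
  adapter <- "AGATCGGAAGAGC"
  base120 <- strrep("C", 120)
  base105 <- strrep("T", 105)
  base99 <- strrep("T", 99)
  # adapter read-through: trimmed back to the genomic prefix
  tr <- trim_read_pairs(paste0(base120, adapter), paste0(base105, adapter),
                        adapter)
  expect_equal(tr$len1, 120L)
  expect_equal(tr$len2, 105L)
  expect_true(tr$keep)
  tr2 <- trim_read_pairs(paste0(base120, adapter), paste0(base99, adapter),
                         adapter)
  expect_equal(tr2$len2, 99L)
  expect_false(tr2$keep)
  # adapter-free 150-base pair is untouched and retained
  free <- strrep("G", 150)
  tr3 <- trim_read_pairs(free, free, adapter)
  expect_equal(tr3$read1, free)
  expect_true(tr3$keep)
})

test_that("proper-pair classification applies distance, orientation and structure", {
  base <- data.table::data.table(
    chrom1 = "chr1", pos1 = 1000L, strand1 = "+", mapped1 = TRUE,
    chrom2 = "chr1", pos2 = 1500L, strand2 = "-", mapped2 = TRUE,
    structure_ok = TRUE)
  expect_true(classify_proper_pairs(base)$proper)
  far <- data.table::copy(base)[, pos2 := 4000L]
  expect_equal(classify_proper_pairs(far)$reason, "too_far")
  same <- data.table::copy(base)[, strand2 := "+"]
  expect_equal(classify_proper_pairs(same)$reason, "same_strand")
  div <- data.table::copy(base)[, `:=`(strand1 = "-", strand2 = "+")]
  expect_equal(classify_proper_pairs(div)$reason, "divergent")
  un <- data.table::copy(base)[, mapped2 := FALSE]
  expect_equal(classify_proper_pairs(un)$reason, "unmapped_mate")
  nostruct <- data.table::copy(base)[, structure_ok := FALSE]
  expect_equal(classify_proper_pairs(nostruct)$reason, "structure")
  # boundary: exactly 2 kb apart is proper
  edge <- data.table::copy(base)[, pos2 := 3000L]
  expect_true(classify_proper_pairs(edge)$proper)
})
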