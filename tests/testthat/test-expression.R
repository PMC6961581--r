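library(data.table)

toy_exons <- data.table(
  gene = c("g1", "g1", "g2"),
  transcript = c("g1.t1", "g1.t1", "g2.t1"),
  chrom = "chr1",
  start = c(1000L, 2000L, 5000L),
  end = c(1499L, 2499L, 5999L),
  strand = "+"
)

test_that("single-cell gene assignment uses the inclusive 50% exon rule", {
  aln <- data.table(
    read_id = c("half", "under", "intronic", "full"),
    bag = "c1", tag = "TTTT", chrom = "chr1",
    pos = c(1462L, 1463L, 1600L, 1100L),
    end = c(1462L, 1463L, 1600L, 1100L) + 75L  # 76-base reads
  )
  out <- assign_reads_to_genes(aln, toy_exons, mode = "singlecell")
  # 38 of 76 bases in exon (pos 1462..1499): counted
  expect_equal(out[read_id == "half", gene], "g1")
  # 37 of 76: not counted
  expect_true(is.na(out[read_id == "under", gene]))
  expect_true(is.na(out[read_id == "intronic", gene]))
  expect_equal(out[read_id == "full", gene], "g1")
})

test_that("bulk assignment demands every aligned base within one transcript's exons", {
  aln <- data.table(read_id = c("inside", "spill"), bag = "c1", tag = "AAAA",
                    chrom = "chr1", pos = c(1100L, 1460L),
                    end = c(1175L, 1535L))
  out_bulk <- assign_reads_to_genes(aln, toy_exons, mode = "bulk")
  expect_equal(out_bulk[read_id == "inside", gene], "g1")
  expect_true(is.na(out_bulk[read_id == "spill", gene]))
  # the same spilling read is fine in single-cell mode (40/76 in exon)
  out_sc <- assign_reads_to_genes(aln, toy_exons, mode = "singlecell")
  expect_equal(out_sc[read_id == "spill", gene], "g1")
})

test_that("reads overlapping two genes are ambiguous and dropped", {
  ex2 <- rbind(toy_exons,
               data.table(gene = "g3", transcript = "g3.t1", chrom = "chr1",
                          start = 2400L, end = 2900L, strand = "+"))
  aln <- data.table(read_id = "amb", bag = "c1", tag = "AAAA", chrom = "chr1",
                    pos = 2420L, end = 2495L)
  out <- assign_reads_to_genes(aln, ex2, mode = "singlecell")
  expect_true(is.na(out$gene))
  expect_equal(attr(out, "ambiguous"), 1L)
})

test_that("the expression matrix counts unique templates, not reads", {
  aln <- data.table(
    read_id = sprintf("r%d", 1:6), bag = "c1",
    tag = c("AAAA", "AAAA", "AAAA", "CCCC", "CCCC", "GGGG"),
    chrom = "chr1", pos = 1100L, end = 1175L)
  out <- assign_reads_to_genes(aln, toy_exons)
  m <- expression_matrix(out)
  expect_equal(unname(m["g1", "c1"]), 3L)  # three distinct tags
  # per-cell gene count never exceeds per-cell template count
  expect_lte(sum(m[, "c1"] > 0), sum(m[, "c1"]))
})

test_that("RPKM follows the formula and genes take their best transcript", {
  cnt <- data.table(gene = c("G", "G", "H"),
                    transcript = c("t1", "t2", "t3"),
                    reads = c(10L, 21L, 0L))
  len <- data.table(transcript = c("t1", "t2", "t3"),
                    length = c(1000L, 3000L, 500L))
  v <- rpkm(cnt, len, total_mapped = 1e6)
  expect_equal(unname(v["G"]), max(10, 21 * 1e9 / (3000 * 1e6)))
  expect_equal(unname(v["G"]), 10)   # t1: 10 RPKM beats t2: 7
  expect_equal(unname(v["H"]), 0)
  expect_error(rpkm(cnt, len, total_mapped = 0), "positive")
})

test_that("PCA separates planted populations and is duplicate-invariant", {
  sim <- simulate_rna_library(n_cells_a = 25, n_cells_b = 20,
                              templates_per_cell = 300, seed = 41)
  run <- run_rna(sim$reads, sim$exons)
  m <- run$matrix
  pca <- run$pca
  pc1 <- pca$scores[, 1]
  lab <- sim$truth[match(colnames(m), bag), population]
  # zero overlap between the two populations along PC1
  expect_true(max(pc1[lab == "A"]) < min(pc1[lab == "B"]) ||
                max(pc1[lab == "B"]) < min(pc1[lab == "A"]))
  # markers split between the two planted marker sets
  mk <- pca$markers
  expect_equal(nrow(mk), 40L)
  marker_genes_a <- sprintf("gene%03d", 1:25)
  marker_genes_b <- sprintf("gene%03d", 26:50)
  pos_set <- mk[direction == "positive", gene]
  neg_set <- mk[direction == "negative", gene]
  expect_true(all(pos_set %in% marker_genes_a) && all(neg_set %in% marker_genes_b) ||
                all(pos_set %in% marker_genes_b) && all(neg_set %in% marker_genes_a))
  # duplicated cells land on identical coordinates
  m2 <- cbind(m, dup = m[, 1])
  colnames(m2) <- c(colnames(m), "dup")
  p2 <- pca_markers(m2)
  d <- abs(p2$scores[1, ] - p2$scores["dup", ])
  expect_true(all(d < 1e-8))
})

test_that("pure noise produces no dominant PC1 (random-matrix regime)", {
  set.seed(51)
  n_genes <- 150L; n_cells <- 60L
  m <- matrix(rpois(n_genes * n_cells, 20), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("c%03d", 1:n_cells)))
  pca <- pca_markers(m)
  # the largest eigenvalue share of a pure-noise scaled matrix stays near
  # the Marchenko-Pastur edge (1 + sqrt(gamma))^2 / p
  gamma <- n_genes / n_cells
  mp_share <- (1 + sqrt(gamma))^2 / n_genes
  expect_lt(pca$var_explained[1], 2.5 * mp_share)
  expect_lt(pca$var_explained[1], 0.2)
})

test_that("bulk profiles project near their own population's cells", {
  sim <- simulate_rna_library(n_cells_a = 15, n_cells_b = 15,
                              templates_per_cell = 300, seed = 43)
  assigned <- assign_reads_to_genes(sim$reads, sim$exons)
  m <- expression_matrix(assigned)
  lab <- sim$truth[match(colnames(m), bag), population]
  # pseudo-bulk from each population as a stand-in bulk profile
  bulk <- cbind(bulkA = rowSums(m[, lab == "A"]),
                bulkB = rowSums(m[, lab == "B"]))
  pca <- pca_markers(m, bulk = bulk)
  pc1 <- pca$scores[, 1]
  ba <- pca$bulk_scores["bulkA", 1]
  bb <- pca$bulk_scores["bulkB", 1]
  mean_a <- mean(pc1[lab == "A"]); mean_b <- mean(pc1[lab == "B"])
  expect_lt(abs(ba - mean_a), abs(ba - mean_b))
  expect_lt(abs(bb - mean_b), abs(bb - mean_a))
})
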