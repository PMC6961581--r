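#' Assign aligned reads to genes through an exon model
#'
#' Bulk mode counts a read only when all of its aligned bases fall within
#' the exons of a single transcript; single-cell mode requires at least half
#' of the read length to fall within exons of some transcript of the gene
#' (the 50% boundary is inclusive). A read meeting the rule for transcripts
#' of two different genes is ambiguous and is not counted.
#'
#' @param aln `data.table` of alignments with `read_id`, `chrom`, `pos`,
#'   `end` (single aligned block per read) and any annotation columns
#'   (`bag`, `tag`, ...), which are carried through.
#' @param exons Exon model: `data.table` with `gene`, `transcript`,
#'   `chrom`, `start`, `end` (1-based inclusive; exons non-overlapping
#'   within a transcript).
#' @param mode `"singlecell"` (default) or `"bulk"`.
#' @return The input with a `gene` column appended (`NA` when unassigned)
#'   and an `ambiguous` attribute counting reads dropped for multi-gene
#'   overlap.
#' @export
assign_reads_to_genes <- function(aln, exons,
                                  mode = c("singlecell", "bulk")) {
  mode <- match.arg(mode)
  a <- as.data.table(aln)
  ex <- as.data.table(exons)
  stopifnot(all(c("read_id", "chrom", "pos", "end") %in% names(a)),
            all(c("gene", "transcript", "chrom", "start", "end") %in% names(ex)))
  setkey(ex, chrom, start, end)
  qq <- a[, .(read_id, chrom, start = pos, end = end)]
  ov <- foverlaps(qq, ex, type = "any", nomatch = NULL)
  if (nrow(ov)) {
    # bases of the read inside each overlapped exon
    ov[, overlap := pmin(i.end, end) - pmax(i.start, start) + 1L]
    ov[, width := i.end - i.start + 1L]
    per_tx <- ov[, .(inside = sum(overlap), width = width[1]),
                 by = .(read_id, gene, transcript)]
    hit <- if (mode == "bulk") {
      per_tx[inside == width]
    } else {
      per_tx[inside >= width / 2]
    }
    per_gene <- unique(hit[, .(read_id, gene)])
    n_genes <- per_gene[, .(k = .N), by = read_id]
    amb <- n_genes[k > 1L, read_id]
    per_gene <- per_gene[!read_id %in% amb]
  } else {
    per_gene <- data.table(read_id = character(0), gene = character(0))
    amb <- character(0)
  }
  out <- per_gene[a, on = "read_id"]
  setcolorder(out, names(a))
  setattr(out, "ambiguous", length(amb))
  out[]
}

#' Gene-by-cell unique-template count matrix
#'
#' Collapses gene-assigned reads by varietal tag: each (cell, tag, gene)
#' combination contributes one template. A tag observed on two genes within
#' a cell is resolved to the gene with more supporting reads; ties are
#' ambiguous and dropped.
#'
#' @param assigned Output of [assign_reads_to_genes()] with `bag` and `tag`
#'   columns.
#' @return Integer matrix, genes in rows, cells in columns.
#' @export
expression_matrix <- function(assigned) {
  a <- as.data.table(assigned)[!is.na(gene)]
  stopifnot(all(c("bag", "tag", "gene") %in% names(a)))
  tpl <- a[, .(n_reads = .N), by = .(bag, tag, gene)]
  # resolve a tag split across genes: majority gene wins, ties dropped
  setorder(tpl, bag, tag, -n_reads)
  tpl[, rank := seq_len(.N), by = .(bag, tag)]
  top2 <- tpl[rank <= 2L]
  tie <- top2[, .(tie = .N == 2L && n_reads[1] == n_reads[2]), by = .(bag, tag)]
  keep <- tpl[rank == 1L][!tie[tie == TRUE], on = c("bag", "tag")]
  counts <- keep[, .N, by = .(gene, bag)]
  genes <- sort(unique(counts$gene))
  cells <- sort(unique(a$bag))
  m <- matrix(0L, length(genes), length(cells), dimnames = list(genes, cells))
  m[cbind(match(counts$gene, genes), match(counts$bag, cells))] <- counts$N
  m
}

#' RPKM per gene from bulk transcript counts
#'
#' `RPKM = reads * 1e9 / (length * total_mapped)` per transcript; a gene
#' with several transcripts takes the value of its highest-RPKM transcript.
#'
#' @param counts `data.table` with `gene`, `transcript`, `reads`.
#' @param lengths `data.table` with `transcript`, `length` (bases,
#'   positive).
#' @param total_mapped Total mapped reads in the library.
#' @return Named numeric vector of gene RPKM values.
#' @examples
#' cnt <- data.frame(gene = "G", transcript = "t1", reads = 10)
#' len <- data.frame(transcript = "t1", length = 1000)
#' rpkm(cnt, len, total_mapped = 1e6)  # 10
#' @export
rpkm <- function(counts, lengths, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be positive")
  cnt <- as.data.table(counts)
  len <- as.data.table(lengths)
  stopifnot(all(len$length > 0))
  x <- len[cnt, on = "transcript"]
  if (anyNA(x$length)) stop("missing transcript lengths")
  x[, rpkm := reads * 1e9 / (length * total_mapped)]
  g <- x[, .(rpkm = max(rpkm)), by = gene]
  setNames(g$rpkm, g$gene)
}

#' PCA of single-cell expression with PC1 marker genes
#'
#' Expression values are first normalized by each cell's mean, then
#' `log(x + 1)` is centred per gene, and principal components are computed
#' on the cells with per-feature centring and unit scaling. Optional bulk
#' profiles are passed through the identical normalization and projected
#' into the same space. Marker genes are the 20 most positively and 20 most
#' negatively PC1-correlated genes; the marker heatmap ordering clusters
#' cells by Euclidean distance with complete linkage.
#'
#' @param mat Gene-by-cell matrix of unique-template counts.
#' @param bulk Optional gene-by-sample matrix of bulk expression on the
#'   same genes.
#' @param n_markers Total marker genes, split evenly between the positive
#'   and negative tails (default 40).
#' @return List of class `expr_pca`: `scores` (cells x PCs), `var_explained`,
#'   `markers` (`data.table` of `gene`, `correlation`, `direction`),
#'   `bulk_scores` (or `NULL`), `heatmap_order` (cell ordering from the
#'   marker-gene clustering), `dropped` (constant genes removed).
#' @export
pca_markers <- function(mat, bulk = NULL, n_markers = 40L) {
  stopifnot(ncol(mat) >= 3, nrow(mat) >= 2)
  normalize <- function(m) {
    cm <- colMeans(m)
    if (any(cm == 0)) stop("cell with zero total expression")
    log1p(sweep(m, 2, cm, "/"))
  }
  x <- normalize(mat)
  centers <- rowMeans(x)
  x <- x - centers              # centre each gene
  keep <- apply(x, 1, var) > 0  # constant genes carry no signal and break scaling
  dropped <- rownames(mat)[!keep]
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("fewer than 2 variable genes")
  pc <- prcomp(t(x), center = TRUE, scale. = TRUE)
  scores <- pc$x
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  cors <- apply(x, 1, function(g) suppressWarnings(cor(g, scores[, 1])))
  cors[is.na(cors)] <- 0
  half <- min(n_markers %/% 2L, nrow(x) %/% 2L)
  pos_idx <- order(cors, decreasing = TRUE)[seq_len(half)]
  neg_idx <- order(cors)[seq_len(half)]
  markers <- data.table(
    gene = c(rownames(x)[pos_idx], rownames(x)[neg_idx]),
    correlation = c(cors[pos_idx], cors[neg_idx]),
    direction = rep(c("positive", "negative"), each = half)
  )
  bulk_scores <- NULL
  if (!is.null(bulk)) {
    xb <- normalize(bulk[rownames(mat), , drop = FALSE]) - centers
    xb <- xb[keep, , drop = FALSE]
    bulk_scores <- predict(pc, newdata = t(xb))
  }
  hm <- x[markers$gene, , drop = FALSE]
  heatmap_order <- hclust(dist(t(hm), method = "euclidean"),
                          method = "complete")$order
  structure(list(scores = scores, var_explained = var_explained,
                 markers = markers, bulk_scores = bulk_scores,
                 heatmap_order = heatmap_order, dropped = dropped),
            class = "expr_pca")
}
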