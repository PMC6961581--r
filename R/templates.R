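#' Collapse annotated reads into uniquely tagged templates
#'
#' Reads sharing an identical (cell barcode, varietal tag, chromosome, map
#' position, strand) key derive from the same original template molecule and
#' are collapsed into one template read set. Tags are matched exactly; no
#' mismatch merging is attempted. The map position is the 5'-most aligned
#' base on the plus strand.
#'
#' @param reads `data.table`/`data.frame` of annotated alignments with
#'   columns `bag`, `tag`, `chrom`, `pos`, `strand` and optionally `end`
#'   (footprint end) and `mapped` (logical; unmapped reads are skipped and
#'   counted).
#' @return `data.table` of class `template_set` keyed by
#'   (`bag`,`tag`,`chrom`,`pos`,`strand`) with `n_reads` and, when `end` is
#'   available, the footprint `end` (maximum over member reads). The number
#'   of skipped unmapped reads is attached as attribute `skipped`.
#' @examples
#' r <- data.frame(bag = "b1", tag = c("AAAA", "AAAA", "CCCC"),
#'                 chrom = "chr1", pos = c(10, 10, 50), strand = "+")
#' collapse_templates(r)
#' @export
collapse_templates <- function(reads) {
  r <- as.data.table(reads)
  need <- c("bag", "tag", "chrom", "pos", "strand")
  stopifnot(all(need %in% names(r)))
  skipped <- 0L
  if ("mapped" %in% names(r)) {
    skipped <- sum(!r$mapped)
    r <- r[mapped == TRUE]
  }
  has_end <- "end" %in% names(r)
  tpl <- if (has_end) {
    r[, .(n_reads = .N, end = max(end)), keyby = need]
  } else {
    r[, .(n_reads = .N), keyby = need]
  }
  setattr(tpl, "skipped", skipped)
  setattr(tpl, "class", c("template_set", class(tpl)))
  tpl[]
}

#' Per-cell library statistics
#'
#' Computes, per cell barcode, the read count, unique template count,
#' reads-per-template multiplicity (RPT) and, when footprints are available,
#' the fraction of the genome covered.
#'
#' @param reads Annotated alignments as in [collapse_templates()].
#' @param genome_size Total genome size in bases (for coverage fractions);
#'   optional.
#' @return `data.table` with one row per `bag`: `reads`, `templates`, `rpt`,
#'   and `genome_fraction` when computable.
#' @export
bag_stats <- function(reads, genome_size = NULL) {
  tpl <- collapse_templates(reads)
  st <- tpl[, .(reads = sum(n_reads), templates = .N), by = bag]
  st[, rpt := reads / templates]
  if (!is.null(genome_size) && "end" %in% names(tpl)) {
    cov <- tpl[, .(covered = .covered_bases(.SD)), by = bag]
    st <- cov[st, on = "bag"]
    st[, genome_fraction := covered / genome_size]
    st[, covered := NULL]
  }
  setcolorder(st, "bag")
  st[]
}

# total bases covered by the union of [pos, end] footprints (both strands)
.covered_bases <- function(tpl) {
  tot <- 0L
  for (ch in unique(tpl$chrom)) {
    d <- tpl[chrom == ch]
    ir <- IRanges::reduce(IRanges::IRanges(start = d$pos, end = d$end))
    tot <- tot + sum(IRanges::width(ir))
  }
  tot
}

#' Strand-of-capture genome fractions
#'
#' Each template is captured as a single strand (the restriction site marks
#' its 3' end), so every covered genomic position is captured from the plus
#' strand, the minus strand, or both. Reports the fraction of the genome in
#' each class.
#'
#' @param templates A [collapse_templates()] result carrying footprint `end`
#'   columns.
#' @param genome_size Total genome size in bases.
#' @return Named numeric vector `c(plus_only=, minus_only=, both=)`.
#' @export
strand_capture_fractions <- function(templates, genome_size) {
  tpl <- as.data.table(templates)
  stopifnot(all(c("chrom", "pos", "end", "strand") %in% names(tpl)),
            genome_size >= 1)
  plus_only <- minus_only <- both <- 0L
  for (ch in unique(tpl$chrom)) {
    d <- tpl[chrom == ch]
    ir_p <- IRanges::reduce(IRanges::IRanges(d$pos[d$strand == "+"],
                                             d$end[d$strand == "+"]))
    ir_m <- IRanges::reduce(IRanges::IRanges(d$pos[d$strand == "-"],
                                             d$end[d$strand == "-"]))
    ir_b <- IRanges::intersect(ir_p, ir_m)
    both <- both + sum(IRanges::width(ir_b))
    plus_only <- plus_only + sum(IRanges::width(IRanges::setdiff(ir_p, ir_b)))
    minus_only <- minus_only + sum(IRanges::width(IRanges::setdiff(ir_m, ir_b)))
  }
  c(plus_only = plus_only / genome_size,
    minus_only = minus_only / genome_size,
    both = both / genome_size)
}

#' Downsampling saturation curve
#'
#' Samples reads without replacement at each requested fraction and
#' recomputes the number of unique templates (and genes, when a `gene`
#' column is present), tracing the saturation behaviour of the library.
#'
#' @param reads Annotated alignments as in [collapse_templates()].
#' @param fractions Numeric vector of sampling fractions in (0, 1\];
#'   default `seq(0.1, 1, by = 0.1)`.
#' @param seed Integer seed for the sampling; default 1.
#' @return `data.table` with columns `fraction`, `reads`, `templates` and,
#'   when available, `genes`.
#' @export
downsample_saturation <- function(reads, fractions = seq(0.1, 1, by = 0.1),
                                  seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  r <- as.data.table(reads)
  if ("mapped" %in% names(r)) r <- r[mapped == TRUE]
  n <- nrow(r)
  has_gene <- "gene" %in% names(r)
  with_seed(seed, {
    rbindlist(lapply(sort(fractions), function(f) {
      k <- if (f == 1) n else floor(f * n)
      idx <- if (f == 1) seq_len(n) else sample.int(n, k)
      sub <- r[idx]
      out <- data.table(fraction = f, reads = k,
        templates = nrow(unique(sub[, .(bag, tag, chrom, pos, strand)])))
      if (has_gene) out[, genes := uniqueN(sub$gene[!is.na(sub$gene)])]
      out
    }))
  })
}

#' Expected unique templates under downsampling
#'
#' Closed-form expectation for the number of templates observed at least
#' once when a fraction `f` of all reads is drawn without replacement:
#' each template with `d` of the `n` reads is missed with hypergeometric
#' probability `choose(n-d, k)/choose(n, k)` where `k = floor(f n)`.
#'
#' @param depths Integer vector of per-template read depths.
#' @param fraction Sampling fraction in (0, 1\].
#' @return Expected number of templates observed.
#' @export
expected_templates_at_fraction <- function(depths, fraction) {
  n <- sum(depths)
  k <- floor(fraction * n)
  miss <- exp(lchoose(n - depths, k) - lchoose(n, k))
  miss[n - depths < k] <- 0
  sum(1 - miss)
}
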