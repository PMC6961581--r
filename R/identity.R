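#' Call source-specific SNVs from two bulk pileups
#'
#' A site is a variant in a source when the non-reference base (at adequate
#' base quality) is seen at least `min_alt_reads` times and in at least
#' `min_alt_frac` of covering reads. A variant is specific to one source
#' only when the other source shows no such variant at a site covered by at
#' least `min_other_depth` qualifying reads; sites under-covered in the
#' other source are not assignable to either. Positions on the exclusion
#' list (e.g. sites prone to anomalous mapping artifacts) are never scored.
#'
#' @param pileup_a,pileup_b Per-site read summaries for the two sources:
#'   `data.table` with `chrom`, `pos`, `ref`, `alt`, `alt_count`, `depth`
#'   (counts already restricted to reads/bases passing mapping- and
#'   base-quality filters).
#' @param min_alt_reads Minimum alternative reads to call a variant
#'   (default 3).
#' @param min_alt_frac Minimum alternative read fraction (default 0.05).
#' @param min_other_depth Minimum depth in the other source to assess
#'   specificity (default 12).
#' @param exclude Optional `data.table` of `chrom`, `pos` never to score.
#' @return `snv_panel`: `data.table` of `chrom`, `pos`, `ref`, `alt`,
#'   `source` (`"A"` or `"B"`).
#' @export
call_source_snvs <- function(pileup_a, pileup_b, min_alt_reads = 3L,
                             min_alt_frac = 0.05, min_other_depth = 12L,
                             exclude = NULL) {
  a <- as.data.table(pileup_a)
  b <- as.data.table(pileup_b)
  need <- c("chrom", "pos", "ref", "alt", "alt_count", "depth")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  if (!is.null(exclude)) {
    ex <- as.data.table(exclude)
    a <- a[!ex, on = c("chrom", "pos")]
    b <- b[!ex, on = c("chrom", "pos")]
  }
  is_variant <- function(p)
    p[alt_count >= min_alt_reads & alt_count >= min_alt_frac * depth]
  specific <- function(var, other) {
    o <- other[, .(chrom, pos, o_alt = alt, o_alt_count = alt_count,
                   o_depth = depth)]
    v <- o[var, on = c("chrom", "pos")]
    # assessable only when the other source is adequately covered there and
    # shows no variant call of its own at the site
    v[!is.na(o_depth) & o_depth >= min_other_depth &
        !(o_alt_count >= min_alt_reads & o_alt_count >= min_alt_frac * o_depth),
      .(chrom, pos, ref, alt)]
  }
  pa <- specific(is_variant(a), b)[, source := "A"]
  pb <- specific(is_variant(b), a)[, source := "B"]
  panel <- rbind(pa, pb)
  setorder(panel, chrom, pos)
  setattr(panel, "class", c("snv_panel", class(panel)))
  panel[]
}

#' Assign each cell a majority source and minority SNV ratio
#'
#' Counts, per cell, the consensus template observations matching each
#' source's panel alleles. The minority SNV ratio `min(a,b)/(a+b)` measures
#' cross-contamination; a cell whose source-A fraction falls strictly inside
#' the (`mixed_low`, `mixed_high`) band is flagged `MIXED` (a doublet or
#' barcode collision), and a cell with no informative observations is
#' `UNASSIGNED`. Observations are counted at the template (consensus)
#' level, decoupling the ratio from amplification depth.
#'
#' @param observations `data.table` of per-cell consensus SNV observations:
#'   `bag`, `chrom`, `pos`, `base` (one row per informative template).
#' @param panel An [call_source_snvs()] panel (`chrom`, `pos`, `ref`,
#'   `alt`, `source`).
#' @param min_templates Cells with fewer total informative observations than
#'   this are dropped before calling (default 0; the three-round RNA
#'   protocol conventionally uses 5000 unique tags as its admission
#'   threshold, applied upstream on total template counts).
#' @param mixed_low,mixed_high Mixed-identity band bounds, exclusive
#'   (defaults 0.15 and 0.85).
#' @return `data.table`: `bag`, `n_a`, `n_b`, `minority_ratio`, `label`
#'   (`"A"`, `"B"`, `"MIXED"` or `"UNASSIGNED"`).
#' @export
assign_identity <- function(observations, panel, min_templates = 0L,
                            mixed_low = 0.15, mixed_high = 0.85) {
  stopifnot(nrow(panel) > 0)
  obs <- as.data.table(observations)
  p <- as.data.table(panel)
  hits <- p[obs, on = c("chrom", "pos"), nomatch = NULL]
  hits <- hits[base == alt]
  calls <- hits[, .(n_a = sum(source == "A"), n_b = sum(source == "B")),
                by = bag]
  # retain cells present in the input even if nothing informative matched
  all_bags <- unique(obs$bag)
  calls <- calls[data.table(bag = all_bags), on = "bag"]
  calls[is.na(n_a), n_a := 0L]
  calls[is.na(n_b), n_b := 0L]
  calls <- calls[n_a + n_b >= min_templates]
  calls[, minority_ratio := ifelse(n_a + n_b == 0, NA_real_,
                                   pmin(n_a, n_b) / (n_a + n_b))]
  frac_a <- with(calls, ifelse(n_a + n_b == 0, NA_real_, n_a / (n_a + n_b)))
  calls[, label := fcase(
    n_a + n_b == 0L, "UNASSIGNED",
    frac_a > mixed_low & frac_a < mixed_high, "MIXED",
    frac_a >= mixed_high, "A",
    default = "B"
  )]
  setorder(calls, bag)
  calls[]
}

#' Expected number of barcode collisions
#'
#' When `n` cells draw barcodes independently and uniformly from a space of
#' `N` composite barcodes, the expected number of barcode values chosen by
#' two or more cells is, by occupancy statistics,
#' `N - N (1 - 1/N)^n - n (1 - 1/N)^(n-1)` (total values minus those chosen
#' zero times and those chosen exactly once). Exact closed form; no
#' simulation.
#'
#' @param n Number of cells drawing barcodes.
#' @param N Number of possible composite barcodes (e.g. `96^2` for two
#'   split rounds, `96^3` for three).
#' @return Expected number of collided barcode values.
#' @examples
#' expected_collisions(235, 96^2)  # about 2.9
#' @export
expected_collisions <- function(n, N) {
  stopifnot(n >= 0, N >= 1)
  N - N * (1 - 1 / N)^n - n * (1 - 1 / N)^(n - 1)
}

#' Observed collision rate
#'
#' The fraction of profiled cells flagged as mixed identity, reported as a
#' percentage: the empirical counterpart of [expected_collisions()] scaled
#' by the cell count.
#'
#' @param n_mixed Number of mixed-identity (collided/doublet) cells.
#' @param n_total Total cells profiled.
#' @return Percentage `100 * n_mixed / n_total`.
#' @examples
#' collision_rate(19, 2875)  # 0.66
#' @export
collision_rate <- function(n_mixed, n_total) {
  stopifnot(n_total >= 1, n_mixed >= 0)
  100 * n_mixed / n_total
}

#' Default exclusion list for human (hg19) runs
#'
#' Six hg19 positions prone to anomalous mapping artifacts, excluded by
#' default when scoring source-specific SNV panels on real data.
#'
#' @return `data.table` with `chrom`, `pos`.
#' @export
default_snv_exclusions <- function() {
  data.table(
    chrom = c("chr1", "chr6", "chr6", "chr6", "chr7", "chr10"),
    pos = c(569874L, 58777419L, 58778584L, 58779097L, 61969087L, 42385520L)
  )
}
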