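BASES <- c("A", "C", "G", "T")

#' All 64 trinucleotide contexts
#' @return Character vector like `"ACA"`, reference-strand frame.
#' @export
trinucleotide_contexts <- function() {
  g <- expand.grid(left = BASES, mid = BASES, right = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$left, g$mid, g$right))
}

#' Consensus base call for one template read set
#'
#' A position is called from a template's reads only when the template has
#' at least `min_reads` members and at least a fraction `min_agree` of them
#' agree on the same base (agreement at exactly the threshold counts). With
#' fewer reads, or with weaker agreement, no call is made: most discordant
#' templates have exactly two reads, one of which carries a sequencing
#' error, and abstaining there is what suppresses read-level error.
#'
#' @param bases Character vector of the member reads' base calls at the
#'   position.
#' @param min_reads Minimum template size (default 2).
#' @param min_agree Minimum agreeing fraction (default 0.8).
#' @return The consensus base, or `NA_character_` for no-call.
#' @examples
#' consensus_call(c("A", "A"))        # "A"
#' consensus_call(c("A", "C"))        # NA: 50% agreement
#' consensus_call(c("A", "A", "C"))   # NA: 66.7%
#' @export
consensus_call <- function(bases, min_reads = 2L, min_agree = 0.8) {
  n <- length(bases)
  if (n < min_reads) return(NA_character_)
  tab <- sort(table(bases), decreasing = TRUE)
  if (tab[1] / n >= min_agree) names(tab)[1] else NA_character_
}

#' Consensus calls for all template read sets
#'
#' Vectorised [consensus_call()] over a table of per-read base observations.
#'
#' @param calls `data.table` with one row per read observation: `bag`,
#'   `tag`, `chrom`, `pos`, `strand`, `base`. Bases are in the reference
#'   frame (as reported by the aligner); templates captured on the minus
#'   strand are therefore directly comparable to plus-strand templates.
#' @inheritParams consensus_call
#' @return `data.table` keyed by (`bag`,`tag`,`chrom`,`pos`,`strand`) with
#'   `depth` and `consensus` (`NA` = no-call).
#' @export
consensus_calls <- function(calls, min_reads = 2L, min_agree = 0.8) {
  cc <- as.data.table(calls)
  stopifnot(all(c("bag", "tag", "chrom", "pos", "strand", "base") %in% names(cc)))
  # vectorised consensus: per-template top base count vs depth
  per_base <- cc[, .(n = .N), by = .(bag, tag, chrom, pos, strand, base)]
  setorder(per_base, bag, tag, chrom, pos, strand, -n, base)
  top <- per_base[, .(depth = sum(n), top_n = n[1], consensus = base[1]),
                  by = .(bag, tag, chrom, pos, strand)]
  top[depth < min_reads | top_n / depth < min_agree, consensus := NA_character_]
  top[, top_n := NULL]
  setkey(top, bag, tag, chrom, pos, strand)
  top[]
}

#' Trinucleotide-context error matrix
#'
#' Tallies mismatches to a donor truth mask (positions where the donor is
#' confidently homozygous reference) by trinucleotide context and
#' alternative base. Two modes: `"raw"` draws one read uniformly per
#' template (the random-sampling baseline); `"consensus"` uses consensus
#' calls from templates of at least two concordant reads. Rates are
#' error count over opportunity count, where the opportunity denominator for
#' a context is the number of calls evaluated in that context; cells with no
#' opportunities report `NA`, not zero.
#'
#' @param calls Per-read base observations as in [consensus_calls()].
#' @param mask `data.table` with `chrom`, `pos`, `ref`, `context` (the
#'   reference trinucleotide centred on `pos`).
#' @param mode `"consensus"` or `"raw"`.
#' @param seed Seed for the raw-mode read sampling (default 1).
#' @return `data.table` of class `error_matrix` with the full 64x3 grid:
#'   `context`, `alt`, `errors`, `opportunity`, `rate`.
#' @export
error_matrix <- function(calls, mask, mode = c("consensus", "raw"), seed = 1L) {
  mode <- match.arg(mode)
  cc <- as.data.table(calls)
  msk <- as.data.table(mask)
  stopifnot(all(c("chrom", "pos", "ref", "context") %in% names(msk)))
  if (mode == "raw") {
    # one uniformly chosen read per template: shuffle, then keep the first
    # read of each template key
    picked <- with_seed(seed, {
      sh <- cc[sample.int(nrow(cc))]
      unique(sh, by = c("bag", "tag", "chrom", "pos", "strand"))
    })
    obs <- picked[, .(chrom, pos, call = base)]
  } else {
    cons <- consensus_calls(cc)
    obs <- cons[!is.na(consensus), .(chrom, pos, call = consensus)]
  }
  obs <- msk[obs, on = c("chrom", "pos"), nomatch = NULL]
  opp <- obs[, .(opportunity = .N), by = context]
  err <- obs[call != ref, .(errors = .N), by = .(context, alt = call)]
  grid <- CJ(context = trinucleotide_contexts(), alt = BASES)
  grid <- grid[substr(context, 2, 2) != alt]
  grid <- opp[grid, on = "context"]
  grid <- err[grid, on = c("context", "alt")]
  grid[is.na(errors), errors := 0L]
  grid[, rate := ifelse(is.na(opportunity) | opportunity == 0,
                        NA_real_, errors / opportunity)]
  grid[is.na(opportunity), opportunity := 0L]
  setcolorder(grid, c("context", "alt", "errors", "opportunity", "rate"))
  setorder(grid, context, alt)
  setattr(grid, "class", c("error_matrix", class(grid)))
  grid[]
}

#' Candidate variants supported by multiple cells
#'
#' A candidate variant is a non-reference consensus call seen concordantly
#' in at least `min_bags` distinct cells (same alternative allele; capture
#' strand may differ). For each candidate the function also reports whether
#' the position is captured by any template on the opposite strand and, if
#' so, whether the alternative allele is also seen there: true variants are
#' carried by both genomic strands, while unilateral template damage is not.
#'
#' @param calls Per-read base observations as in [consensus_calls()].
#' @param mask Donor truth mask as in [error_matrix()].
#' @param min_bags Minimum number of supporting cells (default 2).
#' @return List: `candidates` (`data.table` of `chrom`, `pos`, `ref`,
#'   `alt`, `n_bags`, `opposite_captured`, `complement_observed`) and
#'   `fractions` (`opposite_captured` and `complement_observed` rates over
#'   candidates).
#' @export
candidate_variants <- function(calls, mask, min_bags = 2L) {
  cc <- as.data.table(calls)
  msk <- as.data.table(mask)
  cons <- consensus_calls(cc)[!is.na(consensus)]
  cons <- msk[cons, on = c("chrom", "pos"), nomatch = NULL]
  vars <- cons[consensus != ref]
  support <- vars[, .(n_bags = uniqueN(bag)), by = .(chrom, pos, ref, alt = consensus)]
  cand <- support[n_bags >= min_bags]
  if (nrow(cand)) {
    # strands on which each position was captured at all, and the strands on
    # which the variant allele itself was seen; in reference frame the
    # complement of a variant on the opposite captured strand is the same
    # alternative base
    pos_strands <- cons[, .(captured_plus = any(strand == "+"),
                            captured_minus = any(strand == "-")),
                        by = .(chrom, pos)]
    var_strands <- vars[, .(var_plus = any(strand == "+"),
                            var_minus = any(strand == "-")),
                        by = .(chrom, pos, alt = consensus)]
    cand <- var_strands[cand, on = c("chrom", "pos", "alt")]
    cand <- pos_strands[cand, on = c("chrom", "pos")]
    cand[, opposite_captured := (var_plus & captured_minus) |
                                (var_minus & captured_plus)]
    cand[, complement_observed := var_plus & var_minus]
    cand[, c("captured_plus", "captured_minus", "var_plus", "var_minus") := NULL]
  } else {
    cand[, `:=`(opposite_captured = logical(0), complement_observed = logical(0))]
  }
  fr <- c(
    opposite_captured = if (nrow(cand)) mean(cand$opposite_captured) else NA_real_,
    complement_observed = if (any(cand$opposite_captured))
      mean(cand$complement_observed[cand$opposite_captured]) else NA_real_
  )
  list(candidates = cand[], fractions = fr)
}
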