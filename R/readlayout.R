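#' Protocol-specific read layouts
#'
#' A read layout records where, on the identifying read, the anchor
#' subsequences, split-barcode slices and varietal-tag (UMI) slices sit.
#' Coordinates are 1-based inclusive positions on the read, the convention in
#' which the protocols are described.
#'
#' Four layouts are built in:
#' \describe{
#'   \item{`dna`}{Read 2 carries the structure: the NlaIII cut site `CATG`
#'     must appear at positions 31--34 (at most one mismatch); the composite
#'     cell barcode is positions 1--6 appended to 22--26 (11 bases); the
#'     varietal tag is positions 27--30. Positions 7--21 are a constant
#'     linker and are not validated.}
#'   \item{`rna2a`}{Two-round split-pool RNA, primer-anchored variant: Read 1
#'     must carry `GGG` at 38--40 (exact) and the first-split primer
#'     `AGTGGAAAAGGAAGGTGGT` at 7--25 with up to two mismatches. Barcodes
#'     1--6 + 26--31 (12 bases), tags 32--37 + 43--48 (12 bases).}
#'   \item{`rna2b`}{Two-round split-pool RNA, whitelist variant: `GGG` at
#'     38--40 with up to one mismatch; barcode slices 1--6 and 26--31 must
#'     each match the round's whitelist. Tags as in `rna2a`.}
#'   \item{`rna3`}{Three-round split-pool RNA: `GGG` at 67--69 with up to one
#'     mismatch; whitelisted barcode slices 1--6, 30--35 and 55--60
#'     (18 bases); tags 61--66 + 72--77.}
#' }
#'
#' @param protocol One of `"dna"`, `"rna2a"`, `"rna2b"`, `"rna3"`.
#' @return An object of class `bag_layout`: a list with elements `protocol`,
#'   `source_read`, `anchors` (data.table of `seq`, `start`, `end`,
#'   `max_mismatch`), `barcode_ranges`, `tag_ranges`, `require_whitelist`,
#'   `min_length`, `barcode_length`, `tag_length`.
#' @examples
#' lay <- bag_layout("dna")
#' lay$barcode_length  # 11
#' @export
bag_layout <- function(protocol = c("dna", "rna2a", "rna2b", "rna3")) {
  protocol <- match.arg(protocol)
  rng <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.table(start = m[, 1], end = m[, 2])
  }
  lay <- switch(protocol,
    dna = list(
      source_read = "read2",
      anchors = data.table(seq = "CATG", start = 31L, end = 34L, max_mismatch = 1L),
      barcode_ranges = rng(1L, 6L, 22L, 26L),
      tag_ranges = rng(27L, 30L),
      require_whitelist = FALSE
    ),
    rna2a = list(
      source_read = "read1",
      anchors = data.table(
        seq = c("GGG", "AGTGGAAAAGGAAGGTGGT"),
        start = c(38L, 7L), end = c(40L, 25L),
        max_mismatch = c(0L, 2L)
      ),
      barcode_ranges = rng(1L, 6L, 26L, 31L),
      tag_ranges = rng(32L, 37L, 43L, 48L),
      require_whitelist = FALSE
    ),
    rna2b = list(
      source_read = "read1",
      anchors = data.table(seq = "GGG", start = 38L, end = 40L, max_mismatch = 1L),
      barcode_ranges = rng(1L, 6L, 26L, 31L),
      tag_ranges = rng(32L, 37L, 43L, 48L),
      require_whitelist = TRUE
    ),
    rna3 = list(
      source_read = "read1",
      anchors = data.table(seq = "GGG", start = 67L, end = 69L, max_mismatch = 1L),
      barcode_ranges = rng(1L, 6L, 30L, 35L, 55L, 60L),
      tag_ranges = rng(61L, 66L, 72L, 77L),
      require_whitelist = TRUE
    )
  )
  lay$protocol <- protocol
  lay$min_length <- max(lay$anchors$end, lay$barcode_ranges$end, lay$tag_ranges$end)
  lay$barcode_length <- sum(lay$barcode_ranges$end - lay$barcode_ranges$start + 1L)
  lay$tag_length <- sum(lay$tag_ranges$end - lay$tag_ranges$start + 1L)
  stopifnot(all(lay$anchors$max_mismatch >= 0L))
  structure(lay, class = "bag_layout")
}

#' @export
print.bag_layout <- function(x, ...) {
  cat("<bag_layout>", x$protocol, "on", x$source_read, "\n")
  cat("  anchors:  ", paste(sprintf("%s@%d-%d (<=%d mm)", x$anchors$seq,
    x$anchors$start, x$anchors$end, x$anchors$max_mismatch), collapse = ", "), "\n")
  cat("  barcode:  ", paste(sprintf("%d-%d", x$barcode_ranges$start,
    x$barcode_ranges$end), collapse = " + "),
    sprintf("(%d bases)", x$barcode_length), "\n")
  cat("  tag:      ", paste(sprintf("%d-%d", x$tag_ranges$start,
    x$tag_ranges$end), collapse = " + "),
    sprintf("(%d bases)", x$tag_length), "\n")
  invisible(x)
}

# Hamming mismatches between equal-length substrings and a fixed pattern,
# vectorised over reads.
.anchor_mismatches <- function(seqs, pattern, start, end) {
  sub <- substr(seqs, start, end)
  n <- end - start + 1L
  if (length(sub) == 0L) return(integer(0))
  chars <- matrix(unlist(strsplit(sub, "", fixed = TRUE), use.names = FALSE),
    ncol = n, byrow = TRUE)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  rowSums(chars != matrix(pat, nrow(chars), n, byrow = TRUE))
}

.concat_slices <- function(seqs, ranges) {
  parts <- lapply(seq_len(nrow(ranges)), function(i)
    substr(seqs, ranges$start[i], ranges$end[i]))
  do.call(paste0, parts)
}

#' Validate read structure and extract barcode and tag
#'
#' Checks each read against a [bag_layout()]: every anchor must match within
#' its mismatch allowance and, for whitelist-gated layouts, every barcode
#' slice must be present in the corresponding split round's whitelist. On
#' pass, the composite cell barcode and varietal tag are extracted by
#' concatenating the layout's slices.
#'
#' @param seqs Character vector of read sequences (the layout's source read:
#'   Read 2 for the DNA protocol, Read 1 for the RNA protocols).
#' @param layout A [bag_layout()].
#' @param whitelists A list of character vectors, one per barcode slice in
#'   layout order (each a set of valid 6-base barcodes). Required when
#'   `layout$require_whitelist` is `TRUE`.
#' @param read_ids Optional read identifiers, recycled into the result.
#' @param rescue_mismatch If `TRUE`, a barcode slice absent from its
#'   whitelist is rescued when exactly one whitelist entry lies within one
#'   mismatch. Default off: a barcode either is valid or is not.
#' @return A `data.table` with one row per read: `read_id`, `pass`, `reason`
#'   (`"ok"`, `"too_short"`, `"anchor"`, `"invalid_barcode"`), `bag_barcode`,
#'   `varietal_tag` (`NA` for failing reads).
#' @examples
#' lay <- bag_layout("dna")
#' r2 <- paste0(strrep("A", 30), "CATG", strrep("T", 40))
#' extract_barcodes(r2, lay)
#' @export
extract_barcodes <- function(seqs, layout, whitelists = NULL, read_ids = NULL,
                             rescue_mismatch = FALSE) {
  stopifnot(inherits(layout, "bag_layout"))
  n <- length(seqs)
  if (is.null(read_ids)) read_ids <- sprintf("read%06d", seq_len(n))
  res <- data.table(
    read_id = read_ids,
    pass = rep(TRUE, n),
    reason = rep("ok", n),
    bag_barcode = rep(NA_character_, n),
    varietal_tag = rep(NA_character_, n)
  )
  short <- nchar(seqs) < layout$min_length
  res[short, `:=`(pass = FALSE, reason = "too_short")]
  live <- which(!short)
  if (length(live)) {
    bad_anchor <- rep(FALSE, length(live))
    for (i in seq_len(nrow(layout$anchors))) {
      mm <- .anchor_mismatches(seqs[live], layout$anchors$seq[i],
        layout$anchors$start[i], layout$anchors$end[i])
      bad_anchor <- bad_anchor | (mm > layout$anchors$max_mismatch[i])
    }
    res[live[bad_anchor], `:=`(pass = FALSE, reason = "anchor")]
    live <- live[!bad_anchor]
  }
  if (length(live) && layout$require_whitelist) {
    if (is.null(whitelists))
      stop("layout '", layout$protocol, "' requires per-round barcode whitelists")
    stopifnot(length(whitelists) == nrow(layout$barcode_ranges))
    slices <- lapply(seq_len(nrow(layout$barcode_ranges)), function(i)
      substr(seqs[live], layout$barcode_ranges$start[i], layout$barcode_ranges$end[i]))
    bad_bc <- rep(FALSE, length(live))
    for (i in seq_along(slices)) {
      ok <- slices[[i]] %chin% whitelists[[i]]
      if (rescue_mismatch && any(!ok)) {
        fix <- .rescue_barcodes(slices[[i]][!ok], whitelists[[i]])
        slices[[i]][!ok][!is.na(fix)] <- fix[!is.na(fix)]
        ok[!ok] <- !is.na(fix)
      }
      bad_bc <- bad_bc | !ok
    }
    res[live[bad_bc], `:=`(pass = FALSE, reason = "invalid_barcode")]
    keep <- !bad_bc
    if (any(keep)) {
      bc <- do.call(paste0, lapply(slices, `[`, keep))
      res[live[keep], bag_barcode := bc]
    }
    live <- live[keep]
  } else if (length(live)) {
    res[live, bag_barcode := .concat_slices(seqs[live], layout$barcode_ranges)]
  }
  if (length(live))
    res[live, varietal_tag := .concat_slices(seqs[live], layout$tag_ranges)]
  res[]
}

# unique 1-mismatch whitelist rescue; NA when no or ambiguous match
.rescue_barcodes <- function(bad, whitelist) {
  vapply(bad, function(b) {
    mm <- .anchor_mismatches(whitelist, b, 1L, nchar(b))
    hit <- which(mm == 1L)
    if (length(hit) == 1L) whitelist[hit] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Adapter-trim a read pair and apply the length-retention rule
#'
#' Removes 3' bases matching any adapter or universal-primer sequence by
#' suffix-overlap matching (minimum overlap `min_overlap`, at most
#' `max_mismatch_frac` mismatching bases in the overlap), then retains the
#' pair only if both trimmed mates are at least `min_length` bases.
#'
#' @param read1,read2 Character vectors of mate sequences (same length).
#' @param adapters Character vector of adapter / universal primer sequences.
#' @param min_length Minimum trimmed length for both mates; pairs below it
#'   are dropped (default 100).
#' @param min_overlap Minimum adapter suffix overlap considered (default 5).
#' @param max_mismatch_frac Maximum fraction of mismatches tolerated in the
#'   overlap (default 0.1).
#' @return `data.table` with `read1`, `read2` (trimmed), `len1`, `len2`,
#'   `keep`.
#' @export
trim_read_pairs <- function(read1, read2, adapters, min_length = 100L,
                            min_overlap = 5L, max_mismatch_frac = 0.1) {
  stopifnot(length(read1) == length(read2))
  t1 <- vapply(read1, .trim_one, character(1), adapters, min_overlap,
    max_mismatch_frac, USE.NAMES = FALSE)
  t2 <- vapply(read2, .trim_one, character(1), adapters, min_overlap,
    max_mismatch_frac, USE.NAMES = FALSE)
  data.table(
    read1 = t1, read2 = t2,
    len1 = nchar(t1), len2 = nchar(t2),
    keep = nchar(t1) >= min_length & nchar(t2) >= min_length
  )
}

.trim_one <- function(seq, adapters, min_overlap, max_mismatch_frac) {
  L <- nchar(seq)
  cut <- L + 1L  # first trimmed position
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (ad in adapters) {
    ac <- strsplit(ad, "", fixed = TRUE)[[1]]
    la <- length(ac)
    for (s in seq_len(L - min_overlap + 1L)) {
      if (s >= cut) break
      ov <- min(L - s + 1L, la)
      mm <- sum(sc[s:(s + ov - 1L)] != ac[1:ov])
      if (mm <= floor(max_mismatch_frac * ov)) {
        cut <- s
        break
      }
    }
  }
  if (cut > L) seq else substr(seq, 1L, cut - 1L)
}

#' Classify aligned pairs as proper or improper
#'
#' A pair is proper when both mates map to the same chromosome within
#' `max_distance` of each other, in convergent (forward/reverse, facing)
#' orientation, and the identifying read passed structure validation (for the
#' DNA protocol, the NlaIII `CATG` check on Read 2).
#'
#' @param pairs `data.table`/`data.frame` with columns `chrom1`, `pos1`,
#'   `strand1`, `mapped1`, `chrom2`, `pos2`, `strand2`, `mapped2`,
#'   `structure_ok`.
#' @param max_distance Maximum distance between mate start positions
#'   (default 2000).
#' @return The input with logical `proper` and character `reason` columns
#'   appended.
#' @export
classify_proper_pairs <- function(pairs, max_distance = 2000L) {
  p <- as.data.table(pairs)
  need <- c("chrom1", "pos1", "strand1", "mapped1",
            "chrom2", "pos2", "strand2", "mapped2", "structure_ok")
  stopifnot(all(need %in% names(p)))
  reason <- rep("proper", nrow(p))
  reason[!(p$mapped1 & p$mapped2)] <- "unmapped_mate"
  same_chr <- p$chrom1 == p$chrom2
  reason[reason == "proper" & !same_chr] <- "different_chromosome"
  near <- abs(p$pos1 - p$pos2) <= max_distance
  reason[reason == "proper" & !near] <- "too_far"
  opp <- p$strand1 != p$strand2
  reason[reason == "proper" & !opp] <- "same_strand"
  # convergent: the plus-strand mate must start at or before the minus mate
  fwd_pos <- ifelse(p$strand1 == "+", p$pos1, p$pos2)
  rev_pos <- ifelse(p$strand1 == "+", p$pos2, p$pos1)
  reason[reason == "proper" & opp & fwd_pos > rev_pos] <- "divergent"
  reason[reason == "proper" & !p$structure_ok] <- "structure"
  p[, proper := reason == "proper"]
  p[, reason := reason]
  p[]
}
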