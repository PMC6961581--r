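#' Build empirical equal-count genome bins
#'
#' Bin boundaries are placed at empirical quantiles of a pooled set of
#' template map positions from libraries of constant copy number, so that
#' under constant copy number every bin is expected to receive the same
#' number of templates. Mappability and accessibility biases are thereby
#' absorbed into variable bin widths instead of being modelled.
#'
#' Bins are apportioned to chromosomes so that every bin's target count is
#' `floor(n/B)` or `ceil(n/B)` positions; within a chromosome boundaries are
#' spread by Bresenham rounding. Rebinning the pooled reference against its
#' own scheme therefore yields per-bin counts equal to within one.
#'
#' @param positions `data.table`/`data.frame` with columns `chrom` and
#'   `pos` (pooled template positions), or a numeric vector for a single
#'   chromosome.
#' @param B Number of bins.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param genome Optional [Biostrings::DNAStringSet] (names matching
#'   chromosomes) from which per-bin GC fractions are computed.
#' @return `data.table` of class `bin_scheme`: `chrom`, `start`, `end`
#'   (1-based inclusive, tiling each chromosome) and `gc` (`NA` without a
#'   genome).
#' @examples
#' pos <- data.frame(chrom = "chr1", pos = seq(1, 100000, by = 20))
#' bins <- build_empirical_bins(pos, B = 5, chrom_sizes = c(chr1 = 100000))
#' @export
build_empirical_bins <- function(positions, B, chrom_sizes, genome = NULL) {
  if (is.numeric(positions) && is.null(dim(positions))) {
    stopifnot(length(chrom_sizes) == 1L)
    positions <- data.table(chrom = names(chrom_sizes), pos = positions)
  }
  p <- as.data.table(positions)[, .(chrom, pos)]
  stopifnot(!is.null(names(chrom_sizes)))
  if (B > uniqueN(p, by = c("chrom", "pos")))
    stop("B exceeds the number of distinct positions")
  setorder(p, chrom, pos)
  n_c <- p[, .N, by = chrom]
  n <- sum(n_c$N)
  q <- n %/% B
  if (q < 1L) stop("fewer positions than bins")

  # apportion bins so every bin holds q or q+1 positions
  lower <- pmax(1L, ceiling(n_c$N / (q + 1)))
  upper <- pmax(lower, floor(n_c$N / q))
  bc <- lower
  remaining <- B - sum(bc)
  if (remaining < 0L)
    stop("cannot apportion ", B, " bins across chromosomes; reduce B")
  while (remaining > 0L) {
    load <- ifelse(bc < upper, n_c$N / bc, -Inf)
    k <- which.max(load)
    if (!is.finite(load[k])) stop("cannot apportion bins; reduce B")
    bc[k] <- bc[k] + 1L
    remaining <- remaining - 1L
  }

  out <- vector("list", nrow(n_c))
  for (ci in seq_len(nrow(n_c))) {
    ch <- n_c$chrom[ci]
    pos <- p[chrom == ch, pos]
    m <- length(pos)
    k <- bc[ci]
    idx <- floor(seq_len(k) * m / k)  # Bresenham cut indices
    ends <- pos[idx]
    ends[k] <- chrom_sizes[[ch]]
    starts <- c(1, head(ends, -1) + 1)
    out[[ci]] <- data.table(chrom = ch, start = starts, end = ends)
  }
  bins <- rbindlist(out)
  if (any(bins$end < bins$start))
    stop("degenerate bins (duplicated boundary positions); reduce B")
  bins[, gc := NA_real_]
  if (!is.null(genome)) {
    for (ch in unique(bins$chrom)) {
      i <- which(bins$chrom == ch)
      v <- Biostrings::Views(genome[[ch]], start = bins$start[i], end = bins$end[i])
      bins$gc[i] <- as.numeric(Biostrings::letterFrequency(v, "GC")) /
        (bins$end[i] - bins$start[i] + 1)
    }
  }
  setattr(bins, "class", c("bin_scheme", class(bins)))
  bins[]
}

#' Count positions per bin
#'
#' @param positions As in [build_empirical_bins()] (one row per template).
#' @param bins A `bin_scheme`.
#' @return Integer vector of per-bin counts, in bin order.
#' @export
bin_counts <- function(positions, bins) {
  if (is.numeric(positions) && is.null(dim(positions)))
    positions <- data.table(chrom = bins$chrom[1], pos = positions)
  p <- as.data.table(positions)
  counts <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    pos <- p[chrom == ch, pos]
    pos <- pos[pos >= bins$start[i][1] & pos <= bins$end[i][length(i)]]
    if (!length(pos)) next
    hit <- findInterval(pos, bins$start[i])
    tab <- tabulate(hit, nbins = length(i))
    counts[i] <- counts[i] + tab
  }
  counts
}

#' Normalize a bincount profile and correct GC bias
#'
#' Bin counts are converted to ratios `(count + 1) / mean(count + 1)`, then
#' GC content is corrected by locally weighted regression (lowess, span
#' `f`) of the log ratio on per-bin GC fraction; residuals are exponentiated
#' and rescaled so the normalized vector has mean one, the scale on which
#' integer-grid ploidy estimation operates.
#'
#' Cells are conventionally admitted to copy-number analysis only with at
#' least 100,000 unique templates at full scale; that filter is applied at
#' the pipeline level (see [run_dna()]), not here.
#'
#' @param counts Integer vector of per-bin counts.
#' @param gc Per-bin GC fractions; `NULL` or all-`NA` skips GC correction.
#' @param span Lowess span `f` (default 0.05).
#' @return Numeric vector with mean exactly 1.
#' @export
normalize_profile <- function(counts, gc = NULL, span = 0.05) {
  if (all(counts == 0)) stop("empty profile")
  ratio <- (counts + 1) / mean(counts + 1)
  if (!is.null(gc) && !all(is.na(gc)) && var(gc, na.rm = TRUE) > 0) {
    lw <- lowess(gc, log(ratio), f = span)
    fit <- approx(lw$x, lw$y, xout = gc, rule = 2, ties = mean)$y
    ratio <- exp(log(ratio) - fit)
  }
  ratio / mean(ratio)
}

#' Segment a normalized profile by circular binary segmentation
#'
#' Recursively locates, within each current segment, the arc whose mean most
#' differs from the rest (maximal two-sample t statistic over all arcs of at
#' least `min_width` bins); the split is accepted when its permutation
#' p-value falls below `alpha`, and the procedure recurses into the
#' resulting pieces. Splits whose adjacent segment means differ by less than
#' `undo_sd` residual standard deviations are then undone (the residual SD
#' is the robust MAD of successive bin differences divided by sqrt(2)).
#'
#' @param x Normalized bin-ratio vector (no `NA`/`NaN`).
#' @param alpha Permutation significance level to accept a split
#'   (default 0.02).
#' @param nperm Number of permutations (default 1000).
#' @param undo_sd Undo threshold in residual SD units (default 0.5).
#' @param min_width Minimum segment width in bins (default 3).
#' @param seed Seed for the permutation stream (default 1); results are
#'   deterministic given `x` and `seed`.
#' @return List of class `cn_segments`: `segments` (`data.table` of
#'   `start`, `end`, `nbins`, `mean`), `segmented` (per-bin segment means),
#'   `breakpoints` (bin indices after which a segment ends, excluding the
#'   last).
#' @export
segment_profile <- function(x, alpha = 0.02, nperm = 1000L, undo_sd = 0.5,
                            min_width = 3L, seed = 1L) {
  if (anyNA(x) || any(!is.finite(x))) stop("profile contains NA/NaN")
  stopifnot(alpha > 0, alpha < 1, min_width >= 2)
  n <- length(x)
  bounds <- with_seed(seed, .cbs_recurse(x, 1L, n, alpha, nperm, min_width))
  segs <- .segments_from_bounds(x, bounds, n)
  if (nrow(segs) > 1L && undo_sd > 0) {
    sd_res <- mad(diff(x)) / sqrt(2)
    segs <- .undo_splits(x, segs, undo_sd * sd_res)
  }
  segmented <- rep(segs$mean, segs$nbins)
  structure(list(segments = segs, segmented = segmented,
                 breakpoints = head(segs$end, -1)),
            class = "cn_segments")
}

# depth-first CBS recursion; returns sorted break positions (bin index after
# which a new segment starts)
.cbs_recurse <- function(x, lo, hi, alpha, nperm, min_width) {
  m <- hi - lo + 1L
  if (m < 2L * min_width) return(integer(0))
  seg <- x[lo:hi]
  if (var(seg) < 1e-18) return(integer(0))  # flat: nothing to split
  scan <- .cbs_max_t(seg, min_width)
  if (scan$i < 0) return(integer(0))
  p <- .cbs_perm_pvalue(seg, scan$t, as.integer(nperm), min_width)
  if (p >= alpha) return(integer(0))
  cuts <- integer(0)
  if (scan$i > 0L) cuts <- c(cuts, lo + scan$i - 1L)
  if (scan$j < m) cuts <- c(cuts, lo + scan$j - 1L)
  if (!length(cuts)) return(integer(0))
  pieces <- rbind(c(lo, cuts[1]),
                  if (length(cuts) == 2L) c(cuts[1] + 1L, cuts[2]),
                  c(cuts[length(cuts)] + 1L, hi))
  sub <- lapply(seq_len(nrow(pieces)), function(i)
    .cbs_recurse(x, pieces[i, 1], pieces[i, 2], alpha, nperm, min_width))
  sort(unique(c(cuts, unlist(sub))))
}

.segments_from_bounds <- function(x, bounds, n) {
  ends <- c(bounds, n)
  starts <- c(1L, bounds + 1L)
  data.table(start = starts, end = ends, nbins = ends - starts + 1L,
             mean = vapply(seq_along(ends), function(i)
               mean(x[starts[i]:ends[i]]), numeric(1)))
}

.undo_splits <- function(x, segs, threshold) {
  repeat {
    if (nrow(segs) < 2L) break
    d <- abs(diff(segs$mean))
    k <- which.min(d)
    if (d[k] >= threshold) break
    merged <- data.table(start = segs$start[k], end = segs$end[k + 1])
    merged[, nbins := end - start + 1L]
    merged[, mean := mean(x[merged$start:merged$end])]
    segs <- rbind(segs[seq_len(k - 1L)], merged,
                  segs[-seq_len(k + 1L)])
  }
  segs
}

#' Estimate ploidy by integer grid search
#'
#' A mean-one segmented profile is multiplied by candidate ploidies 1.5,
#' 1.55, ..., 4.5; the multiplier minimizing the bin-weighted sum of squared
#' distances between the scaled segment values and their nearest integers is
#' the ploidy estimate. Rounding is half-away-from-zero; exact ties across
#' multipliers resolve to the smallest multiplier, biasing toward the
#' diploid end of the grid.
#'
#' @param segments A `cn_segments` object or a per-bin segmented vector with
#'   mean approximately 1.
#' @param weights Per-segment (or per-bin) weights; defaults to segment bin
#'   counts (or 1 per bin).
#' @param grid Candidate multipliers (default `seq(1.5, 4.5, by = 0.05)`).
#' @return List: `ploidy` (the chosen multiplier), `scaled` (per-bin scaled
#'   segment values), `integer_states` (per-bin rounded copy number), `sse`
#'   (the attained objective).
#' @examples
#' seg <- rep(c(0.5, 1, 1.5), times = c(25, 50, 25))
#' estimate_ploidy(seg)$ploidy  # 2
#' @export
estimate_ploidy <- function(segments, weights = NULL,
                            grid = seq(1.5, 4.5, by = 0.05)) {
  if (inherits(segments, "cn_segments")) {
    s <- segments$segments$mean
    w <- weights %||% segments$segments$nbins
    expand <- segments$segments$nbins
  } else {
    s <- as.numeric(segments)
    w <- weights %||% rep(1, length(s))
    expand <- rep(1L, length(s))
  }
  sse <- vapply(grid, function(m) {
    v <- m * s
    sum(w * (v - .round_half_away(v))^2)
  }, numeric(1))
  k <- which.min(sse)  # ties resolve to the smallest multiplier
  m <- grid[k]
  scaled <- rep(m * s, expand)
  list(ploidy = m, scaled = scaled,
       integer_states = .round_half_away(scaled), sse = sse[k])
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Hierarchically cluster copy-number profiles
#'
#' Manhattan distances between per-cell segmented profiles, agglomerated
#' with Ward's method (`ward.D2`), the combination under which distinct
#' clones separate into clean heatmap blocks.
#'
#' @param profiles Numeric matrix, one column per cell (bins in rows), or
#'   one row per cell when `cells_in` is `"rows"`.
#' @param cells_in `"columns"` (default) or `"rows"`.
#' @return An [stats::hclust] object over cells.
#' @export
cluster_profiles <- function(profiles, cells_in = c("columns", "rows")) {
  cells_in <- match.arg(cells_in)
  m <- if (cells_in == "columns") t(profiles) else profiles
  if (nrow(m) < 2L) stop("need at least 2 profiles")
  hclust(dist(m, method = "manhattan"), method = "ward.D2")
}

#' Display transform for high-amplitude profiles
#'
#' Genome plots of highly amplified profiles use `log(y + 1)` on the copy
#' number axis, with guide lines conventionally drawn at copy numbers 1, 2,
#' 3, 4, 20, 50 and 80.
#'
#' @param y Copy-number values.
#' @return `log(y + 1)`.
#' @export
cn_display_transform <- function(y) log(y + 1)

#' @export
print.cn_segments <- function(x, ...) {
  cat("<cn_segments>", nrow(x$segments), "segments over",
      length(x$segmented), "bins\n")
  print(x$segments)
  invisible(x)
}
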