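#' Call cell-containing barcodes from a barcode-rank curve
#'
#' Barcodes are ranked by descending count and the cumulative count fraction
#' is plotted against normalized rank. Libraries in which a subset of
#' barcodes received a cell show a sharp inflection ("knee") in this curve;
#' barcodes left of the knee are called as cells. The knee is located as the
#' point of maximum perpendicular distance between the cumulative-fraction
#' curve and the chord joining its endpoints. When no point departs from the
#' chord by more than `min_distance` (e.g. all counts equal, so the curve is
#' a straight line) the call is refused rather than guessed: an empty
#' selection is returned with a `"no_knee"` diagnostic.
#'
#' @param counts Named numeric vector of per-barcode counts (read or
#'   template counts), or a data.frame with columns `barcode` and `count`.
#' @param min_distance Minimum perpendicular distance (both axes normalized
#'   to \[0,1\]) for a knee to be accepted; default 0.05.
#' @param threshold Optional manual count threshold overriding knee
#'   detection: all barcodes with `count >= threshold` are selected.
#' @return A list of class `cell_calls`: `selected` (character vector of
#'   barcodes, a prefix of the descending-count ranking; ties at the knee
#'   count are included), `knee_index`, `diagnostic` (`"ok"` or
#'   `"no_knee"`), and `ranked` (data.table of `barcode`, `count`,
#'   `selected`).
#' @examples
#' counts <- c(a = 100, b = 100, c = 100, d = 1, e = 1, f = 1, g = 1)
#' call_cells(counts)$selected
#' @export
call_cells <- function(counts, min_distance = 0.05, threshold = NULL) {
  if (is.data.frame(counts)) {
    cnt <- as.data.table(counts)
    stopifnot(all(c("barcode", "count") %in% names(cnt)))
  } else {
    stopifnot(!is.null(names(counts)))
    cnt <- data.table(barcode = names(counts), count = as.numeric(counts))
  }
  cnt <- cnt[count > 0]
  if (uniqueN(cnt$barcode) < 2L)
    stop("need at least 2 distinct barcodes with nonzero counts")
  # deterministic ranking: count descending, barcode as tie-break
  setorderv(cnt, c("count", "barcode"), order = c(-1L, 1L))
  n <- nrow(cnt)

  if (!is.null(threshold)) {
    sel <- cnt$count >= threshold
    cnt[, selected := sel]
    return(structure(list(
      selected = cnt$barcode[sel],
      knee_index = if (any(sel)) max(which(sel)) else 0L,
      diagnostic = "manual_threshold", ranked = cnt[]
    ), class = "cell_calls"))
  }

  x <- seq_len(n) / n
  y <- cumsum(cnt$count) / sum(cnt$count)
  # perpendicular distance to the chord from (x1,y1) to (xn,yn)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + x[n] * y[1] - y[n] * x[1]) / sqrt(dx^2 + dy^2)
  knee <- which.max(d)
  if (d[knee] < min_distance) {
    cnt[, selected := FALSE]
    return(structure(list(selected = character(0), knee_index = 0L,
      diagnostic = "no_knee", ranked = cnt[]), class = "cell_calls"))
  }
  # inclusive prefix: extend through barcodes tied with the knee count
  while (knee < n && cnt$count[knee + 1L] == cnt$count[knee]) knee <- knee + 1L
  cnt[, selected := seq_len(n) <= knee]
  structure(list(selected = cnt$barcode[seq_len(knee)], knee_index = knee,
    diagnostic = "ok", ranked = cnt[]), class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat("<cell_calls>", length(x$selected), "of", nrow(x$ranked),
      "barcodes selected;", "knee at rank", x$knee_index,
      sprintf("[%s]\n", x$diagnostic))
  invisible(x)
}
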