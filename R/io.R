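#' Read a FASTQ file
#'
#' Plain or gzip-compressed four-line-record FASTQ.
#'
#' @param path File path.
#' @return `data.table` with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4L)])
  ids <- sub("[ \t].*$", "", ids)
  data.table(read_id = ids,
             seq = lines[seq(2, length(lines), by = 4L)],
             qual = lines[seq(4, length(lines), by = 4L)])
}

#' Write a FASTQ file
#'
#' @param read_ids,seqs Character vectors.
#' @param path Output path (`.gz` suffix writes gzip).
#' @param quals Optional quality strings; defaults to uniform `"I"`.
#' @export
write_fastq <- function(read_ids, seqs, path, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  rec <- as.vector(rbind(paste0("@", read_ids), seqs, "+", quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Demultiplex structured FASTQ reads
#'
#' Validates each read of the identifying mate against the protocol layout,
#' extracts the composite barcode and varietal tag, and annotates passing
#' reads by appending `|<barcode>|<tag>` to the read identifier (the same
#' annotation travels as `CB`/`UB`-style attributes when alignments are
#' written). The mate pair is kept or dropped as a unit.
#'
#' @param fastq_structured Path to the FASTQ carrying the structured read
#'   (Read 2 for the DNA protocol, Read 1 for RNA).
#' @param fastq_mate Optional path to the other mate.
#' @param protocol As in [bag_layout()].
#' @param whitelists Per-round barcode whitelists where the layout requires
#'   them.
#' @param out_prefix If non-`NULL`, annotated FASTQ files
#'   `<out_prefix>_structured.fastq` (and `_mate.fastq`) are written for
#'   the passing reads.
#' @return `data.table`: per-read `read_id`, `pass`, `reason`,
#'   `bag_barcode`, `varietal_tag`.
#' @export
demux_fastq <- function(fastq_structured, fastq_mate = NULL, protocol = "dna",
                        whitelists = NULL, out_prefix = NULL) {
  layout <- bag_layout(protocol)
  fq <- read_fastq(fastq_structured)
  res <- extract_barcodes(fq$seq, layout, whitelists = whitelists,
                          read_ids = fq$read_id)
  if (!is.null(out_prefix)) {
    ok <- which(res$pass)
    ann <- paste0(res$read_id[ok], "|", res$bag_barcode[ok], "|",
                  res$varietal_tag[ok])
    write_fastq(ann, fq$seq[ok], paste0(out_prefix, "_structured.fastq"),
                fq$qual[ok])
    if (!is.null(fastq_mate)) {
      mate <- read_fastq(fastq_mate)
      m <- match(res$read_id[ok], mate$read_id)
      write_fastq(ann, mate$seq[m], paste0(out_prefix, "_mate.fastq"),
                  mate$qual[m])
    }
  }
  res
}

#' Write annotated alignments as SAM text
#'
#' Minimal single-block SAM emission for simulated or annotated alignments;
#' barcode and tag travel both in the read name and as `CB`/`UB` attributes.
#'
#' @param reads Annotated alignment table (`read_id`, `bag`, `tag`,
#'   `chrom`, `pos`, `end`, `strand`).
#' @param chrom_sizes Named chromosome lengths for the header.
#' @param path Output path.
#' @export
write_sam <- function(reads, chrom_sizes, path) {
  r <- as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  len <- r$end - r$pos + 1L
  flag <- ifelse(r$strand == "-", 16L, 0L)
  rec <- sprintf("%s|%s|%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s",
                 r$read_id, r$bag, r$tag, flag, r$chrom, r$pos, len,
                 strrep("N", len), strrep("I", len), r$bag, r$tag)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read annotated alignments from SAM text
#'
#' Inverse of [write_sam()]: accepts `CB`/`UB` attributes or
#' `name|barcode|tag` identifiers.
#'
#' @param path SAM file path.
#' @return Annotated alignment `data.table`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- tstrsplit(lines, "\t")
  flag <- as.integer(f[[2]])
  dt <- data.table(
    read_id = f[[1]], chrom = f[[3]], pos = as.integer(f[[4]]),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapped = bitwAnd(flag, 4L) == 0L
  )
  cigar_len <- as.integer(sub("M$", "", f[[6]]))
  dt[, end := pos + cigar_len - 1L]
  tags <- regmatches(lines, regexpr("CB:Z:[^\t]+", lines))
  if (length(tags) == nrow(dt)) dt[, bag := sub("CB:Z:", "", tags)]
  ub <- regmatches(lines, regexpr("UB:Z:[^\t]+", lines))
  if (length(ub) == nrow(dt)) dt[, tag := sub("UB:Z:", "", ub)]
  if (!"bag" %in% names(dt)) {
    parts <- tstrsplit(dt$read_id, "|", fixed = TRUE)
    if (length(parts) >= 3L) dt[, `:=`(bag = parts[[2]], tag = parts[[3]])]
  }
  dt[]
}
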