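#' Run the single-cell DNA copy-number pipeline end to end
#'
#' Orchestrates cell calling, template collapse, empirical binning,
#' normalization, segmentation, ploidy scaling and clustering over
#' annotated alignments (either from a [simulate_library()] object or
#' supplied directly), accumulating a manifest of per-stage counters.
#'
#' @param input A `bag_sim` object, or a list with elements `reads`
#'   (annotated alignments), `barcode_counts` (for cell calling; computed
#'   from reads when absent) and `reference_positions` (pooled
#'   constant-copy positions for binning; defaults to the pooled selected
#'   cells).
#' @param chrom_sizes Named chromosome lengths (taken from a `bag_sim`'s
#'   config when available).
#' @param B Number of bins (default 200 at desk scale; 5000 or 20000 at
#'   study scale).
#' @param genome Optional [Biostrings::DNAStringSet] for per-bin GC
#'   correction.
#' @param min_templates Minimum unique templates for a cell to enter
#'   copy-number analysis (default 0; the study-scale convention is
#'   100,000).
#' @param alpha,nperm,undo_sd,min_width Segmentation parameters, see
#'   [segment_profile()].
#' @param seed Seed governing segmentation permutations (default 1).
#' @return List of class `bag_run`: `cells` (cell calls), `templates`,
#'   `bins`, `bincounts` (bins x cells), `normalized`, `segments` (per-cell
#'   `cn_segments`), `ploidy` (`data.table` of `bag`, `ploidy`),
#'   `integer_states` (bins x cells), `clusters` ([stats::hclust] or `NULL`
#'   for a single cell), `manifest`.
#' @export
run_dna <- function(input, chrom_sizes = NULL, B = 200L, genome = NULL,
                    min_templates = 0L, alpha = 0.02, nperm = 1000L,
                    undo_sd = 0.5, min_width = 3L, seed = 1L) {
  if (inherits(input, "bag_sim")) chrom_sizes <- input$config$chrom_sizes
  if (is.null(chrom_sizes)) stop("chrom_sizes required")
  reads <- as.data.table(input$reads)
  if (nrow(reads) == 0L) stop("no input reads")
  manifest <- list(stages = list(), seed = seed)
  log_stage <- function(m, name, n_in, n_out) {
    m$stages[[name]] <- list(n_in = n_in, n_out = n_out)
    m
  }

  counts <- input$barcode_counts %||% reads[, .(count = .N), by = .(barcode = bag)]
  calls <- call_cells(counts)
  if (!length(calls$selected)) stop("no cells called")
  sel <- reads[bag %in% calls$selected]
  manifest <- log_stage(manifest, "cell_calling", nrow(reads), nrow(sel))

  tpl <- collapse_templates(sel)
  manifest <- log_stage(manifest, "collapse", nrow(sel), nrow(tpl))

  tpl_counts <- tpl[, .N, by = bag]
  admitted <- tpl_counts[N >= min_templates, bag]
  tpl <- tpl[bag %in% admitted]
  manifest <- log_stage(manifest, "admission", length(calls$selected),
                        length(admitted))
  if (!length(admitted)) stop("no cells pass the template threshold")

  refpos <- input$reference_positions %||% tpl[, .(chrom, pos)]
  bins <- build_empirical_bins(refpos, B, chrom_sizes, genome = genome)

  bags <- sort(admitted)
  bincounts <- vapply(bags, function(b)
    bin_counts(tpl[bag == b, .(chrom, pos)], bins), numeric(nrow(bins)))
  normalized <- apply(bincounts, 2, normalize_profile, gc = bins$gc)
  segments <- lapply(bags, function(b)
    segment_profile(normalized[, b], alpha = alpha, nperm = nperm,
                    undo_sd = undo_sd, min_width = min_width, seed = seed))
  names(segments) <- bags
  pl <- lapply(segments, estimate_ploidy)
  ploidy <- data.table(bag = bags,
                       ploidy = vapply(pl, `[[`, numeric(1), "ploidy"))
  integer_states <- vapply(pl, `[[`, numeric(nrow(bins)), "integer_states")
  segmat <- vapply(segments, `[[`, numeric(nrow(bins)), "segmented")
  clusters <- if (length(bags) >= 2L) cluster_profiles(segmat) else NULL
  manifest <- log_stage(manifest, "cnv", length(bags), length(bags))

  structure(list(cells = calls, templates = tpl, bins = bins,
                 bincounts = bincounts, normalized = normalized,
                 segments = segments, ploidy = ploidy,
                 integer_states = integer_states, clusters = clusters,
                 manifest = manifest),
            class = "bag_run")
}

#' Run the single-cell RNA pipeline end to end
#'
#' Gene assignment, template collapse into a gene-by-cell matrix, optional
#' SNV-based identity calling, and PCA with PC1 marker genes.
#'
#' @param reads Annotated alignments (`read_id`, `bag`, `tag`, `chrom`,
#'   `pos`, `end`).
#' @param exons Exon model as in [assign_reads_to_genes()].
#' @param snv_observations,panel Optional per-cell consensus SNV
#'   observations and source panel for [assign_identity()].
#' @param min_templates Minimum unique templates per cell (cells below are
#'   dropped; the three-round study convention is 5000).
#' @param bulk Optional bulk expression matrix projected into the PCA.
#' @return List of class `bag_run_rna`: `matrix` (genes x cells),
#'   `identity` (or `NULL`), `pca` ([pca_markers()] result, or `NULL` with
#'   fewer than 3 cells), `manifest`.
#' @export
run_rna <- function(reads, exons, snv_observations = NULL, panel = NULL,
                    min_templates = 0L, bulk = NULL) {
  r <- as.data.table(reads)
  if (nrow(r) == 0L) stop("no input reads")
  manifest <- list(stages = list())
  assigned <- assign_reads_to_genes(r, exons, mode = "singlecell")
  manifest$stages$gene_assignment <- list(
    n_in = nrow(r), n_out = sum(!is.na(assigned$gene)),
    ambiguous = attr(assigned, "ambiguous"))
  mat <- expression_matrix(assigned)
  tpl_per_cell <- colSums(mat)
  keep <- names(tpl_per_cell)[tpl_per_cell >= min_templates]
  mat <- mat[, keep, drop = FALSE]
  manifest$stages$admission <- list(n_in = length(tpl_per_cell),
                                    n_out = length(keep))
  idcalls <- NULL
  if (!is.null(snv_observations) && !is.null(panel)) {
    obs <- as.data.table(snv_observations)[bag %in% keep]
    idcalls <- assign_identity(obs, panel)
  }
  pca <- if (ncol(mat) >= 3L) pca_markers(mat, bulk = bulk) else NULL
  structure(list(matrix = mat, identity = idcalls, pca = pca,
                 manifest = manifest),
            class = "bag_run_rna")
}

#' @export
print.bag_run <- function(x, ...) {
  cat("<bag_run>", ncol(x$bincounts), "cells,", nrow(x$bins), "bins\n")
  cat("  ploidies:", paste(format(sort(unique(x$ploidy$ploidy))),
                           collapse = ", "), "\n")
  invisible(x)
}
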