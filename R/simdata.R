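#' Simulation configuration
#'
#' Desk-scale defaults emulate the study conditions the pipeline is built
#' for: a 2-Mb two-chromosome toy genome, 100 cells drawn from two clones
#' (60%/40%) with distinct planted copy-number states, a read-per-template
#' multiplicity of 3.5, composite barcodes drawn from two 96-barcode split
#' rounds, and a background of empty-droplet barcodes at roughly 100-fold
#' lower depth than cells. Error rates default to zero; tests switch on
#' read-level error and template damage explicitly.
#'
#' @param protocol Library layout, as in [bag_layout()].
#' @param seed Integer seed (mandatory; same seed, same outputs).
#' @param chrom_sizes Named chromosome lengths.
#' @param clones Named list of copy-number state tables (`chrom`, `start`,
#'   `end`, `state`); `NULL` uses a diploid clone plus a clone with one
#'   gain and one loss.
#' @param clone_fractions Cell fractions per clone (sums to 1).
#' @param n_cells Number of cells.
#' @param templates_per_cell Mean unique templates per cell.
#' @param rpt Mean reads per template (geometric depth, minimum 1).
#' @param read_length Genomic footprint length per read.
#' @param read_error Per-base read-level (sequencing) error rate.
#' @param damage_error Per-base template-damage rate (errors shared by all
#'   reads of a template).
#' @param contamination Fraction of each cell's templates drawn from
#'   another cell's genome.
#' @param n_background Number of empty-droplet background barcodes.
#' @param background_mean Mean reads per background barcode.
#' @param barcodes_per_round Barcode whitelist size per split round
#'   (default 96).
#' @param unique_barcodes If `TRUE` (default) cells receive distinct
#'   composite barcodes; if `FALSE` barcodes are drawn with replacement so
#'   collisions can occur at the analytic rate.
#' @param reference_n Pooled reference positions (distinct template start
#'   sites from constant-copy libraries) emitted for empirical binning.
#' @return List of class `bag_sim_config`.
#' @export
sim_config <- function(protocol = "dna", seed = 1L,
                       chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
                       clones = NULL, clone_fractions = c(0.6, 0.4),
                       n_cells = 100L, templates_per_cell = 150L,
                       rpt = 3.5, read_length = 100L,
                       read_error = 0, damage_error = 0,
                       contamination = 0, n_background = 200L,
                       background_mean = 20, barcodes_per_round = 96L,
                       unique_barcodes = TRUE, reference_n = 50000L) {
  if (is.null(clones)) {
    clones <- list(
      diploid = .flat_clone(chrom_sizes, 2L),
      tumor = .cnv_clone(chrom_sizes)
    )
  }
  stopifnot(length(clone_fractions) == length(clones),
            abs(sum(clone_fractions) - 1) < 1e-9,
            all(c(read_error, damage_error, contamination) >= 0),
            all(c(read_error, damage_error, contamination) <= 1),
            !is.null(seed))
  if (length(clones) > n_cells)
    stop("more clones than cells: infeasible configuration")
  structure(list(
    protocol = protocol, seed = as.integer(seed), chrom_sizes = chrom_sizes,
    clones = clones, clone_fractions = clone_fractions,
    n_cells = as.integer(n_cells),
    templates_per_cell = templates_per_cell, rpt = rpt,
    read_length = as.integer(read_length),
    read_error = read_error, damage_error = damage_error,
    contamination = contamination, n_background = as.integer(n_background),
    background_mean = background_mean,
    barcodes_per_round = as.integer(barcodes_per_round),
    unique_barcodes = unique_barcodes, reference_n = as.integer(reference_n)
  ), class = "bag_sim_config")
}

.flat_clone <- function(chrom_sizes, state = 2L) {
  rbindlist(lapply(names(chrom_sizes), function(ch)
    data.table(chrom = ch, start = 1, end = chrom_sizes[[ch]], state = state)))
}

# one gain on chr1, one loss on the last chromosome, diploid elsewhere
.cnv_clone <- function(chrom_sizes) {
  cl <- .flat_clone(chrom_sizes, 2L)
  ch1 <- names(chrom_sizes)[1]
  chL <- names(chrom_sizes)[length(chrom_sizes)]
  s1 <- chrom_sizes[[ch1]]
  sL <- chrom_sizes[[chL]]
  gain <- data.table(chrom = ch1,
    start = c(1, floor(s1 * 0.3) + 1, floor(s1 * 0.7) + 1),
    end = c(floor(s1 * 0.3), floor(s1 * 0.7), s1),
    state = c(2L, 3L, 2L))
  loss <- data.table(chrom = chL,
    start = c(1, floor(sL * 0.5) + 1),
    end = c(floor(sL * 0.5), sL),
    state = c(1L, 2L))
  other <- cl[!chrom %in% c(ch1, chL)]
  rbindlist(list(gain, if (ch1 != chL) loss, other))[order(chrom, start)]
}

#' Random toy genome
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Integer seed.
#' @param gc Base composition is uniform; `gc` shifts the G+C probability.
#' @return [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_genome <- function(chrom_sizes, seed = 1L, gc = 0.41) {
  with_seed(seed, {
    seqs <- vapply(chrom_sizes, function(n) {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, names(chrom_sizes)))
  })
}

# random k-mers over ACGT
.random_kmers <- function(n, k) {
  m <- matrix(sample(BASES, n * k, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# whitelists: one set of distinct barcodes per split round; slice widths
# follow the layout (e.g. 6 + 5 bases for the DNA protocol)
.make_whitelists <- function(widths, per_round) {
  lapply(widths, function(k) {
    wl <- unique(.random_kmers(per_round * 4L, k))
    if (length(wl) < per_round) stop("barcode space too small")
    wl[seq_len(per_round)]
  })
}

# sample genomic positions proportional to per-interval copy state
.sample_positions <- function(clone_def, n) {
  w <- clone_def$state * (clone_def$end - clone_def$start + 1)
  if (sum(w) == 0) stop("clone with zero total copy state")
  iv <- sample.int(nrow(clone_def), n, replace = TRUE, prob = w)
  data.table(
    chrom = clone_def$chrom[iv],
    pos = floor(runif(n, clone_def$start[iv], clone_def$end[iv] + 1))
  )
}

#' Simulate a single-cell library with known ground truth
#'
#' Generates, at desk scale, everything the DNA pipeline consumes: cells
#' assigned to clones, composite split-pool barcodes, uniquely tagged
#' templates placed along the genome in proportion to the clone's planted
#' copy-number state, reads amplified from each template at geometric
#' depth, empty-droplet background barcodes, and a pooled constant-copy
#' reference position set for empirical binning. Template-damage errors are
#' planted once per template (shared by all its reads); read-level errors
#' are independent per read. Alignment coordinates are the planted truth,
#' so no external aligner is needed.
#'
#' @param config A [sim_config()].
#' @return List of class `bag_sim`: `reads` (annotated alignment table:
#'   `read_id`, `bag`, `tag`, `chrom`, `pos`, `end`, `strand`, `mapped`),
#'   `barcode_counts` (per-barcode read counts including background, for
#'   cell calling), `reference_positions`, `whitelists`, `truth` (list with
#'   `cells` and `templates` tables), and `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "bag_sim_config"))
  layout <- bag_layout(config$protocol)
  slice_widths <- layout$barcode_ranges[, end - start + 1L]
  with_seed(config$seed, {
    whitelists <- .make_whitelists(slice_widths, config$barcodes_per_round)
    # composite barcodes: one slice per split round
    draw_barcode <- function(n) {
      slices <- lapply(whitelists, function(wl) sample(wl, n, replace = TRUE))
      do.call(paste0, slices)
    }
    if (config$unique_barcodes) {
      bc <- unique(draw_barcode(config$n_cells * 4L))
      if (length(bc) < config$n_cells) stop("barcode space exhausted")
      bc <- bc[seq_len(config$n_cells)]
    } else {
      bc <- draw_barcode(config$n_cells)
    }
    clone_id <- sample(names(config$clones), config$n_cells, replace = TRUE,
                       prob = config$clone_fractions)
    cells <- data.table(cell = seq_len(config$n_cells), bag = bc,
                        clone = clone_id)
    cells[, ploidy := vapply(clone, function(cl) {
      d <- config$clones[[cl]]
      sum(d$state * (d$end - d$start + 1)) / sum(d$end - d$start + 1)
    }, numeric(1))]

    # templates per cell
    tpl <- rbindlist(lapply(seq_len(config$n_cells), function(i) {
      nt <- max(1L, rpois(1, config$templates_per_cell))
      own <- rbinom(1, nt, 1 - config$contamination)
      src_clone <- c(rep(cells$clone[i], own),
                     sample(names(config$clones), nt - own, replace = TRUE))
      parts <- rbindlist(lapply(split(seq_len(nt), src_clone), function(idx) {
        p <- .sample_positions(config$clones[[src_clone[idx[1]]]], length(idx))
        p[, contaminant := src_clone[idx[1]] != cells$clone[i]]
        p
      }))
      parts[, `:=`(cell = i, bag = cells$bag[i])]
      parts
    }))
    tpl[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    tpl[, tag := .random_kmers(.N, layout$tag_length)]
    tpl[, depth := 1L + rgeom(.N, prob = min(1, 1 / max(config$rpt, 1)))]
    tpl[, template_id := .I]

    # expand templates to reads
    reads <- tpl[rep(seq_len(.N), depth),
                 .(template_id, cell, bag, tag, chrom, pos, strand)]
    reads[, end := pos + config$read_length - 1L]
    reads[, mapped := TRUE]
    reads[, read_id := sprintf("sim%08d", .I)]

    # empty-droplet background barcodes at low depth
    bg_counts <- data.table(barcode = character(0), count = integer(0))
    if (config$n_background > 0L) {
      bg_bc <- setdiff(unique(draw_barcode(config$n_background * 4L)), bc)
      bg_bc <- bg_bc[seq_len(min(length(bg_bc), config$n_background))]
      bg_counts <- data.table(barcode = bg_bc,
                              count = rpois(length(bg_bc), config$background_mean))
    }
    cell_counts <- reads[, .(count = .N), by = .(barcode = bag)]
    barcode_counts <- rbind(cell_counts, bg_counts[count > 0])

    # pooled constant-copy reference for empirical binning: distinct
    # template start sites from diploid material
    ref <- .sample_distinct_positions(config$chrom_sizes, config$reference_n)

    structure(list(
      reads = reads[], barcode_counts = barcode_counts[],
      reference_positions = ref, whitelists = whitelists,
      truth = list(cells = cells[], templates = tpl[]),
      config = config
    ), class = "bag_sim")
  })
}

# distinct positions, allocated to chromosomes proportionally to length
.sample_distinct_positions <- function(chrom_sizes, n) {
  alloc <- floor(n * chrom_sizes / sum(chrom_sizes))
  alloc[1] <- alloc[1] + n - sum(alloc)
  rbindlist(lapply(names(chrom_sizes), function(ch) {
    data.table(chrom = ch,
               pos = sort(sample.int(chrom_sizes[[ch]], alloc[[ch]])))
  }))
}

#' Build structured reads from annotations (generator side of extraction)
#'
#' Writes each annotated read's composite barcode, varietal tag and anchor
#' sequences into the positional layout of the protocol, padding unspecified
#' positions (e.g. the DNA linker at 7--21) with a fixed constant filler.
#' [extract_barcodes()] is a left inverse of this function.
#'
#' @param bag_barcodes,varietal_tags Character vectors (lengths matching
#'   the layout).
#' @param layout A [bag_layout()].
#' @param genomic Optional character vector appended after the structured
#'   prefix (e.g. captured genomic sequence).
#' @param anchor_mismatches Integer; plant this many mismatches into each
#'   read's first anchor (to exercise the mismatch allowance). Default 0.
#' @return Character vector of read sequences.
#' @export
build_structured_reads <- function(bag_barcodes, varietal_tags, layout,
                                   genomic = "", anchor_mismatches = 0L) {
  stopifnot(inherits(layout, "bag_layout"),
            all(nchar(bag_barcodes) == layout$barcode_length),
            all(nchar(varietal_tags) == layout$tag_length))
  n <- length(bag_barcodes)
  L <- layout$min_length
  filler <- strrep("A", L)
  reads <- rep(filler, n)
  place <- function(reads, ranges, value) {
    off <- 0L
    for (i in seq_len(nrow(ranges))) {
      w <- ranges$end[i] - ranges$start[i] + 1L
      substr(reads, ranges$start[i], ranges$end[i]) <-
        substr(value, off + 1L, off + w)
      off <- off + w
    }
    reads
  }
  reads <- place(reads, layout$barcode_ranges, bag_barcodes)
  reads <- place(reads, layout$tag_ranges, varietal_tags)
  for (i in seq_len(nrow(layout$anchors))) {
    substr(reads, layout$anchors$start[i], layout$anchors$end[i]) <-
      rep(layout$anchors$seq[i], n)
  }
  if (anchor_mismatches > 0L) {
    a <- layout$anchors[1]
    pos <- a$start  # mismatch the first anchor base
    wrong <- vapply(substr(reads, pos, pos),
                    function(b) setdiff(BASES, b)[1], character(1),
                    USE.NAMES = FALSE)
    substr(reads, pos, pos) <- wrong
  }
  paste0(reads, genomic)
}

#' Simulate a barcode-rank experiment
#'
#' Cell-containing barcodes draw read counts around `cell_mean` and
#' empty-droplet background barcodes around `background_mean` (Poisson);
#' truth labels are emitted for evaluating knee detection.
#'
#' @param n_cells,n_background Barcode counts in each class.
#' @param cell_mean,background_mean Mean reads per barcode per class.
#' @param seed Integer seed.
#' @return `data.table`: `barcode`, `count`, `is_cell`.
#' @export
simulate_barcode_rank <- function(n_cells, n_background,
                                  cell_mean = 1e6, background_mean = 1e3,
                                  seed = 1L) {
  with_seed(seed, {
    data.table(
      barcode = sprintf("bc%06d", seq_len(n_cells + n_background)),
      count = c(rpois(n_cells, cell_mean), rpois(n_background, background_mean)),
      is_cell = rep(c(TRUE, FALSE), c(n_cells, n_background))
    )
  })
}

#' Simulate per-read base calls with planted error processes
#'
#' Observation-level generator for the error model: templates are placed on
#' masked homozygous-reference positions with known trinucleotide contexts;
#' template damage substitutes the template's base once (all reads inherit
#' it), while read-level errors are drawn independently per read. Rates may
#' be scalars or named per-context vectors.
#'
#' @param n_templates Number of templates.
#' @param n_positions Number of masked positions (templates are spread over
#'   them).
#' @param contexts Contexts to use (default all 64).
#' @param depth_mean Mean template depth (geometric, minimum 1); use
#'   `depth_fixed` for a constant depth.
#' @param depth_fixed Optional fixed depth overriding `depth_mean`.
#' @param read_error,damage_error Scalar or per-context named error rates.
#' @param n_bags Number of cells the templates are spread over (default 4).
#' @param seed Integer seed.
#' @return List: `calls` (per-read observations), `mask`, `truth`
#'   (per-template table with `damaged` flag and true base).
#' @export
simulate_base_calls <- function(n_templates, n_positions = 200L,
                                contexts = trinucleotide_contexts(),
                                depth_mean = 3, depth_fixed = NULL,
                                read_error = 1e-3, damage_error = 0,
                                n_bags = 4L, seed = 1L) {
  rate_for <- function(rate, ctx) {
    if (length(rate) == 1L && is.null(names(rate))) rep(rate, length(ctx))
    else {
      r <- rate[ctx]
      r[is.na(r)] <- 0
      unname(r)
    }
  }
  with_seed(seed, {
    mask <- data.table(
      chrom = "chr1", pos = seq_len(n_positions),
      context = sample(contexts, n_positions, replace = TRUE)
    )
    mask[, ref := substr(context, 2, 2)]
    tpl <- data.table(
      template_id = seq_len(n_templates),
      posidx = sample.int(n_positions, n_templates, replace = TRUE),
      bag = sprintf("bag%02d", sample.int(n_bags, n_templates, replace = TRUE)),
      tag = .random_kmers(n_templates, 6L),
      strand = sample(c("+", "-"), n_templates, replace = TRUE)
    )
    tpl[, `:=`(chrom = mask$chrom[posidx], pos = mask$pos[posidx],
               context = mask$context[posidx], ref = mask$ref[posidx])]
    tpl[, depth := if (!is.null(depth_fixed)) depth_fixed
        else 1L + rgeom(.N, prob = min(1, 1 / max(depth_mean, 1)))]
    dmg_rate <- rate_for(damage_error, tpl$context)
    tpl[, damaged := runif(.N) < dmg_rate]
    tpl[, true_base := ref]
    if (any(tpl$damaged)) {
      tpl[damaged == TRUE, true_base := vapply(ref, function(b)
        sample(setdiff(BASES, b), 1L), character(1))]
    }
    calls <- tpl[rep(seq_len(.N), depth),
                 .(template_id, bag, tag, chrom, pos, strand, context,
                   base = true_base)]
    err_rate <- rate_for(read_error, calls$context)
    flip <- runif(nrow(calls)) < err_rate
    if (any(flip)) {
      calls[flip, base := vapply(base, function(b)
        sample(setdiff(BASES, b), 1L), character(1))]
    }
    calls[, context := NULL]
    list(calls = calls[], mask = mask[],
         truth = tpl[, .(template_id, bag, tag, chrom, pos, strand, context,
                         ref, depth, damaged, true_base)])
  })
}

#' Simulate per-cell source-informative SNV observations
#'
#' Two genomes, A and B, each with a panel of source-specific sites. Each
#' singlet cell emits consensus template observations of its own genome's
#' alternative alleles, with a planted fraction drawn from the other
#' genome (cross-contamination); doublets draw from both genomes equally.
#'
#' @param n_cells_a,n_cells_b Singlet cell counts per source.
#' @param n_doublets Doublet (barcode-collision) cells.
#' @param obs_per_cell Informative observations per cell.
#' @param contamination Fraction of a singlet's observations from the other
#'   genome.
#' @param panel_size Source-specific sites per genome.
#' @param seed Integer seed.
#' @return List: `panel` (an `snv_panel`-shaped table), `observations`
#'   (`bag`, `chrom`, `pos`, `base`), `truth` (`bag`, `source`).
#' @export
simulate_identity_obs <- function(n_cells_a, n_cells_b, n_doublets = 0L,
                                  obs_per_cell = 200L, contamination = 0,
                                  panel_size = 500L, seed = 1L) {
  with_seed(seed, {
    panel <- data.table(
      chrom = "chr1", pos = seq_len(2L * panel_size),
      ref = sample(BASES, 2L * panel_size, replace = TRUE),
      source = rep(c("A", "B"), panel_size)
    )
    panel[, alt := vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                          character(1))]
    setcolorder(panel, c("chrom", "pos", "ref", "alt", "source"))
    n <- n_cells_a + n_cells_b + n_doublets
    truth <- data.table(
      bag = sprintf("bag%04d", seq_len(n)),
      source = rep(c("A", "B", "DOUBLET"), c(n_cells_a, n_cells_b, n_doublets))
    )
    obs <- rbindlist(lapply(seq_len(n), function(i) {
      src <- truth$source[i]
      p_a <- switch(src, A = 1 - contamination, B = contamination,
                    DOUBLET = 0.5)
      from_a <- rbinom(1, obs_per_cell, p_a)
      sites <- rbind(
        panel[source == "A"][sample.int(panel_size, from_a, replace = TRUE)],
        panel[source == "B"][sample.int(panel_size, obs_per_cell - from_a,
                                        replace = TRUE)]
      )
      data.table(bag = truth$bag[i], chrom = sites$chrom, pos = sites$pos,
                 base = sites$alt)
    }))
    list(panel = panel[], observations = obs[], truth = truth[])
  })
}

#' Simulate mean-normalized integer-state segment profiles
#'
#' Each profile is a piecewise-constant integer copy-number profile around a
#' true ploidy (always containing at least one segment one state above the
#' base state, so the profile is not a scalar multiple of a lower-ploidy
#' one), mean-normalized to 1 with optional Gaussian noise on the segment
#' values.
#'
#' @param n Number of profiles.
#' @param true_ploidy Base integer copy state.
#' @param n_bins Bins per profile.
#' @param n_segments Segments per profile.
#' @param noise_sd Gaussian noise SD on normalized segment values.
#' @param seed Integer seed.
#' @return List: `profiles` (bins x n matrix of mean-1 vectors), `truth`
#'   (per-profile weighted-mean copy state, the quantity ploidy estimation
#'   recovers).
#' @export
simulate_segment_profiles <- function(n, true_ploidy, n_bins = 200L,
                                      n_segments = 8L, noise_sd = 0.02,
                                      seed = 1L) {
  with_seed(seed, {
    profiles <- matrix(0, n_bins, n)
    truth <- numeric(n)
    for (i in seq_len(n)) {
      cuts <- sort(sample(seq_len(n_bins - 1L), n_segments - 1L))
      sizes <- diff(c(0L, cuts, n_bins))
      # base state everywhere; aberrations (gains and losses of one copy)
      # on a bounded share of the genome, so the profile mean stays near
      # the base ploidy as in real clones; at least one gain segment keeps
      # the profile from being a scalar multiple of a lower-ploidy one
      states <- rep(true_ploidy, n_segments)
      aberrant <- order(sizes)  # flip smaller segments first
      flipped <- 0L
      for (j in aberrant) {
        if (flipped + sizes[j] > 0.3 * n_bins) next
        states[j] <- true_ploidy + (if (flipped == 0L) 1L
                                    else sample(c(-1L, 1L), 1L))
        flipped <- flipped + sizes[j]
      }
      v <- rep(states, sizes)
      mu <- mean(v)
      truth[i] <- mu
      prof <- v / mu + rnorm(n_bins, 0, noise_sd)
      profiles[, i] <- prof / mean(prof)
    }
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate a toy exon model and RNA expression library
#'
#' Genes are tiled along the genome, each with a single transcript of one or
#' two exons. Two cell populations share a common expression baseline but
#' each elevates its own disjoint marker-gene set. Reads fall inside exons
#' with varietal tags, so gene assignment, template collapse and PCA can be
#' exercised end to end with known population labels.
#'
#' @param n_cells_a,n_cells_b Cells per population.
#' @param n_genes Total genes (the first `n_markers` are population-A
#'   markers, the next `n_markers` population-B markers).
#' @param n_markers Marker genes per population (default 25).
#' @param templates_per_cell Mean expressed templates per cell.
#' @param rpt Mean reads per template.
#' @param marker_fold Expression fold-change of a population's own markers
#'   (default 8).
#' @param chrom_size Length of the single toy chromosome.
#' @param seed Integer seed.
#' @return List: `reads` (annotated alignments with `bag`, `tag`, `chrom`,
#'   `pos`, `end`), `exons` (exon model), `truth` (`bag`, `population`).
#' @export
simulate_rna_library <- function(n_cells_a, n_cells_b, n_genes = 120L,
                                 n_markers = 25L, templates_per_cell = 400L,
                                 rpt = 3, marker_fold = 8,
                                 chrom_size = 3e6, seed = 1L) {
  stopifnot(n_genes >= 2L * n_markers)
  with_seed(seed, {
    gene_len <- 2000L
    gap <- floor(chrom_size / n_genes)
    stopifnot(gap > gene_len)
    exons <- rbindlist(lapply(seq_len(n_genes), function(g) {
      gstart <- (g - 1L) * gap + 1L
      # two exons separated by an intron
      data.table(gene = sprintf("gene%03d", g),
                 transcript = sprintf("gene%03d.t1", g),
                 chrom = "chr1",
                 start = c(gstart, gstart + 1200L),
                 end = c(gstart + 799L, gstart + 1999L),
                 strand = "+")
    }))
    genes <- unique(exons$gene)
    w_base <- rep(1, n_genes)
    w_a <- w_b <- w_base
    w_a[seq_len(n_markers)] <- marker_fold
    w_b[n_markers + seq_len(n_markers)] <- marker_fold
    n <- n_cells_a + n_cells_b
    truth <- data.table(bag = sprintf("cell%04d", seq_len(n)),
                        population = rep(c("A", "B"), c(n_cells_a, n_cells_b)))
    exon_by_gene <- split(exons, by = "gene")
    reads <- rbindlist(lapply(seq_len(n), function(i) {
      w <- if (truth$population[i] == "A") w_a else w_b
      nt <- max(1L, rpois(1, templates_per_cell))
      g <- sample(genes, nt, replace = TRUE, prob = w)
      tagv <- .random_kmers(nt, 12L)
      depth <- 1L + rgeom(nt, prob = min(1, 1 / max(rpt, 1)))
      tpl <- data.table(gene_true = g, tag = tagv, depth = depth)
      tpl[, row := .I]
      ex <- rbindlist(exon_by_gene)[match(g, gene)]  # first exon of each gene
      tpl[, `:=`(chrom = "chr1",
                 pos = ex$start + sample.int(700L, nt, replace = TRUE) - 1L)]
      tpl[, end := pos + 75L]
      r <- tpl[rep(row, depth)]
      r[, `:=`(bag = truth$bag[i], row = NULL, depth = NULL)]
      r
    }))
    reads[, read_id := sprintf("rna%08d", .I)]
    reads[, mapped := TRUE]
    list(reads = reads[], exons = exons[], truth = truth[])
  })
}
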