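---
title: "bagseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bagseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagseq)
library(data.table)
```

## The problem

In gel-bead split-pool single-cell sequencing, each cell's DNA or RNA is
captured in a polyacrylamide bead and barcoded by successive split-and-pool
rounds. Every sequenced read carries, at fixed positions on one mate, a
composite cell barcode (two or three 6-base split barcodes), a varietal tag
(a UMI marking the original template molecule), and protocol anchors — a
`CATG` NlaIII cut-site for DNA libraries, a `GGG` template-switch trace for
RNA. Downstream analysis rests on three ideas:

* **Template counting.** Reads sharing an identical (barcode, tag,
  chromosome, position, strand) key descend from one captured molecule.
  Collapsing them yields unbiased per-cell template counts for copy-number
  and expression work, independent of PCR depth.
* **Consensus error correction.** Reads of the same template should agree;
  demanding at least two reads with at least 80% agreement before calling a
  base suppresses independent sequencing errors, while errors introduced
  into the template itself before amplification (damage) survive consensus
  — a diagnostic distinction the error module makes measurable.
* **Genotype-resolved contamination.** With two genomes of known
  source-specific SNVs in one experiment, every informative template votes
  for a source; the minority vote fraction per cell measures
  cross-contamination, and cells with strongly mixed votes flag doublets or
  barcode collisions.

`bagseq` implements the full computational path — read-structure validation
and demultiplexing, barcode-rank cell calling, template collapse and
saturation statistics, empirical-bin copy-number profiles with circular
binary segmentation and grid-search ploidy, trinucleotide-context error
matrices, SNV identity calling with analytic collision expectations, gene
expression matrices with PCA marker analysis — together with a synthetic
data generator that emulates every input with known ground truth.

## Read layouts and demultiplexing

Layouts are positional, 1-based and inclusive, following the protocol
descriptions; `bag_layout()` encodes four: `dna` (Read 2: `CATG` at 31–34
with at most one mismatch; barcode 1–6 + 22–26; tag 27–30), `rna2a`
(primer-anchored two-round RNA), `rna2b` (whitelist-gated two-round RNA),
and `rna3` (three rounds, 18-base composite barcode). Composite barcode
lengths are fixed per protocol (11, 12, 12, 18 bases).

Decisions worth noting:

* **Coordinates.** All coordinates in this package, genomic intervals
  included, are 1-based inclusive — the R/Bioconductor convention — rather
  than mixing conventions at I/O boundaries. Exon models, bins and SAM
  round-trips all agree on it.
* **Whitelist matching is exact** by default: a barcode either is a valid
  split barcode or is not. An optional one-mismatch rescue
  (`rescue_mismatch = TRUE`) accepts a slice with a unique one-mismatch
  whitelist neighbour; it is off because rescue trades contamination for
  yield and the protocol defines validity, not proximity.
* **DNA positions 7–21** sit between the two barcode slices and are treated
  as a constant linker: present, never validated.
* **Adapter trimming** uses 3' suffix-overlap matching with minimum overlap
  5 and at most 10% mismatches; pairs are retained only when both trimmed
  mates keep at least 100 bases. The overlap parameters are the standard
  trimmer contract; the 100-base retention rule is the protocol's.
* Barcode and tag annotations travel in read identifiers
  (`id|barcode|tag`) *and* as `CB`/`UB` attributes when alignments are
  written, so either channel can feed downstream stages.

## Cell calling

Barcodes are ranked by count; the cumulative count fraction against
normalized rank shows a sharp inflection when a minority of barcodes
received cells. The knee is the point of maximum perpendicular distance
between that curve and the chord joining its endpoints — a parameter-free
formalization of "left of the inflection". Two guard rails: the selected
set is always an inclusive prefix (ties at the knee count are kept), and
when no point leaves the chord by more than `min_distance` (default 0.05 in
normalized units) the caller returns an empty set with a `"no_knee"`
diagnostic rather than guessing — a curve without an inflection (all counts
comparable) carries no evidence about which barcodes hold cells. A manual
count threshold override exists for exactly that situation.

## Templates, coverage and saturation

`collapse_templates()` keys on (barcode, tag, chromosome, position,
strand), with exact tag matching — no mismatch merging, since the tag space
is small and merging would silently fuse distinct templates. Strand is part
of the key: capture marks one genomic strand (the cut site fixes the 3'
end), so opposite-strand observations at one position are distinct capture
events; this also powers the strand-of-capture accounting
(`strand_capture_fractions()`) and the complement check in variant calling.
The map position is the 5'-most aligned base on the plus strand.

Saturation analysis samples reads without replacement at fractions of the
library and recomputes unique templates;
`expected_templates_at_fraction()` provides the closed-form hypergeometric
expectation used to verify the sampler.

## Copy number

**Empirical bins.** Bin boundaries are placed at empirical quantiles of
pooled template positions from constant-copy libraries, so each bin expects
the same template count under constant copy number; mappability structure
moves into bin widths instead of needing a model. The construction
apportions bins to chromosomes so that every bin's target count is
`floor(n/B)` or `ceil(n/B)` and spreads boundaries by Bresenham rounding;
rebinning the pooled reference against its own scheme yields counts equal
to within one. Per-bin GC comes from the reference sequence when supplied.

**Normalization.** Counts become ratios `(c + 1) / mean(c + 1)`; GC bias is
removed by lowess of log-ratio on GC with span `f = 0.05`, and the
corrected vector is rescaled to mean exactly one. The normalization is
kept linear (ratios, not log values) because the ploidy step needs a scale
on which integer copy states are equally spaced; the GC fit happens in log
space where the bias is closer to multiplicative. Cells enter copy-number
analysis only above a minimum unique-template count — at study scale the
convention is 100,000 tags; the desk-scale default in `run_dna()` is 0 and
the threshold is a visible parameter.

**Segmentation** is circular binary segmentation, implemented from scratch
(the arc scan and permutation loop in C++): within each segment, the arc
whose mean most differs from its complement (two-sample t statistic over
all arcs, both parts at least `min_width = 3` bins) is tested by permuting
the segment `nperm = 1000` times; the split is accepted when the
permutation p-value falls below `alpha = 0.02`, and the procedure recurses.
Afterwards, adjacent segments whose means differ by less than
`undo_sd = 0.5` residual standard deviations are re-merged (the residual
SD is `mad(diff(x))/sqrt(2)`, robust to the segment structure itself).
Permutations draw from R's RNG under a caller-supplied seed, so results
are reproducible; the p-value uses the `(exceed + 1)/(nperm + 1)`
estimator. The test suite checks the segmenter against an exhaustive
least-squares change-point search on planted one- and two-step profiles.

**Ploidy.** A mean-one segmented profile is multiplied by candidates 1.5,
1.55, …, 4.5; the multiplier minimizing the bin-weighted squared distance
to the nearest integers is the ploidy. Rounding is half-away-from-zero;
exact ties (e.g. the all-ones profile, where 2, 3 and 4 are all perfect)
resolve to the smallest multiplier — a deliberate diploid-leaning default,
documented rather than hidden. Scaling multiplies segment values only, so
boundaries never move.

**Clustering and display.** Profiles cluster under Manhattan distance with
Ward (`ward.D2`) agglomeration; high-amplitude profiles are displayed as
`log(y + 1)` with guide lines at copy numbers 1, 2, 3, 4, 20, 50, 80.

## Error model

`consensus_calls()` applies the ≥2-reads / ≥80%-agreement rule (exactly
80% is a call — "at least"). `error_matrix()` tallies mismatches against a
donor truth mask (positions confidently homozygous reference) over all 64
trinucleotide contexts × 3 alternative bases, with the opportunity
denominator per context; empty cells report `NA`, never a fabricated zero.
The `raw` mode draws one read uniformly per template (seeded) — the
random-sampling baseline against which consensus suppression is measured.
Bases are tallied in the reference frame as reported by the aligner, so
plus- and minus-strand captures are directly comparable and "the
complement of the variant on the other strand" is the same alternative
base.

`candidate_variants()` promotes a non-reference consensus call seen
concordantly in at least two cells (same alternative allele; capture strand
free — requiring equal strand would conflate variant identity with capture
geometry). For each candidate it reports whether the position was captured
on the opposite strand at all, and whether the variant is also seen there:
true somatic variants sit on both genomic strands, unilateral template
damage does not.

## Identity and collisions

Panels of source-specific SNVs are called from two bulk pileups: a variant
needs at least 3 alternative reads and at least 5% of covering reads; it is
source-specific only when the other source is covered by at least 12
qualifying reads and shows no variant there. Six known artifact-prone human
(hg19) positions ship as a default exclusion list for real-data runs.

Per cell, informative template observations vote A or B; the minority
ratio is `min(a, b)/(a + b)`. A cell whose A-fraction falls strictly
inside (0.15, 0.85) is `MIXED` — the band is applied to every protocol,
with the bounds as visible parameters. Votes are counted at template
(consensus) level so amplification depth cannot inflate either side.

Barcode collisions follow occupancy statistics: with `n` cells drawing
uniformly from `N` composite barcodes, the expected number of barcode
values chosen more than once is `N - N(1 - 1/N)^n - n(1 - 1/N)^(n-1)` —
exact, no simulation. `collision_rate()` is its empirical percentage
counterpart.

## Expression

Bulk mode assigns a read to a transcript only when every aligned base lies
within that transcript's exons; single-cell mode requires at least half the
read length within exons of some transcript of the gene (boundary
inclusive). A read satisfying the rule for two different genes is
ambiguous and dropped (counted in the manifest) — the protocols do not
state a policy, and silently double-counting or arbitrarily preferring one
gene would bias marker statistics. Within a cell, a tag observed on two
genes resolves to the gene with more supporting reads; ties are dropped.

Bulk RPKM is `reads x 1e9 / (length x total)` per transcript, and a gene
takes its best transcript. PCA follows the stated sequence literally:
per-cell mean normalization, `log1p`, per-gene centring, then principal
components with per-feature centring *and* unit scaling (the data are
hand-centred and then standardized; both steps are kept because the
procedure is defined that way, not because the second centring changes
much). Markers are the 20 most positively and 20 most negatively
PC1-correlated genes; the marker heatmap orders cells by Euclidean
distance with complete linkage. Bulk profiles pass through the identical
normalization (centred with the single-cell gene means) and are projected
with the fitted rotation.

## The synthetic-data generator

`simulate_library()` and its siblings generate every input the pipeline
consumes, with complete ground truth: per-read true barcode and tag,
per-cell clone and ploidy, per-template damage flags, per-variant source.
The desk-scale defaults are a 2-Mb two-chromosome genome, 100 cells from
two clones (60/40; the aberrant clone carries a one-copy gain over 40% of
one chromosome and a one-copy loss over half the other), 3.5 reads per
template (geometric), two 96-barcode split rounds, and a background of
empty-droplet barcodes at roughly 100-fold lower depth — the regime in
which a barcode-rank knee is sharp. Template damage is planted once per
template and inherited by all its reads; read errors are independent per
read; bincount expectations are proportional to the planted copy state.
Same seed, same output, byte for byte.

What the generator does *not* emulate: polymerase chimeras, barcode
hopping, mappability and GC structure of a real genome (the toy genome is
uniform unless a GC bias is planted explicitly), droplet physics, and
alignment error (emitted coordinates are the planted truth, so tests never
shell out to an aligner). Passing tests therefore demonstrate the
correctness of the computational contracts, not performance on real
sequencing artifacts.

## Problem sizes and determinism

The test suite runs at desk scale by choice: segmentation oracles use
200-bin profiles over 100 seeded trials; ploidy recovery uses 100 profiles
per planted ploidy in {2, 3, 4}; error-model checks plant a 1e-3 read
error over ~150,000 templates at fixed depth 3; the end-to-end round trip
uses 8 cells at 60,000 templates each over 120 bins, where count noise per
bin is well below the half-copy decision distance, so planted integer
states are recovered exactly on every bin that lies inside a single
planted state (a bin straddling a planted breakpoint has no defined state
at bin resolution). Every stochastic step takes an explicit seed and
restores the caller's RNG stream.

## Known limitations

* The segmenter tests every arc exhaustively (O(m²) per scan); profiles of
  20,000 bins segment in seconds thanks to the compiled scan, but no
  hybrid p-value shortcut is implemented — `nperm` is the only speed knob.
* `call_cells()` detects a single knee; libraries with multi-modal count
  structure (e.g. nuclei plus debris plateaus) should use the manual
  threshold.
* The GC fit is a single lowess on all bins; focal amplifications with
  extreme GC could in principle bend the fit, and no bad-bin mask ships by
  default (an exclusion hook exists at the bin-scheme level by filtering
  the input positions).
* Gene assignment handles single-block alignments; spliced multi-block
  reads would need per-block exon intersection.
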