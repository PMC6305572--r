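---
title: "Methods: optically barcoded microwell scRNA-seq, simulated and decoded"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optically barcoded microwell scRNA-seq, simulated and decoded}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Microwell implementations of single-cell RNA-seq co-encapsulate cells with
barcoded mRNA-capture beads. Because beads fall into wells at random, the
live-cell image of a well cannot be matched to the expression profile that
its bead later produces — unless the bead itself can be identified under
the microscope. The approach implemented here gives every bead two
barcodes: the usual cell-identifying *sequencing barcode*, and an
*optical barcode* — a combination of ligatable oligonucleotides (OBOs)
selected from a set of 12, readable on-chip by 12 cycles of reversible
fluorescence hybridization. Linking imaging to expression then reduces to
three computational steps, all implemented in this package:

1. **Look-up table** (`build_lookup()`). During split-pool ligation a
   small fraction of oligonucleotides is sonicated off the beads and
   sequenced, one "bead-free" library per ligation reaction. A
   sequencing barcode's presence in pool $k$ is evidence the bead passed
   through reaction $k$ — i.e. that bit $k$ of its optical code is 1.
2. **Optical demultiplexing** (`demux_stack()`). The hybridization image
   stack is registered, per-well intensities extracted, and each
   occupied well's 12-bit code called.
3. **Linking** (`link()`). A called code is matched against the look-up
   table, restricted to barcodes observed in the expression library of
   that well's array *piece* — the device is cut into $N$ pieces that
   are indexed separately, multiplying the effective barcode capacity to
   $2^{12}\times N$ (40,960 at $N=10$).

Around this core the package carries a complete synthetic-data generator
(`simulate_experiment()`), cell segmentation with a fixed panel of 19
imaging features (`imaging_records()`), two-species mixing validation
statistics (`validation_report()`), and phenotype–expression correlation
(`feature_pca()`, `rank_genes_by_pc()`, `enrichment_score()`).

# The generator and what it emulates

Every input of the pipeline can be simulated, with ground truth retained,
so each stage is testable without experimental data.

**Beads and codes.** The two ligation cycles own 6 OBOs each (cycle 1 →
OBOs 1–6, cycle 2 → 7–12); each bead is routed through a uniformly random
subset of each cycle's reactions, so codes are uniform on the full
$2^{12}$ codespace. How the 12 OBOs are actually partitioned across
cycles is not observable from the outputs; the 6+6 model is the simplest
topology consistent with the stated $2^{12}$ capacity and is
configurable (`n_split_cycles`, `bits_per_cycle`). Exactly
`round(n_wells * bead_loading_rate)` beads are placed in distinct wells
(size exclusion: one bead per well).

**Bead-free libraries.** One read set per pool; each member bead
contributes Poisson(`beadfree_depth`, default 20) reads with per-base
substitution errors at `seq_error_rate`.

**Hybridization stack.** Beads render as uniform disks on a regular
well grid, 16-bit grayscale, with Gaussian camera noise (peak-signal to
noise ratio `snr`), a rigid per-frame translation of up to `jitter_px`,
and per-bead/per-frame bit inversions at `bit_flip_rate`. A bead-stain
reference frame showing every bead is rendered alongside: without it, a
bead whose code is all-zeros would be indistinguishable from an empty
well. (That degeneracy is real: a bead carrying no OBOs also emits no
bead-free reads, so it can never enter the look-up table or be linked.
The code structure offers no redundancy to correct this.)

**Cells, dyes, images.** Wells receive Poisson(`cell_loading_rate`)
cells; the probability of ≥2 cells is multiplied by `doublet_bias` with
the 0/1-cell probabilities renormalised, so the planted multiplet rate
`planted_doublet_rate()` is in closed form and `doublet_bias_for_rate()`
inverts it exactly. Each cell is an ellipse (lognormal size and aspect,
sinusoidal boundary perturbation) with live-stain dye brightness keyed
to its species; cells co-occupying a well are re-placed until their
centres separate (soft physical exclusion — cells are solid objects).
Defaults place the two species at 60/40, matching the unequal mixing
that makes the abundance correction in the validation statistics
non-trivial.

**Expression.** Per-cell totals are Poisson around
`mean_transcripts_per_cell` (default 3600, the capture rate regime this
device design operates in) times a lognormal size factor; genes are
drawn multinomially from species-specific panels with lognormal
abundance weights. A planted module (`module_size` genes of the first
panel) has its weights scaled by (cell area / mean area)^`module_strength`,
the recoverable signal for the phenotype–expression analyses. Every bead
additionally captures mean `ambient_umis_per_bead` (default 15)
cell-free UMIs from the species-weighted pool — this is what makes every
extracted bead's barcode observable in its piece's library, as in a real
experiment. A fraction `crosstalk_rate` of UMIs is reassigned to a
random other barcode; UMIs are conserved, so a singlet's impurity is the
cross-talk rate times the other-species share of the ambient pool, not
the full cross-talk rate.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: realistic optics (point-spread
function, bleaching, flat-field variation), cell motility between
imaging and lysis, library-prep chemistry biases, ambient RNA profiles
that differ from the cell pool, and genome alignment (reads carry a
20-nt gene tag matched exactly against the gene reference; this is the
seam where an aligner to a joint two-species transcriptome would plug
in, and mismatched tags are dropped, which is unbiased with respect to
species).

# Numerical and algorithmic choices

**Barcode absorption.** Bead-free barcodes within Hamming distance
`max_barcode_mismatch` (default 1, the Drop-seq convention) of a
higher-count barcode are absorbed into it; ties in count break
lexicographically, and processing in decreasing-count order makes the
result deterministic. A bit is called present at ≥ `min_reads_per_pool`
(default 2) absorbed reads. Note that two *true* barcodes at distance 1
(about 4 pairs are expected among 2000 random 12-mers) are merged by
design — the same failure a real pipeline has; with error-free input the
natural setting is `max_barcode_mismatch = 0`. Row confidence is the
fraction of reads exactly matching the barcode and sitting in
called-present pools: 1.0 on clean data, decaying with error rate.

**Code calling.** Each frame's occupied-well intensities are split by an
exact two-class (Otsu) threshold — per-frame, because hybridization
efficiency drifts between cycles. A frame whose class separation falls
below 30% of the median bead-stain signal is treated as unimodal
(all-on or all-off) and an absolute threshold at half the median
bead-stain signal is used instead. Margins are signed distances from
the threshold in units of the class separation; a call passes only if
every bit clears 10% (`ambiguity_margin`), and registration failures
force their frame's bits ambiguous. Ambiguous calls are never guessed:
the design goal is that demultiplexing errors fail to link rather than
link wrongly, and `link()` preserves that by never force-resolving
collisions.

**Registration and detection.** Frames are registered to the reference
by maximising normalised binary-mask overlap over integer shifts
(sufficient for rigid jitter of a few pixels; no sub-pixel or non-rigid
model). Occupancy is declared when the bead-disk mean exceeds the
annulus background by 8 standard errors of the disk mean.

**Segmentation and features.** The monochrome image is Gaussian-smoothed
(σ = 0.8 px); the per-well foreground threshold is background plus the
larger of 3.5 robust background sd and 25% of the well's peak signal, so
dim cells segment whole while bright ones are not over-grown. Connected
components under 5 px are discarded. The 19-feature panel is this
package's own fixed definition (the source protocol's exact feature list
is not public): area, perimeter, equivalent diameter, major/minor axis,
aspect ratio, eccentricity, circularity, solidity, extent, convex area,
and eight intensity-distribution features. Perimeter uses a
Crofton-style correction (π/4 × exposed pixel edges) so a digital disk
has circularity ≈ 1; axis lengths include the 1/12 pixel-variance
moment correction; convex area counts lattice points via Pick's theorem.
Features are computed on the union mask of a well's objects (per-well
microscopy granularity) with the object count carried separately.
Per-feature results should not be expected to match any specific
published feature-by-feature table.

**Multiplet detection.** The monochrome flag is
`n_objects ≥ 2 OR area > 2.2 × expected single-cell area OR
solidity < 0.8` — an automated surrogate for manual inspection of
single-channel images. It is deliberately specific rather than
sensitive: heavily overlapping same-species doublets in a ~12-px well
are often a single convex blob. Expression multiplets use the purity
rule: strictly below 0.70 majority-species fraction calls a
cross-species multiplet (a purity of exactly 0.70 is a singlet). The
total multiplet rate is estimated as the observed multiplet fraction
divided by $2p_Ap_B$, since only cross-species multiplets are visible
to purity.

**Abundance-corrected linking accuracy.** The observed imaging/expression
species concordance $C$ overstates accuracy because a randomly wrong
link agrees by chance $C_0=\sum_s p_s^2$. The correction used is
$(C - C_0)/(1 - C_0)$ — a Cohen-kappa-style chance correction, adopted
because the exact published correction is not specified. It is 1 for
perfect linking, ≈0 for random linking, undefined (flagged) for
single-species data, and never exceeds raw concordance when $C_0>0$.
All reported fractions carry Wilson 95% intervals.

**Phenotype–expression correlation.** Features are z-scored (constant
features dropped with a warning) and decomposed by PCA with a
deterministic sign convention (largest-magnitude loading positive).
Counts are normalised per cell to the median total and
log1p-transformed; genes are ranked by Pearson correlation with the
chosen PC, ties broken by identifier, zero-variance genes assigned 0.
The enrichment statistic is the standard weighted KS running sum
(weight = |correlation|, exponent 1); the null permutes set
*membership* (`n_permutations` random same-size sets), the normalised
score divides by the mean |ES| of that null, and the p-value is the
two-sided exceedance with the +1 correction. Gene sets are synthetic
(the planted module, or random sets); a GMT loader is provided so real
collections can be supplied, but no curated collection is bundled and
multiple-testing control across many sets is left to the caller
(`p.adjust`).

# Reproducibility and problem sizes

All randomness flows from one seed through named substreams
(`substream_seed(seed, stage)`), so inserting a stage does not perturb
the draws of the others and every output is byte-identical under a
fixed seed.

The test suite and the acceptance script run the full pipeline on
scaled devices chosen to keep a complete run on one CPU in minutes:
2,500-well grids (50×50, 2,000 beads, ~500–600 cells) for end-to-end
checks, 400–900 wells for per-module checks, and read-level depth of a
few hundred transcripts per cell where the FASTQ path is exercised
(count-level checks use the full 3,600). The error-free round-trip
check uses singlet-only loading (`doublet_bias = 0`) and
`max_barcode_mismatch = 0`: cross-species doublets can flip the
dye-majority vs transcript-majority call, and random barcode pairs at
Hamming distance 1 merge in the absorber — both real phenomena, but
neither a linkage error, which is what that check isolates.

# Known limitations

* The optical code has no error-correcting redundancy; one undetected
  bit error usually produces a code absent from the look-up table
  (failure to link), occasionally a collision, and rarely a wrong link.
* Bead detection, registration and segmentation assume the regular well
  grid of the simulator; real images would need grid fitting and
  flat-field correction first.
* Species assignment stands on the simulated gene tags; plugging in a
  real aligner changes error characteristics in ways the generator does
  not model.
* The monochrome multiplet detector's sensitivity is intrinsically
  limited by geometry at this resolution; its specificity is the design
  priority.
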