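# scopelink

Linking live-cell imaging to single-cell RNA-seq through optically
barcoded beads.

## The problem

Microwell scRNA-seq co-encapsulates single cells with barcoded
mRNA-capture beads. The beads land in wells at random, so the microscope
image of a cell cannot, by itself, be matched to the expression profile
its bead produces on the sequencer. One solution is to give each bead a
second, *optically readable* barcode: a combination of oligonucleotides
(OBOs) chosen from a set of 12 and attached in two cycles of split-pool
ligation. The combination is read out on-chip by 12 cycles of reversible
fluorescence hybridization, and a "bead-free" sequencing library made
from each ligation reaction yields a look-up table from sequencing
barcode to optical barcode. Cutting the array into N separately indexed
pieces multiplies the capacity:

    effective capacity = 2^12 × N        (40,960 at N = 10)

`scopelink` implements the complete computational side of such an
experiment for anyone developing or benchmarking this class of
technology:

* a **synthetic-data generator** for every input — dual-barcoded beads,
  pool-indexed bead-free FASTQs, hybridization TIFF stacks, two-channel
  live-cell images, barcoded expression reads — with ground truth and
  configurable error rates (bit flips, sequencing errors, barcode
  cross-talk, doublet loading);
* **look-up table construction** from bead-free pools (Hamming barcode
  absorption, per-pool evidence thresholds, per-row confidence);
* **optical demultiplexing** of the image stack (bead detection, rigid
  frame registration, per-frame two-class thresholding with margins and
  a fail-safe ambiguity flag);
* **cell phenotyping**: segmentation, a fixed panel of 19 size / shape /
  intensity features, two-channel species labels, monochrome multiplet
  flags;
* **linking** of optical calls to expression barcodes per array piece,
  with a loss taxonomy (collision / lookup dropout / demux failure);
* **validation statistics** for two-species mixing designs: species
  concordance, chance-corrected linking accuracy
  `(C − C0)/(1 − C0)` with `C0 = Σ p_s²`, purity-threshold multiplet
  calls (multiplet if purity < 0.70), detector sensitivity/specificity,
  all with Wilson 95% intervals;
* **phenotype–expression correlation**: PCA of the imaging features,
  gene ranking by correlation with a PC, and a permutation-normalised
  gene-set enrichment score.

## Worked example

Simulate a 2,500-well device (2,000 beads, ~600 cells, five pieces,
realistic error rates) and run the whole pipeline:

```r
library(scopelink)

cfg <- scope_config(n_wells = 2500L, grid_rows = 50L, grid_cols = 50L,
                    n_pieces = 5L, bead_loading_rate = 0.8,
                    cell_loading_rate = 0.25,
                    mean_transcripts_per_cell = 400,
                    n_genes_per_species = 60L, rng_seed = 1L)
run <- run_pipeline(cfg)   # ~1 min on one CPU
print(run)
```

```
Simulated experiment: 2000 beads, 615 cells, 12-frame stack, seed 1
Look-up table: 2374 sequencing barcodes, 12-bit optical codes, mean confidence 0.792
Optical calls: 2000 occupied wells, 2000 pass / 0 ambiguous
Linked cells: 1701/2000 optical calls linked (yield 85.0%)
  collisions 184, not-in-lookup 115, demux-fail 0
Mixing-experiment validation
  expression profiles      : 432 (366 linked, 84.7%)
  link yield (per call)    : 85.0%
  species concordance      : 100.0% (n=351)
  corrected link accuracy  : 100.0% (chance 0.520)
  multiplet sens/spec      : 38.5% / 93.8% (vs purity < 70%)
  one- vs two-colour       : 91.3%
  est. multiplet rate      : 7.4%
```

Reading this: of 2,000 optical calls, 85% link to exactly one
expression barcode. The 184 collisions are two beads drawing the same
code within one piece — with 400 beads per piece on 4,096 codes the
expected unique fraction is `(1 − 1/4096)^399 ≈ 0.907`, i.e. ~186
collisions, which is what the run shows. The 115 lookup dropouts are
codes corrupted by hybridization bit flips (at the default 0.5%/bit,
`0.995^12 ≈ 94%` of codes are error-free). Crucially, errors fail to
link rather than link wrongly: among the 351 linked cells with an
unambiguous species call on both sides, imaging and expression agree
100% here, and the chance-corrected linking accuracy is likewise 100%
(chance agreement 0.52 at the 60/40 species mix). The multiplet
detector flags candidate doublets from monochrome images alone with
high specificity and modest sensitivity, and the purity-based estimate
recovers a total multiplet rate of ~7% under the default loading.

A command-line front end wrapping the same functions is installed at
`exec/scopelink` (subcommands `sim`, `lookup`, `count`, `demux`,
`features`, `link`, `validate`, `correlate`); see the header of that
script for usage.

The methods vignette (`vignettes/methods.Rmd`) documents the generator,
every threshold and tie-break, and the design decisions.

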