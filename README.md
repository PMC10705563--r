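# m6Afootprint

Single-molecule chromatin accessibility footprinting from m6A
methyltransferase base calls.

Treating nuclei with the adenine methyltransferase M.EcoGII marks all
protein-free DNA with N6-methyladenine (m6A). Long-read sequencing of the
resulting molecules reports, for each individual DNA molecule, which
adenines were accessible to the enzyme — and, by absence of methylation,
which ~147-bp stretches were protected by nucleosomes. Two practical
problems make naive footprint calling unreliable: m6A detection from
polymerase kinetics is inefficient and varies widely from molecule to
molecule (so unmethylated gaps arise by chance), and calling efficiency
falls with the local AT content of the sequence. `m6Afootprint`
implements an adjusted binomial model that handles both, and converts
per-molecule m6A calls into per-base-pair chromatin states:
**accessible**, **nucleosomal** or **ambiguous**.

It is aimed at anyone analysing methyltransferase footprinting data on
long reads (yeast or other compact genomes), and at method developers who
want a fully simulatable test bed with ground truth.

## The model

For each read, a 25-bp window slides base by base. A window with *n*
adenines (both strands) and *k* called m6A is compared with its expected
methylation

> p_exp = k(N) · AverageReadMethylation + β(N)

where the slope k(N) and intercept β(N) are fitted per window adenine
count N (N = 3..25, 23 lines in total) on a fully-methylated purified-DNA
control ("gDNA") — this is what absorbs the AT-content calling bias, and
using each read's own average methylation absorbs the molecule-to-molecule
detection variation. Under the null, the observed count follows
X ~ Binomial(n, p_exp); two one-tailed p-values are computed per window,
P(X ≤ k) (evidence for protection) and P(X ≥ k) (evidence for
accessibility), each Benjamini–Hochberg-adjusted within the read. The
central base of a window is called accessible at adjusted p < 0.853 and
nucleosomal at adjusted p < 0.918 — thresholds that hold the
false-positive rate below 1% as measured on the control (a
`calibrateThresholds()` procedure re-derives them from any control).
Boundary zones between states, which are systematically ambiguous, are
resolved by the 12-nt extension rules and short ambiguous runs adjacent
to nucleosomes are reassigned as nucleosomal.

On top of the per-molecule calls the package computes population
aggregates: the TSS-anchored nucleosome density (phasing) profile,
occupancy, footprint-length distributions, and a per-gene
**heterogeneity score** — the mean pairwise Pearson correlation of the
single-molecule state vectors (accessible = 0, ambiguous = 0.5,
nucleosomal = 1) over the TSS ± 300 bp window, which quantifies
cell-to-cell variability in nucleosome positioning.

A seeded simulator generates genomes (with compositional heterogeneity),
fully-accessible gDNA controls, fully-protected reads, and chromatinised
molecules with known footprint maps (NDRs at promoters, phased arrays,
per-molecule positional jitter), so every step can be validated against
ground truth, including the window-level in-silico ROC/AUC test.

## Worked example

```r
library(m6Afootprint)

sc  <- SimConfig(seed = 7)                      # 100-kb genome, 60% AT
g   <- simulateGenome(sc)
ctl <- simulateGdnaReads(sc, g$genome, 2000)    # fully-accessible control
tab <- fitCalibration(ctl, g$genome)
tab
#> CalibrationTable: 25-bp windows, N = 3..25, fit range [0.07, 0.41]
#>   slope range 0.853..1.195, min R^2 0.2256

sim    <- simulateNucleiReads(sc, g$genome, genes = g$genes, readsPerGene = 8)
tracks <- callReads(sim$reads, g$genome, tab)
tracks
#> StateTrackSet with 792 tracks
#>   accessible 25.3%, nucleosomal 48.9%, ambiguous 25.8%

sel  <- selectPhasingGenes(g$genes)             # 99 of 99 genes qualify
prof <- phasingProfile(tracks, sel)             # TSS +/- 400 bp density
min(prof$density)                               # 0.044 at offset -77:
                                                # the promoter NDR
mean(prof$density[prof$offset > 100])           # 0.677 gene-body density

het <- heterogeneityScores(tracks, sel)         # per-gene score
head(het, 3)
#>    gene_id n_reads n_pairs n_skipped_pairs het_score
#> 1 gene0002       8      28               0     0.647
#> 2 gene0003       8      28               0     0.713
#> 3 gene0004       8      28               0     0.649

fl <- footprintLengths(tracks)
nuc <- fl[fl$length >= 50, ]
nuc$length[which.max(nuc$count)]                # 143 bp nucleosomal peak
```

What the numbers mean: the calibration slopes deviate from 1 by the
simulated AT bias (extreme N rows are data-poor at this read count, hence
the low min R² — they are interpolated and flagged). Half of all base
pairs are confidently nucleosomal; the density profile shows a clean NDR
upstream of the TSS (density 0.04) against ~0.68 occupancy inside gene
bodies, and the dominant called footprint length is close to the 147-bp
nucleosome (the run-length histogram also contains many short noise runs
from sporadically significant single windows on low-methylation
molecules, as on real data). With no simulated jitter, heterogeneity
scores below 1 reflect caller noise alone; simulated per-molecule jitter
lowers them further.

Per-molecule results can be written as an IGV-ready annotated BAM
(`writeAnnotatedBam()`: m6A as 1-bp insertions, nucleosomes as mismatch
runs, accessible as matches, ambiguous as deletions), as BED
(`writeStateBed()`), or as a plain TSV interchange table. A thin CLI over
the same pipeline lives at `inst/cli/m6afoot.R`, and `runPipeline()`
orchestrates simulate → calibrate → call → aggregate with a reproducible
manifest.

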