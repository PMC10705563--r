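---
title: "The adjusted binomial footprint model: methods and design notes"
author: "m6Afootprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The adjusted binomial footprint model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

M.EcoGII methylates adenines in any sequence context, so protein-free
DNA in nuclei acquires a dense m6A pattern while nucleosome-wrapped DNA
stays essentially unmethylated. On long single-molecule reads this
yields a per-molecule accessibility footprint at base-pair resolution.
Two measurement artefacts stand between the raw m6A calls and reliable
footprints:

* **Detection inefficiency with wide molecule-to-molecule variation.**
  Even fully methylated control DNA yields reads whose called-m6A
  fraction spans roughly 5–50%. An unmethylated gap that would be a
  convincing footprint on a 30%-methylated molecule arises easily by
  chance on a 6%-methylated one.
* **AT-content calling bias.** The probability that a genuinely present
  m6A is called falls as the local AT density rises (and along poly(A)
  runs), so AT-rich windows look spuriously protected.

# The model

Each read is scanned with a sliding window (default 25 bp — wide enough
to contain several adenines, narrow enough relative to a linker). For a
window with `n` adenines on both strands (the A+T count of the Watson
sequence; every base pair carries its adenine on exactly one strand)
and `k` called m6A, the expected methylation is predicted from the
read's own average methylation `m` through a per-AT-count line:

    p_exp = slope(N) * m + intercept(N),    N = n in 3..25

fitted on a fully-accessible control (purified DNA methylated in
vitro). The window count is then tested against
X ~ Binomial(n, p_exp) with two one-tailed p-values that both include
the observed count: P(X <= k) (protection) and P(X >= k)
(accessibility). Within each read, each family is Benjamini–Hochberg
adjusted separately; the two hypotheses address different alternatives,
so pooling them into one family would mix the two error rates (this is
the package's reading of "adjusted within each read"). The central
nucleotide of each window is labelled accessible when the adjusted
accessibility p-value is below 0.853, nucleosomal below 0.918,
otherwise ambiguous; when both pass, the smaller adjusted p-value wins
and an exact tie stays ambiguous (a case the defining procedure leaves
open).

The null hypothesis is "this window methylates like the read average".
A fully accessible molecule therefore produces mostly *ambiguous*
bases — there is nothing to reject — which is exactly why a
fully-accessible control measures the false-positive rate of both call
types: any rejection on it is spurious. On chromatinised molecules the
read average sits between the accessible and protected levels, so both
tails gain power.

## Boundary resolution

Window centers near a state transition are systematically ambiguous:
as the window slides from accessible DNA into a footprint its count
passes through the expected value. Four rules run in a fixed order:

1. at each accessible-to-nucleosomal transition, the 12 nt downstream
   of the last accessible window center (that window's second half)
   become accessible;
2. symmetrically, at nucleosomal-to-accessible transitions the 12 nt
   downstream of the last nucleosomal center become nucleosomal;
3. bases claimed by both extensions become nucleosomal;
4. remaining ambiguous runs shorter than one window (25 bp) adjacent to
   a nucleosomal run become nucleosomal (a run shorter than a window
   cannot independently support an accessible call).

Two details the defining rules leave open are pinned down here. First,
extensions convert ambiguous bases only — a called base is never
flipped. Second, an extension fires only when the ambiguous gap at the
transition is shorter than one window; longer ambiguous stretches are
not boundary artefacts and are left alone. With these two choices the
operation is provably idempotent (after one pass, every ambiguous run
adjacent to a nucleosomal run is at least a window long, so no rule can
fire again), which the test suite verifies on random label tracks.

## Calibration fitting

Control reads with average methylation inside a closed interval
(default 7–41%, the well-populated range of a methylated-DNA control)
are grouped by average methylation rounded to 1%; window methylation is
averaged per (N, bin) cell; one ordinary least-squares line per N is
fitted across cells. Filtering to the fit range happens before
binning. N rows with fewer than three populated bins are flagged and
filled by linear interpolation in N — the extremes of N are data-poor
on any single data set. Predictions are clamped to
[1e-6, 1 - 1e-6] so they are always valid binomial success
probabilities (the defining formula can go negative for GC-rich windows
at low read methylation).

## Threshold calibration

`calibrateThresholds()` re-derives the two cutoffs from a control
instead of trusting the defaults: it sweeps a grid of candidate
thresholds, runs the full caller (including boundary resolution) on the
fully-accessible control, and returns the largest nucleosomal threshold
whose nucleosomal base fraction stays below the target false-positive
rate (default 1%). A false *accessible* call needs truly protected
truth, which an all-accessible control cannot provide; the accessible
threshold is therefore calibrated on simulated fully-protected reads
(methylated at the intra-footprint rate). This is the one deliberate
departure from deriving both cutoffs from the gDNA control alone.

# The simulator

The generator emulates the statistical structure the model assumes,
with defaults fixed at the study conditions:

| parameter | default | rationale |
|---|---|---|
| genome AT content | 0.60 mean, per-500-bp block SD 0.10 | compact-genome composition; block heterogeneity is what populates extreme window AT counts (an iid-base genome essentially never produces N = 5 windows at 60% AT) |
| read length | 1,000 bp | ~2-kb library sheared reads, desk scale |
| per-read m6A fraction | lognormal, median 0.11, sdlog 0.5 | matches the observed ~11 ± 6% spread on chromatin; gDNA-like controls use median 0.195 (the control's observed median) |
| footprint | 147 bp | nucleosomal DNA |
| linker | max(5, round(Normal(18, 5))) bp | 15–20 bp average linker |
| NDR length | 140 bp | promoter nucleosome-depleted region |
| intra-footprint methylation | 0.01 | ~1–2 called m6A per wrapped footprint |
| read quality | constant 99 | quality filtering is exercised by dedicated fixtures |

Chromatinised molecules are generated against a genome-wide map: an NDR
immediately upstream of every TSS (strand-oriented) and footprint/linker
arrays tiling the DNA between NDRs, phased off both flanking NDRs. Each
molecule sees that map shifted by a normal positional jitter
(`jitterSd`), which is the knob for cell-to-cell heterogeneity. Reads
without a gene annotation get independent arrays of ~8 nucleosomes
separated by NDRs with random phase. Accessible adenines are detected
at a rate solved from the mass balance
`f = q * nucMeth + (1 - q) * pAcc` (f: the drawn per-read fraction, q:
the read's protected adenine fraction), so realised read methylation
matches the configured distribution; AT-count and poly(A) bias
multipliers apply to accessible detection.

Deliberately **not** simulated: sequencing errors, subread/consensus
structure, kinetic (IPD) signal, transcription-factor-sized footprints,
remodeler dynamics. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative assumptions, not
robustness to alignment or base-calling artefacts in real data.

# Validation design and problem sizes

The test suite validates each operation against an independent oracle:
binomial tails against brute-force pmf summation, BH against the
step-up definition, calibration slopes against the generator's analytic
expectation, state calls against simulator truth. The end-to-end checks
run at these sizes (chosen as the package's desk-scale study
conditions): false-positive control with 10,000 1-kb reads split
half/half for calibration and held-out evaluation; calibration
linearity with 20,000 reads under a linear AT bias; the window-level
in-silico test at its design scale of nine conditions x 100,000
windows (m6A fractions 5/10/15%, nucleosomal fractions 60/70/80%, 1%
intra-footprint methylation, accessible methylation solved from the
mass balance); footprint recovery on 400 chromatinised reads; and
heterogeneity monotonicity over jitter SDs {0, 20, 40} bp with 50 genes
x 20 molecules.

# Known limitations

* **Called footprints run a little short at hot linkers.** A window
  centered a few bp inside a footprint still overlaps the adjacent,
  heavily methylated linker and can remain significantly accessible;
  the 12-nt extension then claims those bases. Under dense-array
  conditions (18-bp linkers, 12% methylation) the footprint-length
  histogram therefore peaks slightly below 147 bp (around 130–135) —
  the same systematic shortening the method shows on real chromatin,
  where the called-footprint distribution has its sub-peaks below the
  nominal nucleosomal length. Isolated footprints flanked by long
  accessible stretches are recovered at full length.
* **Per-N calibration linearity is data-hungry at extreme N.**
  Consecutive windows share 24 of 25 bases, so the effective number of
  independent observations per (N, bin) cell is close to the number of
  distinct read-locus combinations, not the window count. At 20,000
  reads the rare N = 5 cells keep a cell-mean standard error of
  roughly 0.02 against a signal SD of ~0.1, capping that row's R^2
  near 0.98; the 0.99-everywhere regime needs several-fold more reads.
  The fitted slopes themselves are accurate (the parameter-recovery
  test bounds them within ±0.05).
* **BH under dependence.** Overlapping windows are strongly
  positively correlated; BH remains valid under this dependence type
  but is conservative, which is partly why useful thresholds sit close
  to 1 on the adjusted scale.
* Transcription-factor-sized footprints are out of scope by design:
  at current detection efficiency, short protections cannot be called
  with confidence.
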