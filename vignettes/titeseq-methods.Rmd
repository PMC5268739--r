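---
title: "Sort-seq titration curves: model, simulator and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-seq titration curves: model, simulator and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titeseq)
```

## The measurement problem

Deep mutational scans of binding proteins usually score variants by
enrichment after selection at a single ligand concentration. Because bound
ligand is a sigmoidal function of affinity, a single concentration resolves
dissociation constants only within about a decade of that concentration, and
enrichment conflates affinity with surface-expression level and specific
activity. A sort-seq *titration* instead repeats the FACS-and-sequence
experiment across a ladder of antigen concentrations, reconstructs a binding
curve per variant from its read counts across sorting bins, and reads off an
absolute dissociation constant in molar units. This package implements the
full computational side of such an experiment for a yeast-displayed scFv
antibody library mutagenized in two 10-codon CDR windows (CDR1H, residues
28–37, and CDR3H, residues 100–109): a forward simulator, the inverse
(fitting) machinery, amplicon read processing, and the downstream
sequence-affinity landscape and structural analyses.

## The binding and observation model

The median fluorescence of cells displaying one variant, labeled at free
antigen concentration $c$, follows the equilibrium isotherm

$$ f(c) \;=\; A\,\frac{c}{c + K_D} \;+\; B, $$

where $A$ is the saturating signal (proportional to the number of functional
antibodies per cell), $B$ the background fluorescence, and $K_D$ the
dissociation constant. Hill coefficients other than 1, avidity and ligand
depletion are out of scope: $c$ is the free, non-depleted concentration.

Single-cell fluorescence spreads around this median through cell-to-cell
variability in display level and cytometer noise. We commit to a log-normal
observation model,

$$ \log_{10} f_{\mathrm{cell}} \sim N\!\big(\log_{10} f(c),\; \sigma^2\big), $$

with the isotherm value as the *median* cell fluorescence. The choice is
motivated by the approximate log-normality of flow-cytometry fluorescence
and by the fact that sorting gates are drawn on a log axis. The spread
$\sigma$ (`log_sd`, log10-units) defaults to 0.5, reproducing the roughly
half-decade width of yeast-display flow histograms. It is treated as shared
across variants: at realistic per-variant read depth a per-variant spread is
not identifiable, and `fit_titeseq(..., fit_log_sd = TRUE)` can profile the
shared value from high-count variants instead of assuming it.

Sorting into $n$ bins with fixed fluorescence boundaries turns this density
into a probability vector per (variant, concentration): the log-normal mass
between consecutive gates (`bin_probabilities()`). Bins are indexed 0 to
$n-1$ from low to high fluorescence, and the mean bin number
$\sum_b b\,p_b$ serves as the sequencing-side proxy for mean cellular
fluorescence.

## What the simulator emulates

`simulate_titeseq()` generates one complete experiment:

1. **Design.** Eleven antigen concentrations — 0 M plus a half-decade ladder
   from $10^{-9.5}$ to $10^{-5}$ M — with four sorting bins each, plus a
   four-bin expression sort: 48 sorted bins. These are the package defaults
   (`sort_design()`).
2. **Sorting.** Cells are allotted to variants multinomially by library
   abundance; each variant's cells fall into bins with the gated log-normal
   probabilities. Drawing per-variant bin counts multinomially is exactly
   equivalent to simulating cells one at a time.
3. **Gates.** One gate set is used across all concentrations of an
   experiment. By default gates sit at the quartiles of the simulated
   library fluorescence at the *highest* antigen concentration, where the
   library spans background to saturation, so the four bins tile the full
   dynamic range. (Calibrating on the antigen-free library was considered
   and rejected: all three quartile boundaries then fall inside the
   background cloud and the titration signal collapses into the top-bin
   fraction.)
4. **Recovery bottleneck.** Sorted cells are thinned binomially by a
   post-sort recovery efficiency (default 0.2) before sequencing. This is
   deliberately exposed as a first-class parameter because inefficient
   post-sort recovery of sequences — not the number of sorted cells or
   reads — is the dominant noise source in this class of experiment.
5. **Sequencing.** Reads are drawn multinomially over the recovered clones
   of each bin up to the bin's read budget (default $2.6\times10^6$ reads
   per bin at full scale, the experimental average).

Cells per concentration sort default to $4\times10^6$ ($10^6$ per bin on
average), a realistic FACS throughput for an 11-concentration day; this
value is not printed in the source experiment and was calibrated once so
that the simulator reproduces the published validation behaviour — accurate
recovery at experimental depth, monotone degradation when sorted cells are
cut $10^3$-fold.

All package tests and the acceptance script run at `scale_design(...,
0.01)` — 1/100 of full experimental depth — with libraries of up to 500
variants; these problem sizes keep the full parameter-recovery studies
comfortably reproducible on a laptop while leaving every noise source
active.

The simulator does **not** emulate: sequencing errors (reads are emitted
error-free; the quality filter is exercised with synthetic low-quality
records), PCR chimeras, optical spillover/compensation, doublets,
cell-cycle effects, or epistasis in the ground truth (each variant has an
independent $K_D$). Passing parameter-recovery tests therefore demonstrates
correctness of the inference machinery under the committed noise model, not
robustness to artifacts outside it.

## Inference

`fit_titration_ml()` maximizes, per variant, the summed multinomial
log-likelihood of the observed bin counts across concentrations, with bin
probabilities from the gated log-normal forward model, over
$(\log_{10} K_D, \log_{10} A, \log_{10} B)$. Numerical choices:

* All $K_D$ arithmetic is in $\log_{10}$-molar; values span four and a half
  decades and linear-scale optimization underflows.
* **Re-weighting.** Read proportions within a bin reflect the clones that
  were sequenced, not the cells that were sorted. When per-bin totals are
  available, each (concentration, bin) count is re-weighted by
  (cells sorted into the bin)/(reads obtained from the bin), then rescaled
  so each concentration keeps its raw total evidence.
* **Optimization.** A coarse, fixed grid over $\log_{10} K_D$ (step 0.25,
  spanning the sensitivity window) with $(A, B)$ profiled by Nelder–Mead at
  each grid point, followed by one box-constrained refinement. No random
  restarts: fits are exactly reproducible.
* **Censoring.** $\log_{10} K_D$ is box-constrained to the sensitivity
  window ($10^{-9.5}$–$10^{-5}$ M, the detection limits of the
  11-concentration ladder). An estimate within $10^{-3}$ decades of a box
  edge is flagged `low`/`high` and reported at the boundary; censored
  values *stay* at their boundary value in every downstream statistic
  (replicate averages, effect matrices, rank tests), mirroring the standard
  reporting convention for out-of-window affinities.
* The 0 M point enters the likelihood and constrains $B$ only.

`fit_titration_meanbin()` is the fast least-squares path: one mean signal
per concentration (mean bin number, or median fluorescence from clonal flow
cytometry — the same fitter serves low-throughput validation curves), with
$(A, B)$ profiled *exactly* by weighted linear least squares at each
$\log_{10} K_D$, since the isotherm is linear in $(A, B)$ given $K_D$. A
fit with vanishing amplitude has no binding signal in range and is flagged
censored-high. Both fitters return a classed `titration_fit` with `print`,
`coef`, `summary`, `predict`, `plot`, `logLik` and `residuals` methods.

Expression scores divide a variant's expression-sort mean bin number by the
mean over the synonymous-WT pool, fixing the pool average at exactly 1;
`aggregate_replicates()` averages $\log_{10} K_D$ across replicates and
quotes the across-replicate standard deviation.

## Landscape analyses

`build_effect_matrix()` condenses single-substitution estimates into a
position × amino-acid matrix of $\Delta\log_{10} K_D$ (a position-specific
affinity matrix), averaging synonymous codon variants (they are replicate
measurements of one substitution) and fixing WT entries at 0.
Per-position sensitivities are mean squared deviations over the 19 non-WT
amino acids,

$$ S_K(i) = \big\langle (\log_{10} K_D^{ia} - \log_{10} K_D^{WT})^2
\big\rangle_{a|i}, \qquad
S_E(i) = \big\langle (E^{ia} - E^{WT})^2 \big\rangle_{a|i}, $$

with unmeasured entries dropped from the average (divisor reduced) — the
matrix records which entries are missing rather than imputing them. The
additive model (`predict_log10_kd()`) sums matrix entries over non-WT
positions; it reproduces every single mutant by construction and ignores
epistasis by design. `random_multimutant_fraction()` Monte-Carlo samples
multi-mutants with positions drawn *without replacement* (the natural
reading of substitutions "scattered across" the windows; allowing repeats
would conflate single- and multi-hit classes).

The enrichment diagnostic re-weights counts by per-bin cell fractions,
forms the (bins 2+3)/(bins 0+1) ratio per variant (zero denominators padded
with a single pseudocount and reported), partitions variants into seven
affinity groups at half-decade boundaries, and computes Spearman
correlations between enrichment and $\log_{10} K_D$ per (group,
concentration). Informative data produce correlations above the 0 M
background band only near the diagonal $c \approx K_D$ — the quantitative
form of the argument that single-concentration enrichment cannot rank
affinities across a wide window.

Between-region comparisons use the Wilcoxon rank-sum test for location and
Levene's test (mean-centered) for variance homogeneity.

## Structural correlates

`residue_environment()` reads a standard PDB coordinate file (via bio3d)
and reports, per CDR residue, the number of contacts within the protein and
the minimum heavy-atom distance to the ligand. Conventions — a 4.5 Å
heavy-atom pair cutoff, exclusion of the $i\pm1$ sequence neighbours, and
minimum-atom (not centroid) ligand distance — are this package's declared
choices; the cutoff is a parameter. `correlate_sensitivity()` reports
ordinary $R^2$ between $S_K$/$S_E$ and each structural covariate. A
synthetic complex (`synthetic_scfv_structure()`, two 10-residue loops plus
a three-atom ligand, labelled synthetic throughout) exercises the code
paths; analyses of the real crystal structure require only pointing the
same functions at the downloaded file.

## Degenerate inputs and tie-breaks

* Non-monotone gate boundaries, negative concentrations, empty libraries
  and all-zero count tables raise immediate errors.
* A zero isotherm median (no background, no signal) places all probability
  mass in bin 0.
* Barcodes are matched with at most one mismatch *and* a unique nearest
  barcode; at pairwise distance exactly 2 a single error can be equidistant
  from two barcodes, and such ties are left unassigned rather than guessed.
* Reads whose mates both cover the insert must agree exactly; fixed-length
  excision rejects indels, which cannot arise in a substitution-only
  library except through sequencing artifacts.

## Known limitations

* Absolute $K_D$ accuracy inherits the committed observation model; if real
  cell fluorescence departs strongly from log-normal, estimates remain
  rank-consistent but may shift.
* The shared `log_sd` trades per-variant flexibility for identifiability.
* Effect matrices built from censored estimates understate effects beyond
  the detection limits — boundary entry is a reporting convention, not an
  extrapolation.
* The enrichment diagnostic needs several variants per affinity group;
  groups with fewer than three measured variants are reported as `NA`.

## A minimal end-to-end run

```{r example, eval = FALSE}
lib <- ground_truth_library(kd = 10^runif(100, -9.5, -5))
design <- scale_design(sort_design(), 0.01)   # desk-scale depth
sim <- simulate_titeseq(lib, design, seed = 1)
est <- fit_titeseq(sim)
head(est)

fit <- fit_titration_ml(sim$affinity_reads[1, , ], sim$design,
                        cell_totals = sim$cell_totals,
                        read_totals = sim$read_totals)
summary(fit)
plot(fit)
```
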