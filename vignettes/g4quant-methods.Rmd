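---
title: "Methods: foci quantification, dose-response and synergy scoring in g4quant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foci quantification, dose-response and synergy scoring in g4quant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4quant)
```

g4quant implements the quantitative core of a cell-imaging and in-vitro
pharmacology workflow built around G-quadruplex (G4) biology: counting
punctate fluorescent foci per cell in 3D z-stacks (a clickable G4 probe, or
γH2AX as a DNA double-strand-break marker), fitting dose–response curves
(IC50 from viability, apparent K~D~ from fluorescence quenching, T~1/2~ from
FRET melting), and scoring drug-pair viability matrices against Bliss
independence. Every analysis stage has a matching synthetic-data generator
with exact ground truth, so the whole pipeline is testable without any
microscope or plate-reader data.

## The per-cell foci quantification model

A field is a two-channel voxel grid indexed `(z, y, x)`: a DAPI channel for
the nucleus and a red channel carrying the punctate staining. The reference
acquisition uses 5 z-planes (probe mode) or 7 (γH2AX mode) at 0.3 µm
spacing; sizes are reported in voxels throughout and no µm³ conversion is
applied (the axial anisotropy is carried as metadata).

For one outlined cell the pipeline is:

1. **Background subtraction** — the red-channel mean over a cell-free region
   is subtracted and the result floored at zero; the estimate is recorded.
2. **ROI clearing** — all voxels outside the cell outline are zeroed in both
   channels, so neighbouring cells cannot contribute.
3. **Nucleus segmentation** — Otsu's threshold on the DAPI intensities
   within the ROI, hole filling per z-slice, then the largest connected
   component. One nucleus per ROI by construction.
4. **Foci segmentation** — red-channel voxels above a threshold, labelled by
   3D connected components. The threshold rule is *background mean + k·SD*
   with `k = 3` by default, estimated once per experiment from cell-free
   regions of the untreated (NT) fields. The protocol requires the same
   segmentation parameters for every condition of one experiment, so the
   parameter object carries its experiment id and `segment_foci()` refuses
   to cross experiments unless explicitly overridden.
5. **Classification and size filtering** — a component with *any* voxel
   overlapping the nucleus mask is nuclear-side; nuclear-side components
   larger than 100 voxels are the morphologically defined nucleoli and are
   removed from the nuclear counts; nuclear foci are kept at 3–100 voxels,
   cytoplasmic foci at 20–100 voxels (smaller cytoplasmic spots are
   indistinguishable from background, larger ones cannot be separated).
   Nothing is dropped silently — every component carries its final
   compartment or a discard reason. In γH2AX mode only nucleus-overlapping
   components of ≥ 2 voxels (configurable) are counted, as foci per nucleus.
6. **QC flagging** — cells with robust z-scores (median/MAD) beyond ±3 on
   DAPI volume or integrated intensity, zero DAPI signal, or (probe mode) no
   segmented nucleolus are marked excluded but retained.
7. **Condition summaries** — per-experiment means first, then the
   across-experiment mean ± SD, matching designs where each independent
   experiment contributes one point. Fold change is the condition mean over
   the NT mean; the NT-corrected delta is their difference.

Three conventions deserve justification because the underlying protocol text
leaves them open. *Connectivity* is 26 in 3D (voxels sharing a face, edge or
corner), the common 3D object-counter default; 6 and 18 are available.
*Nuclear vs cytoplasmic* uses any-overlap with the nucleus mask, the literal
reading of "overlapping with the segmented DAPI staining"; centroid-in-mask
is the plausible alternative and differs only for components straddling the
nuclear envelope. *The threshold rule* (mean + 3 SD from NT fields) is a
documented stand-in: the original macro's operator is not described beyond
its size rules, and any experiment-constant rule preserves the quantity the
analysis actually relies on — trends and fold changes, not absolute counts,
which the protocol itself treats as convention-dependent.

## What the synthetic cells emulate — and what they do not

`simulate_cell_stack()` renders one cell: an ellipsoidal nucleus (default
semi-axes 2.4 × 18 × 18 voxels in a 5 × 64 × 64 grid) inside an ellipsoidal
cell footprint, 2–3 bright nucleoli of 110–160 voxels (always above the
100-voxel cutoff), and planted foci — compact connected voxel sets of
exactly known size, placed with a one-voxel exclusion halo so separate
objects can never merge ("separable" placement). Blob intensity falls off as
a Gaussian of distance from the blob centre but is floored at 60% of the
amplitude; with the default amplitude of 120 on a background of 100 ± 8,
every planted voxel clears the mean + 3 SD threshold by more than 5 noise
SDs, and detection is unambiguous. Focus counts are Poisson (defaults: mean
4 nuclear, 1.5 cytoplasmic per cell), sizes uniform (3–12 nuclear, 20–40
cytoplasmic voxels), and a `fold_change` multiplier scales the means to
emulate treatment. Exact counts or explicit size lists can be planted for
deterministic designs.

The generator deliberately omits: optics (no PSF, no deconvolution
artefacts — inputs are assumed deconvolved), intensity statistics calibrated
to real stacks (none are published for this assay; amplitudes are
conventions), cell-to-cell morphology variation, touching cells, and any
biology in focus placement. Passing tests therefore demonstrate that the
*rules* of the quantification are implemented correctly and that planted
effects are recovered; they do not validate segmentation performance on real
images, where the protocol's own caveat applies — counts reveal trends, not
absolute truth.

Two numerical notes on exactness. The ground-truth voxel counts are exact by
construction because blobs are built as voxel sets of the target size; an
alternative (thresholding a continuous Gaussian at half-maximum) yields only
approximate sizes, which would make exact-recovery tests circular. And the
exact-recovery suite runs with the background noise SD set to zero: with
Gaussian noise and a mean + 3·SD threshold, a boundary-size object (100 vs
101 voxels) flips class whenever a single background voxel adjacent to it
crosses the threshold, so exactness is a noise-free property by nature.
Noisy conditions are exercised by the fold-change recovery study instead,
where a 15% tolerance absorbs threshold effects.

## The demonstration study

`run_demo()` mirrors the imaging study's design: six arms — NT, the
modulator alone, two ligands, and each ligand after modulator pre-treatment
— across 3 independent experiments with 30 cells per condition. Planted
nuclear fold changes are 1, 1.5, 3.8, 4.5, 1.5, 1.5: the two ligand folds
reproduce the reported treatment effects, and the 1.5 of the modulator arms
emulates its reported mild nuclear effect and its suppression of the ligand
response. Per experiment, NT cells are generated first, the segmentation
threshold is frozen from their cell-free regions, and every arm is
quantified with those parameters. At these sizes (540 cells) the demo runs
in about a minute and recovers the planted folds within a few percent;
recovery within 15% is the tested contract, the margin covering Poisson
sampling of ~4 foci per NT cell across 3 experiment-level replicates.

## Dose–response fitting

All curve-shaped readouts go through one four-parameter logistic (4PL),

$$y(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
        {1 + (d/\mathrm{mid})^{h}},$$

fitted by Levenberg–Marquardt least squares with the midpoint on the
log~10~-dose scale. The reported midpoint is the *relative* IC50 (viability
mode) or the apparent K~D~ (binding mode) — the GraphPad-style convention
for this model family, not the absolute-50% crossing. Starting values are
taken from the response extremes and the dose nearest half-range with a
Hill slope of 1; because steep or edge-midpoint curves can make the Jacobian
singular at one start, a small grid of Hill/midpoint starts is swept until
one converges. Bounds: midpoint within one decade beyond the dose range,
Hill slope in [0.1, 10]. Fits need ≥ 5 distinct positive doses; flat
responses are rejected as "no dose dependence"; non-convergence is flagged,
not hidden. Standard errors come from the fit's covariance (the midpoint's
by the delta method); when replicate experiments exist, the spread of
per-experiment estimates is the complementary uncertainty and both are worth
reporting.

Viability is normalized as 100 × absorbance / mean NT absorbance. The
fluorescence-quenching response is the per-well fraction of pre-incubation
fluorescence remaining after an hour, T60/T0 — self-referenced per well so
loading differences cancel; this transformation is a documented choice, as
the assay description names only the model family. In reverse mode (for
intrinsically fluorescent ligands) the labelled oligonucleotide is titrated
against a fixed ligand concentration, which the table must carry.

## FRET melting

FAM emission on the stepwise heating ramp (25–90 °C in 1 °C steps; the
cooling ramp, when present, is parsed but unused) is min–max normalized to
0–100%, making the curve invariant to affine rescaling of the raw signal.
T~1/2~ is the temperature at the first upward 50% crossing, linearly
interpolated between the bracketing measurements after an optional (default)
3-point running-median smooth that guards the first-crossing rule against
isolated noisy points and is the identity on monotone curves. ΔT~1/2~ is
the difference between the ligand-bound and free-DNA curves; ΔΔT~1/2~
differences two such shifts with and without a competitor. Curves must share
one temperature grid and protocol tag (classical competition vs sequential
pre-folding), since shifts across protocols are not comparable.

Two small biases are inherent and documented rather than corrected: if the
transition does not saturate within the ramp, min–max normalization shifts
the 50% level (≈ 7 × 10⁻⁴ °C for a 74.4 °C midpoint of width 2 °C); and
linear interpolation on a 1 °C grid has a secant bias (≈ 4 × 10⁻³ °C at
width 1 °C) unless the midpoint lies on a measured temperature. Both are
orders of magnitude below the assay's 0.1 °C reporting precision.

## Bliss synergy scoring

For inhibition fractions $f_A, f_B$ of the monotherapy margins, Bliss
independence expects combined inhibition $f_A + f_B - f_A f_B$. Each
combination cell is scored as 100 × (observed − expected) percentage points
after replicate averaging, with viability clipped to [0, 100]% first
(stimulated wells are capped; the count of capped wells is logged). The
matrix mean averages combination cells only — the margins define the null
and would dilute it — and pairs scoring > 10 are flagged synergistic. This
is the classical Bliss excess; the popular web tool it mirrors additionally
smooths the response surface before scoring, a divergence we document and do
not implement. No p-value is attached to the matrix mean.

The synthetic matrix generator plants a constant excess over the Bliss
expectation (clipped to [0, 1] before noise) on top of two 4PL monotherapy
curves. Its default dose grids span 0.04–40 nM (drug A) by 0.78–50 µM
(drug B) with the two drugs' measured IC50s (3.3 nM, 51.9 µM) as midpoints;
at those potencies the highest-dose pairs approach full inhibition, where a
positive planted excess is necessarily truncated — visible in the demo as a
matrix mean below the planted value. The recovery *study* therefore places
the midpoints at the top of each grid (expected inhibition ≤ 0.75 per pair,
0.95 with the excess), chosen from that arithmetic so the clip cannot bind
noise-free. Under 10% multiplicative noise a second, subtler truncation
appears: near-zero-effect margins sit at ~100% viability, the cap removes
only the upward noise tail, and the inferred monotherapy inhibition is
biased high, depressing the mean score by about one point. Since both arms
of a recovery comparison share this distortion, the planted excess is
estimated as the difference between the planted-excess arm and an
identically simulated zero-excess arm, which is unbiased; tests require
agreement within twice the Monte-Carlo standard error of that difference.

Foci-based synergy uses the NT-corrected mean foci/nucleus deltas: the
additive expectation for a combination is the sum of the single-agent
deltas, and the fold beyond additive is the combination delta over that sum
— 1 means purely additive, undefined (reported as missing) when the
additive expectation is not positive.

## Reproducibility and numerical conventions

Every generator takes an explicit integer seed and restores the caller's RNG
state; identical configuration and seed give bit-identical output, and
`run_demo()` derives all per-cell seeds from its single seed. Voxel
coordinates are 1-based `(z, y, x)` array indices in R's convention; labels
are assigned in array scan order so labelling is deterministic. Thresholds
sit at documented defaults (size windows 3–100, 20–100, > 100; k = 3;
Bliss call > 10) and are arguments, not constants. Problem sizes used by the
test suite and the acceptance script — 200 random 12 × 12 × 5 masks for the
labelling oracle, 50 cells for exact recovery, 3 × 30 cells per condition
for fold recovery, 500 simulated plates for 4PL bias, 20 matrices per
synergy recovery arm — were chosen as the smallest sizes at which the
Monte-Carlo error is comfortably inside each tolerance.

## Known limitations

Absolute foci counts depend on the threshold convention and are only
meaningful as within-experiment trends. Nucleus segmentation assumes one
nucleus per ROI and two-level DAPI contrast; it has no mitotic-cell or
apoptotic-cell handling. The 4PL midpoint is unreliable when it lies outside
the dosed range (the bounds then bind). T~1/2~ is undefined when the
transition is outside the ramp, and reported as an error rather than
extrapolated. The Bliss implementation scores observed excess only; it does
not model dose–response surfaces and should not be extrapolated between
measured doses.
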