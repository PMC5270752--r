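---
title: "Phenotyping single-cell Raman spectra for Raman-activated cell ejection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping single-cell Raman spectra for Raman-activated cell ejection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(raceSCRS)
```

## The problem

A single-cell Raman spectrum (SCRS) is a label-free biochemical fingerprint
of one bacterial cell. In Raman-activated cell ejection (RACE), cells dried
on a coated chip are measured one by one; cells whose spectra carry
biomarker bands of interest are then ejected by a pulsed laser into
collection wells for whole-genome amplification and sequencing. The
computational core of that workflow is what this package implements:

1. screen out cells whose spectra are dominated by fluorescence,
2. call per-cell phenotypes from biomarker bands -- the three
   resonance-enhanced carotenoid bands (v1 997--1007, v2 1145--1161, v3
   1503--1526 cm^-1^) and the four poly-beta-hydroxybutyrate (PHB) markers
   (839, 1058, 1123, 1403 cm^-1^),
3. resolve carotenoid-positive cells into carotenoid *types* from the exact
   (v1, v2, v3) positions at the ~1 cm^-1^ instrument resolution,
4. confirm by PCA that carotenoid bands drive the cohort's spectral
   variation, and
5. turn the calls into a chip sort plan with control wells and a simulated
   ejection manifest.

Because raw spectra from the original marine survey are not available as
analysis-ready files, the package ships a first-class synthetic generator
that emulates that cohort: 5321 cells, 33% fluorescence-dominated, 23%
carotenoid-containing, measured on a 1019-point grid at 1 cm^-1^ spacing.
Every pipeline stage is exercised against this emulation plus exhaustive
brute-force oracles.

## The wavenumber grid

The instrument reference fixes only the resolution (~1 cm^-1^) and the
point count (1019). The package default places the axis at 700--1718
cm^-1^, which covers every band the classifier uses (785--1660 cm^-1^)
with margin on both sides. Wavenumber coordinates are always physical
cm^-1^ values; no public interface addresses spectra by index.

## The synthetic cohort generator

Each ground-truth phenotype is an *archetype*: a sum of Lorentzian bands
$L(\nu) = h\,(\Gamma/2)^2 / ((\nu-\nu_0)^2 + (\Gamma/2)^2)$ over an
optional smooth background.

* All cell-like archetypes share base bands at 785, 1003, 1245, 1450 and
  1660 cm^-1^ (heights 0.3/0.5/0.3/0.4/0.5, FWHM 20 cm^-1^) -- the
  protein/nucleic-acid background of an ordinary cell.
* Carotenoid cells add the three resonance bands at heights 1.5/3.0/5.0
  (v1/v2/v3, FWHM 12): resonance at 532 nm excitation makes these few
  bands dominate the spectrum, which is exactly why they work as a sorting
  criterion. Their positions are drawn uniformly within the canonical
  windows per cell, so every carotenoid cell carries an individual
  (v1, v2, v3) triplet.
* PHB cells add the four marker bands at height 2.0 (FWHM 12).
* Fluorescent cells carry a broad Gaussian bump (sd 300 cm^-1^, centre
  drawn U(1100, 1500), height 20x the strongest base band) that dwarfs
  their Raman bands.
* "Other-compound" cells are dominated by an unidentified compound with
  bands at 890, 1332 and 1570 cm^-1^ and carry *no* detectable base bands.
  This is deliberate: the phenotype decision rule labels any spectrum with
  two or more base-band matches "typical", so a distinct "other" call is
  only reachable for cells whose unusual chemistry displaces the ordinary
  cell signature -- which is also the situation in which a spectrum reads
  as "a new compound" to an operator.

The default cohort composition is 33% fluorescent, 23% carotenoid, 30%
typical, 7% PHB and 7% other-compound. Only the first two fractions are
anchored by the study being emulated; the 44% remainder split is a package
choice, kept configurable. Label counts are one seeded multinomial draw,
so realised fractions fluctuate binomially around the preset, as they
would over repeated field campaigns.

Measurement noise adds, per cell: a random degree-3 polynomial substrate
background scaled into [0, 0.3] relative units, Gaussian read noise
(sd 0.02) and shot noise (sd $0.05\sqrt{\mathrm{signal}}$). Negative noisy
counts are clipped at zero, preserving the non-negativity of raw counts.
A cosmic-ray hook exists in the noise model but is off by default. What
the generator does *not* emulate: biological band-height variability
between cells of one phenotype, wavenumber miscalibration, detector
etaloning, photobleaching kinetics, and mixed phenotypes (each cell has
exactly one ground-truth label; carotenoid and fluorescent are disjoint
classes, since carotenoid calls are only possible on distinguishable
spectra). Passing tests therefore demonstrate correctness of the
*computation* under controlled conditions, not classifier performance on
real instrument exports.

The seven sorted-sample reference spectra are rendered noiselessly with
pinned triplets chosen inside the canonical windows such that three
samples (P728-5, P709-11, P610-5) share one triplet and the other four
are mutually distinct -- five types in total. The exact values are a
package choice; every inter-type Chebyshev distance exceeds 4 cm^-1^, so
the 5-type structure is robust to one-grid-point peak rounding.

## Preprocessing

**Baseline.** Asymmetric least squares: minimise
$\sum_i w_i (y_i-b_i)^2 + \lambda \sum (\Delta^2 b)^2$ with $w_i = p$
above the baseline and $1-p$ below, iterated 10 times
($\lambda = 10^5$, $p = 0.01$). The penalised system is pentadiagonal and
is solved by a banded Cholesky factorisation in C++, so a 5321-cell cohort
preprocesses in seconds. $\lambda = 10^5$ gives a baseline stiffness
length of roughly $\lambda^{1/4} \approx 18$ grid points: stiff enough to
ignore 12--20 cm^-1^ bands, soft enough to track a 300 cm^-1^-wide
fluorescence bump. A known numerical artefact: around tall narrow bands
the penalty *rings*, leaving far-field baseline oscillations of a few
percent of the peak height; the corrected spectrum inherits small
compensating wiggles. The prominence threshold of the peak detector sits
far above these wiggles, so they do not produce phantom band calls.

**Noise scale.** $\hat\sigma = 1.4826\,\mathrm{med}|d - \mathrm{med}(d)|/\sqrt2$
with $d$ the first differences of the corrected trace. Differencing
removes smooth structure, the MAD resists the remaining peak slopes, and
the estimator is exactly scale-equivariant -- the property that makes the
whole pipeline invariant under rescaling of raw counts.

**Smoothing** (Savitzky-Golay, via the signal package) is available but
off by default: at 1 cm^-1^ resolution, band positions are the signal of
interest and must not be broadened silently.

**Normalisation.** Corrected spectra are scaled to unit Euclidean norm
(default) before classification and PCA; the constant is stored for
inversion. A spectrum with no positive corrected intensity cannot be
normalised and is flagged `low_signal`.

## Classification

The fluorescence index is the baseline share of the raw signal,
$F = \sum b / \sum y \in [0,1]$. A cell is screened out as
fluorescence-dominated when $F > 0.85$ *or* when no peak reaches 3 noise
sds of prominence (nothing distinguishable to sort on). Under the default
generator the two populations are cleanly separated ($F \le 0.75$ for
band-bearing cells, $F \ge 0.95$ for fluorescent ones), so the 0.85
threshold sits mid-gap; neither value is fitted to data.

Peaks are strict local maxima scored by topographic prominence (height
above the higher of the two basin minima, basins bounded by the nearest
strictly higher sample or the signal edge), detected at 5 noise-sd
prominence. Each biomarker window then takes its most prominent in-window
peak (ties: closest to window centre, then lower wavenumber); windows are
required to be pairwise disjoint, which is why the 1003 cm^-1^
phenylalanine band is not a base-cell match window -- it lives inside the
carotenoid v1 window.

The decision order is fixed: fluorescent screen first (an emission bump
dwarfs any band evidence), then carotenoid (all three v windows matched;
a 2-of-3 relaxation exists but is off by default), then PHB (all four
markers; relaxable to 3), then typical (>= 2 base bands), else other.
In the noiseless limit this recovers every archetype exactly; under the
default noise model the cohort-level error is below 0.5%.

## Carotenoid typing

Since spectral resolution is ~1 cm^-1^, cells whose (v1, v2, v3)
triplets differ by more than a couple of cm^-1^ in any coordinate carry
structurally different carotenoids. Typing is single-linkage clustering
under the Chebyshev metric with tolerance 2 cm^-1^ (twice the
resolution, absorbing one grid point of peak jitter per side): two cells
share a type iff a chain of <= 2 cm^-1^ neighbours connects them. Single
linkage was chosen because it equals the connected components of the
threshold graph -- checkable against an exhaustive oracle -- and because
increasing the tolerance then provably only merges, never splits, types.
The flip side is chaining: on a large cohort whose triplets fill the
windows quasi-uniformly, everything links into one type, and the 5-type
resolution is only meaningful for small, well-separated collections such
as the seven sorted samples. Complete linkage is available by
configuration for users who prefer compact clusters. Type labels are
ordered by ascending centroid (v3, v2, v1), making the partition labels
independent of input order.

## PCA and loading windows

PCA runs on the normalised corrected spectra, mean-centred, with
fluorescence-screened cells excluded by default (their residual broadband
amplitude would otherwise own the first component; a flag retains them,
since it is unknown whether the original survey excluded them). Loadings
carry a deterministic sign convention (largest-magnitude entry positive).
Top-loading windows of a component are the maximal contiguous runs with
$|l| \ge \alpha \max |l|$ ($\alpha = 0.5$), merging runs separated by
fewer than 3 grid points.

On the emulation cohort, the global argmax of the PC1 loading magnitude
falls inside the carotenoid v3 window, and v2/v3 both appear as loading
windows -- the PCA justification for using the carotenoid bands as the
sorting criterion. Two further windows appear around the 1450 and 1660
cm^-1^ base bands with |loading| just above half the maximum. This is a
direct consequence of unit-norm normalisation: carotenoid cells spend
most of their norm on the resonance bands, so their base bands are ~5x
weaker than a typical cell's, and the between-group axis must carry
anti-correlated base-band weight. The v1 window, conversely, barely loads:
the carotenoid v1 gain is almost exactly offset by the normalisation loss
of the 1003 cm^-1^ band it overlaps. Interpreting loading windows
therefore requires the sign and the band inventory, not the magnitude
alone -- a known limitation of magnitude-threshold window reports on
normalised spectra.

## Sorting

A 12-well chip always reserves at least one negative control well (must
remain cell-free; the session simulator never ejects into control wells,
and tests assert its count is zero) and one positive control. Target
cells are selected by a query over the call table, ordered by ascending
cell id, and dealt round-robin over the minimum number of non-control
wells compatible with the per-well occupancy cap (1--8 cells); an
explicit per-well composition vector (e.g. 1/1/1/3/5/8/8) is also
accepted. Ejections are spaced by the 5 s acquisition time and succeed
independently with a configurable probability (default 1; the published
ejection-plus-amplification success rate of 7/30 is a documented value
for that knob, not a claim this package recomputes).

## Determinism and problem sizes

Every random stage takes an explicit seed; the pipeline's master seed
fans out to per-stage child seeds through a stable integer hash, and
seeded runs are bit-reproducible (asserted down to report bytes). The
test suite runs the full 5321-cell emulation once (about half a minute)
and shares it between the checks that need it; oracle-backed property
tests use small sizes where exhaustive verification is feasible
(spectra of <= 64 points for peak detection, <= 12 triplets for typing,
20 x 32 matrices for the PCA cross-check) -- sizes chosen so the oracle
itself is obviously correct by inspection.

## Worked example

```{r example, eval = FALSE}
set <- simulate_cohort(preset_red_sea_default(), noise_model(), seed = 1)
proc <- preprocess_spectra(set)
calls <- classify_cohort(proc)
print(calls)

types <- cluster_types(carotenoid_triplets(classify_cohort(
  sorted_samples_reference())))
count_types(types)   # 5

plan <- build_sort_plan(calls, "label == 'carotenoid'")
```
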