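---
title: "FTIR-guided MALDI imaging: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR-guided MALDI imaging: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirguide)
```

## The problem this package addresses

MALDI mass spectrometry imaging (MSI) resolves hundreds of lipid and
metabolite signals per pixel, but acquisition is slow and produces enormous
raw files, especially on FTICR instruments where a single tissue section can
take many hours. FTIR microscopy, by contrast, images the same section
non-destructively in minutes, at finer pixel pitch, and without matrix
deposition — but its vibrational bands do not identify individual molecules.

`ftirguide` combines the two: the FTIR image is segmented into regions of
similar molecular composition, the segment of interest is registered onto
the optical frame used for MS acquisition, and the resulting region of
interest either (a) restricts which MALDI spectra are *interpreted*
(segment-specific m/z signatures) or (b) restricts which pixels are
*acquired* at all, cutting acquisition time and data volume roughly in
proportion to the segment's area fraction.

## The processing model, stage by stage

### FTIR spectral preprocessing

Applied in fixed order by `ftir_preprocess()`; each stage is also exposed
on its own.

1. **AsLS baseline** (`asls_baseline()`). The baseline $z$ minimizes
   $\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2$ with
   $w_i = p$ where $y_i > z_i$ and $1-p$ otherwise, iterated until the
   weights stabilize. Defaults $\lambda = 10^5$, $p = 0.001$, 10
   iterations — the canonical range for absorbance spectra; the asymmetry
   makes the baseline drape under peaks. Because second differences of a
   line vanish, any affine spectrum is reproduced exactly (the test suite
   demands a residual $\infty$-norm below $10^{-8}$).
2. **First derivative** (`first_derivative()`). Savitzky–Golay (window 9,
   polynomial order 2), expressed per cm$^{-1}$ with the sign following the
   descending FTIR axis. A polynomial filter rather than naive differencing:
   it is noise-robust and exact on low-order polynomials, which makes it
   testable against analytic derivatives.
3. **SNV scaling** (`snv()`). Per-spectrum centering and unit sample
   (n−1) variance. Zero-variance (dead) pixels are masked out, not errored,
   so whole-slide runs survive them.
4. **Window selection** (`select_windows()`). Channels inside
   3100–2900 cm$^{-1}$ (C–H stretch) and 1800–950 cm$^{-1}$ (fingerprint),
   inclusive, in the original order.
5. **Edge-preserving denoising** (`epd_denoise()`). Channel-wise 2-D
   Rudin–Osher–Fatemi total-variation denoising via Chambolle's dual
   projection; weight 0.1, at most 100 iterations with an energy-based stop.
   Off-tissue pixels are excluded from the data term by filling them with
   the on-tissue channel mean before denoising and restoring them after, so
   the slide background cannot bleed across the tissue edge.
6. **Background removal** (`remove_background()`). k = 2 k-means++ on the
   preprocessed spectra. Which cluster is "background" is decided by the
   smaller mean total absolute signal of the *baseline-corrected* spectra:
   after SNV every spectrum has unit variance, so amplitude evidence must be
   taken before scaling (raw totals would be dominated by baseline drift).
   If the two clusters' mean signals differ by less than a factor 1.5 the
   cube is kept whole with a warning; an exact tie is broken toward the
   cluster touching the image border.

### Segmentation

`kmeanspp_joint()` pools the on-tissue spectra of all sections and runs one
k-means++ (D² seeding, Lloyd iterations, best of 5 restarts by
within-cluster sum of squares), so a cluster index (IDX) means the same
tissue class in every section. Three deterministic choices remove the usual
k-means arbitrariness:

* clusters are renumbered 1..k by descending pooled member count (ties by
  centroid norm, then original index), so repeated runs are bit-identical;
* an emptied cluster is re-seeded at the point farthest from its centroid;
* sections are pooled in sorted `section_id` order, so the result does not
  depend on the order the cubes are passed in.

`k` is user-supplied (10 for whole-brain surveys, 3 for tumor/margin/rest,
5 for cerebellar layers are typical); automatic model selection is out of
scope and `k` remains the main user-controlled bias.

`spatially_aware_cluster()` is the MSI-side comparator: each pixel's binned
spectrum is replaced by a Gaussian-weighted neighborhood average (radius 3
pixels, $\sigma$ = radius/2 so the kernel has effectively vanished at the
truncation boundary; absent neighbors excluded, weights renormalized)
before the same k-means++. Radius 0 reduces exactly to plain clustering.

### Registration and transfer

`register()` aligns a *moving* FTIR-derived binary tissue shape to the
*fixed* optical/MSI binary by minimizing the mean squared error of the
bilinearly warped moving image over the fixed grid. The transform family is
similarity (translation, rotation, isotropic scale), matching what the
two-modality geometry actually needs. Numerical choices:

* both binaries are smoothed with a 1-pixel Gaussian before the MSE —
  pure binary MSE is piecewise constant in the parameters and gives a
  derivative-free optimizer nothing to follow;
* Nelder–Mead over a 3-level pyramid (×4, ×2, ×1 block-mean), tolerance
  $10^{-4}$ on the normalized MSE, parameters scaled to comparable units
  (fixed-grid pixels, 2°, 2% scale);
* initialization by centroid alignment and the square root of the area
  ratio;
* everything operates in physical micrometers, so a 25 µm FTIR grid against
  a 75 µm MSI grid needs no special casing.

Registration quality is scored by the Dice coefficient of the re-binarized
warp. `transfer_segment()` then pulls every target pixel back through the
inverse transform and assigns it the majority label over a 4×4 supersampled
footprint — majority voting, not nearest neighbor, because target pixels
are typically 2–12× coarser than the source.

### MALDI spectral pipeline

`msi_preprocess()` runs, per pixel: TIC normalization (sum scaled to 1),
top-hat baseline correction (morphological opening with a flat structuring
element, half-width 75 channels — sized for TOF profiles and configurable),
noise estimation by Friedman's supersmoother applied to intensity versus
channel (the smooth curve *is* the noise reference), and peak picking at
local maxima with intensity at least 3× the noise curve; plateau ties
resolve to the leftmost channel. Opening is idempotent and anti-extensive,
so correcting twice changes nothing and corrected intensities stay
non-negative.

`bin_peaks()` pools all pixels' centroids, splits the sorted m/z values at
gaps larger than the tolerance (default 0.1 Da; 2 ppm is the right order
for FTICR data) and bisects any resulting bin still wider than the
tolerance at its largest internal gap. A pixel's feature value is the
maximum of its centroid intensities in the bin, zero if it has none —
absence of a pixel, by contrast, is tracked explicitly and never
zero-filled. Isotope clusters are deliberately *not* collapsed; the ranked
tables may therefore contain isotopologue partners of the same species,
and a de-isotoping step is an explicit non-goal.

### Feature ranking

Two criteria, both rankings rather than hypothesis tests (no multiple
testing correction is applied, and none is implied by a top-10 list):

* `roc_area_criterion()`: $|AUC - 0.5|$, the area between the empirical
  ROC curve of in-segment versus out-segment intensities and the random
  classifier diagonal, computed from the Mann–Whitney statistic with ties
  counted ½. Two-sided, so depleted features rank alongside enriched ones,
  and invariant under monotone intensity transforms.
* `ttest_criterion()`: absolute pooled-variance two-sample t. Degenerate
  inputs rank sensibly: zero pooled variance scores 0 when means agree and
  $\infty$ when they differ.

`rank_features()` returns the top 10 by default, ties broken by ascending
m/z, with the sign of the in-segment mean shift recorded as `up`/`down`.

### Guidance reporting

`make_plan()`/`reduction_report()` model per-pixel acquisition cost as
constant, so time and data reductions both equal
$1 - \text{ROI pixels}/\text{total pixels}$ — reductions are set purely by
segment size. The division is computed as `(total − roi)/total` so the
result is exactly the rational value for counts up to $10^6$.

## What the phantom generator emulates — and what it does not

`generate_phantom()` builds a paired dataset with known truth: a
superellipse tissue outline holding a tumor blob and a margin rim (regions
partition the tissue; parametric shapes keep area and perimeter truths
exact), per-region FTIR band templates (amide I/II, C–H stretch, ester
carbonyl, phosphate bands with region-specific amplitudes) plus per-pixel
affine baseline drift and Gaussian noise, and MALDI profiles with shared
lipid peaks, one marker per region at fold-change 3, two-isotopologue
clusters at +1.0034 Da with an M+1 ratio from a crude carbon count
(≈ 0.011 per carbon, carbons ≈ m/z / 14), a smooth baseline, and Gaussian
noise. The modality frames differ by a known similarity transform
(30 µm, −20 µm, 3°).

The generator's defaults are the package's study conditions and are not
revisited per experiment:

* FTIR noise sd 0.03 — one tenth of the smallest peak-scale separation
  between region templates (0.30 absorbance between tumor and parenchyma at
  2925 cm$^{-1}$), i.e. segmentation is tested at 10:1 band-contrast to
  noise;
* MSI per-pixel, per-peak log-normal variability at CV 0.3 — the
  matrix-crystallization and ionization heterogeneity that TIC
  normalization cannot remove, and the reason direct MSI segmentation
  underperforms FTIR-guided segmentation on matched phantoms;
* `degrade_msi()` adds a smooth multiplicative ion-suppression dip (depth
  0.5) and per-pixel speckle (log-sd 0.2); both scale whole pixel spectra,
  so TIC normalization removes them — exactly as intended, since the
  per-peak CV above is what carries the irreducible MSI noise;
* grids of 48×48 FTIR pixels at 25 µm against 16×16 MSI pixels at 75 µm,
  and registration masks of 256×256 pixels, chosen so every validation
  experiment runs in seconds to a few minutes on one core.

What passing on phantoms does **not** show: real tissue has correlated
(Mie-scattering, atmospheric) FTIR artifacts, mass-dependent ion
suppression, analyte diffusion, and histology whose region boundaries are
nowhere near superellipses. The phantoms validate the machinery —
segmentation consistency, transform recovery, criterion arithmetic,
reduction bookkeeping — not biological performance.

## Numerical choices worth knowing about

* The AsLS normal equations have condition number of order $\lambda/p$
  ($10^8$ at the defaults). The banded LDL$^\top$ solve is followed by two
  steps of iterative refinement with extended-precision residuals, and the
  reweighting loop exits early once the baseline interpolates the spectrum
  to $10^{-10}$ relative — without that exit, weights keep flipping on
  roundoff-level residuals and slowly amplify the error.
* The supersmoother noise reference tracks broad structure; peaks wider
  than the smallest smoother span (5% of the axis) inflate the local noise
  estimate and can suppress their own detection. Profile axes should be
  long relative to peak widths (the phantom uses 5001 channels for
  0.12 Da-wide peaks).
* Contour tracing walks directed pixel-edge segments; at corners where two
  components touch diagonally the walk takes the turn that hugs the current
  pixel, keeping 4-connected components as separate rings. Signed ring
  areas (holes negative) therefore sum exactly to pixel count × pixel
  area.
* `tissue_shape_mask()` decides which intensity cluster is tissue by
  distance from the *border* mean intensity rather than by absolute level,
  which makes the mask invariant to contrast inversion (dark-on-bright and
  bright-on-dark slides give the same shape).
* Empty-both-masks Dice is defined as 1 with a warning (identical
  emptiness); registration of an empty mask is an error.
* imzML I/O shifts the format's 1-based coordinates to the package's
  0-based, row-major, y-down convention at the boundary, writes 64-bit
  little-endian arrays, and round-trips bit-exactly; a pixel missing from
  the file is reported absent, never zero.

## Validation problem sizes

The shipped validation suite uses: 20-seed registration trials on 256×256
masks (perturbations up to 15% extent translation, 15° rotation, ±10%
scale, boundary flips at probability 0.3); joint clustering of 4 phantom
sections; 20-seed planted-marker (10 features, fold 3, CV 0.3 among 50),
peak-picking (19 peaks at SNR 10 on 2000 channels) and modality-robustness
(FTIR vs degraded MSI) experiments; and exhaustive small-sample oracles for
the AUC, Dice and reduction arithmetic. `scripts/acceptance.R` re-runs the
same experiments from scratch for any seed.

## Known limitations

* No de-isotoping: ranked tables can spend slots on isotopologue partners.
* The default transform family is similarity; tissues that deform
  non-rigidly between sections are outside the model.
* `k` must be chosen by the user.
* Atmospheric-vapor and Mie-scattering correction of FTIR spectra are not
  implemented; inputs are assumed instrument-corrected.
* Vendor-proprietary FTIR/MS formats are not read; ENVI-style, CSV and
  imzML 1.1 are the interchange formats.
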