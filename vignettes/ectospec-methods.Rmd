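---
title: "Identifying ectomycorrhizal fungi from ATR-FTIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ectomycorrhizal fungi from ATR-FTIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectospec)
```

## The problem

Ectomycorrhizal (ECM) fungi ensheath tree root tips with a hyphal mantle.
Identifying which fungal species formed a given mycorrhiza normally requires
morphotyping plus ITS sequencing. Attenuated total reflectance FTIR
spectroscopy offers a faster route: the evanescent wave penetrates only the
outer ~2 µm of the sample, i.e. exclusively the outer fungal mantle, so the
mid-infrared absorbance spectrum of a pressed root tip is a biochemical
fingerprint of the fungus (cell-wall chitin and glucans, mannans, lipids,
protein secondary structure). `ectospec` implements the complete analysis
chain used for this kind of chemotaxonomy — second-derivative
preprocessing, Ward clustering, Fourier self-deconvolution (FSD), peak
picking and band comparison — together with a synthetic-spectrum generator
that emulates a five-species field study, so the pipeline is fully testable
without instrument data.

## Spectral representation

All spectra live on a canonical ascending wavenumber grid, 600–4000 cm⁻¹
at 2 cm⁻¹ per point (1701 points). The 2 cm⁻¹ step is the package's
choice: instruments of this class digitize at or below their 4 cm⁻¹
optical resolution, and a 2× oversampling keeps every diagnostic window at
an integer point count. Input spectra on other grids are linearly
interpolated; extrapolation is refused (a spectrum must cover the full
canonical range) so no values are invented outside the measured range.
Windows are inclusive at both endpoints; window bounds off the grid are
snapped outward (lo floored, hi ceiled) so the stated interval is always
contained.

## Preprocessing

Feature vectors for clustering are built as:

1. **Savitzky–Golay second derivative** — 17 smoothing points, polynomial
   order 3, derivative taken with respect to wavenumber (values divided by
   the grid step squared, so they are grid-independent). The second
   derivative removes baseline (any offset and linear ramp vanish exactly;
   the filter is exact on polynomials up to order 3) and sharpens
   overlapping bands; band maxima become derivative minima. Edge points
   are fitted one-sidedly rather than padded, so no data are fabricated at
   600/4000 cm⁻¹. Order 3 is the standard choice for second derivatives
   that preserves band positions; it is exposed in
   `preprocess_config(sg_polyorder=)`.
2. **Window extraction** — the default clustering region is the pair of
   windows 3000–2800 cm⁻¹ (fatty acids) and 1700–600 cm⁻¹, the region on
   which the dendrogram is actually built; the alternative
   `windows = "five_region"` configuration offers the classic five-window
   layout (fatty acids, amide I, amide II+III, polysaccharides,
   fingerprint region). The two named sets differ: the five windows leave
   the gaps 1600–1575 and 1300–1200 cm⁻¹ out, the two-window set keeps
   them. The two-region set is the default because it is the region the
   classification is defined on.
3. **Vector normalization** — the concatenated window vector is
   mean-centered and scaled to unit Euclidean norm. Normalizing the final
   feature vector (rather than each window separately) makes the
   clustering input invariant to per-sample intensity scaling and offsets,
   which is the purpose of the step; per-window normalization would be an
   equally defensible reading and can be emulated by running windows
   separately.

## Clustering and heterogeneity

Dissimilarity is the Euclidean distance between feature vectors. Linkage
is Ward's minimum-variance method in the `ward.D2` convention: merge
heights are reported in distance units, with height² equal to twice the
increase in total within-cluster sum of squares, so two singletons at
distance *d* merge at height *d*. This is the variant consistent with
feeding unsquared Euclidean distances to the algorithm; `ward_d` is
available as a sensitivity check. "Heterogeneity" of a group is
operationalized as the dendrogram height at which the group forms — the
same quantity the instrument software displays. `species_report()` cuts
the tree at *k*, labels each cluster with its majority species (ties
alphabetical, with a warning) and counts misassignments;
`heterogeneity_ratio()` compares subtree root heights. The implementation
is tested for exact agreement (merge heights and all k-partitions, 10⁻⁹)
with an exhaustive oracle that recomputes the Ward objective from scratch
at every step, on random instances with up to eight samples.

## Fourier self-deconvolution

FSD narrows bands to reveal overlapped components. A Lorentzian band of
full width Γ contributes a factor `exp(-π Γ |t|)` to the Fourier transform
of the spectrum along the conjugate variable *t* (cm). `fsd()` implements
the re-convolution form of the method: the interferogram is multiplied by

```
W(t) = exp(π · Γ_assumed · (1 − 1/K) · |t|) · A(t)
```

which removes the assumed intrinsic lineshape (`band_fwhm`, default
12 cm⁻¹) and restores a Lorentzian narrowed by the enhancement factor *K*
(default 2). A matched band therefore comes out with FWHM ≈ `band_fwhm/K`
and unchanged integrated area (the t = 0 weight is 1). `A(t)` is an
apodization that tapers the outer half of the usable interferogram
(`triangle_squared` by default; `bessel`-type; or `boxcar`, i.e. no taper)
to bound noise amplification; the realized worst-case amplification is
attached to the result and the transform refuses configurations whose
weight would exceed 10⁶. Two limits pin the implementation down: with
K → 1 and boxcar apodization the transform is the identity, and
deconvolving a 12 cm⁻¹ Lorentzian at K = 2 yields a ~6 cm⁻¹ band with its
area conserved within 2%. The choice of defaults (12 cm⁻¹, K = 2,
triangle-squared) follows common practice for protein-region work; all
are exposed in `fsd_config()`.

For group comparisons the default is to average spectra first and
deconvolve the mean (`average_before_fsd = TRUE`); deconvolving each
sample and averaging afterwards is available as a switch since the two
orders give slightly different noise behaviour (FSD is linear, so the
noiseless results coincide).

## Peak picking and band comparison

Peaks are picked as local minima of the SG second derivative within a
window — band maxima of the raw spectrum, independent of baseline. Minima
with depth at least `rel_threshold` (default 0.1) times the deepest
minimum are peaks; those between `shoulder_floor` (0.05) and the threshold
are flagged shoulders (a descriptive label, never used for clustering).
Minima closer than `min_separation` (default 6 cm⁻¹) merge, keeping the
deeper (ties to the higher wavenumber). All thresholds are relative, so
peak picking is invariant to intensity scaling. `compare_band_sets()`
matches two peak lists greedily, closest pairs first, within a tolerance
of 4 cm⁻¹ — the instrument resolution, below which two bands are
indistinguishable; unmatched bands are "supplementary" to their group.
`cellulose_screen()` applies the same machinery to the four cellulose
markers (1641, 1427, 1335, 1160 cm⁻¹): at least three matches flag plant
contamination, which in practice indicates the ATR crystal saw root tissue
rather than fungal mantle.

## The synthetic generator

`generate_dataset()` emulates the field study the analysis is designed
for: 181 root-tip spectra of five ECM species (61 *Cenococcum geophilum*,
67 *Lactarius subdulcis*, 23 *Xerocomus pruinatus*, 17 *Amanita
rubescens*, 13 *Russula ochroleuca*) split between mono-specific beech and
mixed deciduous stands plus a 17-sample *C. geophilum* group from a second
geographic region (the Swabian Jura). Each spectrum is a sum of Lorentzian
bands from the packaged per-species template table
(`inst/extdata/band_templates.csv`):

- **Band positions** are literature values: shared cell-wall bands
  (chitin 1373/1154/1003, β-1,3-glucan 1031 with a 1075 shoulder shifted
  to 1090 in *A. rubescens*, lipids 2925/1451, tyrosine 1515), the
  species-specific amide I maxima (Ls 1632, Xp 1630, Ar 1633, Cg 1617, Ro
  1627 + 1618 plus a random-coil 1649), the α-helix doublet 1548/1542 in
  Xp and Ar only, glycogen shoulders at 1153 vs 1161, Russulaceae-only
  lipid bands 2850/1740, and the ascomycete markers 1108 and 831 with the
  990/976 mannan shoulders absent.
- **Widths and relative amplitudes are invented** — the source data report
  positions, not intensities. Broad amide/polysaccharide bands use
  16 cm⁻¹, sharp bands 10 cm⁻¹; amplitudes anchor amide I at 1.0 with
  majors at 0.45–0.8 and minor/shoulder bands at 0.25–0.45. They were
  calibrated once so that the default-noise pipeline separates the five
  species (accuracy ≥ 0.97 with the two-cluster cut isolating the
  ascomycete) and then frozen in the shipped table.
- **Environment modifiers** express the study's key contrast: mixed-stand
  *C. geophilum* gains bands at 2363, 1663, 1453, 1372 and 830 cm⁻¹ that
  beech-stand samples lack entirely (implemented as mixed-context
  additions plus mono-context removal of the overlapping core bands 1451,
  1373, 1370 and 831 — without the removals the "missing" bands would
  still be matched within the 4 cm⁻¹ tolerance); Xp gains 1313 and Ar
  1544/1372 in mixed stands, Ar 1407 in beech stands; Swabian
  *C. geophilum* gains 1621 and 1234. Modifier bands enter at half their
  class amplitude (`modifier_amplitude_scale = 0.5`), encoding the finding
  that environmental effects are weaker than species identity.
  *L. subdulcis* has no modifiers at all — its litter-bound niche shows no
  environment signal. Host tree species affects metadata only, not the
  spectrum.
- **Noise model**: per-band Gaussian center jitter (sd 1.5 cm⁻¹), per-band
  log-normal amplitude variation (CV 0.20, unit mean), a random degree-2
  baseline (coefficient scale 0.01) and i.i.d. Gaussian detector noise
  (sd 0.002 absorbance). The jitter and CV values are plausible choices
  for within-species biochemical variability, not measurements — no field
  spectra are available to fit them.

Randomness is counter-based: each sample draws from a 31-bit substream
keyed on (seed, sample id), so datasets are bit-reproducible and a
sample's spectrum does not depend on the composition row order.

What the generator does **not** emulate: ATR penetration-depth dispersion,
scattering artifacts, atmospheric CO₂/H₂O lines, correlated (pink)
detector noise, within-species covariance between bands, or absolute
absorbance levels. Passing tests on synthetic data therefore demonstrate
that the analysis chain is implemented correctly and recovers structure of
the assumed form; they do not re-establish the empirical discrimination
rate on real mycorrhizas.

## Numerical choices and degenerate inputs

- Peak centers are reported on the grid (no sub-grid interpolation); a
  band centered between two grid points may land on either neighbour, so
  positional assertions use a one-grid-step tolerance.
- A flat spectrum yields an empty peak list; constant vectors cannot be
  vector-normalized (zero norm) and raise an error.
- Ties in peak merging go to the higher wavenumber; majority-label ties in
  cluster reports go to the alphabetically first species, with a warning.
- The FFT path of `fsd()` subtracts the endpoint ramp and zero-pads to the
  next power of two ≥ 2n to suppress wrap-around.
- Duplicate sample ids, non-numeric cells, non-monotone wavenumber
  columns, and JCAMP-DX dialects beyond uncompressed `(X++(Y..Y))` /
  `XYPOINTS` are rejected with explicit errors; transmittance input is
  converted only on request (`convert = TRUE`, −log₁₀ with T clipped at
  10⁻⁶).

## Problem sizes used in the test-suite

Dataset-level tests run the full 181-sample composition where the claim
concerns the study conditions (discrimination rate, phylum split,
environment contrasts, noiseless separability) and a reduced composition
(~2–4 samples per group) for plumbing checks. The Ward oracle comparison
uses 100 random instances of up to 8 samples; accuracy-vs-noise
monotonicity uses 3 seeds per noise level. A full pipeline run takes
around a second.

## Known limitations

- "Heterogeneity" in distance units follows the ward.D2 convention; other
  software may display the Ward objective itself. Topology and every
  reported comparison are unaffected, absolute heights differ.
- The real-data magnitudes of site effects (the Russulaceae similarity
  factor, the Swabian sub-cluster heterogeneity ratio) are properties of
  the undeposited field spectra; the synthetic data reproduce only their
  direction (a Swabian subgroup tighter than its species cluster).
- The JCAMP-DX reader covers the uncompressed AFFN subset only.
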