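---
title: "Vascular and metabolic mapping from multi-parametric intravital microscopy"
author: "mpfm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular and metabolic mapping from multi-parametric intravital microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfm)
```

# Scope

`mpfm` analyzes paired acquisitions from a multi-parametric intravital
microscope: a multispectral dark-field diffuse-reflectance stack of the
same tissue site (540/560/580/610 nm, calibrated against a 20%
reflectance standard) and two timestamped fluorescence uptake series —
2-NBDG, a fluorescent deoxyglucose analog reporting glucose uptake, and
TMRE, a cationic dye reporting mitochondrial membrane potential. From
these it derives per-pixel vascular maps (hemoglobin oxygen saturation
StO2 and total/oxy/deoxy-hemoglobin indicators), vessel-excluded
metabolic endpoint maps (2-NBDG60, TMRE80), spatial-heterogeneity
statistics, and regional group/correlation statistics.

Because such animal image sets are rarely shareable, the package ships
a forward-model generator that emulates both the tissue-mimicking
phantom experiments used for instrument characterization and
tongue-like vascular scenes with full per-pixel ground truth. Every
analysis stage is therefore testable end to end, from rendered counts
to cohort statistics.

# The vascular model

Per pixel and wavelength, tissue absorbance is modeled with a modified
Beer-Lambert relation:

$$A(\lambda) \;=\; \log_{10}\!\frac{I_{cal}(\lambda)}{I_{tissue}(\lambda)}
\;=\; b_0 + b_1\,\mu_{eff}(\lambda) + \varepsilon_{HbO_2}(\lambda)\,C_{HbO_2}
 + \varepsilon_{Hb}(\lambda)\,C_{Hb},$$

where $I_{cal}$ is the reflectance-standard intensity, $b_0$ absorbs
source-intensity variability, $\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$
is the effective attenuation coefficient of the background tissue
(diffusion approximation) with scale factor $b_1$, and the $C_i$ are
concentration-pathlength products of oxy- and deoxy-hemoglobin. The
four-wavelength absorbance vector is fitted per pixel by non-negative
least squares over all four coefficients; fits are accepted when the
coefficient of determination about the absorbance mean reaches 0.9.
Then $THb = C_{HbO_2} + C_{Hb}$ and $StO_2 = C_{HbO_2}/THb$, restricted
to vessel pixels.

Assumptions worth keeping in mind:

* **Superficial-layer optics.** The background $\mu_{eff}$ stands for a
  thin, normal-tissue-like superficial layer. `defaultTongueBackground()`
  ships representative placeholder values for soft tissue at
  540–610 nm, *not* measured tongue properties; substitute measured
  $\mu_a,\mu_s'$ when available.
* **Indicator units.** The unknown optical path length folds into the
  $C_i$, so THb/Hb/HbO2 are relative indicators (M·cm), not absolute
  concentrations. StO2, a ratio, is dimensionless and needs no
  normalization.
* **Log base.** The model is written base-10, matching the convention
  of molar extinction coefficients. `computeAbsorbance(logBase=)`
  supports other bases; the extinction/attenuation columns must then be
  rescaled by `log(10)` accordingly.
* **Non-negativity of all four coefficients.** The constraint set
  includes $b_0$ and $b_1$, taking the fitting description literally.
  With four unknowns and four wavelengths the unconstrained fit is
  exact, so $R^2 < 1$ — and hence rejection — occurs exactly when
  non-negativity binds or the absorbance vector is degenerate. A flat
  absorbance vector (zero total sum of squares) is rejected with an
  undefined $R^2$.

## The NNLS solver

With four coefficients the non-negative least-squares optimum is found
*exactly* by enumerating all $2^4$ support sets: the optimum restricted
to its support is that support's unconstrained least-squares solution,
so the global optimum is the minimum-residual feasible candidate among
the 16 faces. The enumeration is batched across pixels (one QR per
support set, dense matrix products across the whole image), which makes
pixelwise unmixing of a full frame a few milliseconds. The test suite
checks this solver against an independent KKT-enumeration oracle and
against `pracma::lsqnonneg` on thousands of random systems.

# Metabolic endpoints

Fluorescence frames are baseline-subtracted (the pre-injection frame at
$t=0$); negative differences are clipped at zero by default since
sub-baseline fluorescence carries no uptake information (`clip = FALSE`
keeps signed values). Vessel regions distort fluorescence through
hemoglobin absorption, so quantification is restricted to the
non-vessel *analysis mask*: the union of the reflectance-derived vessel
mask (major vessels, translated by the inverse of the estimated
displacement between the two acquisitions) and the fluorescence-derived
mask (small vessels), dilated by 1 px to absorb edge bleed, then
complemented. Co-registration is an exhaustive integer-shift search
(±10 px) maximizing normalized cross-correlation over the overlap, with
ties broken by the smaller displacement and then row-major order — the
two acquisitions are about an hour apart, so only rigid translation is
corrected.

Uptake kinetics are the masked per-timepoint means; the endpoints are
the frames nearest 60 min (2-NBDG) and 80 min (TMRE) post-injection
(ties to the earlier frame, 5-min tolerance). With the 20-min staggered
injection the two endpoints describe the same wall-clock instant.

# Heterogeneity and regional statistics

The local-range map assigns each pixel the difference between its 3×3
neighborhood maximum (center included, replicate-padded borders) and
its own value — non-negative, zero where the pixel dominates its
neighborhood, and insensitive to global intensity offsets. The window
is configurable but 3×3 is the most sensitive choice. A
`"max-minus-min"` switch provides classical range-filter semantics,
since the literature uses both conventions. Binarizing each endpoint
against its animal-wide mean (strictly greater = high, ties low) and
crossing the two probes yields the four metabolic clusters
(1 = low/low, 2 = low NBDG/high TMRE, 3 = high NBDG/low TMRE,
4 = high/high).

Vascular and metabolic maps are not pixel-matched (vessel vs non-vessel
supports), so cross-parameter statistics use a regional average: each
map is split into nine equal nonants (bands of `floor(n/3)` pixels,
remainder to the last band; 0-based half-open ranges, row-major order),
and each animal contributes nine nonant means per parameter. Group
comparisons use the two-sample Student's t-test on nonant means pooled
across animals (equal variances pooled; Welch behind a flag), and the
six vascular-metabolic parameter pairs are correlated per group with
Pearson's r (t-distribution p on $n-2$ df, pairwise deletion of
incomplete nonants). THb and the metabolic intensities are first
normalized to their global maximum across both groups — an affine
rescaling that leaves r unchanged but puts the scatter on a common
axis. Pixel-level distributions are summarized with a Gaussian KDE
(Silverman bandwidth, 256-point grid over data range ±3 bandwidths)
together with the sample mean. No multiplicity correction is applied,
matching the analysis convention this package follows.

# The synthetic generator

`simulateTongueScene()` draws branching vessel ribbons by seeded random
walks (widths ~2–12 px, i.e. a few to ~25 µm at the default 1.04 µm/px
pitch; coverage kept within 2–20% of the field) and lays smooth
ground-truth fields over them. The tumor-like parameter set encodes the
direction of the in-vivo contrasts: lower StO2 (0.45 vs 0.75), lower
THb indicator (1.3 vs 2.4 µM·cm-scale products), higher metabolic
amplitudes, and a high-frequency component in the metabolic fields that
makes them spatially rougher. Uptake kinetics are a
difference-of-exponentials for 2-NBDG (τ_rise = 1 min,
τ_decay = 80 min: peak at 4.4 min, inside the observed 2–6 min window,
with roughly half the peak remaining at 60 min) and a saturating
mono-exponential for TMRE (τ = 20 min, 95% of plateau by 60 min).
Noise is multiplicative Gaussian with configurable CV (default 1%
reflectance, 2% for dilution series); every generator is bit-exactly
reproducible from its seed.

`simulatePhantomSeries()` emulates the instrument-characterization
phantoms: three reduced-scattering levels (5/10/15 cm⁻¹) with five
hemoglobin steps spanning average absorption 1.0–5.5 cm⁻¹ at StO2 0.95
(freshly oxygenated hemoglobin), rendered as homogeneous stacks through
the same forward model. The hemoglobin concentration at each step is
chosen so its band-averaged extinction reproduces the requested
absorption coefficient, with a 0.1 cm effective path folding into the
indicator units. `simulateDilutionSeries()` models fluorescence probe
linearity as `gain · concentration` with multiplicative noise.

What the generator deliberately does **not** emulate — and what passing
tests therefore cannot certify about real data: photon transport (the
forward model is exactly the inverted fitting model, so inversion
accuracy on synthetic scenes is an upper bound), camera physics beyond
a linear scale, fluorescence distortion by absorption/scattering,
tissue curvature, depth structure, or segmentation error (vessel masks
are ground truth, not hand-traced; registration shifts are zero by
construction). The synthetic-cohort "direction" checks establish that
the pipeline propagates group contrasts of realistic magnitude with the
correct signs — not that the in-vivo effect sizes are reproduced.

# Numerical and design choices

* **Float image container.** Parameter maps and stacks are stored as
  NIfTI (float64) with YAML sidecars because this round-trips
  arbitrary floats (including NaN missing values) bit-exactly with the
  R imaging stack; TIFF and PNG are accepted for masks and unit-range
  images. Missing is always NaN/NA, never zero.
* **Tie-breaks**, all deterministic: registration prefers the smaller
  then row-major-earlier shift; endpoint selection prefers the earlier
  frame; binarization sends ties to "low".
* **Degenerate inputs** raise informative errors rather than silent
  values: all-invalid stacks, empty masks or analysis regions,
  all-equal KDE input, sub-3×3 partitions, zero-variance correlation
  input. Pixels with non-positive intensity are flagged invalid and
  propagate as missing through every downstream map.
* **Acceptance-threshold semantics**: gating is per pixel; the
  accepted fraction is reported per stack.
* **Problem sizes.** Examples and tests run scenes at 64–128 px and
  phantom frames at 24–32 px; these sizes were chosen so the full
  suite exercises every stage (including two complete cohort runs) in
  well under a minute while leaving per-pixel statistics stable. The
  generator defaults to 256 px scenes; a full 2.5 mm² field at
  instrument sampling (~1536²) is representable via `pixelPitch`.
* **Seeds.** Every stochastic generator takes an explicit seed and
  derives independent substreams (per phantom step, per probe, per
  animal), so cohorts, series and stacks are reproducible individually
  and jointly.

# Worked example

```{r example, eval = FALSE}
scene <- simulateTongueScene(128, 128, seed = 1)
stack <- renderReflectance(scene, defaultTongueBackground(),
                           builtinExtinctionTable(), noiseCv = 0.01)
design <- buildDesignMatrix(wavelengths(stack), defaultTongueBackground(),
                            builtinExtinctionTable())
chrom <- unmixStack(computeAbsorbance(stack), design, verbose = TRUE)
vasc <- makeVascularMaps(chrom, vesselMask(scene))
vasc

series <- simulateFluorSeries(scene, "NBDG", noiseCv = 0.01)
amask <- buildAnalysisMask(vesselMask(scene), vesselMask(scene))
curve <- uptakeKinetics(series, amask)
endpoint <- endpointMap(series, amask)

## full cohort, on disk
manifest <- simulateCohort(tempfile("cohort"), nNormal = 5, nTumor = 5,
                           size = 128, seed = 1)
results <- runPipeline(manifest, tempfile("results"))
results$statistics$groupComparisons$StO2
```

# Known limitations

* The modified Beer-Lambert inversion inherits the superficial-layer
  assumption; accuracy degrades when tumor optical properties deviate
  strongly from the background values supplied.
* Only rigid integer translation is corrected between acquisitions; no
  subpixel or nonrigid registration.
* Fluorescence intensities are not corrected for absorption/scattering
  distortion; vessel exclusion mitigates but does not remove this.
* Vessel segmentation is out of scope: masks are inputs (manual or
  synthetic truth).
* With four wavelengths and four coefficients the fit has zero
  residual degrees of freedom; the acceptance gate is a constraint
  diagnostic, not a goodness-of-fit test in the classical sense.
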