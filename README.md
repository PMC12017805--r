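# mpfm — multi-parametric intravital microscopy analysis

`mpfm` is an R package for analyzing paired vascular and metabolic
acquisitions from multi-parametric intravital microscopy of small-animal
tumor models: multispectral dark-field diffuse-reflectance stacks of a
tissue site together with 2-NBDG (glucose uptake) and TMRE
(mitochondrial membrane potential) fluorescence time series of the same
site. It is aimed at labs doing optical tumor-microenvironment imaging
who need the full chain from calibrated counts to cohort statistics in
one tested, scriptable pipeline.

## The model

Per pixel and wavelength, tissue absorbance follows a modified
Beer-Lambert relation

```
A(λ) = log10( I_cal(λ) / I_tissue(λ) )
     = b0 + b1·μeff(λ) + ε_HbO2(λ)·C_HbO2 + ε_Hb(λ)·C_Hb
```

with `μeff = sqrt(3·μa·(μa+μs'))` the effective attenuation of the
background tissue. The four-wavelength absorbance vector
(540/560/580/610 nm, calibrated against a 20% reflectance standard) is
fitted per pixel by **non-negative least squares** over all four
coefficients — solved exactly by batched support-set enumeration — and
gated at a per-pixel R² of 0.9. Vessel-restricted maps follow as
`THb = C_HbO2 + C_Hb` (a relative indicator; the unknown path length
folds into the units) and `StO2 = C_HbO2 / THb`.

Metabolic endpoints (2-NBDG60, TMRE80) are baseline-subtracted frames
at 60/80 min post-injection, restricted to non-vessel tissue via the
union of reflectance- and fluorescence-derived vessel masks after
integer pixel-shift co-registration. Spatial heterogeneity is
quantified with 3×3 local-range maps and a four-group
2-NBDG×TMRE clustering; regional statistics split each map into nine
equal nonants and use Student's t-tests and Pearson correlations on
nonant means.

A forward-model generator (`simulateTongueScene`,
`simulatePhantomSeries`, `simulateFluorSeries`,
`simulateDilutionSeries`, `simulateCohort`) emulates the hemoglobin /
fluorophore phantom experiments and tongue-like scenes with known
per-pixel truth, so every stage is testable without animal data.

## Worked example

```r
library(mpfm)

scene <- simulateTongueScene(128, 128, seed = 1)   # known ground truth
stack <- renderReflectance(scene, defaultTongueBackground(),
                           builtinExtinctionTable(), noiseCv = 0.01,
                           seed = 1)
design <- buildDesignMatrix(wavelengths(stack), defaultTongueBackground(),
                            builtinExtinctionTable())
chrom <- unmixStack(computeAbsorbance(stack), design, verbose = TRUE)
#> unmixed 16384 pixels: 60.1% accepted (R2 >= 0.90)
vasc <- makeVascularMaps(chrom, vesselMask(scene))
vasc
#> VascularMaps: 128 x 128 px; 1869 vessel pixels with defined StO2
#>   mean StO2 0.779; mean THb 2.29e-06 (indicator units)
median(abs(stO2Map(vasc) - scene@stO2True), na.rm = TRUE)
#> [1] 0.0736
```

The rejected pixels are almost exclusively non-vessel background, where
the flat spectra make the non-negativity constraints bind under noise;
vessel pixels fit cleanly, and the recovered mean StO2 (0.78) and THb
indicator track the generator's normal-tissue truth (StO2 ≈ 0.75).

```r
series <- simulateFluorSeries(scene, "NBDG", noiseCv = 0.01, seed = 1)
curve <- uptakeKinetics(series, !vesselMask(scene))
curve$time[which.max(curve$meanIntensity)]
#> [1] 4                      # uptake peak, min post-injection
endpoint <- endpointMap(series, !vesselMask(scene))
mean(endpoint@image, na.rm = TRUE)
#> [1] 31.3                   # mean 2-NBDG60 over 14515 tissue pixels
```

For a whole cohort on disk (`simulateCohort()` then `runPipeline()`),
the results directory contains per-animal parameter maps, kinetic
curves, cluster counts, a tidy `nonant_summary.csv`,
`statistics.json` (group comparisons and the six vascular-metabolic
correlations) and `provenance.json`. A thin CLI wrapper lives at
`inst/cli/mpfm.R` (`simulate`, `run`, `demo` subcommands).

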