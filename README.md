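# oxyhsi

Hyperspectral blood-oxygen mapping with reflective and transmissive
detection: a Monte Carlo photon-transport simulator for layered tissue, and
the complete modified Beer–Lambert / non-negative least-squares pipeline
that converts 23-band hyperspectral image stacks into per-pixel oxygen
saturation (SO2) maps, hypoxia dynamics and tumor annulus profiles.

## Who this is for

Biomedical-optics researchers comparing detection geometries for
wide-field oximetry, and anyone processing narrow-band visible
hyperspectral stacks (500–720 nm, 10 nm steps) into SO2 maps. Reflective
detection loses vascular spectral contrast within a fraction of a
millimetre of scattering tissue; transmissive detection, applicable to
thin samples (ears, dorsal skinfolds, phantoms), preserves it to
millimetre depths. The package quantifies that trade-off in simulation and
implements the imaging pipeline used on real stacks.

## The model

Blood absorption follows the hemoglobin mixture,

    mu_a(lambda) = ln(10) * B * [eps_oxy(lambda) * S + eps_deoxy(lambda) * (1 - S)]

and the vascular absorbance seen through a background-referenced ratio
obeys the modified Beer–Lambert law

    A(lambda) = B * [eps_oxy * S + eps_deoxy * (1 - S)] * L + xi.

On the 23-band grid this is a linear model `A ≈ X c` with design matrix
`X = [1, eps_oxy, eps_deoxy]` and `c = (xi, B*S*L, B*(1-S)*L)`, solved by
non-negative least squares; the saturation is `S = c2 / (c2 + c3)`,
accepted when the Pearson correlation between measured and fitted spectra
is at least 0.9. The Monte Carlo engine is standard layered-slab
photon-packet transport (implicit capture, Henyey–Greenstein phase
function, Fresnel boundaries, Russian roulette) with reflective and
transmissive tallies from the same run. See the methods vignette
(`vignettes/hyperspectral-oximetry.Rmd`) for assumptions, parameter
defaults and design decisions.

## Worked example

Noise-free round trip through the forward model and the solver:

```r
library(oxyhsi)
A <- theoretical_absorbance(blood_spec(0.98), path_length = 0.05,
                            offset = 0.1)
unmix(A)
#> <unmix_result> SO2 = 98.00% (r = 1.0000, 23 bands)
```

The fitted coefficients are `(xi, B*S*L, B*(1-S)*L) = (1.000e-01,
1.140e-04, 2.326e-06)`: the offset 0.1 is recovered exactly and
`c2/(c2+c3) = 0.98`, the preset saturation.

Simulated comparison of the two detection geometries for a vascular layer
0.5 mm deep in skin (arterial preset 98%, 2e4 photons per band):

```r
det <- paired_detection(skin_model(vessel_depth = 0.05, so2 = 0.98),
                        photons = 2e4, seed = 1)
for (md in c("reflective", "transmissive")) {
  d <- det[det$mode == md, ]
  print(unmix(vessel_absorbance(d$sample_fraction, d$background_fraction)))
}
#> <unmix_result> SO2 = 43.42% (r = 0.9290, 23 bands)
#> <unmix_result> SO2 = 84.86% (r = 0.9966, 23 bands)
```

Half a millimetre of dermis is already enough to corrupt the reflective
estimate (43% recovered for a 98% vessel, correlation near the acceptance
gate), while the transmissive spectrum stays clean. Multiple scattering
compresses both estimates relative to the preset; the simulation studies
therefore compare trends (sensitivity slopes, acceptance depth, error
ratios) rather than absolute saturations — see
`run_depth_study()` / `sensitivity_analysis()`.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "oxyhsi.R", package = "oxyhsi")` with subcommands
`simulate`, `map`, `study`, `make-phantom`, `dynamics`, `annuli`.

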