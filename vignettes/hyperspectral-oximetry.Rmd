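---
title: "Hyperspectral oximetry: models, parameters and design choices"
author: "oxyhsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral oximetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oxygen saturation (SO2) — the fraction of hemoglobin carrying oxygen — can
be mapped optically because oxy- and deoxyhemoglobin have distinct
absorption spectra in the visible band. A hyperspectral imager records a
stack of narrow-band images; per pixel, the spectral shape of the vascular
absorbance encodes the local SO2. The catch is geometry: with reflective
detection the light that returns to the camera is dominated by superficial
scattering, so vessels more than a fraction of a millimetre deep lose
spectral contrast. Transmissive detection, where the light crosses the
whole (thin) sample, preserves vascular contrast to millimetre depths.
This package implements both the photon-transport simulator used to
quantify that trade-off and the complete image-processing pipeline that
turns 23-band stacks into SO2 maps and dynamics.

## Forward model

The blood absorption coefficient at band center $\lambda$ is

$$\mu_{a}(\lambda) = \ln(10)\, B\,[\varepsilon_{oxy}(\lambda)\,S +
\varepsilon_{deoxy}(\lambda)\,(1-S)]$$

with $B$ the hemoglobin concentration (mol/L), $S$ the saturation and
$\varepsilon$ the decadic molar extinction coefficients. All absorbances in
the package are base-10 (the spectroscopic convention); the $\ln(10)$
factor converts decadic extinction to the natural-log transport coefficient
used by the Monte Carlo engine. The modified Beer–Lambert law writes the
vascular absorbance as

$$A(\lambda) = B\,[\varepsilon_{oxy} S + \varepsilon_{deoxy}(1-S)]\,L + \xi,$$

where $L$ is an effective optical path and the wavelength-flat offset $\xi$
absorbs every non-hemoglobin loss. On a grid of $n$ bands this is a linear
model $A \approx X c$ with $X = [\,1, \varepsilon_{oxy},
\varepsilon_{deoxy}\,]$ and $c = (\xi,\; B S L,\; B(1-S)L)$, solved by
non-negative least squares; then $S = c_2/(c_2+c_3)$. A fit is accepted
when the Pearson correlation between measured and fitted spectra is at
least 0.9 and the hemoglobin coefficients are not degenerate; rejections
carry a reason code (`bad_bands`, `no_hemoglobin`, `low_r`).

Key modelling choices:

* **All three coefficients are constrained non-negative**, including
  $\xi$ — the offset represents a physical loss. Constraining it avoids the
  indeterminacy of trading a negative offset against inflated hemoglobin
  terms.
* **The Pearson gate compares the measured spectrum against the fitted
  one** over the usable bands. Bands flagged non-detectable (nothing
  reached the detector, or the signal sits at the noise floor) are excluded
  from both the fit and the correlation; a pixel with fewer than 10 usable
  bands is rejected outright. Ten bands is a pragmatic floor: it leaves at
  least a 3:1 ratio of observations to parameters.
* **Saturation is reported as $c_2/(c_2+c_3)$ and clipped to [0, 1]**
  (non-negativity already guarantees the range; the clip guards rounding).

## The wavelength grid and the extinction table

The default grid is 500–720 nm in 10 nm steps — 23 bands, matching a
liquid-crystal tunable filter layout; each 7 nm-wide band is treated as a
delta function at its center because the forward model is monochromatic.
The extinction table shipped with the package
(`inst/extdata/hemoglobin_extinction_synthetic.csv`) is a synthetic
log-spline reconstruction through canonical landmark values of the
hemoglobin spectra — the oxyhemoglobin Q-band doublet (peaks near 542 and
577 nm, valley near 560 nm), the deoxyhemoglobin 555 nm peak, the
classical isosbestic neighbourhoods, the ~10:1 deoxy-to-oxy ratio at
650 nm and the near-infrared crossover — at 1 nm resolution over
450–1000 nm. It is *not* a published compilation; absolute extinction
magnitudes are approximate at the 5–10% level. This matters less than it
might appear: the same table generates the design matrix and (in
simulations and phantoms) the forward spectra, so saturation estimates are
self-consistent, and on real data a systematic extinction error perturbs
the effective path length far more than the recovered saturation ratio.

Default hemoglobin concentration: whole blood carries about 150 g/L of
hemoglobin at 64,500 g/mol, i.e. $B \approx 2.326\times10^{-3}$ mol/L.

## Monte Carlo transport

`mc_simulate()` implements standard photon-packet transport in a layered
slab: exponential free paths with $\mu_t = \mu_a + \mu_s$, implicit
capture (weight deduction by $\mu_a/\mu_t$ per interaction),
Henyey–Greenstein scattering, Fresnel reflection/refraction at every
index-mismatched boundary, and Russian roulette termination (threshold
$10^{-4}$, survival probability 0.1 — the conventional setting). The flat
illumination beam (default 4 cm diameter) is launched at normal incidence;
specular reflection at the top surface is computed analytically and kept
out of the diffuse tallies.

Numerical choices worth recording:

* **Exact weight bookkeeping.** Russian roulette conserves weight only in
  expectation; the engine debits/credits the roulette transfer against the
  absorbed tally so that specular + reflected + transmitted + absorbed
  equals 1 to floating-point rounding on *every* run, which makes weight
  conservation a sharp invariant rather than a statistical one.
* **Detection aperture.** Tallies record photons exiting the top
  (reflective) or bottom (transmissive) surface within a co-axial
  detection radius, by default the beam radius. Weight exiting beyond the
  aperture is reported separately (`lost_fraction`), so the conservation
  identity always closes; with the default wide beam the lost weight is
  of order $10^{-3}$. A radial tally (100 bins of 0.05 cm) is available
  as a diagnostic.
* **Reproducible streams.** The engine uses a counter-based 64-bit
  generator (splitmix-seeded xoshiro256++); every (band, model) pair runs
  on a stream derived from the master seed, a model tag and the band
  index, so sweeps are bitwise reproducible and embarrassingly parallel
  in principle.
* **Coordinates.** z increases downward from the illuminated surface;
  vessel depth is measured to the *top* of the vascular layer.

The default layered skin model (`skin_model()`) uses literature-typical
optics — epidermis 0.01 cm ($\mu_a$ 1.0, $\mu_s$ 150 cm$^{-1}$, g 0.8),
dermis ($\mu_a$ 0.3, $\mu_s$ 120, g 0.9), refractive index 1.4, total
thickness 0.3 cm — with a 0.05 cm vascular layer whose absorption follows
the blood forward model. Only that layer's $\mu_a$ varies with wavelength;
everything else is wavelength-independent, which isolates the hemoglobin
signature. The vascular layer is modelled as a blood-rich plexus with a
blood volume fraction of 0.2 (effective $B$ = 0.2 × whole blood): a layer
of pure whole blood 0.5 mm thick would be optically opaque (about 6 OD)
across 500–600 nm, which is neither realistic for a tissue layer nor
measurable by any detector with finite dynamic range; at fraction 0.2 the
vessel absorbance peaks near 1 OD, comparable to what the detection chain
can actually see. The matched background model replaces the blood
absorption with the host dermis value, leaving geometry, scattering and
indices untouched, so the sample/background ratio cancels source and bulk
terms exactly as the absorbance definition requires.

## Imaging pipeline

For camera data the background-referenced ratio per pixel and band is

$$\frac{R}{R_{bg}} = \frac{(I - I_{dark})/(I_{ref} - I_{dark})}
{(I_{bg} - I_{dark})/(I_{ref} - I_{dark})},$$

and $A_{vessel} = -\log_{10}(R/R_{bg})$. The background spectrum is the
per-band *median* of the corrected intensity over a user-designated
avascular region (median for robustness against stray vessels — how the
background is obtained from a real image is an operator decision, and a
region of the same image is the default). Bands whose ratio falls below a
detectability floor (`min_ratio`, default 0.02, about 1.7 OD of usable
dynamic range for a 1000-count camera with a couple of counts of read
noise) are flagged non-detectable for that pixel: a band at the noise
floor carries no spectral information, only the noise-limited ceiling, and
feeding it to the fit biases the saturation. Pixels are processed
independently, so the map is order-invariant and failures surface as
per-pixel reason codes.

Dynamics: $\Delta SO_2(t) = (S_i - S_{BL})/S_{BL}$ with the baseline the
mean over the pre-stimulus window. The *peak response* is the maximal
relative decrease after stimulus onset; the *recovery time* is the time
from onset until the series first returns to baseline, linearly
interpolated between frames and required to hold for 2 consecutive samples
(an unstated-in-the-field guard against noise-triggered early recovery).
Per-vessel time series are reduced by the median of accepted pixels in the
vessel ROI. Tumor quantification averages accepted SO2 in concentric
0.5 mm annuli out to 4.5 mm; rings with outer radius within 3 mm form the
tumor region, the rest the adjacent region. Ring membership is by
pixel-center distance with 0-based row/column pixel coordinates.

## Synthetic data: what it emulates, what it does not

`generate_stack()` builds phantom stacks that emulate an intralipid slab
(2 mm; reduced scattering 10 cm$^{-1}$ at 550 nm with $1/\lambda$ scaling,
$\mu_a$ 0.02 cm$^{-1}$, g 0.7, n 1.33 — literature-typical for a 1%
dilution) with a blood-filled capillary (0.5 mm inner diameter) inserted
diagonally so depth ramps linearly across the image (default 0–1.5 mm:
deeper ramps require a thicker medium, since the capillary must remain
inside the slab). Two fidelity levels exist: a fast analytic forward
(1-D effective-attenuation background, Beer–Lambert vessel chords;
milliseconds, used in unit tests) and an `"mc"` level that takes the
per-band background from a cached Monte Carlo sweep of the slab.

Two features make the phantom lose vessels the way real data do. First,
the scattering overburden blurs the image: each column is convolved with a
Gaussian of width 1.0 mm per mm of vessel depth in reflective mode (light
crosses the turbid layer twice) versus 0.05 in transmissive mode
(transmitted quasi-ballistic light keeps near-single-vessel resolution).
Second, the detector adds read noise (2 counts on a 1000-count scale)
under multiplicative shot-like noise (σ = 0.01). Together these produce
the characteristic behaviour: reflective acceptance collapses beyond
about 1 mm while transmissive acceptance persists past 1.5 mm, and
blur-corrupted saturated bands are removed per pixel by the detectability
floor rather than biasing the fit.

What the phantom does *not* emulate: speckle, motion artefacts, vessel
curvature (the cylinder is straight), chromatic aberration, and the full
radiative transfer of the vessel-medium interaction (the vessel acts as a
pure absorber along local chords). Passing the closed-loop tests therefore
demonstrates the correctness of the pipeline's algebra and its noise
robustness, not performance on in vivo data.

## Study drivers and problem sizes

`run_depth_study()` executes the simulation protocol per (depth, preset)
cell: paired sample/background sweeps, vascular absorbance, NNLS unmixing.
One background sweep per depth is shared across presets — the background
optics do not depend on the preset — while each sample sweep runs on its
own random stream. `sensitivity_analysis()` reduces a preset-ramp study to
per-(depth, mode) sensitivity slopes (recovered-vs-preset) and mean
absolute errors of the recovered *relative* SO2 change against the truth,
plus the per-depth reflective/transmissive error fold-ratio.

Problem sizes were chosen to keep a full study desk-scale: $10^5$ photons
per band for study-grade runs (a few hundred milliseconds per band), 2 ×
$10^4$ or less in unit tests. At $10^5$ photons the per-band absorbance
noise is well below the spectral structure being fitted, and a complete
depth study (9 depths × 23 bands × sample/background) runs in a few
minutes on one core. Recovered saturations in the Monte Carlo loop are
compressed relative to the preset (multiple scattering makes the effective
path wavelength-dependent, which the single-$L$ Beer–Lambert inversion
absorbs as bias); trends across depth and mode, not absolute saturation
accuracy, are therefore the quantities the studies report — sensitivity
slopes, acceptance depth, and error fold-ratios.

## Known limitations

* The planar vascular layer is an idealization; the cylindrical capillary
  appears only in the imaging phantom.
* Extinction magnitudes are approximate (synthetic table); absolute
  absorbance values are not comparable across extinction compilations.
* No polarization, fluorescence, or time-resolved transport.
* Motion-artefact removal and vessel segmentation are out of scope; ROIs
  are supplied by the user.
* `pracma::lsqnonneg` can fail to converge on degenerate spectra; the
  solver then falls back to exact active-set enumeration (8 candidate
  supports), which is always well-defined for the 3-column design.
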