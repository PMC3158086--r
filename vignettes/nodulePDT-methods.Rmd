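---
title: "Methods: synthetic nodule cultures and the high-content viability pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic nodule cultures and the high-content viability pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nodulePDT` analyses high-content fluorescence images of adherent 3D
ovarian-cancer nodule cultures treated with photodynamic therapy (PDT)
or chemotherapy: well-level live/dead viability, per-nodule
segmentation and morphometry, power-law size–response fits, penetration
depth of photosensitizer uptake, ratiometric pH imaging, apoptosis
co-localization, and spectral fluence-rate correction between treatment
wavelengths. Because no microscopy data are deposited with the source
study, the package also ships a seeded synthetic renderer of nodule
fields whose defaults state the conditions the study reports; the test
suite and the acceptance script close the loop by requiring the
pipeline to recover those stated outcomes from rendered images.

# The analysis pipeline

## Well viability

Each well contributes a live and a dead channel. The background of each
channel is the modal intensity of a 256-bin histogram over the
channel's observed range (bin centre of the maximal bin, earliest on
ties); images are dominated by background pixels, so the mode tracks
the camera offset. After subtraction, negative values are clipped to
zero — intensities are physical. Viability is
`sum(live) / (sum(live) + sum(dead))`, and all viabilities are
normalized to the mean of the no-treatment (NT) control wells, whose
normalized mean is therefore exactly 1.

Two invariances follow and are enforced by tests: a common positive
gain on both channels cancels exactly, and a common additive offset is
removed by the background subtraction up to the mode-estimation
granularity (the histogram bin width).

Group comparisons use the classical pooled-variance Student's t-test
(two-sided, `n_a + n_b - 2` degrees of freedom); a Welch variant is
available behind a flag but is not the default because the source
analysis specifies Student's test. No multiple-testing correction is
applied, matching the source analysis.

The half-kill light dose (LD50) is read off by linear interpolation of
the per-dose mean normalized viabilities — the lowest 0.5 crossing if
there are several — rather than by fitting a four-parameter logistic:
the quantity reported by the study is a crossing dose, not fit
parameters.

An irradiance series at fixed fluence is summarized by the irradiance
of minimal mean viability and by the plateau onset: the smallest
irradiance whose mean lies within a tolerance (default 0.02, i.e. two
percentage points) of the highest-irradiance mean.

## Nodule morphometry

The two background-subtracted channels are summed into one intensity
image, thresholded with Otsu's method (exhaustive within-class variance
minimization over 256 histogram cuts, ties to the lowest threshold),
and decomposed into 8-connected components. Components with equivalent
diameter below 30 µm are discarded as debris (the study's smallest
analysed nodules are larger). Components touching the image border are
excluded from records — truncated geometry corrupts diameter and
volume — and reported separately.

Equivalent diameter is `2 * sqrt(area / pi)`; volume assumes a sphere,
`(pi/6) * d^3`, the only size-consistent choice when converting a 2D
section to the volume axis of the live:dead scatter. The live:dead
ratio for a nodule with zero dead signal is reported as
`live / (dead + 1)` and flagged, keeping log–log fits defined. The
size–response relation is fitted by ordinary least squares of
`log(ratio)` on `log(volume)`.

Penetration depth of an uptake profile is defined by the 1/e rule on
boundary-referenced shells: mean background-subtracted intensity in
1-pixel-wide Euclidean-distance shells from the mask boundary, and the
linearly interpolated depth at which the profile first falls below 1/e
of the boundary-shell value. The study quotes a "penetration depth"
without defining an estimator; 1/e is the standard depth idiom for
near-exponential profiles, and on rendered exponential profiles the
estimator recovers the generating decay length within ~1 µm plus
discretization. If the profile never falls below 1/e the nodule is
flagged fully penetrated and the inradius is returned.

## Ratiometric pH imaging

pH maps come from the ratio of the 570 and 650 nm emission bands of a
hyperspectral cube (550–800 nm, 5 nm interval, 10 nm bandwidth). Each
band is the single plane at the named centre — no re-integration across
neighbouring planes, matching the acquisition. Both bands are
background-subtracted; pixels whose denominator band is within
`low_signal_factor` (default 5) noise standard deviations of the
background are masked. The noise scale is estimated robustly from the
background-dominated pixels near the histogram mode, because a nodule
can cover most of a tight field of view and must not inflate the
estimate. The default factor of 5 is chosen so that, at megapixel
background areas, the expected number of unmasked background pixels is
below one; the cost is only a one-pixel-scale erosion at the dimmest
nodule rim.

The ratio is converted to pH through a calibration curve. The vendor's
dye spectra are not reproducible from the study, so the package derives
its parametric calibration from its own two-state dye model (below) and
also accepts user-supplied tabulated monotone (ratio, pH) curves. The
parametric inversion is the standard two-state form
`pH = pKa + log10(span_factor * (r_acid - R) / (R - r_base))`, where
`r_acid`, `r_base` are the band-ratio endpoints of the pure acid and
base forms and `span_factor` is the acid/base emission ratio at the
denominator band. Ratios at or beyond the endpoints are masked as
out-of-range rather than clamped to a finite pH. Radial profiles report
shell medians over 10 equal-width normalized-radius bins, with core
(`r < 0.33`) and edge (`r > 0.8`) medians; medians resist the isolated
point artifacts that autofluorescence produces in real data, and an
optional 3×3 median despeckle exists but is off by default.

## Apoptosis co-localization

PI and apoTRACE channels are background-subtracted and Otsu-thresholded
independently; the bitwise AND of the binary masks marks apoptotic
death, and the apoptotic fraction is taken over PI-positive pixels.
This is pixel-level, not per-cell — the source map is a binary image,
and no instance segmentation is attempted. No morphological cleanup is
applied by default; a small-object removal flag exists.

## Fluence-rate correction

When the treatment wavelength moves (652 → 670 nm in the hypoxia
experiments), the correction factor applied to the new laser's fluence
rate is the ratio of emission-weighted mean absorbances,
`(∫ L_a A / ∫ L_a) / (∫ L_b A / ∫ L_b)`, integrated trapezoidally on
the union wavelength grid of the overlap. The study's actual laser and
absorber spectra are not printed, so the published 5% figure is treated
as context; the operation is validated against analytic narrow-line
limits, identity, reciprocity and scale invariance instead.

# The synthetic culture generator

The generator states a world; it is calibrated once and then left
alone. Nodules are rendered as circles (equatorial sections) with
diameters drawn log-uniformly — sizes in these cultures span a log
axis — placed without overlap (minimum surface gap 4 µm) in a field,
largest first so that packing rejections cannot skew the size
distribution. Each nodule has a concentric core region at radius
fraction 0.55, standing for the acidic, hypoxic centre of nodules
larger than ~200 µm.

## Survival model

Survival under PDT is logistic in log-dose,
`S(D) = 1 / (1 + (D / d50_eff)^hill)`. The two photochemical channels
of the core-concentrating photosensitizer give the periphery and core
different effective half-kill fluences:

* periphery: `d50_eff = d50 * (1 + (irradiance / irr_scale)^irr_hill)`
  — at high irradiance the oxygen-consuming Type II channel depletes
  oxygen and shuts off, so periphery killing weakens;
* core: `d50_eff = d50 / (diameter / size_ref)^size_gamma`,
  irradiance-free — the Type I radical channel needs no oxygen, and
  larger nodules have larger, more acidic cores that accumulate more
  photosensitizer, making core killing more effective with size;
* severe hypoxia (100% N₂) multiplies every effective `d50` by
  `hypoxia_factor` (default 1.5): overall cytotoxicity is reduced but
  not abolished.

The periphery-localizing agents (BPD, carboplatin) instead kill with
probability decaying exponentially with depth from the boundary on the
agent's penetration length (default 125 µm), leaving cores intact.
These two spatial modes are what makes the fitted live:dead-vs-volume
exponents discriminate the agents: rim-limited killing leaves a
surviving bulk that grows like R³ against a dead rim growing like R²
(rising ratio, positive exponent), while size-sensitized core killing
pulls the ratio down with size.

Each nodule pixel is assigned live or dead by a Bernoulli draw from the
survival probability of its region; live and dead pixels light their
channels at a fixed per-pixel brightness.

## Calibration of the defaults

The defaults are data, stored versioned in
`inst/extdata/default_config.json`, and were fixed once as follows.
Shape constants were set a priori: `hill = 2.5` (a moderately steep
dose response), `irr_scale = 60` mW/cm² and `irr_hill = 3` (so that the
Type II shut-off is essentially complete by 100 mW/cm², where the
reported viability plateau begins, while 50 mW/cm² is still clearly off
the plateau), `size_gamma = 0.25` (enough size sensitization to
separate the agents' exponents without dominating well-to-well
variance), core radius fraction 0.55, reference irradiance 25 mW/cm²
(the maximal-killing irradiance). Given those, the one calibrated
constant, `d50`, is solved by `calibrate_dose_response()` so that the
analytic area-weighted expected well viability of the default culture
equals 0.5 at 20 J/cm² — the study's reported LD50 — at the reference
irradiance. The solution (`d50 ≈ 19.38` J/cm²) is computed from the
model, not fitted to pipeline output; the `calibrate` CLI command
reproduces it.

## Uptake, pH and dye models

Core-concentrating uptake follows classical diffusion into a sphere
with the surface held at the bath concentration (truncated series
solution; `tau = R²/D`), multiplied by a pH-partitioning weight
`10^(s * (ph_edge - pH(r)))` that models accumulation of the cationic
dye along the acid gradient; fill time of the centre scales as
diameter², matching nodules filling within hours. Periphery-localizing
uptake is `exp(-depth / decay_length)` with a 125 µm default.

The radial pH profile is
`pH(r) = ph_core + (ph_edge - ph_core) * r^exponent` with defaults
`ph_core = 5.6`, `ph_edge = 7.2`, `exponent = 2`: sub-6 cores under a
near-neutral rim, with the acidity confined to the inner half of the
radius as hypoxic-core staining suggests. The ratiometric dye is a
two-state emitter with Henderson–Hasselbalch mixing
(`alpha = 1 / (1 + 10^(pH - pKa))`), Gaussian acid/base emission
spectra peaked at 580 and 640 nm (σ = 30 nm, unit peak) and
`pKa = 6.4`, the manufacturer's nominal value for the dye; the vendor
spectra themselves are not printed anywhere reproducible, and any
smooth pair of spectra with these peaks yields the strictly monotone
570/650-vs-pH relation the method needs.

## Camera model

Rendered signal plus a constant background offset passes through
Poisson shot noise at `photon_scale` photons per intensity unit
(default 10), then Gaussian read noise (σ = 3), then clipping at zero;
files are written as 16-bit grayscale TIFF with saturation. Defaults
put the background at 100 with ~4.4 units of total noise — a
high-quality cooled-camera regime in which an NT well scores viability
above 0.98 after background subtraction. `noise_free()` switches the
camera off for estimator-accuracy tests. Pixels are 2 µm square
(pixel-centred coordinates); the study does not state its montage
magnification, so this default is ours.

## What the generator does not emulate

Circular sections, uniform staining brightness, sharp region
boundaries, and independent per-pixel survival are idealizations: real
nodules are irregular, stain unevenly, and die in correlated patches.
There is no 3D rendering, no point-spread function, no confocal depth
attenuation, and no mechanistic photochemical kinetics. A green test
therefore establishes that the pipeline's estimators are unbiased and
correctly plumbed on data with the stated spatial, spectral, dose and
noise structure — not that they are robust to every artifact of real
microscopy.

# Numerical choices

* Otsu threshold: 256 bins over the observed range; exhaustive cut
  search; ties to the lowest cut; constant images are rejected.
* Diffusion series: terms to `exp(-n² π² t/τ) < 1e-10`, with an error
  if more than 10⁴ terms would be needed (vanishing `t`); the `t = 0`
  limit is returned exactly.
* LD50 interpolation requires a bracketing crossing; a series that
  never crosses 0.5 is an out-of-range error, not an extrapolation.
* Power-law fits refuse non-positive volumes or ratios.
* The parametric pH inversion masks ratios at the calibration
  endpoints (infinite pH) and anything outside the physical window
  [4, 9].
* All randomness is seeded through one helper; every render is
  bit-identical for identical inputs and seed, and derived per-well
  seeds stay inside 32-bit integer range.

# Known limitations

* Background estimation is per image (the study does not say whether
  it pooled per plate); constant-offset accuracy is limited by the
  histogram bin width.
* The spherical volume assumption biases volumes of non-spherical
  nodules; the study's 2D-to-volume conversion is unstated.
* Penetration depth assumes a near-monotone radial profile; profiles
  with interior maxima (core-concentrating uptake) are reported as
  fully penetrated.
* The power-law fit treats nodules as independent points; wells and
  days are not modelled as random effects.
* Replicate counts per condition in the source figures are not stated;
  the synthetic defaults use 3 wells per condition.
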