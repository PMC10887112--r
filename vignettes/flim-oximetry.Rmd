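---
title: "Single-spheroid oximetry from frequency-domain FLIM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-spheroid oximetry from frequency-domain FLIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimox)
```

## The measurement problem

A multicellular spheroid sealed in a nanolitre-scale microwell consumes the
oxygen dissolved around it. The well is filled with a ruthenium-based dye
(RTDP) whose excited-state lifetime is collisionally quenched by oxygen, so
the dye's lifetime is a non-invasive oxygen probe: several hundred
nanoseconds at zero oxygen, shortening as oxygen rises. Homodyne
frequency-domain FLIM reads that lifetime per pixel: the excitation and the
camera gain are modulated at a frequency `f` (here 250 kHz), the relative
phase between them is stepped over `K` equally spaced angles, and each pixel
records a sampled sinusoid whose phase lag and demodulation encode the
lifetime.

`flimox` implements the whole chain — forward simulation of the raw phase
stacks with known ground truth, per-pixel lifetime estimation, Stern–Volmer
oxygen conversion with empty-chamber reference normalization, chamber
detection, consumption kinetics, and brightfield/viability quantification —
so that every stage can be validated against ground truth before it is
trusted on real data.

## Signal model

With `omega = 2 * pi * f`, a single-exponential emitter of lifetime `tau`
produces, at phase step `theta_k = 2 * pi * k / K`,

    I_k = DC * (1 + m_sys * m(tau) * cos(theta_k - phi(tau)))
    phi(tau) = atan(omega * tau),    m(tau) = 1 / sqrt(1 + (omega * tau)^2)

`demodulate()` recovers phase and modulation from the complex first harmonic
`F = (2/K) * sum_k I_k * exp(-i * theta_k)`, which for any `K >= 3` equals
`DC * m_sys * m * exp(-i * phi)` exactly — so recovery on noise-free input is
exact to machine precision, a property the test suite asserts for
`K in {3, 4, 8, 16}` and lifetimes from 50 to 1000 ns. Two lifetime estimates
follow:

    tau_phi = tan(phi) / omega        (phase lifetime)
    tau_m   = sqrt(1/m^2 - 1) / omega (modulation lifetime)

They agree for single-exponential decays (the phasor lies on the universal
semicircle), and their agreement is kept as a per-pixel QC check. The oxygen
pipeline consumes `tau_phi` only: the phase lifetime is insensitive to a
miscalibrated system modulation depth, whereas `tau_m` is biased by it
multiplicatively. Pixels where the phase is non-positive or at/beyond
`pi/2`, or where the DC is zero, are flagged invalid and excluded from every
regional statistic — never silently zeroed.

## Stern–Volmer oximetry and reference normalization

Collisional quenching gives `tau0 / tau = 1 + Kq * O2`. The quenching
constant is calibrated once from lifetimes in nitrogen-flushed (`tauN`,
0% O2) and air-equilibrated (`tauA`, ambient `O2A = 20.9%`) dye:

    Kq = (tauN - tauA) / (tauA * O2A),    tau0 = tauN

With the published dye references (533 ns and 381 ns) this yields
`Kq = 0.019089` per % O2, and converting `tauA` back through the model
returns 20.9% exactly — the calibration's self-validation. Oxygen is
expressed in percent throughout; `Kq` therefore carries per-percent units,
which is the only convention consistent with every printed oxygen value.

In a device, the dye's effective unquenched lifetime is not the bench
calibration value: optical differences and progressive photoquenching of the
~9.4 nL dye volume shift it. Wells left without spheroids are therefore
exploited as in-situ references: at each timepoint the pixel-weighted mean
lifetime `tauE(t)` over all empty-chamber interiors anchors

    tau0(t) = tauE(t) * (1 + Kq * 20.9)

and every pixel is converted with that per-timepoint `tau0(t)`. Because the
drift multiplies all chambers alike, the normalization cancels it exactly:
the test suite simulates drifts of 0, 6.4 and 15 ns over the hour and checks
the references read 20.9% at every timepoint to numerical precision.
A pixel-weighted (rather than chamber-weighted) mean was adopted for `tauE`;
with the simulator's equal-sized chambers the two coincide, and
pixel-weighting uses all photons. Negative computed oxygen (when
`tau > tau0`) is reported and counted, not clipped, so reference problems
surface in QC rather than disappearing.

Chamber means are taken over interior pixels within 90% of the chamber
radius, excluding rim pixels where the wall and the ROI rasterization mix
dye and background signal.

## The forward simulator

`simulate_device()` generates everything the pipeline consumes, with ground
truth attached:

* **Geometry.** Cylindrical wells of 200 um diameter and 300 um height
  (volume `chamber_volume(200, 300) = 9.42 nL`) on a configurable pixel
  grid. The camera's pixel scale is a free parameter; the bundled device
  configuration uses 4 um/px so a well spans 50 px.
* **Kinetics.** Chamber oxygen follows a mono-exponential approach to a
  plateau, `O2(t) = p + (i - p) * exp(-r * max(0, t - d))` — the minimal
  form reproducing a rapid decline to a stable level. Untreated defaults are
  `i = 19.2`, `p = 13.8`, with `r = log(54)/25 = 0.1596` per min chosen so
  `O2(25 min) = 13.9`. The onset delay `d` emulates ATP-synthase inhibition
  (oligomycin): respiration suppressed for ~20 min, then a slow decline.
* **Dye and drift.** Lifetimes follow the inverse Stern–Volmer relation.
  A linear, spatially uniform drift of the unquenched lifetime moves the
  empty-chamber reading from 371.3 to 364.9 ns over the hour by default,
  exercising the per-timepoint normalization. Whether real drift is
  spatially uniform is unknown; uniform is the modelled case.
* **Noise.** Poisson shot noise at a configurable photon budget — defined as
  the expected photons per pixel *per phase-step frame* at the DC level —
  plus optional Gaussian read noise. At the default budget of 1e4 the
  per-pixel phase-lifetime deviation of a uniform 400 ns field is ~3.7 ns,
  inside the instrument's stated 5 ns field bound; the estimator is unbiased
  there within Monte-Carlo error.
* **Intra-spheroid gradient.** Occupied wells can carry a radial linear ramp
  from the chamber oxygen at the spheroid rim down to a configurable core
  fraction. Chamber-summary simulations (the bundled device, the consumption
  cohorts) default to a well-mixed chamber (`gradient_core_fraction = 1`)
  because the recovery target there is the chamber-level trajectory, which
  only equals the kinetics value without an interior sink; the gradient
  option exists for image-level demonstration of spatial oxygen structure
  and is qualitative, not a diffusion–reaction model.
* **Brightfield and viability channels.** Spheroids render as dark disks of
  the configured diameter; live/dead pairs place `n` disjoint uniform
  disks (random sequential placement with a spacing that guarantees
  disjoint rasterized components), with `round(dead_fraction * n)` in the
  red channel only. Real cells are not uniform disks and dense spheroid
  cores merge under staining — the generator validates the counting
  machinery, not biological appearance.

All randomness flows from one seed recorded in the output metadata;
re-running a pipeline with the same seed and configuration reproduces every
artifact checksum, which the test suite verifies.

### What passing tests do and do not show

The simulator emulates the *statistical* structure of the measurement
(homodyne sampling, shot noise, common-mode drift, known geometry). It omits
optical blur, multi-exponential dye decay, PDMS oxygen exchange,
autofluorescence and stage drift. Recovery on synthetic data therefore
demonstrates that the estimators are correct and well-conditioned under the
stated noise model — not that a particular physical device meets the same
error bounds.

## Chamber detection and occupancy

Wells are located by normalized cross-correlation against a disk template of
the known design diameter, with greedy non-maximum suppression at one
chamber diameter spacing; detections truncated by the image border are
refused, and zero detections raise an error carrying the template response
range. A matched filter was preferred over a Hough transform because the
radius is known a priori from the device design. Occupancy is primarily a
design-level assignment (`set_occupancy()`), mirroring how reference wells
are empty by construction; image-based classification
(`classify_occupancy()`: a connected dark region exceeding 10% of the well
area) is the fallback, and a manual override always wins.

## Consumption metrics and group comparison

Per-chamber series (empty wells excluded — they are references, not samples)
are summarized by: the negated least-squares slope over the first 5 points
(0–20 min) as the initial rate; the mean of the last 7 points (30–60 min) as
the plateau; the first timepoint within 0.5% O2 of the plateau as the time
to plateau (censored if never reached); and the total drop. The window
defaults straddle the observed ~25 min phase boundary and are arguments, not
constants. An optional molar rate converts %/min to mol/min via the chamber
volume and an overridable oxygen solubility (200 uM for air-equilibrated
aqueous buffer at 37 °C).

Group comparisons run a two-sided two-sample Student's t-test per timepoint
(equal variance, since that is the test named by the convention being
followed; Welch behind a flag), flagging p < 0.05. No multiple-testing
correction is applied by default, matching per-timepoint starring
conventions; Bonferroni is available.

## Morphometry and viability

Brightfield spheroid size: robust percentile contrast stretch (1st–99th),
Otsu threshold on the inverted image, hole filling, largest connected
component, equivalent diameter `2 * sqrt(area/pi) * pixel_size`. A contrast
guard returns a flagged zero-size result when the Otsu split separates class
means by less than 0.15 intensity units — otherwise contrast enhancement
amplifies background noise into spurious components in empty wells. A
percentile stretch replaced full histogram equalization as the enhancement
step because equalization of a background-dominated ROI destroys the
bimodality Otsu needs. Rendered disks at the observed day-0 diameter
(114.9 um at 1 um/px) are measured within 2 px.

Live/dead channels are thresholded at the midpoint between the background
median and the channel maximum (sparse spots make the histogram far too
unbalanced for Otsu), cleaned with a 4 px² minimum-area filter, and counted
as connected components; viability is live/(live + dead). Because dense
staining can merge physical cells, a pixel-area mode (green stained-area
fraction) is provided; component counting is the default and the two modes
are both exposed. Both-channels-blank yields a flagged undefined viability.

## Numerical and interface choices

* `qc_lifetime_field()` reports the *population* SD (divisor n), so a
  two-valued {381, 533} ns field reads exactly 76 ns.
* TIFF samples are stored at 32-bit depth in [0, 1] with a power-of-two
  intensity scale in the JSON sidecar; integer photon counts are flagged and
  snapped back to the integer grid on read, making the round trip
  bit-identical.
* Optional square binning sums intensities over b x b blocks before
  demodulation for low-photon data; pixels are otherwise processed
  independently with no spatial regularization.
* Problem sizes used by the tests and the acceptance analysis — a 6-chamber
  device at 160 x 240 px and 13 timepoints, 256 x 256 uniform fields,
  200-cell viability scenes — were chosen as the smallest configurations
  that still exercise every code path with thousands of pixel replicates
  per statistic.

## Known limitations

No optical PSF, no multi-exponential or multi-frequency phasor analysis, no
phasor-space unmixing, no mechanistic (Michaelis–Menten or
diffusion–reaction) uptake modelling, no chamber tracking across timepoints
(the stage is assumed stationary), and no temperature/salinity correction of
the quenching constant. The molar consumption rate depends linearly on the
assumed oxygen solubility and should be treated as an order-of-magnitude
estimate unless the solubility of the actual medium is supplied.
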