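---
title: "Ionoacoustic range verification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionoacoustic range verification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionoacoustics)
```

This vignette documents the physical models behind the package, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where several reasonable
options existed. It states no empirical result beyond what the package's
tests and the acceptance script themselves compute.

## The physical chain

A proton pulse deposits dose `D(r)` (Gy per proton) in water, peaked at the
Bragg peak near the end of range. Under stress confinement the instantaneous
initial pressure is `p0 = Gamma * rho * D`, with the dimensionless
Grueneisen parameter `Gamma = beta * v_s^2 / C_p` expressing how efficiently
deposited energy density converts to pressure. For an idealized point
detector, the pressure kernel for a delta pulse is the solid-angle average
of `p0` over the sphere of radius `v_s * t` centered on the detector, times
`t`. A real pulse of normalized temporal shape `H_t(t)` (unit integral)
produces the convolution of the kernel with `dH_t/dt`, scaled by the number
of protons in the pulse; the transducer response is approximated by a causal
first-order Butterworth band-pass over its -6 dB bandwidth.

Three modelling consequences shape everything downstream:

* a rectangular pulse contributes a positive copy of the kernel (beam on)
  plus a delayed negative copy (beam off) — compression and rarefaction;
* the signal's rise time is set by the width of the Bragg peak divided by
  the sound speed, so wider peaks (higher energies) mean longer signals and
  lower frequencies;
* amplitude saturates once the pulse outlasts that rise time, which is why a
  dose-normalized SNR has an interior maximum over pulse duration.

## Water properties

`water_properties()` evaluates published pure-water correlations: Kell
(1975) for density (and its analytic derivative for the thermal expansion
coefficient), Marczak (1997) for the sound speed, and a quartic fit to
IAPWS-95 isobaric heat capacities at atmospheric pressure (fit residual
below 0.6 J kg^-1 K^-1 on 0-60 degC). At 20.1 degC these give
`Gamma = 0.109`. The correlations are authoritative; any field can be
overridden, and the Grueneisen parameter is always recomputed from the
effective expansion coefficient, sound speed and heat capacity. The
experimentally adopted sound speed of 1482 m/s is reproduced exactly with
`overrides = list(sound_speed = 1482)`; at 22.4 degC the correlation itself
gives about 1489.5 m/s, and range estimates scale linearly with whichever
value is used.

## Analytic dose engine

The per-proton depth dose uses a power-law range-energy relation
`R = alpha * E^p` with `alpha = 0.022 mm/MeV^p`, `p = 1.77` — placing the
Bragg peak at 4.3 mm for 20 MeV (after the beamline-window shift below) and
305 mm for 220 MeV — and the pristine stopping power
`S(z) = (R - z)^(1/p - 1) / (p alpha^(1/p))`, which integrates exactly to
the beam energy. Range straggling broadens it by convolution with a Gaussian
of `sigma_R = 0.012 * R^0.935` (cm units), combined in quadrature with the
range spread from any relative beam energy spread. The convolution is
evaluated per depth by 160-node Gauss-Legendre quadrature after the
substitution `x = v^2` that removes the integrable end-of-range singularity.

The exit windows of the preclinical beamline (11.4 um titanium, 50 um
kapton) enter as a single water-equivalent range shift,
`tandem_window_shift()` = 0.112 mm, computed once from thickness times
density ratio times mass-stopping-power ratio.

The lateral profile (flat rectangle or Gaussian spot) is depth-independent
and multiplies the depth dose as a separable fluence density; for the
clinical 220 MeV configuration the default spot is a 5 mm sigma Gaussian, a
typical delivered spot size at that energy. Grids default to 20 um voxels at
or below 30 MeV and 450 um above, with the depth spacing refined to a
quarter of the straggling width where needed to resolve the peak.

**Known limitation.** The engine is monoenergetic and collimation-sharp: it
reproduces ranges and acoustic amplitudes well, but its Bragg peak is
sharper than a Monte Carlo model of a full beamline (slit scattering, beam
divergence, accelerator energy spread). Two consequences are visible in the
test suite and are deliberate: the peak voxel dose per proton at 20 MeV
comes out higher than the published beamline-modelled value, and the ideal
pulse durations at 20 MeV come out at the short end of the published
100-230 ns plateau (about 110 ns rather than 150-170 ns), because the
sharper peak saturates the signal earlier. The 220 MeV results are
insensitive to this (straggling dominates all beamline effects at clinical
energies). The acoustic amplitude is also insensitive: the solid-angle dose
integral that sets the pressure is conserved when a real beam spreads
laterally. We chose not to calibrate an artificial energy spread to the
published dosimetry: reproducing the 20 MeV peak dose that way would demand
a range spread near 0.45 mm, which is incompatible with both a tandem
accelerator and the MHz frequency content of the measured signals.

## Acoustic kernel quadrature

`pdelta()` integrates the interpolated dose over spherical caps by a product
midpoint rule, uniform in `cos(theta)` and azimuth, restricted to the
angular cap that encloses the dose grid as seen from the detector (the dose
is zero outside the grid, so the restriction is exact and buys resolution
where it matters — essential in far-field geometries where the dose subtends
a small solid angle). Dose values are trilinearly interpolated; the default
128 x 256 node grid reproduces the closed-form shell average of an
isotropic Gaussian ball to better than 1% L2, which the test suite checks.
The kernel is evaluated per proton in Pa s; pressure scaling uses
`protons = current * effective_duration / e`, with the effective
(charge-equivalent) duration `1 / max(H_t)`.

Convolutions and correlations are FFT-based with zero padding; the discrete
convolution carries the factor `dt`. Heating derivatives are analytic for
rectangular (impulse pair, or boxcar pair with finite rise time) and
Gaussian shapes, and central finite differences for measured profiles —
differentiating the known pulse shape exactly avoids amplifying noise that
numerical differentiation of a convolved trace would introduce.

The detector surrogate is causal (bilinear-transform Butterworth applied as
a one-pass LTI filter), not zero-phase: a physical transducer is causal and
the phase distortion is part of the template. The focused aperture is not
surface-integrated; the band-pass stands in for all transducer effects.

## Detection and SNR conventions

`normalized_crosscorr()` uses the global energy normalization (zero-lag
autocorrelations), bounding values to [-1, 1]; the lag axis is anchored so a
waveform at time `t_s` inside the template arriving at `t_a` in the
measurement peaks at lag `t_a - t_s`. Ties break to the earliest lag, and
peaks are refined by three-point parabolic interpolation.

Signal windows follow the 20% amplitude threshold rule (first crossing on
the rising edge into the maximum; last crossing after the minimum); windows
for correlation functions come from the autocorrelation zero-crossings
adjacent to zero lag. The moving-average power uses
`n = max(2, round(d/dt))` samples per window; the SNR is the maximum
windowed power over the search region divided by the mean power over a
noise window that must precede any possible arrival (an `arrival_hint` can
exclude secondary signals and reflections from the search).

In the duration sweeps the raw-branch noise power is constant across
durations (the detector noise floor does not depend on the beam, and a
constant cancels in the argmax); the correlation branch takes its signal
power from the template autocorrelation and its noise power from
correlating the template with one fixed seeded white-noise realization.
These correlation powers are deliberately unnormalized: the Eq-1 style
normalization cancels in any SNR computed from a single correlation trace,
but in the simulation-side construction the noise power must remain
proportional to the template energy — the matched filter's defining
trade-off — and normalizing each factor separately would destroy that.
White noise stands in for a recorded laboratory noise trace; its RMS is a
configuration parameter that cancels in every argmax and enters only
absolute SNR values, which depend on laboratory noise floors and are not
reproduction targets.

## Range estimation

The entrance-window echo is modelled as the time-reversed, sign-inverted
direct waveform: the backward-travelling wave from a compact axial source
is the time mirror of the forward one, and the water/air-backed foil is a
pressure-release boundary (reflection coefficient -1, configurable — the
exact 180 degree phase assumption is a known possible systematic). The
reflection search is restricted to lags later than the direct peak by at
least the template duration, and the peak must exceed 3x the correlation
noise floor, defined as the largest correlation magnitude at lags well
before the direct arrival (an extreme-value-aware floor; a standard
deviation would be exceeded by pure noise over thousands of lags). Time of
flight converts to range as `R = v_s * ToF / 2`; trigger-based one-way
conversion gives the Bragg-peak-to-detector distance, which is not the
proton range.

## The synthetic scene generator

`synthesize_measurement()` composes, on a common clock started at the beam
pulse: the direct template at `d / v_s`, an optional entrance-window signal
(a scaled copy, default amplitude ratio 0.5 — a qualitative stand-in chosen
to resemble the relative prominence seen in measurements) at
`(d + R) / v_s`, the echo at `(d + 2R) / v_s`, and seeded white Gaussian
noise whose power scales as `1/n_shots` under averaging. Arrivals are
quantized to the sample grid and the placed times are recorded in the
ground-truth output, so estimator tests can distinguish quantization from
estimation error. 1/R spreading corrections along the reflected path are
ignored by default (the path difference is small when the detector distance
is large compared to the range).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: colored and non-stationary laboratory noise,
transducer ring-down, acoustic attenuation and dispersion, heterogeneous
sound speed, tissue interfaces producing additional reflections, beam
current fluctuations between shots, and template mismatch from transducer
misalignment. Ranges recovered at micrometre accuracy from these scenes
demonstrate estimator correctness, not experimental accuracy.

## Study conventions and problem sizes

Duration sweeps use 24 log-spaced points per sweep (50 ns - 1 us at
20 MeV; 1 - 20 us at 220 MeV), argmax by parabolic interpolation in
log-duration (ties to the shorter duration), and a 90% plateau band by
linear interpolation on the log axis. The energy study scales each energy's
duration grid to the straggling-broadened Bragg-peak transit time and runs
in far-field mode: broadband point sensor on axis at ten times the range.
The spectral "central frequency" is the parabolic-interpolated maximum of
the zero-padded amplitude spectrum (a spectral centroid is an equally
defensible definition; the peak was chosen because the quantity accompanies
a peaked band-limited signal). The chopped-versus-single comparison uses
Gaussian shapes for the single-pulse branch (the ideal-rectangle assumption
of negligible rise time fails for very short pulses) and a continuous
dose-matched averaging count for the chopped branch. Sampling defaults are
156 MS/s for sub-microsecond pulses and 15.6 MS/s for microsecond-scale
clinical pulses. These sizes keep every study in the seconds range on one
CPU while resolving each optimum to a few percent; all stochastic routines
take explicit seeds and reproduce bit-identically.

## Serialization

Traces are two-column delimited text (time, amplitude) with a JSON sidecar
for the time base, kind tag and scalar metadata; dose grids are MetaImage
(.mhd header + little-endian raw, doubles on write, bit-exact round trip);
template banks are plain-text directory containers (per-template CSV plus a
JSON index); configurations are YAML with a content hash embedded in
outputs so identical configuration and seed imply identical artifacts.
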