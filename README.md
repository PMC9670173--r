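# ionoacoustics

Simulation and signal-processing toolbox for **ionoacoustic (protoacoustic)
range verification** in proton therapy.

A pulsed proton beam stopping in water deposits its dose in a sharply peaked
Bragg curve. The sudden local heating launches a pressure wave; an ultrasound
detector placed distal to the Bragg peak records it. Because the acoustic
source sits at the Bragg peak, the arrival times of the direct wave and of
its reflection at the beam entrance window encode the proton range — the
quantity radiotherapy most wants to verify in vivo. The practical obstacle is
the poor signal-to-noise ratio at clinically acceptable dose levels; this
package implements the two levers studied for that problem: optimal beam
pulse timing and matched-filter (cross-correlation) post-processing with
simulated templates.

## What the package computes

**Forward model.** The pressure at the detector for a delta-like beam pulse
is the solid-angle integral of the initial pressure over spheres centered on
the detector,

```
P_delta(t) = t / (4 pi) * \oint Gamma * rho * D(r', theta', phi') dOmega,
R' = v_s t,
```

with `Gamma = beta v_s^2 / C_p` the Grueneisen parameter of water (0.109 at
20.1 degC from published correlations). A finite pulse gives
`p(t) = [dH_t/dt * P_delta](t)` scaled by the protons per pulse, where `H_t`
is the beam current normalized to unit integral; the transducer is a causal
first-order Butterworth band-pass over its -6 dB bandwidth. The per-proton
3D dose comes from an analytic Bragg-curve engine (power-law range-energy
relation `R = alpha E^p`, Gaussian range straggling) or from an external
MetaImage dose grid.

**Detection.** Measurements are filtered by normalized cross-correlation
with the simulated template,

```
CC(tau) = sum_t M(t) T(t+tau) / sqrt(AC_MM(0) AC_TT(0))  in [-1, 1],
```

and quantified by the average signal power over a moving window divided by
the pre-arrival noise power (SNR). Dividing by the deposited peak dose gives
the dose-limited `SNR_D = SNR / D`, whose maximum over pulse duration defines
the ideal pulse length for a beam energy and detector.

**Range estimation.** The time of flight between the direct correlation peak
and the peak against the time-reversed, sign-inverted template (the
entrance-window echo) gives the range via `R = v_s * ToF / 2`, with
three-point parabolic sub-sample refinement.

**Studies.** Sweeps of dose-limited SNR over pulse duration (rectangular and
Gaussian), beam-current scaling at fixed total dose, single-pulse versus
chopped-and-averaged trains, and ideal durations with spectral central
frequencies across clinical energies (20-260 MeV). A seeded synthetic-scene
generator (direct signal + echo + optional entrance-window signal + noise)
provides ground-truth measurements for every stage.

## Worked example

Simulate the preclinical configuration — a 20 MeV beam collimated to
2.5 x 3 mm entering a water tank, a 3.5 MHz focused transducer 25.4 mm
beyond the Bragg peak — then recover the range from a noisy synthetic
measurement:

```r
library(ionoacoustics)

med  <- water_properties(20.1, overrides = list(sound_speed = 1482))
beam <- beam_spec(20, lateral_rectangular(2.5, 3),
                  range_shift = tandem_window_shift())
det  <- axial_detector(beam, 25.4, band = olympus_band())

pulse <- rectangular_pulse(130e-9, dt = 1 / 156e6, current = 4.5e-6)
tmpl  <- simulate_template(beam, pulse, det, med)

R0    <- range_energy(20, tandem_window_shift())   # 4.31 mm
scene <- scene_spec(tmpl, detector_distance_to_peak = 25.4, range = R0,
                    noise_rms = max(abs(tmpl$samples)) / 8, seed = 7)
meas  <- synthesize_measurement(scene, med)

estimate_range(meas$measurement, tmpl, medium = med)
#> direct_reflection: ToF 5.808 us -> 4.304 mm (v_s = 1482.0 m/s)
```

The estimate sits within a few micrometres of the ground-truth 4.306 mm at a
raw power SNR near 25. The ideal-pulse-duration study for the same setup:

```r
sw <- sweep_pulse_duration(beam, det,
                           durations = exp(seq(log(50e-9), log(1e-6),
                                               length.out = 24)))
sw
#> pulse-duration sweep (rectangular, 20 MeV, 24 points 5e-08-1e-06 s)
#>   SNR_D,S argmax 1.088e-07 s  (90% band 6.7e-08-1.35e-07 s)
#>   SNR_D,C argmax 1.133e-07 s  (90% band 7.81e-08-1.52e-07 s)
```

i.e. a broad optimum near 110 ns for raw signals, slightly longer for the
correlation-filtered branch, with the 90% plateau showing the freedom of
choice around it.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ionoacoustics` (subcommands `simulate-template`,
`simulate-measurement`, `filter`, `snr`, `range`, `sweep-duration`).

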