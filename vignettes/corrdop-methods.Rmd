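---
title: "Correlational photoacoustic Doppler flowmetry: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlational photoacoustic Doppler flowmetry: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

An acoustic-resolution photoacoustic microscopy (AR-PAM) endoscope fires a
laser pulse and an ultrasound pulse per A-line at a 1 kHz repetition rate and
digitizes the returned RF at 180 MHz while the imaging head rotates in 0.36
degree steps (1000 A-lines per revolution). The photoacoustic amplitude mixes
optical fluence and absorption, so amplitude alone is a poor perfusion
surrogate. Flow, however, leaves a purely kinematic signature: absorbers
moving along the beam displace the RF speckle pattern between consecutive
A-lines. `corrdop` estimates that displacement by time-domain
cross-correlation and converts it to a velocity map.

## Velocity model

A correlation shift of one interpolated sample between A-lines acquired
$1/f_{prf}$ apart corresponds to the axial velocity resolution

$$V_{res} = \frac{c}{2}\cdot\frac{f_{prf}}{f_s\, n_{res}}
          = \frac{1540\ \mathrm{m/s}}{2}\cdot
            \frac{1\ \mathrm{kHz}}{180\ \mathrm{MHz}\times 3}
          \approx 1.43\ \mathrm{mm/s},$$

under the pulse-echo (round-trip) depth convention $r = c\,t/2$ that the
package uses throughout (a one-way convention is available and the simulator
always matches the active one). The axial velocity of a window with
correlation shift $P_{shift}$ (interpolated samples) is
$V_c = P_{shift} V_{res}$, positive toward the transducer. The flow speed
follows by angle compensation, $V = V_c / \cos\theta$, with $\theta$ the
beam-to-flow angle; because the factor diverges as $\theta \to 90^\circ$, the
angle used is capped at `angle_cap` (70 degrees by default), trading
under-recovery above the cap for bounded error.

## Processing chain

1. **Band-pass** each A-line with a linear-phase windowed-sinc FIR filter,
   3--30 MHz passband, group delay compensated. 301 Hamming taps are used:
   at $f_s = 180$ MHz the Hamming transition width ($\approx 3.3 f_s/N$)
   must be below $\sim$3 MHz for the filter to provide 40 dB of rejection at
   half the lower band edge, which a shorter (e.g. 101-tap) design cannot do.
2. **Noise floor**: mean absolute amplitude over a signal-free region (the
   first 200 samples, or everything shallower than the detected surface minus
   one pulse length). For a Gaussian noise channel of standard deviation
   $\sigma$ this estimates $\sigma\sqrt{2/\pi}$.
3. **Amplitude mask**: keep samples whose analytic-signal envelope is at
   least `noise_factor` (3) times the floor. For pure noise the envelope is
   Rayleigh, so the expected pass fraction is
   $\exp\!\big(-(3\sqrt{2/\pi})^2/2\big)\approx 5.7\%$ per sample; requiring
   the whole 25-sample window to pass on both lines of a pair, plus the
   correlation gate below, reduces noise-only false positives to below 1% of
   windows.
4. **Axial interpolation** by `nres = 3` using Fourier zero-padding.
   Band-limited interpolation preserves the pulse shape the correlator
   matches; linear interpolation would bias sub-sample shifts.
5. **Correlation**: for each adjacent A-line pair and each 25-point window
   (centers every `window_hop = 12` interpolated samples), find the integer
   lag in $[-15, 15]$ maximizing the normalized cross-correlation; record the
   lag and the coefficient $\rho$. Ties prefer the smaller $|$lag$|$, then
   the non-negative lag. `max_lag = 15` interpolated samples spans roughly
   $\pm 21$ mm/s axially — comfortably beyond the 0.63--6.3 mm/s study range
   after the $\cos 60^\circ$ projection, while excluding the first carrier
   sidelobe of the correlation function ($\approx 36$ interpolated samples at
   15 MHz). The hop of half a window halves compute relative to a dense
   stride with negligible information loss; both are configurable.
6. **Gate** windows with $\rho <$ `rho_min` (0.7). The threshold is a
   configuration default chosen so that noise-only scans pass $\le 1\%$ of
   windows while plug-flow speckle (whose pair correlation at 20 dB SNR is
   $\approx 0.99$) is untouched.
7. **Sub-sample refinement** (`subsample_refine`): a parabola through the
   correlation peak and its two neighbours. Off by default — the basic
   estimator is integer-valued — but switched on in the validation
   experiments, where integer quantization ($V_{res}/2 \approx 0.7$ mm/s)
   would dominate the error at the low end of the speed range.
8. **ROI averaging** (`roi_average`): mean of valid velocities over blocks of
   `roi_lines = 100` consecutive A-line pairs. Besides suppressing
   correlation noise, block averaging cancels integer alignment jitter: the
   per-pair lag errors introduced by integer surface shifts telescope, so a
   block of $N$ pairs retains only the endpoint quantization error $O(1/N)$.

## Rotational scans: alignment and angle estimation

For endoscopic scans the tissue surface moves relative to the probe.
The US channel provides the water--tissue interface: per line, the time of
arrival is the first sample whose envelope exceeds the noise floor by
`toa_threshold_db` (10 dB). Two robustness layers follow:

* **Outlier rejection**: a sliding circular median (15 lines); arrivals more
  than 5 MAD from it (MAD floored at one sample, the arrival quantization
  unit) are replaced by it.
* **Profile smoothing** (`smooth_surface`): circular running median (15) then
  running mean (9). Threshold crossing in the foot of the interface echo
  carries multi-sample jitter at realistic noise levels; aligning on raw
  arrivals would inject inter-line shifts larger than the flow signal itself.
  The physical surface is smooth at the 0.36 degree line pitch, so the
  smoothed profile is the better displacement estimate; the raw arrivals
  remain available on the profile object.

PA lines are then shifted by integer samples to a common arrival, processed,
and the window coordinates shifted back for co-registration with the
unaligned US image.

Per-line beam-to-flow angles come from the surface geometry under the
assumption that flow runs parallel to the surface. With consecutive surface
points at radii $r_{i-1}, r_i$ (radius = probe offset + depth of the
arrival) separated by the angular step $\Delta\varphi$, the default mode
computes the exact chord angle at vertex $i$ — the interior angle between the
chord and the radial beam direction, satisfying the law of sines
$r_{i-1}/\sin\theta_i = r_i/\sin(180^\circ - \Delta\varphi - \theta_i)$
without approximation and without needing an initial condition. The
small-angle recursive form
$\sin\theta_i = r_i \sin(\Delta\varphi + \theta_{i-1})/r_{i-1}$ is available
behind `mode = "recursive"` (seeded with the exact angle) but accumulates
approximation error. Angles are folded to $[0^\circ, 90^\circ]$ and capped at
70 degrees before compensation; a constant-radius surface gives the
near-perpendicular chord angle $(180^\circ - \Delta\varphi)/2 \approx
89.8^\circ$, hence the cap.

## The scan simulator

Physical flow phantoms are replaced by a simulator that is kinematically
exact and acoustically idealized:

* Point absorbers are convolved with a Gaussian-enveloped 15 MHz, 115%
  fractional-bandwidth pulse evaluated continuously, so fractional-sample
  positions and displacements are represented without resampling error.
* Plug flow (uniform speed across the 580 um tube bore) is the default, so
  each PRF interval displaces the whole speckle pattern axially by exactly
  $v\cos\theta/f_{prf}$; a parabolic profile is available. Scatterers leaving
  the beam-intersected chord re-enter at the far end, keeping density
  stationary.
* The beam is a line: no diffraction, focusing, or attenuation. White
  Gaussian noise is added after synthesis, scaled to the requested RMS SNR
  inside the flow region (the realized levels are recorded in `meta`).
* Rotational scans place a dominant surface echo in the US channel and ride
  the whole A-line content on the surface profile: a one-cycle sinusoidal
  eccentricity (0.15 mm default) for the spiral phantom, or an arbitrary
  radius function for lumen scans. The spiral tube sits at a fixed depth
  below the surface with a constant, known beam-to-flow angle — either given
  directly or derived from a probe tilt via the analytic helix-tangent map
  `helix_beam_angle()` (the physical spiral-phantom correction angle is a
  free parameter of the setup, so the simulator makes it explicit rather
  than guessing a value).

What passing the in-silico experiments does **not** show: robustness to
speckle decorrelation from lateral beam translation, acoustic attenuation and
depth-dependent blur, tissue motion between non-adjacent lines, reverberation
or multiple scattering, or fluence inhomogeneity. The simulator validates
the estimator's kinematics and the geometry chain, not transducer physics.

## Validation experiments and problem sizes

The package ships three experiment drivers mirroring the phantom studies, at
sizes chosen to give stable statistics on a single CPU within minutes:

* `experiment_linearity()`: ten speeds 0.63--6.3 mm/s at a 60 degree
  beam-to-flow angle, SNR 20 dB, 201 A-lines per scan, three seeds per speed;
  fixed-angle compensation; reports per-speed means, an OLS fit with $R^2$,
  and the maximum relative error.
* `experiment_angle_sweep()`: fixed 6.3 mm/s, angles varied; reports
  uncompensated ($\approx v\cos\theta$) and compensated estimates, including
  the deliberate under-recovery above the 70 degree cap.
* `experiment_spiral()`: six speeds 1--6 mm/s, full 1000-line revolutions,
  surface detection + alignment, constant 60 degree compensation, 100-line
  ROI averaging, three seeds per speed.

All randomness flows from a single base seed through recorded per-run seeds,
so reports are byte-reproducible.

## Numerical choices and degenerate inputs

* Zero-variance correlation windows (flat signal) are invalid, not errors;
  fully masked pairs yield all-invalid rows.
* The parabolic refinement is only applied at interior lags with a concave
  three-point neighbourhood; the offset is confined to $\pm 0.5$ and the
  total to the search range.
* A detected-arrival profile that is constant up to sample quantization
  passes outlier rejection unchanged (the MAD floor).
* `to_polar` uses bilinear sampling with azimuthal wrap; pixels outside the
  scanned annulus are `NA`. Note the raster pixel pitch is typically coarser
  than the axial sample pitch.
* Degenerate t-test inputs (zero pooled variance) return $t=0, p=1$ for
  equal means and are flagged `degenerate` with $p=0$ otherwise.

## Known limitations

* Flow orthogonal to the beam is invisible to the method by construction;
  compensation only rescales what was measured along the beam.
* Area-based angle compensation assumes flow parallel to the surface; it
  cannot recover per-vessel directions.
* Above the 70 degree cap the estimate deliberately under-recovers by
  $\cos\theta/\cos 70^\circ$.
* Integer-sample alignment plus detection jitter makes single-pair
  velocities noisy on rotational scans; ROI averaging is required there and
  per-pair maps should be read qualitatively.
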