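---
title: "Models and methods behind optomotr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optomotr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomotr)
```

This vignette explains the models implemented in optomotr, the choices
made where the design was genuinely open, and what the synthetic-data
tests do and do not establish about real experiments.

## Projection geometry

The display model is a pinhole projection of a fly-centered virtual
cylinder onto a flat panel at distance $d$ (default 35 mm): azimuth
$\theta$ maps to screen offset $x = d\tan\theta$, and only
$|\theta| < 90^\circ$ projects onto the screen plane (the functions throw
a domain error beyond it). Because the fly sits on the cylinder axis, a
pixel's luminance depends only on the *angle* of the ray through it, never
on the cylinder diameter — the test suite checks the closed form against a
brute-force per-pixel ray cast at two different diameters.

Sign conventions, fixed once and used everywhere: azimuth 0° is straight
ahead, positive azimuth is to the fly's right, and positive angular
velocity ("clockwise", CW) moves the pattern toward positive azimuth. With
the spatial axis plotted right-to-left and time downward, CW motion tilts
space-time streaks down and to the left.

The physical panel dimensions are not uniquely determined by a ~130°/100°
field of view; we adopt 151.8 × 83.4 mm at 1024 × 600 px (a common 7-inch
panel), which gives 130.49° × 99.98°. Elevation uses the same flat
projection — the virtual cylinder has no vertical curvature. Angles are
degrees at every interface and radians only inside trigonometric calls.

## Stimuli and protocols

Gratings are ideal square waves: bright on the first half of each spatial
period. The initial phase puts a bright bar at azimuth 0 (the protocols do
not depend on this choice; it is simply fixed). Bar sweeps default to a
travel span of 175.5° — the default panel's visible azimuth (~130.5°) plus
the 45° bar width — so the bar starts fully off one screen edge and ends
fully off the other; this span also reproduces the 0.13–7.8 s range of
sweep durations across the six standard speeds exactly. During bar
pre/post epochs the visible screen is therefore uniformly dark without any
special casing.

Block randomization draws one uniform permutation of the condition list
per block, so every condition appears exactly once per block for any seed.
The direction assignment is part of the condition (CW and CCW variants are
distinct conditions), which makes the per-block histogram flat by
construction; whether the original experiments balanced directions within
blocks differently is not recoverable from the protocol description, and
does not affect the analysis, which folds directions at the end. All
randomization runs on isolated RNG state (`withr::with_seed`), leaving the
session RNG untouched. Closed-loop trials can be interleaved; the default
cadence is one per block, configurable, since only "interleaved" is known.

## Engine: clocks, frames, and latency

One simulated clock (integer microseconds) serves both the "server"
(protocol scheduler) and the "client" (renderer); modeling two skewed
clocks is out of scope. Parameter updates travel through an injectable
transport with per-message one-way latencies — constant, or exponential
with a given mean — delivered in order. The client renders one frame per
refresh interval and always applies the latest *delivered* parameters: if
an update misses the frame deadline, the previous content is shown again.
A frame is "on time" when its content request completes within one nominal
inter-frame interval (1000/60 ≈ 16.7 ms); delayed frames are binned by
whole frame intervals (1, 2, ≥3). A deterministic spike injector
(`spike_every`, `spike_ms`) exists purely to construct exact accounting
scenarios, e.g. one dropped frame per 1000 giving a 99.9% on-time rate by
counting.

For closed-loop dynamics the package models the fly as a proportional
(optionally proportional–integral) controller of retinal slip. With
stimulus coupling gain $g$ and fly proportional gain $c$, the slip obeys
$s_{k+1} = \omega + g\,c\,s_k$ and converges to $\omega/(1-gc)$ whenever
$|gc|<1$; with $g=-1$ the residual slip shrinks as the fly's gain grows,
and any integral action drives it to zero. This is deliberately the
simplest closed-loop model that exhibits stabilization; it makes no claim
about real fly controllers.

## Rendering and the net-motion index

Frames sample the stimulus at pixel-column centers with no anti-aliasing
(square-wave LCD content); an optional supersampling factor exists to
emulate a finite sensor aperture, used by the spatial-averaging tests
(fine gratings lose modulation depth through a ~5 mm sensor, and more so
as the sensor grows). Frames are zero-order-hold between refreshes, so a
TF = 30 Hz grating on the 60 Hz display alternates between the pattern and
its half-period complement — counterphase flicker.

The net-motion index resamples a space-time diagram onto a uniform azimuth
grid (so perspective distortion cannot masquerade as direction), removes
the mean, and compares opponent quadrant energies of the 2-D Fourier
spectrum: drift toward positive azimuth concentrates energy where the
temporal and spatial frequencies have opposite signs. The index is
normalized to $[-1, 1]$, antisymmetric under time reversal and mirroring
(to numerical precision: the nearest-neighbor resample leaves residuals of
order $10^{-4}$, which is why the flicker-null tests use a $10^{-3}$
tolerance against a signal of ~0.58 for true motion), and ~0 for the
aliased condition.

## FicTrac I/O

The 25-column layout is addressed through a format descriptor (heading in
column 17, movement speed in 19, timestamp in 22, delta timestamp in 24 by
default) because column conventions drift between tool versions; only
these columns are interpreted and the rest round-trip opaquely. Movement
speed is taken as radians of sphere rotation per camera frame — the only
reading under which multiplying by the sphere radius (9 mm ball) and
dividing by the frame interval yields a walking speed, and the one that
puts the synthetic flies at their configured ~10 mm/s. Yaw velocity
unwraps heading (adding/subtracting $2\pi$ at jumps larger than $\pi$)
before differencing; integrating it back recovers the total heading change
to floating-point precision.

## Synthetic fly

The tuning model is log-Gaussian in temporal frequency,
$r(\mathrm{TF}) = r_{peak}\exp\!\big(-\ln^2(\mathrm{TF}/\mathrm{TF}_{opt})/2w^2\big)$,
the minimal unimodal, log-symmetric shape consistent with an optomotor
optimum; the analysis pipeline never assumes this form — it only computes
empirical means. Defaults: $\mathrm{TF}_{opt} = 4$ Hz, $r_{peak} = 50$
deg/s (a typical walking optomotor magnitude), $w = 1.2$ (broad tuning),
50 ms response latency, per-frame motor noise of SD 100 deg/s at the
180 Hz camera rate, and forward speed 10 ± 3 mm/s truncated at zero. These
are the package's study conditions, chosen once.

Crucially, the fly consumes the *rendered* stimulus: each condition's
drive direction and gate come from the net-motion index of its space-time
diagram, so the 30 Hz condition (no net motion on the display) drives zero
mean turning without any special-casing — the recovery pipeline then
measures ~0 there because nothing was there to follow. Bar sweeps drive
turning through an effective TF of $|\omega|/90^\circ$ while the bar is on
screen; an optional midline gate (turning only once the bar has crossed
the visual midline into progressive motion) is off by default because no
functional form for the position dependence is established.

What the simulator does *not* emulate: trial-to-trial adaptation, pauses
and grooming, saccadic structure in the turning, translation-rotation
coupling, or realistic FicTrac estimation noise. Passing recovery tests
therefore show that the pipeline's bookkeeping, unit conversions,
averaging order, and direction folding are correct — not that it is robust
to every pathology of real treadmill data.

## Analysis chain

Camera frames are aligned to trials by event-log timestamps (the two
streams run at different rates, so frame counters cannot be used); epochs
are half-open, $[\mathrm{on}, \mathrm{off})$, so a frame exactly at motion
onset is a motion frame. Smoothing is a centered 5-camera-frame moving
average (~28 ms at 180 Hz) whose window truncates to the available samples
at series edges, applied to the continuous yaw series *before* any trial
averaging — where the ordering was ambiguous, smoothing-first was chosen
and is fixed here. Averaging is two-stage (trials within fly, then flies
with equal weight), SEM is $sd/\sqrt{n_{flies}}$ across flies (undefined
and flagged for a single fly), and the combined response is
$(\mathrm{CW} - \mathrm{CCW})/2$, which cancels constant turning bias
exactly — both properties are asserted by simulation in the test suite.
Closed-loop trials are carried through merging and labeling but are
excluded from every tuning computation.

## Problem sizes and numerics

The parameter-recovery study runs 30 synthetic flies through 6 blocks of
the 14-condition temporal protocol at the full 180 Hz camera rate
(~1.8 million camera frames end to end) and completes in well under a
minute on one CPU; unit tests use a 128-column panel and one- or
two-block protocols, which exercise identical code paths at a fraction of
the cost. Per-condition drive tables are rendered once and shared across
flies. The dominant-frequency estimator is a periodogram argmax excluding
DC and warns on constant traces instead of fabricating a peak. Timestamps
are integral microseconds; event logs round-trip their CSV serialization
exactly.

## Known limitations

No photometric calibration, gamma, or IPS intensity-falloff modeling; no
real network or browser client (the transport interface is where one would
plug in); no biomechanics in the fly model; and the closed-loop controller
is a didactic minimal model. The bar-following profile reports the
deterministic bar trajectory for overlay but does not model
position-dependent gain by default.
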