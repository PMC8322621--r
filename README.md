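# optomotr

A headless, fully testable re-implementation of an inexpensive
spherical-treadmill virtual-reality stack for walking *Drosophila*. A
tethered fly walks on an air-supported sphere in front of a flat tablet
display; the software renders cylinder-projected visual stimuli corrected
for the viewing angle, schedules open- and closed-loop trials, accounts for
every display frame and network round trip, reads and writes
FicTrac-format treadmill data, simulates a temporal-frequency-tuned
synthetic fly, and runs the turning-response analysis that produces
optomotor tuning curves. Everything runs on a simulated clock and an
injectable transport, so the complete experiment-and-analysis loop is
reproducible on a laptop with no hardware, animals, or network.

It is aimed at behavioral neuroscientists building or validating treadmill
rigs, and at anyone who wants an executable, testable description of this
class of experiment.

## The science in brief

**View-angle correction.** The stimulus lives on a virtual cylinder
(305 mm diameter) centered on the fly, which sits d = 35 mm in front of a
flat panel. An azimuth angle θ maps to the physical screen offset
x = d·tan θ, so a bar spanning a fixed angular width must be drawn
physically wider toward the screen edges — a 10° bar centered at 55°
azimuth is ~3.1× as wide on the panel as a 10° bar at the center. The
default 151.8 × 83.4 mm panel subtends ~130° of azimuth and ~100° of
elevation from the fly's position.

**Stimuli and protocols.** Square-wave gratings of spatial period λ drift
at angular velocity ω; their temporal frequency is TF = |ω|/λ. Three
standard protocols are built in: temporal-frequency tuning (λ = 90°,
ω = ±22.5…2700 °/s → TF = 0.25…30 Hz, 14 conditions), spatial-period
tuning (λ = 5…120° at TF = 7.5 Hz, 14 conditions), and single 45°
bright-bar sweeps (±22.5…1350 °/s, 12 conditions, 0.13–7.8 s per sweep).
Conditions are presented in randomized blocks (default 6), each trial
bracketed by 500 ms stationary epochs. On a 60 Hz display the TF = 30 Hz
grating steps by exactly half a period per frame: it is counterphase
flicker with zero net motion, and serves as a built-in control.

**Turning analysis.** FicTrac-format files encode the sphere rotation;
heading is unwrapped, differenced, and divided by the frame interval to
give yaw velocity in deg/s, and the movement speed (rad/frame) times the
sphere radius (9 mm diameter ball) gives walking speed in mm/s. Yaw traces
are smoothed with a 5-camera-frame sliding window, averaged per fly and
then across flies, counterclockwise responses are scaled by −1 and folded
onto clockwise ones (cancelling any direction-independent bias), and the
motion-epoch mean per condition yields mean ± SEM tuning curves.

**Synthetic fly.** A log-Gaussian TF-tuned optomotor model (default
optimum 4 Hz, peak 50 deg/s, heavy motor noise, ~10 mm/s forward walking,
180 Hz camera) that responds to the *rendered* stimulus — via the signed
net-motion index of each condition's space-time diagram — so the aliased
30 Hz condition correctly drives no turning.

## Worked example

```r
library(optomotr)

geom <- display_geometry()
geom
#> <display_geometry> 151.8 x 83.4 mm (1024 x 600 px), viewed from 35.0 mm @ 60 Hz
#>   field of view: 130.5 deg azimuth x 100.0 deg elevation

azimuth_to_screen_x(45, geom)                              # 35 mm: x = d tan(45)
arc_screen_width(50, 60, geom) / arc_screen_width(-5, 5, geom)
#> [1] 3.09                                      # edge bars drawn ~3x wider

p <- build_protocol("temporal")                 # 14 conditions, 6 blocks
res <- run_tuning_experiment(p, n_flies = 5, seed = 1)
as.data.frame(res$curve)
#>       x base_id   mean   sem n_flies
#> 1  0.25  tf0.25  4.059 0.432       5
#> 2  1.00     tf1 25.224 0.848       5
#> 3  2.00     tf2 42.603 0.518       5
#> 4  4.00     tf4 48.936 0.845       5
#> 5  7.50   tf7.5 42.045 0.772       5
#> 6 15.00    tf15 26.284 0.824       5
#> 7 30.00    tf30  0.673 0.381       5
```

The curve peaks at the synthetic flies' injected 4 Hz optimum
(48.9 deg/s mean turning, close to the 50 deg/s model peak; the small gap
is the response latency clipping the motion epoch), and the 30 Hz flicker
control sits at ~0.7 ± 0.4 deg/s — no response to motion that is not
there. `plot(res$curve)` draws the mean ± SEM curve.

Single pieces are available on their own: `space_time()` renders the
stimulus as a frames × pixels luminance matrix, `photodiode_trace()` +
`dominant_frequency()` emulate the brightness measurement at a display
corner, `run_experiment()` gives frame-by-frame on-time accounting under a
configurable transport, and `read_fictrac()` / `yaw_velocity()` /
`translational_speed()` work on real FicTrac files too.

A thin CLI wraps the same functions (`inst/scripts/optomotr`): `validate`,
`run` (configured experiment → artifact directory + manifest), and
`spacetime` (diagram export). Configs are YAML; see `experiment_config()`.

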