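---
title: "Methods: a fail-safe virtual light sheet microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fail-safe virtual light sheet microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spimsim)
```

`spimsim` models an unsupervised light sheet fluorescence microscope as four
cooperating layers — specimen, peripherals, supervisor, interaction/rendering
— with telemetry across all of them. This vignette explains the model each
layer implements, the assumptions behind it, the tunable parameters and the
numerical choices, and what the simulated conditions do and do not tell you
about a physical instrument.

## The specimen: a two-channel vasculature phantom

The virtual camera needs something to image. `generate_phantom()` builds a
stand-in for a fluorescently labelled zebrafish in an 8-bit intensity range
(`Imax = 255`; 8-bit keeps all lookup-table arithmetic exact and matches
common exhibition-grade cameras after binning):

* **Fluorescence channel.** `n_vessels` centrelines are correlated 3D random
  walks (step 0.5 voxel, direction perturbed by Gaussian increments of
  weight 0.25, reflected back when approaching the body boundary). Each is
  rasterised as a tube with radius drawn from 1–3 voxels. The radial profile
  is a *saturated core* (full intensity within 0.9 voxels of the centreline)
  with a Gaussian skirt of width `sigma = radius / 2`, cut off at
  `core + 3 sigma`. A pure Gaussian profile cannot guarantee a bright voxel
  on a thin tube — the nearest voxel centre can be up to `sqrt(3)/2 ≈ 0.87`
  voxels off the continuous centreline, so a 1-voxel tube would render dim;
  the 0.9-voxel core covers exactly that offset and guarantees a saturated
  centreline at every tube thickness.
* **Transmission channel.** A bright background (`0.9 Imax`) with a darker
  ellipsoidal body silhouette (`0.35 Imax`, semi-axes 0.46 of each
  dimension). Centrelines are confined far enough inside the ellipsoid that
  the entire rendered tube stays within the silhouette, so every bright
  fluorescence voxel lies inside the body — the co-registration a real
  sample would show.
* **Noise.** Additive Gaussian noise (`noise_sd = 2` intensity units) on a
  background offset of 5 keeps the vessel-free floor far below `0.05 Imax`.

Generation is seeded and restores the caller's RNG state, so identical
arguments are bit-identical and never perturb a user's random stream. The
pair is cached by `ensure_dataset()` as two multi-page grayscale TIFFs
(z-ascending pages, plane 0 = most dorsal), the standard interchange format
for microscopy stacks; a corrupt or mis-sized cache is regenerated.

The default dimensions, 64×64×32 with 5 vessels, are deliberately small:
large enough that depth colour coding and occlusion are visible, small
enough that a full scripted day, including many phantom generations, runs
comfortably on one CPU. Nothing in the code assumes these values.

**What the phantom does not emulate:** optics. There is no point spread
function, no light sheet thickness, no scattering or attenuation with depth,
no photobleaching. Tests passing on this phantom therefore validate the
*control and rendering logic*, not image fidelity on a physical microscope.

## Peripherals: contracts, two tiers, injected faults

Each peripheral is an environment of closures implementing a small contract
(camera: `set_exposure`, `start_acquisition`, `snap`, `stop`, `close`;
stage: `move`, `position`; laser: `on/off/set_power/is_on`). Two tiers
implement every contract:

* the **primary simulation** scales intensities by
  `min(1, exposure / exposure_ref)`, multiplies fluorescence by the laser
  power fraction, returns only a noisy background plane when the laser is
  off, and adds seeded Gaussian read noise from a per-device RNG stream;
* the **fall-back playback tier** serves the cached phantom planes verbatim
  and ignores exposure, power and noise — its job is to keep the instrument
  *looking* functional, not to be photometrically honest.

Stage moves clamp silently at the configured bounding box. That is a
deliberate safety choice for unattended use: a visitor holding a button at a
limit must never reach an error path.

`inject_faults()` wraps any device and raises classed `hardware_error`
conditions exactly per schedule: `fail_on_init`, or `fail_after = n`
operational calls (call *n+1* raises), with `persistent` deciding whether a
close/re-initialise cycle clears the fault. Faults are raised *before* the
inner call executes, so a failed call leaves the device (and its noise
stream) untouched — which is what makes "recovered run equals no-fault run"
provable. An empty schedule is a bit-identical passthrough.

## The supervisor: modes, recovery, watchdog

`detect_hardware()` initialises every primary device; one failure switches
*all* devices to the fall-back tier. The degradation is all-or-nothing
because the instrument has a single simulating mode, not per-device
degradation — mixing a real stage with a played-back camera would render
inconsistent scenes. If a fall-back device fails too, the session is
`FATAL`: the only rendered output is an emergency screen asking for the
visitor's patience.

At runtime (state `NORMAL`), a hardware error triggers: log + notify, close
every device (best-effort; close errors are swallowed and logged),
re-initialise, then retry once. "Retry" is a side-effect-free probe of the
failing device rather than a replay of the user's action: replaying, say, a
half-finished preview move would double-move the stage, so the failed action
is discarded and the visitor simply presses again. If the probe also fails,
the session exits with code 1. One retry defines "persisted" — the smallest
policy that distinguishes a transient glitch from a dead peripheral without
stalling the exhibit in a retry loop. In `FALLBACK` there is no hardware to
re-initialise; errors are logged and the session continues.

`watchdog()` re-invokes the session while it exits with code 1 (restart),
stopping immediately on 0 (scheduled shutdown) or 2 (fatal; restarting a
hopeless instrument would loop forever, which is why fatal has its own
code). The production default cap is unbounded; tests use small caps. The
exit-code numbering itself (0/1/2) is a package choice; only the
restart-on-error semantics is architectural. Restarted sessions resume the
simulated clock at the failure time so log timestamps stay non-decreasing.

Daily operation is a schedule (`boot_time`, `shutdown_time`, defaults
08:00/18:00) evaluated against an injectable clock — `schedule_daily()` maps
a vector of clock ticks to start/shutdown actions; real power management and
the keep-window-in-foreground action (heartbeat every
`foreground_interval_s = 5` s) live behind no-op platform hooks, so desk-side
tests never touch the OS.

## Interaction: debounce, LED, dispatch

The debouncer re-implements, host-side, the filtering a microcontroller
would do at the panel. Per button independently, a switch (press *or*
release) at time *t* is accepted iff no accepted switch on that button falls
in the open window `(t − refractory, t)`; accepted presses are emitted,
accepted releases only restart the window. The refractory default is 50 ms.
The window is per button, not global: pin-level edge detection is
per-channel, and a global lockout would let one busy button mask another.
Press-edge semantics (act on press, ignore hold) is the simplest behaviour
that cannot auto-repeat into the stage limits.

The LED policy is a pure function: on iff a press (or session start)
occurred within `led_timeout_s` (default 300 s = 5 min) before `now`; the
boundary itself is off (`now − last ≥ timeout`).

`dispatch()` implements the seven-button mapping; the laser button holds the
laser for `laser_dwell_s` (default 10 s) and then releases it — an
indefinitely-on laser contradicts unattended operation, and the dwell is the
smallest surprise-free interpretation of a manual laser button.

## Rendering

Both pipelines work in normalised `[0,1]` colour and quantise to 8-bit only
on PNG export.

* **Preview.** Grey = transmission; fluorescence adds to the green channel,
  clipped at 1 (additive overlay is the simplest blend whose zero-signal
  case is *exactly* grey, which the tests assert as zero saturation). The
  plane is scaled linearly from `s_front = 1` at the front plane to
  `s_back = 0.85` at the back and drawn centred over a receding grey
  coordinate box for a 3D impression.
* **Stack.** Planes are composited back to front with the over operator,
  `out ← α·(c_z·I/Imax) + (1−α)·out`, with the squared-intensity
  transparency `α = (I/Imax)²` (the proportionality constant is fixed by
  requiring α(Imax) = 1) and one colour per plane from a pre-calculated
  depth LUT. The default LUT is a blue→red HSV hue ramp — distinct hues for
  up to 256 planes with blue = dorsal, red = ventral; any `hcl.colors`
  palette can be substituted. Resampling is bilinear about the canvas
  centre and is the exact identity at scale 1, which lets the compositor be
  checked against a per-pixel oracle at tolerance 1e−9. Acquisition sweeps
  back to front so the progressive on-screen composite grows in the same
  order it is blended.

Numerical conventions worth stating: intensities are integers 0–255
throughout acquisition; compositing happens in double precision; a
single-plane LUT maps to the colormap's 0-endpoint; degenerate ranges
(`z_min == z_max`) yield fraction 0 in the plane indicator and `s_front` as
the scale.

## Telemetry

JSONL for the action log (append-safe, recoverable line by line; malformed
lines are skipped and counted) and CSV for the website table (byte-stable:
no embedded timestamps, fixed column order). Stacks are counted from
explicit `stack_acquired` records rather than stack-button presses, so a
stack aborted by a hardware fault is not counted. The archive keeps the
*last* rendering per calendar day (last-writer-wins matches "most recent")
plus an unconditional latest snapshot. Telemetry is crash-isolated: an
unwritable sync directory buffers records in memory and flushes on
recovery, and no telemetry failure can change the supervisor state. The
button histogram counts debounced presses — raw edges would count bounce,
which the panel hardware would have filtered anyway.

## What the tests establish, and at what sizes

The suite checks every contract at small, fast sizes: phantom oracles at
20×20×10, compositor oracles on 8×8×8 stacks against a per-pixel
over-operator implementation (tolerance 1e−9), the debouncer against a
brute-force scan on ~1000 random trains up to 10⁴ events, 500 random fault
schedules driven end-to-end (every session must terminate in clean /
restart / fatal with the matching exit code), a scripted 30-day telemetry
log against an independent tally, and byte-identity of two replays of one
scripted day. `scripts/acceptance.R` repeats the headline quantities on the
default 64×64×32 phantom with a 200-press day and one injected transient
fault. These sizes were chosen so the whole suite runs in well under a
minute per property on one CPU; all algorithms are size-agnostic.

## Known limitations

* No optics: rendering fidelity on real data is out of scope.
* No GUI, serial protocol or vendor APIs — the interfaces stop where the
  manufacturer's SDK would begin.
* The fall-back tier shares the process; a crash of the R session itself is
  only covered by the (out-of-process) restart loop pattern, which the
  in-process `watchdog()` models but does not replace.
* Scripted time: sessions advance on event timestamps, not wall-clock
  callbacks, so timing races (e.g. a press during a stack sweep) cannot
  occur in simulation.
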