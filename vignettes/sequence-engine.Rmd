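---
title: "The mrforge sequence engine: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mrforge sequence engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrforge)
```

## The compilation model

An MR sequence in `mrforge` is not a list of hardware events but a
*definition*: a tree of blueprints plus a set of parameter rules. Three
element kinds exist. **Modules** give the tree its structure. **Loops**
repeat their children while an integer counter ascends; the counter is an
ordinary source node of the parameter graph, so per-iteration quantities
(a phase-encode amplitude, an RF phase, a Hadamard row) are plain rules
that depend on it. **Atomics** are flagged leaf modules; their `raw` rule
returns the hardware events of one execution block — at most one RF pulse,
up to three gradients on the logical read/phase/slice axes, at most one
ADC with its acquisition header.

Rules are pure functions with *declared dependency names* and no statement
of calculation order. Assembly resolves every dependency (local rules
first, then ancestor rules and enclosing loop counters nearest-first, then
protocol values), proves the whole graph acyclic, and stops — no hardware
event is computed at assembly time. Evaluation is lazy and cached: a
node's value is recomputed exactly when a transitive input changed. This
is what makes both long protocols (only the events near the play-out
cursor exist) and real-time adaptation (a feedback write invalidates
precisely its dependents) cheap.

The blueprint language is the host language: rules are registered R
functions. An embedded scripting language would add a parser and sandbox
without changing the contract that matters — declarative structure,
declared dependencies, pure evaluation — so the package deliberately does
not have one.

### Streaming and feedback

`block_iterator()` walks the tree depth-first, writes loop counters into
the graph as it descends, and yields blocks in strictly increasing time
with no gaps: `next$start_ns == prev$start_ns + prev$duration_ns`.
`stream_blocks()` cuts that stream into buffers of `buffer_ms` (default
100 ms; the accepted 30–300 ms range reflects what feedback applications
tolerate). Every buffer boundary is a sync point: scheduled feedback
arrivals up to that time become pending, and pending values are written
into the graph *before* any block after the boundary is built — delivered
blocks are never mutated, so an update becomes visible at latest one
in-flight buffer plus one window after it arrives. With
`sync_policy = "at_marked_atomics"` the iterator additionally applies
feedback immediately before each sync-marked atomic (slice excitations in
the library), the natural point of interest for motion correction. An
in-flight buffer is never cancelled; the contract is append-only.

The feedback service is specified at the message level: JSON objects
`{"op": "set"|"get"|"list", "name": ..., "value": ..., "timestamp": ...}`
against a `feedback_state()`. `set` acknowledges immediately and applies
at the next sync point; between sync points the last writer wins. The
reference transport in a deployed system would be a WebSocket server; the
package implements the endpoint as an in-process object
(`feedback_service()$handle`), which keeps the full contract — versioning,
atomic application, rejection of unknown names — testable and
deterministic.

## Timing conventions

* All times are integer nanoseconds stored in doubles (exact to 2^53;
  R's 32-bit integers overflow at ~2.1 s). Rasters: RF 1 µs, gradient
  10 µs, block granularity 10 µs — common vendor values.
* γ = 42.577478518 MHz/T, configurable everywhere.
* RF amplitude is scaled so the on-resonance small-tip flip equals
  `2πγ∫B1 dt`. Sinc pulses are Hanning-apodized by default — there is no
  vendor-independent definition of "the" sinc pulse, so the apodization
  and time-bandwidth product are explicit options. Pulse bandwidth is
  `TBW/duration`; the slice gradient is `G = BW/(γΔz)`.
* Realized TE is defined from the excitation pulse's isodelay point to the
  acquired echo center (first echo for RARE, center echo of the EPI train,
  spin-echo-aligned center echo for GRASE) and is held to the protocol TE
  within one gradient raster by rule-computed fill durations. Fill rules
  that come out negative raise at block build; `check_protocol()` instead
  *reports* them along with the computed minimum TE/TR, hardware-limit
  violations and RF/ADC overlaps. One solve handler is built in: a TR
  below the feasible minimum is extended to it with a warning.
* k-space bookkeeping: k resets to zero at each excitation center and is
  negated at each refocusing center (gradient-echo convention).

## The sequence library

Families share blueprints: slab/slice-selective excitation (whose RF
frequency follows the exposed `slice_offset_mm`, the hook geometry
feedback uses), refocusing with crusher pairs, spectral saturation (fat at
−3.35 ppm, water at 0), hard inversions, phase/partition encoding tables,
and trapezoidal readouts with centered ADCs. Encoding tables implement
partial Fourier (the late, center-containing portion is acquired) and
regular undersampling; the sampled non-reference count is
`⌈N·PF/accel⌉`, and an optional fully sampled center band provides
integrated reference lines (default 24 where used; positions already on
the pattern are not duplicated).

Family-specific choices worth knowing:

* **bSSFP** prepends linearly ramped preparation pulses
  (`α·(i+0.5)/n`) and alternates excitation phase by π across the whole
  train including preparation.
* **MPRAGE** nests inversion → FLASH train per partition shot; TI is
  measured inversion center → first excitation center.
* **FLAIR** splits slices into two interleaved groups (concatenations)
  within each TR, each preceded by its own inversion.
* **Diffusion EPI** schedules one b = 0 volume plus each nonzero b on each
  of three orthogonal axes (seven volumes; trace weighting happens in
  reconstruction via the geometric mean). Encoding uses one bipolar pair
  on each side of the refocusing pulse; each pair's first moment vanishes,
  so the two pairs' b-values add and each carries half the target. The
  amplitude is solved from the rasterized waveform's numeric
  `b = (2πγ)²∫(∫G)² dt` (the fixed slew-limited ramp makes b scale exactly
  with G², so the solve is closed-form and lands well inside 0.1%). The
  b = 0 volume plays zero-amplitude lobes of identical duration so all
  volumes share timing. With the bipolar scheme and a 40 mT/m limit the
  shortest TE for b = 600 s/mm² is ≈ 75 ms; the shipped preset uses
  TE = 100 ms.
* **pCASL GRASE** time-encodes seven subboli with a Walsh-ordered
  Hadamard-8 matrix (rows sorted by sign-change count; +1 labels,
  −1 controls); subbolus duration 0.4 s and post-labeling delay 0.6 s give
  inflow times 1.0–3.4 s in 0.4 s steps. Two background-suppression
  inversions are placed by numerically minimizing the residual
  longitudinal magnetization of the two stated T1 species (700/1400 ms)
  at excitation, with the inversions constrained into the post-labeling
  delay (labeling cannot be interrupted); within that constraint the
  nulling is least-squares, not exact. The readout interleaves refocusing
  pulses (one per partition encode) with EPI-like gradient-echo trains
  (one echo per phase encode), CAIPIRINHA-style 2×2 acceleration in the
  preset giving the 24 × 12 train.
* **Radial UTE** starts the ADC with the readout gradient ramp (the
  ultrashort-echo property); golden-angle directions come from the 2D
  golden means (increments 0.4656 in z, uniform in z so spherical caps are
  sampled uniformly, and 0.6823 of the azimuth). The delay-calibration
  prescan acquires 180 directions at 2° increments in each of the xy, xz
  and yz planes (540 spokes), each with a small dephaser so the echo forms
  mid-readout.
* **STEAM/PRESS** select the voxel with three orthogonal selective pulses;
  STEAM forms the stimulated echo TE/2 after the third pulse with a TM
  mixing period; PRESS splits TE as TE/4–TE/2–TE/4 around two refocusing
  pulses. Water suppression and Q2TIPS-style saturation are timing/flag
  placeholders (a spectrally selective pulse plus spoiler), not
  literature-exact pulse trains.

## The virtual scanner

The Bloch engine is an isochromat summation with the hard-pulse
approximation: shaped RF is split into sub-pulses capped at 5° *and*
10 µs (the time cap keeps concurrent gradient/off-resonance precession
finely interleaved — dropping it visibly distorts slice profiles), with
exact piecewise-linear gradient integrals and T1/T2 relaxation between
sub-pulses. Diffusion enters as a multiplicative `exp(−bD)` per contrast;
full Bloch–Torrey dynamics are out of scope. ADC samples record the
proton-density-weighted transverse sum demodulated with the ADC
frequency/phase.

Gridding follows standard practice: density compensation, convolution
onto a 2× oversampled grid with a Kaiser–Bessel kernel of width 4
(Beatty β), inverse FFT, deapodization, crop. Two implementation details
matter for accuracy: the deapodizer is the *discrete* transform of the
raster-sampled kernel (which makes a unit DC sample reconstruct an exactly
flat unit image and Cartesian data match the direct FFT to rounding), and
kernel mass is wrapped periodically at the grid edge (correct under the
FFT's implicit periodicity; with 2× oversampling the wrap lands in the
guard band). Radial density compensation is the analytic |k| ramp with a
plateau at the Nyquist radius.

Gradient delays are estimated per axis by cross-correlating each
calibration echo's magnitude with its time-reversed opposed-angle partner
(sub-sample peak via parabolic interpolation; the lag equals twice the
projected delay) and solving `τ(θ) = Δa·cos²θ + Δb·sin²θ` over all angles
of all three planes by least squares. This is a functional calibration
validated by self-consistency on simulated spokes (zero delay recovers
zero within half a dwell; 10 µs recovers within 0.1 µs), not a
re-derivation of any particular published estimator.

Registration minimizes the sum of squared intensity differences over the
six rigid parameters with a three-level multiresolution pyramid and
Nelder–Mead; identical volumes short-circuit to the identity. The
motion-correction demonstration closes the loop at the image level: each
volume is rendered in the current acquisition frame, registered to the
first volume, and the estimated residual is sent through the feedback
machinery, arriving during the next volume and applying at the following
sync point — so a step displacement at volume v is corrected from volume
v + 2 on, the same one-volume-plus-sync latency a scanner implementation
has. Severity is scored by mean voxel displacement,
`mean‖T(r) − r‖` over a voxel grid.

## Synthetic phantoms: what they do and do not show

Phantoms are analytic: ellipsoids with closed-form Fourier transforms
(sharp edges, for reconstruction tests) and Gaussian blobs (smooth
gradients, for registration). They emulate spatial structure, relaxation
and off-resonance maps, diffusion coefficients, and rigid motion with
seeded reproducibility. They do not emulate coil sensitivities (a single
uniform channel is assumed), physiological noise, susceptibility-induced
distortion, or flow — so a passing test demonstrates the correctness of
the sequence/reconstruction machinery, not in vivo image quality. The
white-matter-like ADC recovery test uses a ground truth of
0.80×10⁻³ mm²/s at SNR 50 (a realistic clinical operating point) and the
published three-b-value protocol.

## Problem sizes

Tests and the acceptance script run toy matrices (8–32 per dimension,
hundreds to ~1300 blocks per family), 40³ volumes at 5 mm isotropic for
the registration-accuracy checks (coarser 16–24³ grids for the
closed-loop demo, whose criterion is relative improvement), 36–180
calibration angles, and 1000 randomized cache-oracle operations; these
sizes were chosen so the full validation completes in a couple of minutes
while still exercising every structural feature (multi-shot trains,
concatenations, Hadamard encoding, ramp sampling). The engine itself is
size-agnostic: the in-vivo presets assemble in milliseconds because
assembly never evaluates hardware events, and streaming is constant-memory
in the buffer size.

## Known limitations

* Logical-axis export: Pulseq files carry gx/gy/gz as read/phase/slice;
  slice rotation matrices are applied by `logical_to_physical()` but not
  baked into the export. Acquisition counters require the JSON sidecar.
* The bundle format stores rule functions as source plus captured data;
  it is self-describing JSON but not byte-compatible with any other
  framework's bundle.
* SAR/PNS models, vendor drivers, SLR/adiabatic pulse design,
  spiral/PROPELLER readouts and multi-coil reconstruction are out of
  scope.
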