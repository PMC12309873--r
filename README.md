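# mrforge

Declarative MR pulse-sequence construction, real-time buffered streaming,
and a virtual-scanner validation stack — in R.

## The problem

MR pulse sequences are conventionally programmed against vendor-specific
toolchains, which makes sequences hard to exchange between sites and
scanners and rules out real-time sequence adaptation (e.g. prospective
motion correction) on most research platforms. `mrforge` implements the
alternative architecture used by modern vendor-independent sequence
frameworks:

1. **Declarative definition.** A sequence is a hierarchy of reusable
   *blueprints*: modules structure the tree, *loops* repeat branches while
   a counter ascends, and *atomics* are flagged leaf modules that compile
   to single hardware execution blocks. Physics is written as *parameter
   rules* — pure functions over other parameters and protocol values, with
   declared dependencies but no calculation order.
2. **Assembly to a parameter graph.** Assembly instantiates the element
   tree and registers every rule as a node of a directed acyclic
   dependency graph with lazily evaluated, cached values. Requesting an
   atomic's *raw representation* (its RF / gradient / ADC events plus
   acquisition header) pulls exactly the dependency closure it needs;
   caches are invalidated precisely when an input — a loop counter, a
   protocol value, a feedback parameter — changes.
3. **Chronological buffered streaming.** Blocks are produced in strict
   time order and delivered in bounded buffers of 30–300 ms of sequence
   time. Buffer boundaries (and, optionally, the moments just before
   slice excitation) are *sync points* where pending feedback-parameter
   updates are applied atomically — the mechanism behind closed-loop
   prospective motion correction. Only the current buffer is ever
   materialized, so arbitrarily long protocols stream in constant memory.
4. **Interchange and validation.** Sequences export to and import from the
   open Pulseq text format (acquisition counters travel in a JSON
   sidecar), serialize losslessly to a JSON *bundle* that keeps the
   sequence logic (not a static event dump), and run against a virtual
   scanner: an isochromat Bloch simulator, k-space trajectory computation
   (`k(t) = γ∫G dτ`), Kaiser–Bessel gridding reconstruction (2×
   oversampling, window width 4.0), gradient-delay calibration from
   plane-wise radial prescans, pixelwise ADC fitting of
   `S(b) = S₀·exp(−bD)`, Walsh-ordered Hadamard-8 ASL decoding, rigid
   volume registration and a closed-loop motion-correction demonstration
   scored by mean voxel displacement.

A library of ten sequence families is included — FLASH, bSSFP, MPRAGE,
RARE, FLAIR, diffusion-weighted spin-echo EPI, Hadamard-encoded
pCASL GRASE, 3D radial UTE with golden-angle sampling, and STEAM/PRESS
single-voxel spectroscopy — built from shared excitation / encoding /
readout / inversion / saturation / labeling blueprints, together with the
whole-brain measurement protocols they were demonstrated with.

## Worked example

```r
library(mrforge)

p <- mr_protocol(TR_ms = 12, TE_ms = 5, flip_deg = 10,
                 fov_mm = c(128, 128, 32), matrix_size = c(16L, 8L, 2L))
seq <- build_sequence("flash", p)
print(describe_sequence(seq))
#> <flash> 64 blocks, 16 readouts, 0.192 s
#>   min TE: 1.310 ms
#>   min TR: 6.110 ms

st <- stream_blocks(seq, runtime_config(buffer_ms = 100))
writeLines(head(dump_blocks(st$blocks), 3))
#> t=       0.000ms dur=    1.240ms RF[excitation 10.0deg f=+0Hz ph=0.00] Gsl[+2.94mT/m trap] Gsl[-14.97mT/m trap] SYNC
#> t=       1.240ms dur=    3.690ms
#> t=       4.930ms dur=    1.180ms Gre[-8.31mT/m trap] Gph[-2.04mT/m trap] Gsl[-2.04mT/m trap] Gre[+18.35mT/m trap] Gre[+25.34mT/m trap] Gph[+2.04mT/m trap] Gsl[+2.04mT/m trap] ADC[16x10.0us lin=0 par=0 slc=0 avg=0 ctr=0]
```

The 16×8×2 toy FLASH compiles to 64 blocks (excitation, echo-time fill,
readout, repetition fill per TR), each readout carrying its phase/partition
counters in an ISMRMRD-style acquisition header; the first excitation is a
sync point for geometry feedback. The derived minimum TE/TR come from the
assembled event durations.

Protocol arithmetic of the shipped in-vivo presets:

```r
scan_duration(build_sequence("steam", protocol_preset("steam")))
#> [1] 196                      # (2 prescans + 96 averages) x 2.0 s = 3:16
asl_inflow_times(asl_spec())
#> [1] 3.4 3.0 2.6 2.2 1.8 1.4 1.0   # PLD 0.6 s + k x 0.4 s subboli
```

Real-time feedback, Pulseq export, and the virtual scanner:

```r
state <- feedback_state(exposed = list(slice_offset_mm = "protocol.slice_offset_mm"))
fb_schedule(state, 0.05e9, "slice_offset_mm", 10)   # arrives at t = 50 ms
st <- stream_blocks(seq, runtime_config(buffer_ms = 30), feedback = state)
# blocks after the next sync point excite the shifted slice

export_pulseq(seq, file = "flash.seq")              # + flash.labels.json sidecar

ph  <- phantom_gaussians(5, seed = 1)
est <- rigid_register(phantom_render(ph, 24, transform = rigid_transform(c(3, 0, 0))),
                      phantom_render(ph, 24), voxel_mm = 200 / 24)
```

A command-line front end (`inst/scripts/mrforge.R`) wraps the same
functions: `build`, `describe`, `stream` and `export-pulseq` over protocol
and bundle JSON files.

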