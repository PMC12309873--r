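Package: mrforge
Title: Declarative MR Pulse Sequence Construction, Real-Time Streaming,
    and Virtual Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building magnetic-resonance pulse sequences from
    reusable declarative blueprints. Sequences are assembled into an
    element hierarchy (modules, loops, atomics) plus a lazily evaluated,
    cached parameter dependency graph, compiled to a vendor-independent
    hardware-event representation (RF, gradient, ADC events with
    acquisition headers), and streamed chronologically in bounded time
    buffers with sync points for real-time feedback such as prospective
    motion correction. Includes a library of standard sequence families
    (FLASH, bSSFP, MPRAGE, RARE, FLAIR, spin-echo EPI diffusion,
    Hadamard-encoded pCASL GRASE, 3D radial UTE, STEAM, PRESS),
    bidirectional Pulseq text-format interchange, and a virtual-scanner
    validation stack: Bloch simulation against digital phantoms, k-space
    trajectory computation, Kaiser-Bessel gridding reconstruction,
    gradient-delay calibration, apparent-diffusion-coefficient mapping,
    Hadamard decoding, rigid registration and a closed-loop
    motion-correction demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    codetools,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
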