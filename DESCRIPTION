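Package: laminarwave
Title: Laminar Neural-Field Simulation of Traveling Waves of Orientation
    Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and closed-form analysis toolkit for a bilaminar
    neural-field model of primary visual cortex, in which an
    orientation-independent deep layer supports a traveling activity front
    that drives orientation-tuned bump activity in a superficial layer of
    coupled hypercolumn ring networks. Provides exact (Heaviside-limit)
    front speeds for exponential kernels, an implicit-equation speed solver
    for arbitrary kernels, Amari bump existence and stability analysis on
    the orientation ring, FFT-based forward-Euler integrators for the
    coupled model in one and two spatial dimensions (including anisotropic
    long-range horizontal connections), and diagnostics for interface
    tracking, wave-speed estimation, bump-phase extraction and the
    quiescent/queuing/integrating/bump decomposition of the wave profile.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
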