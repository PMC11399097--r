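Package: trwaxs
Title: Time-Resolved Wide-Angle X-Ray Scattering Analysis for MHz Pulse Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for microsecond time-resolved wide-angle X-ray
    scattering (TR-WAXS) recorded as alternating light/dark pulse trains at a
    MHz-repetition-rate free-electron laser. Provides a synthetic pulse-train
    generator with Poisson photon noise and train-level common-mode jitter,
    detector-image reduction with correlation-based train filtering and
    light-minus-dark difference computation, global kinetic decomposition of
    difference scattering into sequential-model basis spectra by variable
    projection, Debye-formula scattering profiles and radii of gyration from
    atomic models, and absolute-scale structural ensemble fitting with
    photoactivation-yield selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
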