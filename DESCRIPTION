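Package: starperf
Title: Stack-of-Stars First-Pass Myocardial Perfusion MRI Simulation and
    Spatio-Temporal Constrained Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for free-breathing three-dimensional
    first-pass myocardial perfusion MRI based on stack-of-stars (hybrid
    radial-Cartesian) sampling. Generates dynamic contrast-enhanced cardiac
    phantoms with tracer-kinetic signal models, inducible hypoperfusion
    defects of graded severity, respiratory motion and ECG mis-triggering;
    encodes them with multicoil golden-angle stack-of-stars trajectories;
    reconstructs by density-compensated gridding or by iterative
    spatio-temporal total-variation constrained reconstruction (STCR) with
    L-curve regularisation-weight selection; and reads the results as AHA
    16-segment signal-time curves with automatic discrimination of transient
    dark artefacts from persistent perfusion defects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    rhdf5,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
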