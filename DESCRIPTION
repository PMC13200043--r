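Package: chainflow
Title: Simulation of Rotating Magnetic Nanochain-Enhanced Lateral Flow
    Immunoassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coupled reaction-transport simulators for lateral flow
    immunoassays enhanced by rotating magnetic nanochains.  A microscale
    model solves steady creeping (Stokes) flow stirred by rigidly rotating
    nanochains in a square fluid domain and transient antigen
    advection-diffusion with Langmuir-type uptake on the chain surfaces,
    yielding antigen-removal curves versus rotation frequency.  A
    porous-membrane model combines an analytical Lucas-Washburn wetting
    front, Darcy flow and a three-species cooperative capture network
    (mobile nanochains, immobilised antibodies, immobilised complexes) on
    a nitrocellulose strip with a test line, yielding capture totals and
    spatial-asymmetry metrics over parametric sweeps.  Capture-efficiency
    data-analysis helpers, a structured configuration format, fixture
    generation and CSV/VTK export are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
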