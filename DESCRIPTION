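Package: ocperfusion
Title: Microenvironment Simulation for Dual-Chamber Osteochondral
    Perfusion Bioreactors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the steady perfusion microenvironment inside a
    dual-chamber bioreactor holding an additive-manufactured bilayered
    osteochondral scaffold. Provides a parametric lattice-scaffold and
    chamber geometry generator with voxelization, a synthetic micro-CT
    pathway (printing-artifact injection, grayscale rendering, bilateral
    smoothing, Otsu segmentation) emulating the CAD-versus-manufactured
    geometry discrepancy, a staggered-grid Stokes-Brinkman flow solver
    with solid penalization, a hybrid upwind/central advection-diffusion
    solver for differentiation-media mixing, fluid-induced shear stress
    estimation on strut surfaces, per-layer microenvironment reporting,
    and classification against literature-derived effective
    chondrogenic/osteogenic culture regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
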