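Package: aneuscale
Title: Aspect-Ratio Scaling of Intracranial Aneurysm Models and
    Bernoulli Energy-Loss Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for longitudinal, aspect-ratio-controlled resizing of an
    intracranial aneurysm sac on a fixed parent vessel, and for the
    hemodynamic energy-loss metrics used to compare the with-aneurysm and
    pre-aneurysm conditions. Provides STL surface-mesh input/output,
    neck-plane mesh splitting and hole capping, aneurysm morphometry
    (perpendicular height, neck diameter, aspect ratio, sac volume), a graded
    sac-scaling transform that leaves the parent artery and neck unchanged,
    pre-aneurysm vessel reconstruction, Bernoulli energy-loss computation
    from inlet/outlet plane flow series with Reynolds-number
    characterization, and deterministic synthetic sidewall-aneurysm and
    pulsatile-flow generators for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
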