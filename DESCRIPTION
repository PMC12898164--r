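Package: hbspec
Title: Hemoglobin Spectroscopy, Oxygen Affinity and Binding Kinetics Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of hemoglobin-ligand preparations from
    optical and biophysical assays: four-wavelength spectrophotometric
    quantification of oxy-, deoxy- and methemoglobin, full-spectrum
    least-squares deconvolution with baseline and Rayleigh-type scattering
    correction, deoxygenation and autoxidation time courses, hydroxyl-radical
    scavenging clearance, oxygen-dissociation-curve (Hill/P50/Bohr) analysis,
    1:1 Langmuir fitting of surface plasmon resonance sensorgrams, and
    consistency auditing of MM/GBSA binding free-energy tables. Includes a
    seeded synthetic-data generator with recorded ground truth for every
    assay, and a reproducible pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
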