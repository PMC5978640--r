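Package: tomoqa
Title: Automated Image-Quality Analysis for a Digital Breast Tomosynthesis QA Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated quality-assurance analysis of reconstructed digital
    breast tomosynthesis (DBT) volumes of a multi-purpose QA phantom:
    phantom pose (roll, pitch, yaw) from alignment markers, chest-wall
    offset (missing tissue) from stair-step gauges, slice sensitivity
    profiles and slice width (FWHM) from folded bead ramps, slice
    incrementation, z-axis geometry from aluminum beads, artifact spread
    functions, in-plane PSF/MTF from bead point sources, regional and
    global uniformity, SNR and CNR over an aluminum square, noise-versus-mAs
    power-law fitting, and a contrast-detail noise model from low-contrast
    spheres. Includes a synthetic phantom-volume simulator with ground-truth
    records so the entire pipeline is testable without scanner data, readers
    and writers for multi-frame DICOM and TIFF+JSON volumes, and a
    consolidated machine-readable QA report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
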