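Package: faceasym
Title: Landmark-Based Quantification of Three-Dimensional Facial Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes a coordinate-system-free, signed facial asymmetry index
    per anatomical landmark from 3D-CT landmark coordinates. The index is the
    root-sum-of-squares of distance differences from fixed cranial reference
    landmarks (sella, nasion, MidZ for bilateral pairs; the Z-point and porion
    pairs for midline landmarks), signed positive for leftward and negative
    for rightward deviation. Includes packaged normative reference ranges with
    a symmetry classification rule, the menton-to-midsagittal-plane cohort
    screen, Dahlberg method-error and paired-t reliability statistics, a
    synthetic landmark generator with controllable asymmetry for testing,
    polygonal (radar) chart rendering, pre/post-surgical comparison reports,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
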