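Package: oxyhsi
Title: Hyperspectral Blood Oxygen Saturation Mapping with Reflective and
    Transmissive Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo photon transport in layered tissue models with
    reflective and transmissive hyperspectral detection, and a modified
    Beer-Lambert / non-negative least-squares pipeline that converts
    23-band hyperspectral image stacks into per-pixel oxygen saturation
    (SO2) maps, SO2 dynamics during hypoxia, and concentric-annulus
    quantification around growing tumors. Includes synthetic phantom
    generators (intralipid slab with an embedded blood-filled capillary)
    and drivers for vessel-depth and detection-sensitivity studies
    comparing the two detection geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
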