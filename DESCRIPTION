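Package: fossilbracket
Title: Bracketing Lineage Divergence Times with Fossil Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for converting fossil occurrence data into calibration
    brackets on lineage divergence times. Robust minimum age constraints are
    derived from apomorphy-bearing first appearance data (FADs); soft maximum
    constraints are estimated with classical stratigraphic confidence
    intervals on ranges of fossil localities, with extensions for
    thickness-transformed axes and nonuniform fossil recovery potential, a
    paleontologically parameterized lognormal prior on the gap between the
    FAD and the true time of origin, taphonomic-control-group brackets,
    super-taxon projection of multiple FADs onto an uncalibrated ultrametric
    tree, and a budding birth-death simulator of clade growth and fossil
    sampling for validating coverage and quantifying missing basal history.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
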