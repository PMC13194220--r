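Package: osteoplate
Title: Automated Osteosynthesis Plate Placement for Distal Radius
    Osteotomy Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Plans the position of a volar osteosynthesis plate on a
    segmented distal radius for corrective osteotomy surgery.  Reads bone
    and plate surface meshes (STL), standardizes their anatomical
    coordinate frames by principal-axis analysis, extracts the osteotomy
    planes, midplane, alignment line and watershed line, computes a
    deterministic initial plate pose, and refines it by bounded
    quasi-Newton minimization of a penalty objective combining
    plate-to-bone distance, corner distances, mesh penetration, axis
    alignment and shaft centering.  Includes placement-comparison metrics
    (unpaired maximum Hausdorff distance, total 3D rotation and
    translation) and a parametric synthetic radius/plate generator with
    analytic ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
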