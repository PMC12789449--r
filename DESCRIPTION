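Package: implacc
Title: Accuracy Analysis for Guided Dental Implant Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how accurately dental implants were placed
    relative to a virtual surgical plan. Reads planned and post-placement
    implant meshes (binary or ASCII STL), extracts implant poses (coronal
    centre, apical centre, long axis), rigidly registers scans (Kabsch and
    iterative closest point), infers sub-gingival implant positions from
    scan-body scans, computes the standard guided-surgery deviation metrics
    (coronal and apical 3D deviation, angular deviation), and reproduces the
    SPSS-style two-group comparison (group summaries, Levene screen, Student
    and Welch t tests). A hierarchical synthetic-study generator with shared
    per-guide and independent per-implant error components makes the whole
    pipeline testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
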