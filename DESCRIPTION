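Package: clawfsa
Title: Functional-Space Analysis of Claw Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative functional morphology of claws (unguals):
    read, measure and scale tetrahedral claw meshes; solve three standardized
    linear-elastic load scenarios (scratch-digging, hook-and-pull, piercing)
    with a constant-strain tetrahedral finite-element solver; quantify von
    Mises stress fields with the intervals method; ordinate interval vectors
    by principal component analysis into a two-dimensional functional space;
    build per-specimen functional triangles with area, centroid, and signed
    side-length divergence metrics; and regress functional performance
    against claw shape ratios and size. A parametric claw-mesh and stress
    simulator makes the whole pipeline testable without scan data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
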