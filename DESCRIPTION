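Package: porescope
Title: Geometric and Functional Annotation of Ion Channel Pores
Version: 0.1.0
Authors@R:
    person("porescope", "developers", email = "porescope@example.org",
           role = c("aut", "cre"))
Description: Structural and functional annotation of ion channel permeation
    pathways. A spherical probe is swept through a hard-sphere model of the
    protein to trace the pore, the probe centres are interpolated into an
    arc-length parameterized centerline spline, and particle positions are
    mapped into curvilinear pathway coordinates. From solvated structures or
    trajectories the package estimates a one-dimensional water density by
    kernel density estimation and Boltzmann-inverts it into a free-energy
    profile of pore hydration, enabling the detection of hydrophobic gates
    that do not sterically occlude the pore. Pore-lining and pore-facing
    residues are classified from pathway coordinates and combined into
    kernel-smoothed hydrophobicity profiles using bundled amino-acid
    hydrophobicity scales. A synthetic-pore fixture generator with analytic
    ground truth supports validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
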