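Package: coilspect
Title: Coiled-Coil Geometry, Packing, Crosslink and Assembly Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization pipeline for alpha-helical coiled-coil bundles,
    built around the heterotetrameric honeybee silk system. Generates ideal
    two- to four-helix bundles from Crick parameters with threaded heptad
    registers and known ground truth; fits superhelical axis, radius, pitch,
    handedness, chain orientations and heptad register from atomic
    coordinates; detects knobs-into-holes core packing and interhelical salt
    bridges; maps crosslinking mass-spectrometry restraints with linker
    distance cutoffs; computes per-heptad-position composition statistics;
    analyses circular dichroism spectra and two-state thermal melts; and
    models stepwise hetero-oligomer assembly stoichiometry with size-exclusion
    profile prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
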