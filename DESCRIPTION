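Package: cgdamage
Title: Coarse-Grained Direct Radiation Damage Modelling for DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating direct (non-radical) radiation damage to
    DNA from first principles. Builds three-bead coarse-grained models
    (phosphate, deoxyribose, base) from atomic DNA coordinates, derives
    per-bead strand-break threshold energies from Morse and Lennard-Jones
    pair potentials of the underlying atomic clusters, scores stochastic
    energy-deposition events against those thresholds inside a spherical
    water phantom, classifies the resulting strand breaks into single- and
    double-strand break subtypes with a 10-base-pair clustering rule, and
    fits supercoiled/open-circular/linear plasmid dose-response data with
    the McMahon model to quantify experimental strand-break yields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
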