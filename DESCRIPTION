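Package: helixkink
Title: Kink Angles in Alpha-Helices with Confidence Intervals and
    Conservation Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures kink angles in protein alpha-helices by fitting
    cylinders to six-residue backbone segments and taking the angle between
    the axes of adjacent segments. Attaches a heuristic 95 percent
    confidence interval to every angle, predicted from the quality of the
    two flanking cylinder fits and calibrated by a Monte-Carlo perturbation
    simulation. Classifies kink conservation across homologous helix pairs
    and aligned helix families (Conserved Straight, Conserved Kinked, Not
    Conserved, Other), with supporting sequence-identity and per-site
    correlation statistics. Includes a parametric synthetic-helix generator
    so the whole pipeline is testable without external structure downloads,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
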