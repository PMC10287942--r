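Package: phageject
Title: Directionality of Bacteriophage DNA Ejection: Simulation and
    Single-Molecule Orientation Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study which end of a packaged phage genome leaves the
    capsid first (first-in-first-out versus last-in-first-out). Provides a
    coarse-grained Langevin-dynamics simulator of a bead-spring DNA chain
    packaged into, resting in, and ejecting from a spherical capsid through a
    narrow portal channel; ensemble statistics over ejection trajectories
    (pathway probabilities with Wilson intervals, converged ejection fractions,
    energy-versus-ejection landscapes); a sequence-composition model that maps
    GC content to region persistence lengths and bending constants; an
    orientation caller that assigns ejection direction to one-dimensional
    AT-stain intensity profiles of stretched molecules by Pearson correlation
    against expected genome barcodes; and a synthetic-data generator producing
    block-composition genomes and noisy molecule profiles with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
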