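Package: oliveSI
Title: Self-Incompatibility Modeling for the Olive Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive tools for the two-locus sporophytic self-incompatibility
    system of the olive tree (Olea europaea L.). A di-allelic screen at the
    stigma (two S-alleles, two compatibility groups) is followed by a
    poly-allelic screen at the ovary (six S-alleles under a dominance
    hierarchy), and time-dependent degradation of S-determinants turns
    categorical incompatibility into allele-dependent leakage that permits
    selfing and late fruit set. The package predicts cross verdicts, builds
    the full stigma-by-pollen compatibility matrix, computes mate-availability
    probabilities against variety-frequency panels, simulates orchard
    pollination seasons with father attribution, diagnoses paradoxical
    paternity-test results, and infers S-genotypes from diallel cross-outcome
    tables by constraint search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
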