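Package: codeAdapt
Title: Adaptability Landscape of the Genetic Code via a Niching Genetic
    Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to explore the error-minimization fitness landscape of
    hypothetical genetic codes. Generates alternative codes under a
    restrictive model (amino acid permutations over the canonical codon
    blocks) and an unrestrictive model (free codon assignments with three
    stop codons), scores them with the mean squared change in polar
    requirement under single-base substitutions (MS) and its
    transition/transversion and mistranslation weighted variant (tMS),
    evolves populations of codes with a genetic algorithm that supports
    fitness sharing (niching), and quantifies the canonical code's position
    in the landscape through distances to the canonical code,
    inter-distance histograms, canonical-code survival, random-code
    statistics and the percentage distance minimization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
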