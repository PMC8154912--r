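Package: codonDistortion
Title: Codon-Usage-Weighted Mutational Robustness of the Genetic Code
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the expected physicochemical distortion of the standard
    genetic code under a two-parameter (transition/transversion) background
    mutation model, weighted by per-taxon codon usage extracted from coding
    sequences. Four amino-acid property scales (polar requirement, hydropathy,
    molecular volume, isoelectric point) yield four distortion measures per
    taxon, which are regressed on GC-content and environmental optima
    (temperature, NaCl, pH) by phylogenetic generalized least squares under a
    Brownian-motion covariance. Includes a synthetic-data generator (Yule
    trees, Brownian traits, codon usage with planted environmental effects)
    for end-to-end validation, and a file-based pipeline over FASTA, Newick
    and TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
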