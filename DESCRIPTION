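Package: cpspec
Title: Quantitative Peptidomics Profiling of Carboxypeptidase Substrate
    Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for determining the substrate specificity of
    metallocarboxypeptidases from multiplex stable-isotope (TMAB)
    quantitative peptidomics experiments. Includes monoisotopic peptide
    mass and b/y fragment chemistry with identification-acceptance
    filters, grouping of LC-MS features into isotopic-label multiplets,
    enzyme/no-enzyme intensity ratio quantification, threshold
    classification of substrates and products, P1/P1' cleavage-site
    frequency profiling, Michaelis-Menten kinetic fitting for
    fluorogenic substrate assays, in-silico tryptic digestion, and a
    synthetic-data generator that simulates sequential C-terminal
    exopeptidase digestion and full multiplex LC-MS experiments with
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
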