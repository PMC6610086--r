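Package: crisparray
Title: Design and In Silico Assembly of Modular One-Pot CRISPR Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for designing multi-spacer CRISPR arrays that are built
    by one-pot Golden-Gate-style assembly through junctions placed in the
    trimmed, non-hybridizing ends of spacers. Covers junction/overhang set
    validation and proposal, repeat-spacer unit and annealing-oligo design for
    Cas9-, Cas12a- and Cas13a-family nucleases (including composite
    multi-nuclease arrays and combinatorial libraries), simulation of Type IIS
    digestion and cyclic ligation with misassembly enumeration, crRNA
    biogenesis simulation including extraneous terminal-repeat crRNAs,
    secondary-structure risk screening of transcribed arrays by a
    maximum-pairing dynamic program with Boltzmann pair probabilities, and
    amplicon-based quantification of array-library abundance uniformity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
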