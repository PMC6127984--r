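Package: adratio
Title: Coverage-Based Assignment of Genome Scaffolds to Autosomes and the
    Z Sex Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns nuclear genome scaffolds of ZW-system species (males ZZ,
    females ZW) to autosomes, the Z chromosome, or the W chromosome by
    comparing standardized whole-genome sequencing depth between male and
    female libraries (the AD-ratio: male/female depth, with expectation 1 for
    autosomes, 2 for Z, 0 for W). Implements parsing of Popoolation2
    "synchronized" allele-count files, per-scaffold mean-depth aggregation
    normalized by mapped-read counts, a replicate-concordance rule that flags
    scaffolds with irreproducible ratios as ambiguous, a minimum mean-depth
    filter that leaves poorly covered scaffolds un-annotated, an a posteriori
    concordance check against genes of known chromosomal location, and a
    synthetic ZW depth simulator with overdispersed count noise so the whole
    pipeline runs and is testable without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
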