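Package: clonespect
Title: Mutational Signature Dissection from Clonally Expanded Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects per-compound mutational signatures from variant calls of
    clonally expanded mutant genomes. Implements colony-exclusive variant
    selection within joint-calling groups, parental-variant removal,
    COSMIC-style SBS96 / DBS78 / ID83 channel classification (trinucleotide
    context with pyrimidine strand collapsing, adjacent-SNV doublet merging,
    homopolymer / repeat / microhomology indel binning), control-spectrum
    subtraction, replicate aggregation, and cosine-similarity matching
    against reference signature catalogs. Includes a synthetic
    clonal-expansion experiment simulator with per-mutation ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
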