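Package: tarisa
Title: Taxon-Targeted ARISA Community Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for taxon-targeted automated ribosomal intergenic spacer
    analysis (ARISA) of diatom communities. Predicts diagnostic ITS2 fragment
    lengths from reference sequences amplified in silico with degenerate IUPAC
    primers, converts capillary-electrophoresis peak tables into taxon-binned
    relative-abundance matrices, computes Shannon-Wiener diversity and Pielou
    evenness, compares communities by Bray-Curtis dissimilarity with
    group-average (UPGMA) clustering and non-metric multidimensional scaling,
    and links community structure to environmental gradients via Spearman
    correlation matrices and exhaustive-subset BIOENV/BEST selection with
    permutation testing. Includes a synthetic-data generator for mixed-species
    peak profiles with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vegan,
    ape,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
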