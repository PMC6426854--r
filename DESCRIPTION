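Package: dairytrace
Title: Tracing Bacterial Taxa and Strains Across a Dairy Production Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for following bacterial taxa and individual strains along
    a raw-milk cheese production chain (cow feces, litter, milk, fresh
    cheese). Implements prevalence-based shared-taxon and shared-OTU
    analysis with core-microbiota tables, alpha diversity (Chao1, Shannon,
    rarefaction), selection of strain marker contigs from metagenomic
    assemblies, strain-specific primer design with exact-substring
    specificity screening and in-silico PCR, strict (100% identity, 100%
    coverage) read-mapping presence calls, SNP allele-frequency profiles
    with pairwise distances and same-strain decisions, fragment-based
    average nucleotide identity, and an RPKM fold-change expression screen.
    A synthetic-data module generates communities, strain genomes, and read
    sets with planted transmission structure so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    tools,
    vegan,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
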