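Package: bacuchar
Title: Baculovirus Genome Characterization and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotation and comparative analysis of circular baculovirus
    genomes. Enumerates open reading frames on circular dsDNA genomes and
    applies evidence-based annotation filters; discovers homologous regions
    (hrs, clusters of imperfect palindromic repeats) and intergenic tandem
    direct-repeat regions (drs); detects cross-genome homology blocks
    diagnostic of interspecies recombination; computes Kimura two-parameter
    pairwise distances with the 0.05 substitutions/site species-demarcation
    criterion; filters and classifies intra-isolate sequence variants; and
    generates synthetic genomes with known truth for validation. Reports are
    produced per genome (characterization) and per genome pair (comparison).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
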