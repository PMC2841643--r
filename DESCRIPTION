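Package: metaprof
Title: Community Profiling and Functional Potential Analysis for Shotgun Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for profiling chemotrophic microbial
    communities from shotgun metagenome sequence: best-nucleotide-hit
    taxonomic binning with percent-identity banding, fragment recruitment
    and fold-coverage estimation, oligonucleotide word-frequency principal
    component analysis of assemblies, six-frame open-reading-frame candidate
    extraction with greedy dereplication, pathway completeness and activity
    scoring against a reaction database using reaction specificity weights,
    and a rule-based marker-gene screen with false-positive elimination.
    Includes a synthetic shotgun-community generator (Markov or GC-setpoint
    genome composition models, paired Sanger-style reads, planted pathway
    content and marker genes) so every stage is testable against known
    ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
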