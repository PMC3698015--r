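Package: nucleoscope
Title: Nucleosome Architecture Around RNA Polymerase III Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for nucleosome positioning around
    short RNA polymerase III transcribed genes (tDNAs) in budding yeast.
    Generates synthetic genomes with planted chromatin architecture (positioned
    upstream nucleosome, nucleosome-free region over the gene, variable
    downstream nucleosome, phased upstream array), simulates MNase tiling-array
    and MNase-seq readouts and pol III ChIP-seq with multi-mapping reads, and
    recovers the architecture via hidden-Markov-model segmentation, kernel peak
    calling, strand-aware meta-gene profiling, differential chromatin
    classification across condition presets, and occupancy/transcription
    correlation including relative qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
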