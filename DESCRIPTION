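Package: gbskit
Title: Genotyping-by-Sequencing Simulation, Demultiplexing, SNP Calling and
    Population Genetics
Version: 1.0.0
Authors@R: person("GBS", "Maintainer", email = "gbskit@example.org",
    role = c("aut", "cre"))
Description: A reduced-representation sequencing (genotyping-by-sequencing,
    GBS) toolkit: in-silico restriction digestion and fragment-size
    profiling, barcode demultiplexing with cut-site remnant checking,
    64-nt sequence-tag counting, reference-anchored SNP discovery and
    genotyping with the mnMAF/mnF/call-rate filter cascade, downstream
    population-genetic summaries (minor allele frequency spectra,
    heterozygosity, allele-sharing distances, neighbor-joining trees,
    per-chromosome marker density), read-depth copy-number scanning, and
    a fully specified synthetic multi-breed experiment generator with
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
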