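Package: sangermeta
Title: Concordance of Sanger Sequencing and HTS Metabarcoding for
    Dominant Symbiont Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing conventional
    Sanger sequencing with high-throughput amplicon metabarcoding when
    profiling intrathalline lichen photobionts (Trebouxia green algae).
    Generates panels of closely related ITS haplotypes, per-thallus
    photobiont communities, multinomial read-count tables and
    mixed-template Sanger chromatograms; applies standard OTU-table
    abundance and prevalence filters with an optional predominant-taxon
    rescue rule; calls bases from chromatograms with the 25%
    secondary-peak IUPAC ambiguity rule; assigns called sequences to OTU
    references by global-alignment percent identity with 95%/99%
    acceptance criteria; and summarises per-abundance-category sequencing
    success and Sanger-vs-metabarcoding concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
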