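Package: evrny5
Title: Simulation and Analysis of RNY5 Fragment Cargo in Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying how the 83-nt RNY5 Y RNA is
    processed into 23/29/31-nt fragments and selectively packaged into
    extracellular vesicles (EVs). Provides the printed RNY5 oligonucleotide
    set with motif and perturbation operations, a synthetic small RNA-seq
    library generator with pseudogene decoy loci and declared truth, a
    deterministic brute-force short-read aligner honouring a five-mismatch /
    ten-locus mapping contract, union-mode unique-mapper gene counting with
    reads-per-million normalisation, RNA-family abundance and EV-versus-cell
    enrichment tables, transcript-coordinate fragment start/stop profiling
    with pseudogene-aware multimapper attribution, a rule-based in vitro
    processing simulator, and two-channel flow-cytometry cell-death gating
    with condition comparison and dose-response summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    dplyr,
    rlang,
    tibble,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
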