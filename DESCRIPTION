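Package: resistamp
Title: Targeted Amplicon Sequencing Toolkit for Insecticide-Resistance Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for dual inline-barcode amplicon
    sequencing assays used in molecular surveillance of insecticide
    resistance in Anopheles funestus mosquitoes. Demultiplexes pooled
    paired-end reads by 8-bp forward/reverse barcode combinations, trims
    barcodes, primers and low-quality tails, assigns reads to panel
    amplicons by primer, aligns them with a banded glocal affine-gap
    aligner, builds base-quality-filtered pileups, calls and filters
    variants (allele depth >= 20, base Phred > 30), classifies genotypes
    from alternate-allele fractions (hom-ref < 20%, het 20-80%,
    hom-alt > 80%), annotates codon-level consequences against the panel
    CDS maps, matches known resistance markers (kdr, ace-1 N643I/N485I,
    rdl A296S, GSTe2 L119F, the CYP6P9a promoter 2-bp insertion), builds
    depth-masked consensus sequences, and computes population-genetic
    summaries: nucleotide and haplotype diversity, per-site diversity,
    linkage disequilibrium r-squared, Weir-Cockerham Fst, minimum-spanning
    haplotype networks and percent-identity species assignment. A
    synthetic-cohort simulator with truth tables makes every stage
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    igraph,
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
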