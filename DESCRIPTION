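Package: satseeker
Title: Discovery, Verification and Quantification of Polyadenylated
    Pericentromeric Satellite (HS2/HS3) Transcripts in Unstranded RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting human pericentromeric satellite
    (HS2/HS3) transcripts in unstranded RNA-seq data: oligonucleotide
    half-probe exact-match screening of assembled contigs, polyA-tail
    verification by re-anchoring untrimmed reads, greedy centroid clustering
    with center-star consensus calling, strand-agnostic k-mer
    equivalence-class EM quantification (TPM), ATTCC/GGAAT motif annotation
    with satellite block segmentation and in-silico PCR, 2^-ddCt qPCR
    arithmetic with reference-gene stability checks, and a synthetic-data
    generator that emulates HS2/HS3 array structure, polyadenylated
    transcripts, unstranded error-bearing reads and paired GV/MII donor
    panels with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
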