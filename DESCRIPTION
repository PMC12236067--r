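Package: sorfkit
Title: Discovery and Evidence Tiering of Small ORF-Encoded Proteins
Version: 0.1.0
Authors@R: person("sorfkit", "developers", role = c("aut", "cre"),
    email = "sorfkit@example.org")
Description: An integrated proteogenomic toolkit for discovering small open
    reading frames (sORFs) and the proteins they encode (SEPs) from transcript
    annotations. Builds a candidate ORFome by three-frame enumeration of
    AUG-initiated ORFs with nonsense-mediated-decay (50-nt rule) filtering and
    biotype assignment; classifies evolutionary conservation against a
    per-base score track with cutoffs derived from canonical coding sequence;
    tiers ribosome-profiling evidence by recurrence across samples and
    datasets with per-ORF negative-binomial dispersion fits; aggregates
    peptide-spectrum-match evidence with canonical-proteome mismatch
    filtering; performs differential-abundance analysis of intensity matrices
    with probabilistic quotient normalization and left-censored Gibbs
    imputation; and maps disease variants and GWAS SNPs onto ORF genomic
    structures with coding-consequence annotation. Ships a synthetic-data
    generator with a planted-truth ledger so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
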