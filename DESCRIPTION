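Package: cryptomap
Title: Proteogenomic Discovery and Characterization of Cryptic MHC Class I Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a proteogenomic workflow for discovering MHC class
    I-associated peptides (MAPs) translated from non-canonical reading frames.
    Builds a personalized canonical-proteome (control) database and an
    all-frames peptide database by six-frame sliding-window translation of raw
    RNA-seq reads with seen-count (S-value) filtering, optimizes joint
    search-score/MHC-affinity thresholds at a fixed target-decoy FDR, splits
    identifications into conventional and putative cryptic MAPs, locates and
    classifies peptide-coding regions by genomic origin (UTRs, out-of-frame
    exons, introns, junctions, antisense, intergenic), predicts source-protein
    ORFs with Kozak-context start-codon rules, scans 3'UTRs for stability
    elements, and runs the downstream immunopeptidome statistics. A synthetic
    fixture generator with planted ground truth makes every stage testable at
    toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
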