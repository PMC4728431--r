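# cryptomap

Proteogenomic discovery and characterization of **cryptic MHC class
I-associated peptides (MAPs)** — peptides presented to CD8 T cells but
translated outside canonical reading frames: 5'/3' UTRs, introns, UTR–exon
and intron–exon junctions, antisense and intergenic transcripts, and
out-of-frame exonic reading. The package is aimed at immunopeptidomics /
proteogenomics analysts who have RNA-seq reads, a peptide-spectrum-match
(PSM) table from a search engine, and predicted MHC-binding affinities, and
want to find and characterize the cryptic fraction of the immunopeptidome.

## Method

Two personalized databases are built from the subject's own data:

* **Control database** — subject variants are integrated into the reference
  genome and every annotated CDS is translated in its canonical frame: the
  personalized proteome.
* **All-frames database** — every read is translated in all six reading
  frames with a 33-bp sliding window (1-nt step; 33 = 3 × 11, the maximum
  MAP length). Products shorter than 8 residues (stop codon inside the
  window) are excluded. Each peptide gets an *S-value* (seen-value), the
  number of times it was produced across all reads/offsets/strands, and
  only peptides with **S ≥ 10** are kept — sequencing errors yield
  near-unique products and are filtered out, while transcribed sequence is
  seen by many overlapping reads.

Identifications are filtered at a target-decoy FDR,

```
FDR% = 100 × n_decoys / n_targets ,
```

choosing the (search score ≥ s, min IC50 over the subject's allotypes ≤ a)
pair that admits the most target peptides at FDR ≤ 5%, optimized on the
control-database identifications and then applied to the all-frames
identifications (whose decoy FDR is re-evaluated and reported). Peptides
identified with both databases are conventional MAPs; all-frames-only
peptides are putative cryptic MAPs and pass a stringent cascade — unique
genomic locus, unambiguous source gene (same-strand overlap beats antisense
beats intergenic), region classification on the most-expressed isoform
(5UTR, 5UTR/EXON, EXON, INTRON/EXON, INTRON, RETAINED_INTRON, 3UTR,
ANTISENSE, INTERGENIC), and reading-frame validation (in-frame exonic
candidates are conventional, not cryptic).

Downstream modules predict each cryptic MAP's source protein (start-codon
rules: upstream AUG in any Kozak context, else a near-cognate start in an
optimal `GCC(A/G)CC·start·G` or strong `(A/G)NN·start·G` context, else the
first codon after the upstream in-frame stop; stop = first in-frame stop
after the peptide), detect upstream ORFs, scan 3'UTRs for
stabilizing/destabilizing elements, classify SNPs by mutate-and-translate,
compute rare-codon usage (30 rare / 34 common codons under the bundled
human usage table), and run the C-terminal signature, length, allotype and
HLA-restriction statistics with Fisher's exact and Wilcoxon rank-sum tests.

A first-class simulator (`simulate_reference()`, `simulate_reads()`,
`simulate_psms()`) plants one ground-truth peptide per category plus
multi-locus and in-frame decoys, so the whole pipeline is testable at toy
scale without any external data.

## Worked example

```r
library(cryptomap)

ref    <- simulate_reference(sim_config(), seed = 3)   # planted ground truth
reads  <- simulate_reads(ref, seed = 3)
ctrl   <- build_control_db(apply_variants(ref$genome, ref$variants), ref$models)
search <- simulate_psms(ref, ctrl, seed = 3)

res <- run_pipeline(ref$genome, ref$models, ref$expression, ref$variants,
                    reads, search$psms, search$affinities, ref$cfg$alleles)
res$manifest$counts[c("n_allframes_identified", "n_conventional",
                      "n_putative_cryptic", "n_validated_cryptic")]
res$cryptic[, c("peptide", "cryptic_status")]
```

prints

```
$n_allframes_identified   24
$n_conventional           13
$n_putative_cryptic       11
$n_validated_cryptic       9

      peptide  cryptic_status
  AGGSNAPPCQQ      INTERGENIC
  CCHLGQWRALC RETAINED_INTRON
  FEICMEEVWWF       5UTR/EXON
  FILEAWGYPHA            EXON
  FLHVKMFRKQH       ANTISENSE
  IIFCNPFIFKK            5UTR
  KDENVTSEGAP          INTRON
  KTKFVGIMLEQ     INTRON/EXON
  RMESGHSDNES            3UTR
```

24 peptides pass the all-frames FDR filter; 13 are also found with the
control database (conventional), 11 are putative cryptic, of which 9 are
validated with exactly the planted category — the remaining 2 are the
planted decoys, discarded as `multi_locus` and `frame_conventional`. The
same run is available from the shell via the thin CLI at
`inst/cli/cryptomap.R` (`simulate`, `build-control-db`,
`build-allframes-db`, `fdr-filter`, `run`).

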