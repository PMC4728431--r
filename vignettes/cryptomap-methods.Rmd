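---
title: "Methods: proteogenomic discovery of cryptic MHC class I peptides"
author: "cryptomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic discovery of cryptic MHC class I peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MHC class I-associated peptides (MAPs) are 8-11-residue peptides presented at
the cell surface for CD8 T-cell surveillance. Conventional mass-spectrometry
identification matches spectra against the annotated proteome and is
therefore blind to peptides translated from "non-coding" regions: 5' and 3'
UTRs, introns, UTR-exon and intron-exon junctions, antisense and intergenic
transcripts, and out-of-frame exonic reading. `cryptomap` implements a
proteogenomic workflow that makes these cryptic MAPs discoverable by
searching spectra against a database built from the six-frame translation of
the subject's own RNA-seq reads, and then characterizes the validated
cryptic MAPs (source ORFs, transcript features, immunopeptidome statistics).

## The two databases

**Control database.** Subject-specific single-nucleotide variants are
integrated into the reference genome (`apply_variants()`), and the annotated
CDS of every protein-coding transcript is translated in its canonical frame
(`build_control_db()`). A CDS with an internal stop is emitted truncated,
with a warning, rather than dropped: the 5' fragment is still a real
translation product.

**All-frames database.** Every read is translated in all six reading frames
with a 33-bp sliding window (3 x 11 residues, the maximum MAP length),
stepping 1 nt. Each window is translated in its own frame on the forward
sequence and on the window's reverse complement; across offsets this visits
each of the six frames exactly once per frame-aligned window, which is the
only stepping rule under which "six frames" and "33-bp sliding window" are
simultaneously satisfied without gaps. Translation stops at the first stop
codon and the prefix is kept; products shorter than 8 residues are excluded,
and windows containing N are skipped rather than translated with wildcards.

Each distinct peptide receives an **S-value** (seen-value): the number of
window products equal to it, summed over all reads, offsets and strands,
duplicate reads included. The S-value is a raw seen-count, so the database
is invariant to read order and to reverse-complementing the read set, and a
peptide is retained only with S >= 10. Sequencing errors produce
mostly-unique products, so the S filter removes them while true transcripts
-- covered by many overlapping reads -- pass easily. A consequence of
1-nt stepping is that 8-10-mers appear as entries only when stop-truncated;
shorter interior peptides are still reachable by an enzyme-unspecific search
as subsequences of 11-mer entries. We count a peptide once per window, not
once per read (a window of one read that emits the same peptide twice counts
twice); reads shorter than 33 bp are skipped entirely.

## FDR filtering

A peptide-level record passes a threshold pair when its search score is at
least `score_min` and its minimum predicted IC50 over the subject's HLA-A/B
allotypes is at most `ic50_max_nM` (a peptide need only bind one allotype).
PSMs are collapsed to the best-scoring record per (peptide, database, decoy
flag) before counting, matching peptide-level MAP reporting. The
target-decoy FDR is

    FDR% = 100 x n_decoys / n_targets

over the passing records. `optimize_thresholds()` searches the grid of
observed scores x observed per-peptide minimum affinities and returns the
pair admitting the most targets subject to the FDR bound, breaking ties
toward lower FDR, then lower score cut, then higher (more permissive)
affinity cut. The grid uses observed values because the empirical pass set
only changes at observed values; any continuous optimum is equivalent to an
observed one. Thresholds are optimized on the control-database
identifications and then applied to the all-frames identifications, whose
decoy FDR is re-evaluated and reported (database size inflates it) but never
used as a gate. Peptides accepted with both databases are conventional MAPs;
peptides accepted only with the all-frames database are putative cryptic
MAPs.

## The cryptic validation cascade

Each putative cryptic peptide passes through, in order:

1. **Locus search** (`locate_pcr()`): exhaustive exact search of all six
   genome frames for nucleotide encodings of the peptide (desk-scale path),
   or spliced loci from supplied BED12 alignments. More than one distinct
   locus discards the peptide (`multi_locus`); an unlocatable peptide is
   recorded with its own reason.
2. **Spectrum validation flag**: peptides marked invalid upstream are
   discarded (`unvalidated_spectrum`); manual spectrum inspection itself is
   out of scope.
3. **Source gene** (`assign_source_gene()`): genes overlapping the locus by
   >= 1 bp on the same strand win over antisense over intergenic; two
   same-strand genes are discarded as ambiguous (`multi_gene`) -- the
   stringent reading of "unambiguously assigned to a single gene".
   Opposite-strand-only overlap yields ANTISENSE; none, INTERGENIC.
4. **Region classification** (`classify_region()`) on the most highly
   expressed isoform (FPKM > 0 = expressed; ties break to the smallest
   transcript id; with no expressed isoform, the longest, with a warning):
   5UTR, 5UTR/EXON, EXON, INTRON/EXON, INTRON, RETAINED_INTRON or 3UTR.
   Junction statuses require at least one base on each side of the
   boundary. RETAINED_INTRON is assigned only when the selected isoform's
   biotype is `retained_intron` and the locus overlaps a segment exonic in
   that isoform but intronic in a sibling isoform. Region combinations
   outside this vocabulary (for example CDS/3'UTR straddles) raise an
   explicit error rather than guessing.
5. **Reading-frame validation** (`validate_reading_frame()`): an exonic
   candidate is "in frame" when it lies fully within the CDS, its
   transcript-coordinate offset from the CDS start is 0 mod 3, and the
   canonical translation of that stretch equals the peptide; such
   candidates are conventional, not cryptic (`frame_conventional`).

Every input peptide ends as exactly one MAP record or one discard record;
`run_pipeline()` enforces this reconciliation in its manifest.

## Source-protein ORF prediction

For sense MAPs the context is the mature transcript; for antisense,
intronic and intergenic MAPs it is the personalized genomic flank, 750 bp
**per side** of the locus (the narrower reading of an ambiguous "750 bp
long"; a one-sided total would often leave no upstream context at all).
Within the in-frame window bounded upstream by the nearest in-frame stop,
the start codon is chosen by three ordered rules: (i) the 5'-most AUG in
any Kozak context; (ii) the 5'-most near-cognate codon (the nine
single-substitution neighbours of AUG) in an optimal or strong context;
(iii) the first codon after the stop. The 5'-most qualifying codon is taken
because it maximizes the ORF consistent with scanning initiation; a nearest
mode can be added trivially. Kozak classes are: optimal when positions
-6..-1 are GCC(A/G)CC and +4 is G; strong when -3 is A/G and +4 is G; weak
otherwise (insufficient flanking context is weak, flagged). The trailing
"[V]" decoration in some published renderings of these patterns is treated
as annotation noise: both classes require +4 = G, the classical
determinant. The stop codon is the first in-frame stop downstream of the
peptide-coding region; with none before the sequence end the protein is
flagged truncated. The initiator is reported verbatim in the prediction but
decoded as methionine in the protein string, the standard initiator-tRNA
behaviour, so a CUG-initiated protein begins with M.

Upstream ORFs are AUGs in optimal or strong context starting in the 5'UTR,
extended to their first in-frame stop: stops before the CDS start are
contained uORFs, the rest overlap the 5'UTR-exon junction; both count.

## Transcript features and statistics

3'UTR length is the exonic 3'UTR nucleotide count; the 3'UTR intron count
requires both intron flanks inside the 3'UTR. Stability-element scans count
**all** exact occurrences, overlapping included (an ambiguous "number of
elements"; overlap counting is the choice that is monotone under motif-set
refinement), with U/T normalized; motif lists are user-supplied
configuration, with a small synthetic list bundled for tests. Group
comparisons use the prescribed tests: two-sided Wilcoxon rank-sum for 3'UTR
length and expression, one-sided (cryptic greater) for element counts,
two-sided Fisher's exact for intron presence, uORF proportions, C-terminal
class usage, length distributions, ns-SNP frequency and HLA restriction.
Odds ratios are (ad)/(bc) with 0.5 added to every cell when any cell is
zero (reporting only; p-values use the uncorrected table), so group swaps
invert reported ORs exactly. The two-sided exact p-value is the sum of
probabilities of tables at most as probable as the observed one.

Codons are rare when their within-family usage fraction is below 1/(family
size) and common when above; exact ties (ATG, TGG, and balanced codons) go
to common, the only convention consistent with a 30/34 split of the 64
codons under the bundled standard human usage table (stop codons form a
3-member family). SNPs overlapping a peptide-coding region are classified
by mutate-and-translate: substitute the alternate allele (complemented on
minus-strand loci), translate the region in its own frame, and call the SNP
synonymous exactly when the peptide is unchanged; substituting the
reference allele is therefore always synonymous. ns-SNP frequencies are
per deduplicated PCR base pair per group.

The default amino-acid class table (HL = FILMVWY, HS = ACGP, PL = EHKQR,
PS = DNST) is configuration, not dogma: the published grouping is cited
without membership, so the table is editable and every signature function
takes it as an argument. Flanking positions P1'-P4' come from the predicted
(cryptic) or annotated (conventional) source protein; proteins ending at
the MAP C terminus contribute to P4-P1 only.

## The synthetic-fixture generator

`simulate_reference()` builds one toy gene per planted peptide on its own
contig -- three exons, two introns, 90 + 60 nt of 5'UTR, a 61-codon CDS and
a 240-nt 3'UTR -- plus an intergenic contig. One peptide of each category
is planted by construction: in-frame CDS (conventional), out-of-frame CDS,
5'UTR, 5'UTR/CDS boundary (the planted peptide carries a methionine whose
codon becomes the start codon, so the annotation stays honest), intron,
intron/exon boundary, 3'UTR, an intron of a gene whose dominant isoform
retains it, the antisense strand of a host gene, and intergenic sequence.
Two decoys are planted for the filtering steps: a peptide at two loci and
an in-frame CDS peptide fed to the cryptic path. Planted peptides default
to 11-mers so each is itself a database entry. A verification pass re-runs
the locator and the control build and redraws on (astronomically rare)
collisions; variants are placed in coding sequence outside every planted
region, never creating stop codons, so personalization cannot disturb a
plant.

`simulate_reads()` tiles each gene's **pre-mRNA** span (plus an antisense
unit per antisense plant and the intergenic contig) at uniform depth 20
with 100-nt reads; an interior 33-bp window is then fully contained in
about 14 reads, comfortably above the S >= 10 cut. Tiling pre-mRNA rather
than spliced mRNA is what gives intronic plants read support -- the
biological reading is that intron-containing precursors are translated,
which is exactly the phenomenon the intronic categories model. Errors are
independent per-base substitutions (no indels, keeping frame semantics
clean).

`simulate_psms()` emits correct target identifications for the planted
peptides plus a filler population of real control-proteome substrings
(scores uniform on 50-70; one deliberately low-scoring and one
deliberately weak-binding filler identification keep the optimized
control thresholds permissive enough that every genuine planted binder
passes -- planted presenting-allele affinities are drawn from 30-600 nM,
under the filler anchor at 1,200 nM). Incorrect targets and decoys are
drawn **symmetrically**: the same score distribution (normal, shifted down
by 20) and the same broad log-uniform affinity distribution, which is what
makes the decoy-based FDR estimate consistent for the realized false rate.
The contamination level is `fraction_incorrect_psms`.

What the simulator does not emulate: base-quality structure, GC and
positional coverage bias, paired-end mates, indels, spliced-junction
peptides (PCRs are genomically contiguous by construction), modified
peptides, and search-engine score semantics. Green tests therefore
demonstrate the correctness of the pipeline's logic and bookkeeping on
clean inputs, not robustness to every artefact of real data.

## Problem sizes and determinism

The test suite runs the six-frame oracle comparison on 1,000 random reads,
the FDR calibration at 500 PSMs x 20 seeds (asserting the mean
estimate-minus-realized difference is within 2 percentage points: at ~40
accepted targets a single decoy moves the estimate by ~2.5 points, so a
per-seed bound would measure counting noise, not calibration), exact-test
agreement with hypergeometric enumeration for all 2x2 tables with margins
up to 15, and the full pipeline on the one-peptide-per-category reference.
All simulator outputs are bit-reproducible under a seed; every stochastic
test fixes one.

## Known limitations

* The desk-scale locus search is exhaustive over the genome's six frames
  and is meant for toy genomes; genome-scale runs should supply spliced
  alignments as BED12.
* Conventional MAPs whose sequence occurs in proteins of several genes are
  reported as ambiguous rather than assigned.
* Non-coding (biotype) source transcripts have no frame to validate;
  exonic hits on them are labelled EXON with reading frame "none".
* The 9%-style FDR inflation on the all-frames database is reported, never
  gated on, and its magnitude depends on database size, which at toy scale
  is far from the real study's.

## Session

```{r}
library(cryptomap)
sessionInfo()
```
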