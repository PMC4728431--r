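#' Construct a peptide-coding region (PCR) locus
#'
#' @param contig Contig name.
#' @param blocks Two-column matrix of 0-based half-open genomic intervals in
#'   genomic order (more than one block for spliced PCRs).
#' @param strand "+" or "-".
#' @param nt_sequence The coding nucleotide sequence read 5' to 3' (its
#'   translation must equal the peptide).
#' @param peptide The encoded peptide.
#' @return An object of class `PcrLocus`.
#' @export
pcr_locus <- function(contig, blocks, strand, nt_sequence, peptide) {
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  if (sum(blocks[, 2L] - blocks[, 1L]) != 3L * nchar(peptide))
    stop("PCR block lengths do not sum to 3 x peptide length")
  if (translate_nt(nt_sequence) != peptide)
    stop("PCR nucleotide sequence does not translate to the peptide")
  structure(list(contig = contig, blocks = blocks, strand = strand,
                 nt_sequence = nt_sequence, peptide = peptide),
            class = "PcrLocus")
}

# 0-based genomic positions covered by a locus, in genomic order.
locus_bases <- function(locus) {
  unlist(lapply(seq_len(nrow(locus$blocks)), function(i)
    seq.int(locus$blocks[i, 1L], locus$blocks[i, 2L] - 1L)))
}

locus_key <- function(locus) {
  paste(locus$contig, locus$strand,
        paste(locus$blocks[, 1L], locus$blocks[, 2L], sep = "-", collapse = ";"))
}

#' Locate the peptide-coding region(s) of a peptide in the genome
#'
#' Without alignments, performs an exhaustive exact search of all six reading
#' frames of every contig (the desk-scale path). With spliced alignments
#' (BED12 rows from [read_bed()]), loci are taken from the alignment blocks
#' and checked by translation. Duplicate loci are merged.
#'
#' @param peptide Amino-acid string.
#' @param genome Named character vector of contig sequences.
#' @param alignments Optional data.frame from [read_bed()] giving spliced
#'   alignments of peptide-encoding reads.
#' @return List of `PcrLocus` objects (possibly empty).
#' @export
locate_pcr <- function(peptide, genome, alignments = NULL) {
  if (!is.null(alignments)) return(.loci_from_bed(peptide, genome, alignments))
  loci <- list()
  plen <- nchar(peptide)
  for (ctg in names(genome)) {
    seqs <- c("+" = genome[[ctg]], "-" = revcomp(genome[[ctg]]))
    Lc <- nchar(genome[[ctg]])
    for (strand in c("+", "-")) {
      s <- seqs[[strand]]
      for (frame in 0:2) {
        aa <- translate_nt(substr(s, frame + 1L, nchar(s)))
        hits <- gregexpr(peptide, aa, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (h in as.integer(hits)) {
          off <- frame + (h - 1L) * 3L           # 0-based on this strand
          nt <- substr(s, off + 1L, off + 3L * plen)
          blocks <- if (strand == "+") c(off, off + 3L * plen) else
            c(Lc - off - 3L * plen, Lc - off)
          loci[[length(loci) + 1L]] <-
            pcr_locus(ctg, matrix(blocks, ncol = 2L), strand, nt, peptide)
        }
      }
    }
  }
  loci[!duplicated(vapply(loci, locus_key, character(1)))]
}

.loci_from_bed <- function(peptide, genome, alignments) {
  loci <- list()
  for (nm in unique(alignments$name)) {
    a <- alignments[alignments$name == nm, , drop = FALSE]
    ctg <- a$contig[1L]; strand <- a$strand[1L]
    blocks <- as.matrix(a[order(a$start), c("start", "end")])
    parts <- substring(genome[[ctg]], blocks[, 1L] + 1L, blocks[, 2L])
    nt <- paste0(parts, collapse = "")
    if (strand == "-") nt <- revcomp(nt)
    if (translate_nt(nt) != peptide) next
    loci[[length(loci) + 1L]] <- pcr_locus(ctg, blocks, strand, nt, peptide)
  }
  loci[!duplicated(vapply(loci, locus_key, character(1)))]
}

#' Keep peptides with a unique genomic locus
#'
#' @param peptide The peptide.
#' @param loci List of loci from [locate_pcr()].
#' @return The single `PcrLocus` when unique; a discard record (list with
#'   peptide and reason "multi_locus") when several distinct loci exist.
#'   Zero loci is an error.
#' @export
filter_unique_locus <- function(peptide, loci) {
  if (length(loci) == 0L) stop("peptide ", peptide, " is unlocatable in the genome")
  keys <- unique(vapply(loci, locus_key, character(1)))
  if (length(keys) > 1L)
    return(list(peptide = peptide, reason = "multi_locus"))
  loci[[1L]]
}

# Gene-level table: one row per gene with its span over all transcripts.
gene_spans <- function(models) {
  gid <- vapply(models, `[[`, character(1), "gene_id")
  rows <- lapply(unique(gid), function(g) {
    ms <- models[gid == g]
    data.frame(gene_id = g, contig = ms[[1L]]$contig, strand = ms[[1L]]$strand,
               start = min(vapply(ms, function(m) m$exons[1L, 1L], integer(1))),
               end = max(vapply(ms, function(m) m$exons[nrow(m$exons), 2L], integer(1))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign a source gene to a validated locus
#'
#' Genes overlapping the locus by at least 1 bp on the same strand are
#' candidate sources: exactly one candidate is assigned; several yield a
#' multi-gene discard; with none, an opposite-strand overlap yields
#' ANTISENSE (the opposite gene is recorded) and no overlap at all yields
#' INTERGENIC.
#'
#' @param locus A `PcrLocus`.
#' @param models Named list of TranscriptModel objects.
#' @return List with `type` ("gene", "antisense", "intergenic" or "discard"),
#'   `gene_id` (NA for intergenic) and `reason` (for discards).
#' @export
assign_source_gene <- function(locus, models) {
  gs <- gene_spans(models)
  gs <- gs[gs$contig == locus$contig, , drop = FALSE]
  pcr <- IRanges::IRanges(start = locus$blocks[, 1L] + 1L, end = locus$blocks[, 2L])
  gr <- IRanges::IRanges(start = gs$start + 1L, end = gs$end)
  ov <- IRanges::countOverlaps(gr, pcr, minoverlap = 1L) > 0L
  same <- ov & gs$strand == locus$strand
  opp <- ov & gs$strand != locus$strand
  if (sum(same) == 1L)
    return(list(type = "gene", gene_id = gs$gene_id[same], reason = NA_character_))
  if (sum(same) > 1L)
    return(list(type = "discard", gene_id = NA_character_, reason = "multi_gene"))
  if (any(opp))
    return(list(type = "antisense", gene_id = gs$gene_id[opp][1L],
                reason = NA_character_))
  list(type = "intergenic", gene_id = NA_character_, reason = NA_character_)
}

#' Select the source isoform of a gene
#'
#' Returns the most highly expressed isoform (maximal FPKM among transcripts
#' with FPKM > 0; ties broken toward the lexicographically smallest
#' transcript id). Without any expressed isoform, falls back to the longest
#' transcript with a warning.
#'
#' @param gene_id Gene identifier.
#' @param models Named list of TranscriptModel objects.
#' @param expression Optional data.frame (transcript_id, fpkm) overriding the
#'   models' fpkm fields.
#' @return A `TranscriptModel`.
#' @export
select_source_isoform <- function(gene_id, models, expression = NULL) {
  ms <- models[vapply(models, `[[`, character(1), "gene_id") == gene_id]
  if (length(ms) == 0L) stop("no transcripts for gene ", gene_id)
  fpkm <- vapply(ms, function(m) {
    if (!is.null(expression)) {
      hit <- match(m$transcript_id, expression$transcript_id)
      if (!is.na(hit)) return(as.numeric(expression$fpkm[hit]))
    }
    as.numeric(m$fpkm)
  }, numeric(1))
  expressed <- !is.na(fpkm) & fpkm > 0
  if (!any(expressed)) {
    warning("gene ", gene_id, " has no expressed isoform; using the longest")
    lens <- vapply(ms, tx_length, integer(1))
    ids <- names(ms)[lens == max(lens)]
    return(ms[[sort(ids)[1L]]])
  }
  ms <- ms[expressed]; fpkm <- fpkm[expressed]
  ids <- names(ms)[fpkm == max(fpkm)]
  ms[[sort(ids)[1L]]]
}

# Per-base genomic labels of a locus relative to one transcript:
# "utr5"/"cds"/"utr3" (coding transcripts), "exon" (non-coding transcripts),
# "intron" (within the transcript span but not exonic), "outside".
.locus_base_labels <- function(locus, transcript) {
  bases <- locus_bases(locus)
  span <- c(transcript$exons[1L, 1L], transcript$exons[nrow(transcript$exons), 2L])
  tx <- genomic_to_tx(transcript, bases)
  labels <- ifelse(!is.na(tx), "exon",
                   ifelse(bases >= span[1L] & bases < span[2L], "intron", "outside"))
  regions <- derive_transcript_regions(transcript)
  if (nrow(regions) > 0L) {
    for (i in which(labels == "exon")) {
      r <- regions$region[regions$tx_start <= tx[i] & tx[i] < regions$tx_end]
      labels[i] <- r
    }
  }
  labels
}

#' Classify a cryptic locus by its position within the source transcript
#'
#' Maps the PCR onto the transcript's 5'UTR/CDS/3'UTR/intron structure and
#' returns one of 5UTR, 5UTR/EXON, EXON, INTRON/EXON, INTRON,
#' RETAINED_INTRON or 3UTR. Junction statuses require at least one base on
#' each side of the boundary. RETAINED_INTRON is assigned only when the
#' transcript biotype is retained_intron and the PCR overlaps a segment that
#' is exonic in this isoform but intronic in another isoform of the same
#' gene (when `models` is supplied; otherwise any exonic hit on a
#' retained_intron isoform qualifies).
#'
#' @param locus A `PcrLocus` (same strand as the transcript).
#' @param transcript The selected source `TranscriptModel`.
#' @param models Optional full annotation set (for the retained-intron rule).
#' @return The cryptic status label.
#' @export
classify_region <- function(locus, transcript, models = NULL) {
  labels <- .locus_base_labels(locus, transcript)
  if (all(labels == "outside") || any(labels == "outside"))
    stop("PCR does not lie within transcript ", transcript$transcript_id)
  if (transcript$biotype == "retained_intron" && any(labels == "exon")) {
    if (is.null(models) || .overlaps_retained_segment(locus, transcript, models))
      return("RETAINED_INTRON")
  }
  exonic <- c("utr5", "cds", "utr3", "exon")
  has <- function(x) any(labels == x)
  if (has("intron") && any(labels %in% exonic)) return("INTRON/EXON")
  if (all(labels == "intron")) return("INTRON")
  if (all(labels == "utr5")) return("5UTR")
  if (has("utr5") && has("cds")) return("5UTR/EXON")
  if (all(labels == "cds")) return("EXON")
  if (all(labels == "utr3")) return("3UTR")
  if (all(labels == "exon")) return("EXON")
  stop("unclassifiable region combination for peptide ", locus$peptide, ": ",
       paste(sort(unique(labels)), collapse = "+"))
}

.overlaps_retained_segment <- function(locus, transcript, models) {
  bases <- locus_bases(locus)
  exonic_here <- !is.na(genomic_to_tx(transcript, bases))
  others <- models[vapply(models, `[[`, character(1), "gene_id") == transcript$gene_id]
  others <- others[names(others) != transcript$transcript_id]
  for (m in others) {
    span <- c(m$exons[1L, 1L], m$exons[nrow(m$exons), 2L])
    intronic <- is.na(genomic_to_tx(m, bases)) & bases >= span[1L] & bases < span[2L]
    if (any(exonic_here & intronic)) return(TRUE)
  }
  FALSE
}

#' Validate the reading frame of an exonic cryptic candidate
#'
#' For statuses EXON, 5UTR/EXON and INTRON/EXON, checks whether the PCR is
#' translated in the transcript's canonical frame: "in" requires the PCR to
#' lie fully within the CDS, its transcript-coordinate start to be a
#' multiple of 3 from the CDS start, and the canonical translation of that
#' CDS stretch to equal the peptide. In-frame candidates are conventional,
#' not cryptic. Other statuses (and non-coding transcripts) return "none".
#'
#' @param locus A `PcrLocus`.
#' @param transcript The source `TranscriptModel`.
#' @param genome Genome used for the translation identity check.
#' @param status The [classify_region()] status.
#' @return "in", "out" or "none".
#' @export
validate_reading_frame <- function(locus, transcript, genome,
                                   status = classify_region(locus, transcript)) {
  if (!status %in% c("EXON", "5UTR/EXON", "INTRON/EXON")) return("none")
  if (is.null(transcript$cds_span)) return("none")
  labels <- .locus_base_labels(locus, transcript)
  if (!all(labels == "cds")) return("out")
  if (locus$strand != transcript$strand) return("out")
  regions <- derive_transcript_regions(transcript)
  cds_tx_start <- regions$tx_start[regions$region == "cds"]
  pcr_tx_start <- min(genomic_to_tx(transcript, locus_bases(locus)))
  if ((pcr_tx_start - cds_tx_start) %% 3L != 0L) return("out")
  protein <- translate_nt(cds_sequence(genome, transcript))
  aa_off <- (pcr_tx_start - cds_tx_start) %/% 3L
  stretch <- substr(protein, aa_off + 1L, aa_off + nchar(locus$peptide))
  if (stretch == locus$peptide) "in" else "out"
}

#' Transcriptomic read coverage of a PCR
#'
#' Counts the reads (BED records) overlapping any PCR block by at least
#' 1 bp.
#'
#' @param locus A `PcrLocus`.
#' @param read_alignments Data.frame from [read_bed()].
#' @return Integer count of overlapping reads.
#' @export
pcr_coverage <- function(locus, read_alignments) {
  a <- read_alignments[read_alignments$contig == locus$contig, , drop = FALSE]
  if (nrow(a) == 0L) return(0L)
  pcr <- IRanges::IRanges(start = locus$blocks[, 1L] + 1L, end = locus$blocks[, 2L])
  reads <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  hit <- IRanges::countOverlaps(reads, pcr, minoverlap = 1L) > 0L
  length(unique(a$name[hit]))
}

#' Normalized position of a MAP start within its source transcript
#'
#' The transcript length is normalized to 1 and the transcript-coordinate
#' start of the PCR is placed on that 0-1 scale (0 = 5' end). MAPs from
#' intergenic, intronic and antisense loci have no (annotated, overlapping)
#' source transcript position and return NA.
#'
#' @param locus A `PcrLocus`.
#' @param transcript The source `TranscriptModel`.
#' @param status The cryptic status (conventional MAPs: pass "EXON").
#' @return Number in [0, 1], or NA for excluded categories.
#' @export
positional_bias <- function(locus, transcript, status) {
  if (status %in% c("INTERGENIC", "INTRON", "ANTISENSE")) return(NA_real_)
  tx <- genomic_to_tx(transcript, locus_bases(locus))
  tx <- tx[!is.na(tx)]
  if (length(tx) == 0L) return(NA_real_)
  min(tx) / tx_length(transcript)
}
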