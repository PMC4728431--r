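#' Annotate putative cryptic MAPs
#'
#' Runs the filtering and validation cascade on putative cryptic peptides:
#' locate the peptide-coding region (discarding multi-locus peptides), drop
#' peptides whose spectrum failed validation, assign a source gene
#' (discarding multi-gene peptides; antisense and intergenic loci become MAP
#' records without a source transcript), classify the genomic region of
#' sense peptides on the most highly expressed isoform, and discard
#' candidates translated in the canonical frame. Every input peptide ends as
#' exactly one MAP record or one discard record.
#'
#' @param peptides Character vector of putative cryptic peptides.
#' @param genome Personalized genome (named character vector).
#' @param models Named list of TranscriptModel objects.
#' @param expression Optional expression data.frame (transcript_id, fpkm).
#' @param alignments Optional BED12 data.frame of spliced peptide-read
#'   alignments (see [locate_pcr()]).
#' @param validated Optional named logical vector; peptides marked FALSE are
#'   discarded as unvalidated_spectrum (default: all validated).
#' @return List with `maps` (data.frame of MAP records), `discards`
#'   (data.frame with peptide and reason) and `loci` (named list of
#'   `PcrLocus` for the retained MAPs).
#' @export
annotate_cryptic <- function(peptides, genome, models, expression = NULL,
                             alignments = NULL, validated = NULL) {
  maps <- list(); discards <- list(); loci <- list()
  add_discard <- function(p, reason)
    discards[[length(discards) + 1L]] <<- data.frame(
      peptide = p, reason = reason, stringsAsFactors = FALSE)
  add_map <- function(p, status, gene, tx, locus, frame)
    maps[[length(maps) + 1L]] <<- data.frame(
      peptide = p, kind = "cryptic", cryptic_status = status,
      source_gene_id = gene, source_transcript_id = tx,
      contig = locus$contig,
      blocks = paste(locus$blocks[, 1L], locus$blocks[, 2L],
                     sep = "-", collapse = ";"),
      strand = locus$strand, reading_frame = frame, stringsAsFactors = FALSE)

  for (p in peptides) {
    found <- locate_pcr(p, genome, alignments)
    if (length(found) == 0L) { add_discard(p, "unlocatable"); next }
    res <- filter_unique_locus(p, found)
    if (!inherits(res, "PcrLocus")) { add_discard(p, res$reason); next }
    locus <- res
    if (!is.null(validated) && !is.na(validated[p]) && !validated[p]) {
      add_discard(p, "unvalidated_spectrum"); next
    }
    src <- assign_source_gene(locus, models)
    if (src$type == "discard") { add_discard(p, src$reason); next }
    if (src$type == "antisense") {
      add_map(p, "ANTISENSE", src$gene_id, NA_character_, locus, "none")
      loci[[p]] <- locus; next
    }
    if (src$type == "intergenic") {
      add_map(p, "INTERGENIC", NA_character_, NA_character_, locus, "none")
      loci[[p]] <- locus; next
    }
    iso <- select_source_isoform(src$gene_id, models, expression)
    status <- classify_region(locus, iso, models)
    frame <- validate_reading_frame(locus, iso, genome, status)
    if (frame == "in") { add_discard(p, "frame_conventional"); next }
    add_map(p, status, src$gene_id, iso$transcript_id, locus, frame)
    loci[[p]] <- locus
  }
  maps <- if (length(maps)) do.call(rbind, maps) else
    data.frame(peptide = character(), kind = character(),
               cryptic_status = character(), source_gene_id = character(),
               source_transcript_id = character(), contig = character(),
               blocks = character(), strand = character(),
               reading_frame = character(), stringsAsFactors = FALSE)
  discards <- if (length(discards)) do.call(rbind, discards) else
    data.frame(peptide = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(maps) <- rownames(discards) <- NULL
  list(maps = maps, discards = discards, loci = loci)
}

#' Map conventional MAPs to their source transcripts and loci
#'
#' For each conventional peptide, finds the control-database proteins
#' containing it; peptides matching proteins of more than one gene are
#' reported as ambiguous. The source transcript is the most highly expressed
#' isoform of the gene whose protein contains the peptide, and the PCR locus
#' is derived from the in-frame position within that transcript's CDS.
#'
#' @param peptides Character vector of conventional peptides.
#' @param control_db Data.frame from [build_control_db()].
#' @param genome Personalized genome.
#' @param models Named list of TranscriptModel objects.
#' @param expression Optional expression data.frame.
#' @return List with `maps` (data.frame, kind "conventional"), `ambiguous`
#'   (peptides hitting several genes) and `loci`.
#' @export
map_conventional <- function(peptides, control_db, genome, models,
                             expression = NULL) {
  maps <- list(); ambiguous <- character(0); loci <- list()
  for (p in peptides) {
    hit <- grepl(p, control_db$sequence, fixed = TRUE)
    genes <- unique(control_db$gene_id[hit])
    if (length(genes) != 1L) { ambiguous <- c(ambiguous, p); next }
    # most highly expressed coding isoform whose protein contains the peptide
    cand <- control_db$identifier[hit & control_db$gene_id == genes]
    fpkm <- vapply(cand, function(tid) {
      if (!is.null(expression)) {
        m <- match(tid, expression$transcript_id)
        if (!is.na(m)) return(as.numeric(expression$fpkm[m]))
      }
      as.numeric(models[[tid]]$fpkm %||% NA_real_)
    }, numeric(1))
    fpkm[is.na(fpkm)] <- 0
    best <- sort(cand[fpkm == max(fpkm)])[1L]
    iso <- models[[best]]
    prot <- translate_nt(cds_sequence(genome, iso))
    aa_off <- regexpr(p, prot, fixed = TRUE) - 1L
    regions <- derive_transcript_regions(iso)
    cds_tx_start <- regions$tx_start[regions$region == "cds"]
    tx_pos <- cds_tx_start + 3L * aa_off + seq_len(3L * nchar(p)) - 1L
    gpos <- sort(tx_to_genomic(iso, tx_pos))
    blocks <- .runs_to_blocks(gpos)
    nt <- substr(cds_sequence(genome, iso), 3L * aa_off + 1L,
                 3L * aa_off + 3L * nchar(p))
    locus <- pcr_locus(iso$contig, blocks, iso$strand, nt, p)
    loci[[p]] <- locus
    maps[[length(maps) + 1L]] <- data.frame(
      peptide = p, kind = "conventional", cryptic_status = NA_character_,
      source_gene_id = genes, source_transcript_id = iso$transcript_id,
      contig = iso$contig,
      blocks = paste(blocks[, 1L], blocks[, 2L], sep = "-", collapse = ";"),
      strand = iso$strand, reading_frame = "in", stringsAsFactors = FALSE)
  }
  maps <- if (length(maps)) do.call(rbind, maps) else
    data.frame(peptide = character(), kind = character(),
               cryptic_status = character(), source_gene_id = character(),
               source_transcript_id = character(), contig = character(),
               blocks = character(), strand = character(),
               reading_frame = character(), stringsAsFactors = FALSE)
  rownames(maps) <- NULL
  list(maps = maps, ambiguous = ambiguous, loci = loci)
}

# Collapse a sorted vector of genomic positions into half-open blocks.
.runs_to_blocks <- function(gpos) {
  breaks <- which(diff(gpos) != 1L)
  starts <- gpos[c(1L, breaks + 1L)]
  ends <- gpos[c(breaks, length(gpos))] + 1L
  cbind(start = starts, end = ends)
}
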