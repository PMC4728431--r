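#' Classify the Kozak context of a start codon
#'
#' Optimal: positions -6..-1 are GCC(A/G)CC and position +4 (the base after
#' the codon) is G. Strong: position -3 is A or G and +4 is G. Anything else
#' (including insufficient flanking context) is weak.
#'
#' @param sequence Nucleotide string.
#' @param start_pos 0-based position of the first base of the start codon.
#' @return "optimal", "strong" or "weak" (with attribute
#'   `insufficient_context` when fewer than 6 nt upstream or 4 nt downstream
#'   are available).
#' @export
kozak_context <- function(sequence, start_pos) {
  n <- nchar(sequence)
  if (start_pos < 6L || start_pos + 4L > n)
    return(structure("weak", insufficient_context = TRUE))
  up <- substr(sequence, start_pos - 5L, start_pos)       # -6..-1 (1-based)
  plus4 <- substr(sequence, start_pos + 4L, start_pos + 4L)
  minus3 <- substr(up, 4L, 4L)
  if (plus4 == "G" && grepl("^GCC[AG]CC$", up)) return("optimal")
  if (plus4 == "G" && minus3 %in% c("A", "G")) return("strong")
  "weak"
}

#' Predict the translation start codon upstream of a PCR
#'
#' The search region runs over in-frame codons from just after the nearest
#' upstream in-frame stop codon (or the first in-frame position of the
#' sequence) up to and including the PCR start. Rules are applied in order:
#' (i) the 5'-most ATG in any Kozak context; (ii) the 5'-most near-cognate
#' codon (single-substitution neighbour of ATG) in an optimal or strong
#' context; (iii) the first codon of the search region.
#'
#' @param sequence Nucleotide string (source transcript, or genomic flank for
#'   antisense/intronic/intergenic MAPs), 5' to 3', in frame with the PCR.
#' @param pcr_offset 0-based offset of the PCR start within `sequence`.
#' @return List with position (0-based), codon, codon_class ("AUG",
#'   "near_cognate" or "other"), kozak and rule_applied ("i", "ii" or "iii").
#' @export
predict_start <- function(sequence, pcr_offset) {
  frame <- pcr_offset %% 3L
  starts <- seq.int(frame, pcr_offset, by = 3L)          # 0-based codon starts
  codons <- substring(sequence, starts + 1L, starts + 3L)
  stops <- which(codons %in% .STOP_CODONS & starts < pcr_offset)
  first <- if (length(stops)) max(stops) + 1L else 1L
  region <- first:length(starts)
  mk <- function(i, class, rule) {
    list(position = starts[i], codon = codons[i], codon_class = class,
         kozak = as.character(kozak_context(sequence, starts[i])),
         rule_applied = rule)
  }
  aug <- region[codons[region] == "ATG"]
  if (length(aug)) return(mk(aug[1L], "AUG", "i"))
  nc <- region[codons[region] %in% .NEAR_COGNATE]
  nc <- nc[vapply(nc, function(i)
    kozak_context(sequence, starts[i]) %in% c("optimal", "strong"), logical(1))]
  if (length(nc)) return(mk(nc[1L], "near_cognate", "ii"))
  mk(region[1L], "other", "iii")
}

#' Predict the source-protein ORF of a cryptic MAP
#'
#' Translates from the predicted start codon (the initiator is decoded as
#' methionine regardless of codon identity, the standard initiator-tRNA
#' behaviour) to the first in-frame stop codon downstream of the PCR; when
#' no stop occurs before the sequence end, the protein is truncated there.
#'
#' @param sequence Nucleotide string, 5' to 3', in frame with the PCR.
#' @param pcr_offset 0-based offset of the PCR start within `sequence`.
#' @param peptide The MAP (used for the containment check).
#' @return List with start (a [predict_start()] record), stop_position
#'   (0-based position of the stop codon, or "sequence_end"), protein,
#'   length_aa and truncated_at_end.
#' @export
predict_orf <- function(sequence, pcr_offset, peptide) {
  start <- predict_start(sequence, pcr_offset)
  pcr_end <- pcr_offset + 3L * nchar(peptide)
  n3 <- nchar(sequence) - (nchar(sequence) - start$position) %% 3L
  body <- substr(sequence, start$position + 1L, n3)
  aa <- translate_nt(body)
  # first in-frame stop at or after the PCR end
  min_codon <- (pcr_end - start$position) %/% 3L + 1L
  stars <- which(strsplit(aa, "")[[1L]] == "*")
  stars <- stars[stars >= min_codon]
  if (length(stars)) {
    stop_codon <- stars[1L]
    protein <- substr(aa, 1L, stop_codon - 1L)
    stop_position <- start$position + 3L * (stop_codon - 1L)
    truncated <- FALSE
  } else {
    protein <- gsub("*", "", aa, fixed = TRUE)
    stop_position <- "sequence_end"
    truncated <- TRUE
  }
  substr(protein, 1L, 1L) <- "M"
  if (!grepl(peptide, protein, fixed = TRUE) &&
      !grepl(peptide, paste0(substr(translate_nt(body), 1L, 1L),
                             substr(protein, 2L, nchar(protein))), fixed = TRUE))
    stop("predicted ORF does not contain the MAP ", peptide)
  list(start = start, stop_position = stop_position, protein = protein,
       length_aa = nchar(protein), truncated_at_end = truncated)
}

#' Find upstream ORFs in a transcript
#'
#' Scans the transcript 5' to 3' for ATG codons in an optimal or strong
#' Kozak context that start within the 5'UTR; each defines an ORF running to
#' its first in-frame stop codon (or the transcript end). ORFs terminating
#' before the CDS start are contained uORFs; the rest overlap the
#' 5'UTR-exon junction. Both count as upstream ORFs.
#'
#' @param transcript_sequence Mature transcript sequence (5' to 3').
#' @param regions Region map from [derive_transcript_regions()].
#' @return Data.frame with start_position, stop_position (0-based transcript
#'   coordinates; stop is NA when the ORF runs to the transcript end) and
#'   location ("contained_5UTR" or "junction_5UTR_exon").
#' @export
find_uorfs <- function(transcript_sequence, regions) {
  empty <- data.frame(start_position = integer(), stop_position = integer(),
                      location = character(), stringsAsFactors = FALSE)
  utr5 <- regions[regions$region == "utr5", ]
  if (nrow(utr5) == 0L || utr5$tx_end == 0L) return(empty)
  cds_start <- regions$tx_start[regions$region == "cds"]
  n <- nchar(transcript_sequence)
  rows <- list()
  for (pos in seq.int(0L, utr5$tx_end - 1L)) {
    if (substr(transcript_sequence, pos + 1L, pos + 3L) != "ATG") next
    if (!kozak_context(transcript_sequence, pos) %in% c("optimal", "strong")) next
    n3 <- n - (n - pos) %% 3L
    aa <- translate_nt(substr(transcript_sequence, pos + 1L, n3))
    star <- as.integer(regexpr("*", aa, fixed = TRUE))
    if (star > 0L) {
      stop_pos <- pos + 3L * (star - 1L)
      loc <- if (stop_pos + 3L <= cds_start) "contained_5UTR" else "junction_5UTR_exon"
    } else {
      stop_pos <- NA_integer_
      loc <- "junction_5UTR_exon"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start_position = pos, stop_position = stop_pos, location = loc,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Extract the in-frame context sequence for ORF prediction of one MAP
#'
#' Sense MAPs with an assigned source transcript use the mature transcript
#' sequence (PCR mapped to transcript coordinates). Antisense, intronic and
#' intergenic MAPs use the personalized genomic sequence flanking the PCR
#' (750 bp on each side), read on the PCR strand.
#'
#' @param map_row One row of an [annotate_cryptic()] maps data.frame.
#' @param locus The corresponding `PcrLocus`.
#' @param genome Personalized genome.
#' @param models Named list of TranscriptModel objects.
#' @param flank_bp Flank width per side for non-transcript MAPs (default 750).
#' @return List with `sequence` and `pcr_offset` ready for [predict_orf()].
#' @export
orf_context <- function(map_row, locus, genome, models, flank_bp = 750L) {
  status <- map_row$cryptic_status
  use_flank <- status %in% c("ANTISENSE", "INTERGENIC", "INTRON") ||
    is.na(map_row$source_transcript_id)
  if (!use_flank) {
    tx <- models[[map_row$source_transcript_id]]
    tpos <- genomic_to_tx(tx, locus_bases(locus))
    if (anyNA(tpos)) {                       # partially intronic: genomic flank
      use_flank <- TRUE
    } else {
      return(list(sequence = extract_transcript_sequence(genome, tx),
                  pcr_offset = min(tpos)))
    }
  }
  contig <- genome[[locus$contig]]
  lo <- max(0L, locus$blocks[1L, 1L] - flank_bp)
  hi <- min(nchar(contig), locus$blocks[nrow(locus$blocks), 2L] + flank_bp)
  seg <- substr(contig, lo + 1L, hi)
  if (locus$strand == "+") {
    list(sequence = seg, pcr_offset = unname(locus$blocks[1L, 1L] - lo))
  } else {
    list(sequence = revcomp(seg),
         pcr_offset = unname(hi - locus$blocks[nrow(locus$blocks), 2L]))
  }
}
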