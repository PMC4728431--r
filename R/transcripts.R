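#' Construct a transcript model
#'
#' A TranscriptModel is the package's strand-aware view of one transcript:
#' ordered exons (0-based half-open genomic intervals), an optional CDS span
#' (from the first base of the start codon to the last base of the stop
#' codon), a biotype label and an optional FPKM expression value. All internal
#' coordinates in the package are 0-based half-open; GTF input/output converts
#' at the boundary.
#'
#' @param transcript_id,gene_id,gene_name,biotype Character scalars
#'   (gene_name and biotype may be "unknown").
#' @param contig Contig name.
#' @param strand "+" or "-".
#' @param exons Two-column integer matrix (start, end), 0-based half-open.
#' @param cds_span Optional length-2 integer vector (start, end) or NULL.
#' @param fpkm Optional non-negative expression value.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds_span = NULL, gene_name = gene_id,
                             biotype = "unknown", fpkm = NA_real_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon in ", transcript_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in ", transcript_id)
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    stopifnot(length(cds_span) == 2L, cds_span[2L] > cds_span[1L])
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_name = gene_name, biotype = biotype, contig = contig,
                 strand = strand, exons = exons, cds_span = cds_span,
                 fpkm = fpkm),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cds <- if (is.null(x$cds_span)) "none" else
    sprintf("[%d,%d)", x$cds_span[1L], x$cds_span[2L])
  cat(sprintf("TranscriptModel %s (%s, %s%s) %d exon(s), CDS %s, length %d nt\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), cds, tx_length(x)))
  invisible(x)
}

#' Transcript (mature mRNA) length in nucleotides
#' @param model A TranscriptModel.
#' @return Integer length.
#' @export
tx_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

# Map 0-based genomic positions to 0-based transcript coordinates (5'->3').
# Non-exonic positions map to NA.
genomic_to_tx <- function(model, gpos) {
  ex <- model$exons
  before <- c(0L, cumsum(ex[, 2L] - ex[, 1L]))
  plus <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- gpos >= ex[i, 1L] & gpos < ex[i, 2L]
    plus[hit] <- before[i] + (gpos[hit] - ex[i, 1L])
  }
  if (model$strand == "+") plus else tx_length(model) - 1L - plus
}

# Map 0-based transcript coordinates to 0-based genomic positions.
tx_to_genomic <- function(model, tpos) {
  L <- tx_length(model)
  if (any(tpos < 0L | tpos >= L)) stop("transcript coordinate out of range")
  plus <- if (model$strand == "+") tpos else L - 1L - tpos
  ex <- model$exons
  before <- c(0L, cumsum(ex[, 2L] - ex[, 1L]))
  out <- rep(NA_integer_, length(plus))
  for (i in seq_len(nrow(ex))) {
    hit <- plus >= before[i] & plus < before[i + 1L]
    out[hit] <- ex[i, 1L] + (plus[hit] - before[i])
  }
  out
}

#' Parse Ensembl-dialect GTF annotations into transcript models
#'
#' Reads exon and CDS features, groups them by transcript_id, converts 1-based
#' inclusive GTF coordinates to the internal 0-based half-open convention and
#' attaches the gene_biotype/transcript_biotype attribute (verbatim, falling
#' back to "unknown"). Transcripts whose CDS falls outside their exon union
#' are excluded with a warning.
#'
#' @param x Path to a GTF file, or a character vector of GTF lines.
#' @param expression Optional expression data.frame (transcript_id, fpkm) used
#'   to populate the models' fpkm field.
#' @return Named list of `TranscriptModel` objects (names = transcript ids).
#' @export
parse_annotations <- function(x, expression = NULL) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  recs <- list()
  for (i in idx) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop("GTF line ", i, ": fewer than 9 fields")
    if (!f[3L] %in% c("exon", "CDS")) next
    at <- .parse_gtf_attributes(f[9L], i)
    if (is.null(at[["transcript_id"]]) || is.null(at[["gene_id"]]))
      stop("GTF line ", i, ": exon/CDS feature lacks transcript_id/gene_id")
    recs[[length(recs) + 1L]] <- list(
      contig = f[1L], feature = f[3L],
      start = as.integer(f[4L]) - 1L, end = as.integer(f[5L]),
      strand = f[7L], attrs = at, line = i)
  }
  if (length(recs) == 0L) return(structure(list(), names = character(0)))
  tx_ids <- vapply(recs, function(r) r$attrs[["transcript_id"]], character(1))
  models <- list()
  for (tid in unique(tx_ids)) {
    rs <- recs[tx_ids == tid]
    exons <- do.call(rbind, lapply(Filter(function(r) r$feature == "exon", rs),
                                   function(r) c(r$start, r$end)))
    cdss <- Filter(function(r) r$feature == "CDS", rs)
    if (is.null(exons)) {
      warning("transcript ", tid, " has CDS but no exon features; excluded")
      next
    }
    a <- rs[[1L]]$attrs
    biotype <- a[["gene_biotype"]] %||% a[["transcript_biotype"]] %||% "unknown"
    cds_span <- NULL
    if (length(cdss) > 0L) {
      cds_span <- c(min(vapply(cdss, function(r) r$start, integer(1))),
                    max(vapply(cdss, function(r) r$end, integer(1))))
    }
    m <- transcript_model(tid, a[["gene_id"]], rs[[1L]]$contig, rs[[1L]]$strand,
                          exons, cds_span = cds_span,
                          gene_name = a[["gene_name"]] %||% a[["gene_id"]],
                          biotype = biotype)
    if (!is.null(cds_span) && !.cds_within_exons(m)) {
      warning("transcript ", tid, ": CDS outside exon union; excluded as invalid")
      next
    }
    if (!is.null(expression)) {
      hit <- match(tid, expression$transcript_id)
      if (!is.na(hit)) m$fpkm <- expression$fpkm[hit]
    }
    models[[tid]] <- m
  }
  models
}

.parse_gtf_attributes <- function(s, line) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec('^(\\S+)\\s+"([^"]*)"$', p))[[1L]]
    if (length(m) != 3L)
      stop("GTF line ", line, ": malformed attribute '", p, "'")
    out[[m[2L]]] <- m[3L]
  }
  out
}

.cds_within_exons <- function(model) {
  cs <- model$cds_span
  !is.na(genomic_to_tx(model, cs[1L])) && !is.na(genomic_to_tx(model, cs[2L] - 1L))
}

#' Write transcript models as Ensembl-dialect GTF
#'
#' Inverse of [parse_annotations()]: emits one exon feature per exon and one
#' CDS feature per exonic CDS segment, converting back to 1-based inclusive
#' coordinates.
#'
#' @param models Named list of TranscriptModel objects.
#' @param path Output path (or NULL to return the lines).
#' @return The GTF lines, invisibly when `path` is given.
#' @export
write_gtf <- function(models, path = NULL) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     m$gene_id, m$transcript_id, m$gene_name, m$biotype)
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(m$contig, "cryptomap", "exon",
                              m$exons[i, 1L] + 1L, m$exons[i, 2L], ".",
                              m$strand, ".", attrs, sep = "\t"))
      if (!is.null(m$cds_span)) {
        s <- max(m$exons[i, 1L], m$cds_span[1L])
        e <- min(m$exons[i, 2L], m$cds_span[2L])
        if (e > s) {
          lines <- c(lines, paste(m$contig, "cryptomap", "CDS", s + 1L, e, ".",
                                  m$strand, ".", attrs, sep = "\t"))
        }
      }
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Derive 5'UTR/CDS/3'UTR structure in transcript coordinates
#'
#' Partitions the mature transcript [0, length) into 5'UTR, CDS and 3'UTR
#' intervals. On the minus strand the 5'UTR is the genomically rightmost
#' segment; the returned coordinates always run 5' to 3' along the mRNA.
#' Non-coding transcripts (no CDS) return an empty region map.
#'
#' @param model A TranscriptModel.
#' @return A data.frame with columns region, tx_start, tx_end (0-based
#'   half-open transcript coordinates); zero rows for non-coding transcripts.
#' @export
derive_transcript_regions <- function(model) {
  empty <- data.frame(region = character(), tx_start = integer(),
                      tx_end = integer(), stringsAsFactors = FALSE)
  if (is.null(model$cds_span)) return(empty)
  L <- tx_length(model)
  ends <- genomic_to_tx(model, c(model$cds_span[1L], model$cds_span[2L] - 1L))
  if (anyNA(ends))
    stop("transcript ", model$transcript_id, ": CDS span not congruent with exon union")
  cds_tx <- c(min(ends), max(ends) + 1L)
  cds_len <- sum(!is.na(genomic_to_tx(model, seq.int(model$cds_span[1L],
                                                     model$cds_span[2L] - 1L))))
  if (cds_len %% 3L != 0L)
    warning("transcript ", model$transcript_id, ": CDS length ", cds_len,
            " not divisible by 3 (annotation end-phase exception)")
  out <- data.frame(
    region = c("utr5", "cds", "utr3"),
    tx_start = c(0L, cds_tx[1L], cds_tx[2L]),
    tx_end = c(cds_tx[1L], cds_tx[2L], L),
    stringsAsFactors = FALSE)
  out[out$tx_end > out$tx_start, , drop = FALSE]
}

#' Extract the mature spliced transcript sequence
#'
#' Concatenates the exon sequences and reverse-complements on the minus
#' strand, returning the mRNA sequence read 5' to 3'.
#'
#' @param genome Named character vector of contig sequences.
#' @param model A TranscriptModel.
#' @return Single nucleotide string.
#' @export
extract_transcript_sequence <- function(genome, model) {
  contig <- genome[[model$contig]]
  if (is.null(contig)) stop("contig ", model$contig, " not in genome")
  if (any(model$exons[, 2L] > nchar(contig)) || any(model$exons[, 1L] < 0L))
    stop("exon out of contig bounds for ", model$transcript_id)
  parts <- substring(contig, model$exons[, 1L] + 1L, model$exons[, 2L])
  s <- paste0(parts, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}
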