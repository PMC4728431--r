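#' Configuration for the all-frames database build
#'
#' The sliding window is 33 bp = 3 x 11, so a window translates to at most an
#' 11-mer; products shorter than `min_peptide_len` (stop codon inside the
#' window) are excluded, and only peptides seen at least `s_min` times across
#' all windows of all reads (the S-value) are retained.
#'
#' @param window_bp Sliding-window width in base pairs (default 33).
#' @param min_peptide_len,max_peptide_len Retained peptide length range
#'   (defaults 8 and 11).
#' @param s_min Minimum S-value (seen count) to retain a peptide (default 10).
#' @return A `BuildConfig` list.
#' @export
build_config <- function(window_bp = 33L, min_peptide_len = 8L,
                         max_peptide_len = 11L, s_min = 10L) {
  stopifnot(window_bp == 3L * max_peptide_len,
            min_peptide_len <= max_peptide_len, s_min >= 1L)
  structure(list(window_bp = as.integer(window_bp),
                 min_peptide_len = as.integer(min_peptide_len),
                 max_peptide_len = as.integer(max_peptide_len),
                 s_min = as.integer(s_min)),
            class = "BuildConfig")
}

#' Integrate single-nucleotide variants into a genome
#'
#' Substitutes the alternate allele at each variant position, producing the
#' personalized genome used for both databases. Each variant's reference
#' allele must match the genome; two variants at one position are an error.
#'
#' @param genome Named character vector of contig sequences.
#' @param variants Data.frame with columns contig, pos (1-based), ref, alt.
#' @return The personalized genome (same contigs, same lengths).
#' @export
apply_variants <- function(genome, variants) {
  genome <- validate_genome(genome)
  if (is.null(variants) || nrow(variants) == 0L) return(genome)
  key <- paste(variants$contig, variants$pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("two variants at one position: ", d)
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$contig %in% names(genome))
      stop("variant contig ", v$contig, " not in genome")
    have <- substr(genome[[v$contig]], v$pos, v$pos)
    if (have != v$ref)
      stop("reference mismatch at ", v$contig, ":", v$pos,
           " (genome has ", have, ", variant says ", v$ref, ")")
    if (v$ref == v$alt) stop("ref equals alt at ", v$contig, ":", v$pos)
    substr(genome[[v$contig]], v$pos, v$pos) <- v$alt
  }
  genome
}

#' Six-frame sliding-window translation products of one read
#'
#' Slides a `window_bp`-wide window along the read in 1-nt steps; each window
#' is translated in its own frame on the forward sequence and on the reverse
#' complement of the window, which in aggregate covers all six reading frames.
#' Translation stops at the first stop codon (the prefix is emitted);
#' products shorter than `min_peptide_len` are discarded and windows
#' containing N are skipped.
#'
#' @param read Nucleotide string over \{A,C,G,T,N\}.
#' @param cfg A [build_config()].
#' @param read_id Identifier recorded with each product.
#' @return Data.frame with columns peptide, read_id, window_offset (0-based),
#'   strand ("forward"/"revcomp") and truncated.
#' @export
sixframe_window_products <- function(read, cfg = build_config(), read_id = "read") {
  w <- cfg$window_bp
  n <- nchar(read)
  empty <- data.frame(peptide = character(), read_id = character(),
                      window_offset = integer(), strand = character(),
                      truncated = logical(), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  offsets <- 0L:(n - w)
  fwd <- substring(read, offsets + 1L, offsets + w)
  ok <- !grepl("N", fwd, fixed = TRUE)
  if (!any(ok)) return(empty)
  offsets <- offsets[ok]
  fwd <- fwd[ok]
  rev <- revcomp(fwd)
  one_strand <- function(windows, strand) {
    tr <- .translate_windows(windows, cfg$max_peptide_len)
    keep <- nchar(tr$peptide) >= cfg$min_peptide_len
    data.frame(peptide = tr$peptide[keep],
               read_id = rep.int(read_id, sum(keep)),
               window_offset = offsets[keep],
               strand = rep.int(strand, sum(keep)),
               truncated = tr$truncated[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(fwd, "forward"), one_strand(rev, "revcomp"))
  rownames(out) <- NULL
  out
}

# Vectorized stop-aware translation of equal-width windows: returns the
# prefix before the first stop codon of each window and a truncation flag.
.translate_windows <- function(windows, n_codons) {
  n <- length(windows)
  gc <- .codon_table()
  aa <- matrix("", n, n_codons)
  for (ci in seq_len(n_codons)) {
    codon <- substring(windows, 3L * ci - 2L, 3L * ci)
    a <- unname(gc[codon])
    a[is.na(a)] <- "X"
    aa[, ci] <- a
  }
  full <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
  stop_at <- rep.int(n_codons + 1L, n)
  hits <- which(aa == "*", arr.ind = TRUE)
  if (nrow(hits) > 0L) {
    o <- order(hits[, 2L], decreasing = TRUE)   # smallest column wins last
    stop_at[hits[o, 1L]] <- hits[o, 2L]
  }
  list(peptide = substr(full, 1L, stop_at - 1L),
       truncated = stop_at <= n_codons)
}

#' Build the all-frames peptide database from reads
#'
#' Computes the S-value of every sliding-window translation product (the
#' number of times the peptide was seen across all reads, offsets and
#' strands; duplicate reads count) and retains peptides with S >=
#' `cfg$s_min`. The result is independent of read order.
#'
#' @param reads Named character vector of read sequences.
#' @param cfg A [build_config()].
#' @return Data.frame with columns sequence and s_value, sorted
#'   lexicographically by sequence; attribute "stats" carries build counts.
#' @export
build_allframes_db <- function(reads, cfg = build_config()) {
  if (length(reads) == 0L) {
    warning("no input reads; all-frames database is empty")
    out <- data.frame(sequence = character(), s_value = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "stats") <- list(n_reads = 0L, n_products = 0L, n_retained = 0L)
    return(out)
  }
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  peps <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    peps[[i]] <- sixframe_window_products(reads[[i]], cfg, ids[[i]])$peptide
  }
  all_peps <- unlist(peps, use.names = FALSE)
  counts <- table(all_peps)
  counts <- counts[counts >= cfg$s_min]
  out <- data.frame(sequence = sort(names(counts)),
                    s_value = as.integer(counts[sort(names(counts))]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "stats") <- list(n_reads = length(reads),
                             n_products = length(all_peps),
                             n_retained = nrow(out))
  out
}

#' Build the control (canonical proteome) database
#'
#' Translates the annotated CDS of every protein-coding transcript of the
#' (personalized) genome in its canonical reading frame. The trailing stop is
#' removed; a CDS with an internal stop is emitted truncated at that stop
#' with a warning.
#'
#' @param genome Named character vector of contig sequences (typically the
#'   personalized genome from [apply_variants()]).
#' @param models Named list of TranscriptModel objects.
#' @return Data.frame with columns identifier (transcript id), gene_id and
#'   sequence (protein).
#' @export
build_control_db <- function(genome, models) {
  rows <- list()
  for (m in models) {
    if (is.null(m$cds_span)) next
    cds <- cds_sequence(genome, m)
    aa <- translate_nt(cds)
    aa <- sub("\\*$", "", aa)
    star <- regexpr("*", aa, fixed = TRUE)
    if (star > 0L) {
      warning("internal stop codon in CDS of ", m$transcript_id,
              "; protein truncated")
      aa <- substr(aa, 1L, star - 1L)
    }
    if (nchar(aa) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      identifier = m$transcript_id, gene_id = m$gene_id, sequence = aa,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(identifier = character(), gene_id = character(),
               sequence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Spliced CDS sequence (5'->3') of a coding transcript.
cds_sequence <- function(genome, model) {
  regions <- derive_transcript_regions(model)
  cds <- regions[regions$region == "cds", ]
  tx <- extract_transcript_sequence(genome, model)
  substr(tx, cds$tx_start + 1L, cds$tx_end)
}

#' Write a peptide database as FASTA
#'
#' Headers follow the dialect `>pep|{sequence}|S={svalue}`; with
#' `include_decoys`, a trailing block of reversed-sequence decoys
#' (`>rev_pep|...`) is appended. Output order is lexicographic by sequence,
#' so the file is deterministic.
#'
#' @param entries Data.frame with columns sequence and s_value.
#' @param path Output path (NULL returns the FASTA lines).
#' @param include_decoys Append a reversed-peptide decoy block.
#' @return FASTA lines, invisibly when `path` is given.
#' @export
write_peptide_db <- function(entries, path = NULL, include_decoys = FALSE) {
  if (anyDuplicated(entries$sequence))
    stop("duplicate peptide sequences in database")
  o <- order(entries$sequence)
  entries <- entries[o, , drop = FALSE]
  lines <- as.vector(rbind(
    sprintf(">pep|%s|S=%d", entries$sequence, entries$s_value),
    entries$sequence))
  if (include_decoys && nrow(entries) > 0L) {
    revseq <- vapply(strsplit(entries$sequence, ""), function(x)
      paste0(rev(x), collapse = ""), character(1))
    lines <- c(lines, as.vector(rbind(
      sprintf(">rev_pep|%s|S=%d", revseq, entries$s_value), revseq)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read back a peptide database FASTA
#'
#' @param path Path to a FASTA written by [write_peptide_db()].
#' @param include_decoys Keep decoy (`rev_pep`) records too.
#' @return Data.frame with columns sequence, s_value and is_decoy.
#' @export
read_peptide_db <- function(path, include_decoys = FALSE) {
  ss <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(ss), "|", fixed = TRUE)
  out <- data.frame(
    sequence = as.character(ss),
    s_value = as.integer(sub("^S=", "", vapply(hdr, `[`, character(1), 3L))),
    is_decoy = vapply(hdr, `[`, character(1), 1L) == "rev_pep",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!include_decoys) out <- out[!out$is_decoy, , drop = FALSE]
  out
}

#' Write a protein database as FASTA
#'
#' @param entries Data.frame with columns identifier and sequence.
#' @param path Output path.
#' @param include_decoys Append reversed-sequence decoys (`rev_` prefix).
#' @return Invisibly, `path`.
#' @export
write_protein_db <- function(entries, path, include_decoys = FALSE) {
  lines <- as.vector(rbind(paste0(">", entries$identifier), entries$sequence))
  if (include_decoys && nrow(entries) > 0L) {
    revseq <- vapply(strsplit(entries$sequence, ""), function(x)
      paste0(rev(x), collapse = ""), character(1))
    lines <- c(lines, as.vector(rbind(paste0(">rev_", entries$identifier), revseq)))
  }
  writeLines(lines, path)
  invisible(path)
}
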