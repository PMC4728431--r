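#' Read a genome FASTA
#'
#' Loads a FASTA file into the package's genome representation: a named
#' character vector of uppercase contig sequences over \{A,C,G,T,N\}.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (one element per contig).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  validate_genome(g)
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- validate_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

validate_genome <- function(genome) {
  if (length(genome) == 0L) stop("genome has no contigs")
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
    stop("all contigs must be named")
  if (anyDuplicated(names(genome)))
    stop("duplicate contig names: ", paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  if (any(nchar(genome) == 0L)) stop("empty contig sequence")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("contig ", names(genome)[bad][1L], " contains characters outside {A,C,G,T,N}")
  genome
}

#' Read sequencing reads from FASTQ
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return Named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  r <- toupper(as.character(ss))
  names(r) <- sub("\\s.*$", "", names(ss))
  r
}

#' Write reads to FASTQ
#'
#' Writes reads with a constant placeholder base quality; the workflow treats
#' base qualities as an upstream concern and never consumes them.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  txt <- paste0("@", ids, "\n", reads, "\n+\n", qual)
  writeLines(txt, path)
  invisible(path)
}

#' Read single-nucleotide variants from a minimal VCF
#'
#' Only CHROM, POS, ID, REF, ALT and QUAL are consumed. Multi-allelic rows are
#' split into one record per alternate allele; rows whose REF or ALT is not a
#' single nucleotide are skipped with a warning (the workflow only integrates
#' single-nucleotide substitutions).
#'
#' @param path Path to a VCF file.
#' @param min_qual Minimum QUAL to retain a record (default 0: no extra
#'   filtering beyond what the upstream caller applied).
#' @return A data.frame with columns contig, pos (1-based), id, ref, alt, qual.
#' @export
read_vcf_snvs <- function(path, min_qual = 0) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 6L
  if (any(short)) stop("VCF record with fewer than 6 fields at data line ", which(short)[1L])
  out <- do.call(rbind, lapply(fields, function(f) {
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    data.frame(contig = f[1L], pos = as.integer(f[2L]), id = f[3L],
               ref = toupper(f[4L]), alt = toupper(alts),
               qual = suppressWarnings(as.numeric(f[6L])),
               stringsAsFactors = FALSE)
  }))
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    warning(sum(!snv), " non-SNV VCF record(s) skipped")
    out <- out[snv, , drop = FALSE]
  }
  out$qual[is.na(out$qual)] <- 0
  out <- out[out$qual >= min_qual, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with a header and columns peptide, score, database, is_decoy
#' and optionally modifications and spectrum_validated.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of PSM records.
#' @export
read_psms <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "score", "database", "is_decoy")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("PSM table missing column(s): ", paste(miss, collapse = ", "))
  d$is_decoy <- as.logical(d$is_decoy)
  if (any(d$score < 0)) stop("negative PSM score")
  d
}

#' Read a per-peptide per-allotype affinity table
#'
#' @param path TSV with columns peptide, allele, ic50_nM.
#' @return A data.frame of affinity records.
#' @export
read_affinities <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "ic50_nM")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("affinity table missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$ic50_nM <= 0)) stop("non-positive IC50")
  d
}

#' Read a transcript expression table
#'
#' @param path TSV with columns transcript_id, fpkm.
#' @return A data.frame with transcript_id and fpkm.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("transcript_id", "fpkm"), names(d))
  if (length(miss)) stop("expression table missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$fpkm < 0)) stop("negative FPKM")
  d
}

#' Read stabilizing/destabilizing element motif lists
#'
#' @param path TSV with columns motif and class (one of destabilizing,
#'   stabilizing). U is mapped to T internally.
#' @return A list with character vectors `destabilizing` and `stabilizing`.
#' @export
read_element_lists <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("motif", "class"), names(d))
  if (length(miss)) stop("element table missing column(s): ", paste(miss, collapse = ", "))
  motif <- chartr("Uu", "Tt", toupper(d$motif))
  if (any(!nzchar(motif))) stop("empty motif")
  bad <- setdiff(unique(d$class), c("destabilizing", "stabilizing"))
  if (length(bad)) stop("unknown element class: ", paste(bad, collapse = ", "))
  list(destabilizing = motif[d$class == "destabilizing"],
       stabilizing   = motif[d$class == "stabilizing"])
}

#' Read alignment intervals from a BED file
#'
#' BED6 rows become single-block records; BED12 rows are expanded into their
#' blocks (used for spliced peptide-coding regions).
#'
#' @param path Path to a BED6/BED12 file.
#' @return A data.frame with columns contig, start, end (0-based half-open),
#'   name, strand and block index.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("BED line ", i, " has fewer than 3 fields")
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    name <- if (length(f) >= 4L) f[4L] else paste0("rec", i)
    strand <- if (length(f) >= 6L) f[6L] else "+"
    if (length(f) >= 12L) {
      sizes <- as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1L]])
      offs <- as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1L]])
      data.frame(contig = f[1L], start = start + offs, end = start + offs + sizes,
                 name = name, strand = strand, block = seq_along(sizes),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(contig = f[1L], start = start, end = end, name = name,
                 strand = strand, block = 1L, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
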