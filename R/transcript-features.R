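#' 3'UTR length and intron count of a transcript
#'
#' Length is the number of exonic 3'UTR nucleotides; the intron count is the
#' number of annotated introns whose both flanks lie within the genomic span
#' of the 3'UTR.
#'
#' @param model A protein-coding TranscriptModel.
#' @return List with length_nt, intron_count and has_utr3.
#' @export
utr3_metrics <- function(model) {
  regions <- derive_transcript_regions(model)
  utr3 <- regions[regions$region == "utr3", ]
  if (nrow(utr3) == 0L)
    return(list(length_nt = 0L, intron_count = 0L, has_utr3 = FALSE))
  len <- utr3$tx_end - utr3$tx_start
  gpos <- tx_to_genomic(model, seq.int(utr3$tx_start, utr3$tx_end - 1L))
  span <- range(gpos)
  ex <- model$exons
  n_introns <- 0L
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      # intron between exon i and i+1, with both flanking bases in the 3'UTR
      if ((ex[i, 2L] - 1L) >= span[1L] && ex[i + 1L, 1L] <= span[2L] + 1L &&
          !is.na(genomic_to_tx(model, ex[i, 2L] - 1L)) &&
          (ex[i, 2L] - 1L) %in% gpos && ex[i + 1L, 1L] %in% gpos)
        n_introns <- n_introns + 1L
    }
  }
  list(length_nt = as.integer(len), intron_count = n_introns, has_utr3 = TRUE)
}

#' Count stability-element motif occurrences in a 3'UTR
#'
#' Counts all exact (possibly overlapping) occurrences of every motif in
#' each list.
#'
#' @param utr_sequence Nucleotide string (U is mapped to T).
#' @param lists List with character vectors `destabilizing` and
#'   `stabilizing` (see [read_element_lists()]).
#' @return List with destabilizing_count and stabilizing_count.
#' @export
scan_elements <- function(utr_sequence, lists) {
  utr_sequence <- chartr("Uu", "Tt", toupper(utr_sequence))
  count_list <- function(motifs) {
    if (length(motifs) == 0L) {
      warning("empty motif list")
      return(0L)
    }
    total <- 0L
    for (m in motifs) {
      k <- nchar(m)
      n <- nchar(utr_sequence)
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      total <- total + sum(substring(utr_sequence, starts, starts + k - 1L) == m)
    }
    as.integer(total)
  }
  list(destabilizing_count = count_list(lists$destabilizing),
       stabilizing_count = count_list(lists$stabilizing))
}

#' Compare 3'UTR stability profiles between cryptic and conventional groups
#'
#' 3'UTR lengths are compared with a two-sided Wilcoxon rank-sum test,
#' element counts with a one-sided test (alternative: cryptic greater), and
#' intron presence (none versus at least one) with a two-sided Fisher's
#' exact test.
#'
#' @param cryptic,conventional Data.frames with columns length_nt,
#'   intron_count, destabilizing_count, stabilizing_count (one row per
#'   source transcript).
#' @return List of test results and per-group medians, or a marker list with
#'   `insufficient_data = TRUE` when a group has fewer than 2 profiles.
#' @export
compare_stability <- function(cryptic, conventional) {
  if (nrow(cryptic) < 2L || nrow(conventional) < 2L)
    return(list(insufficient_data = TRUE))
  wt <- function(x, y, alternative)
    suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))$p.value
  intron_tab <- rbind(
    cryptic = c(sum(cryptic$intron_count == 0L), sum(cryptic$intron_count > 0L)),
    conventional = c(sum(conventional$intron_count == 0L),
                     sum(conventional$intron_count > 0L)))
  list(
    insufficient_data = FALSE,
    utr3_length = list(
      median_cryptic = stats::median(cryptic$length_nt),
      median_conventional = stats::median(conventional$length_nt),
      p_value = wt(cryptic$length_nt, conventional$length_nt, "two.sided")),
    destabilizing = list(
      median_cryptic = stats::median(cryptic$destabilizing_count),
      median_conventional = stats::median(conventional$destabilizing_count),
      p_value = wt(cryptic$destabilizing_count, conventional$destabilizing_count,
                   "greater")),
    stabilizing = list(
      median_cryptic = stats::median(cryptic$stabilizing_count),
      median_conventional = stats::median(conventional$stabilizing_count),
      p_value = wt(cryptic$stabilizing_count, conventional$stabilizing_count,
                   "greater")),
    introns = contingency_result(intron_tab, "two.sided"))
}

#' Compare source-gene expression between MAP groups
#'
#' @param cryptic_fpkm,conventional_fpkm Positive FPKM values of the source
#'   genes of each MAP group.
#' @param all_fpkm Optional FPKM of all expressed genes (context medians).
#' @return List with per-group log10-FPKM medians and a two-sided rank-sum
#'   p-value between the cryptic and conventional groups.
#' @export
expression_compare <- function(cryptic_fpkm, conventional_fpkm, all_fpkm = NULL) {
  lc <- log10(cryptic_fpkm[cryptic_fpkm > 0])
  lv <- log10(conventional_fpkm[conventional_fpkm > 0])
  out <- list(
    median_log10_cryptic = stats::median(lc),
    median_log10_conventional = stats::median(lv),
    p_value = suppressWarnings(stats::wilcox.test(lc, lv)$p.value))
  if (!is.null(all_fpkm))
    out$median_log10_all <- stats::median(log10(all_fpkm[all_fpkm > 0]))
  out
}

#' Load a codon usage table
#'
#' Reads a TSV with columns codon and frequency (any unit proportional to
#' usage, e.g. occurrences per thousand codons) and normalizes frequencies
#' within each synonymous family (stop codons form their own 3-member
#' family). The package bundles a standard published human codon usage
#' table as `system.file("extdata", "codon_usage_human.tsv", package =
#' "cryptomap")`.
#'
#' @param path Path to the TSV (default: the bundled human table).
#' @return Named numeric vector of within-family usage fractions for all 64
#'   codons, with attribute "family_size".
#' @export
read_codon_usage <- function(path = system.file("extdata", "codon_usage_human.tsv",
                                                package = "cryptomap")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("codon", "frequency"), names(d))
  if (length(miss)) stop("codon table missing column(s): ", paste(miss, collapse = ", "))
  codons <- chartr("Uu", "Tt", toupper(d$codon))
  freq <- as.numeric(d$frequency)
  names(freq) <- codons
  gc <- .codon_table()
  if (length(setdiff(names(gc), codons)) > 0L)
    stop("codon table missing codon(s): ",
         paste(setdiff(names(gc), codons), collapse = ", "))
  fam <- gc[names(freq)]
  fam_tot <- tapply(freq, fam, sum)
  frac <- freq / as.numeric(fam_tot[fam])
  fam_size <- table(gc)
  attr(frac, "family_size") <- as.integer(fam_size[fam])
  frac
}

#' Classify codons as rare or common
#'
#' A codon is rare when its observed within-family usage fraction is below
#' the expected uniform fraction (1 / family size) and common when above;
#' exact ties (single-codon families, or balanced usage) go to common.
#'
#' @param usage Named fraction vector from [read_codon_usage()].
#' @return List with character vectors `rare` and `common` partitioning all
#'   64 codons.
#' @export
classify_codons <- function(usage) {
  if (length(usage) != 64L) stop("codon usage table must cover all 64 codons")
  expected <- 1 / attr(usage, "family_size")
  rare <- names(usage)[usage < expected - 1e-9]
  list(rare = sort(rare), common = sort(setdiff(names(usage), rare)))
}

#' Rare-codon enrichment between two groups of coding sequences
#'
#' Counts rare and common codons over each group's in-frame sequences and
#' tests the 2x2 group-by-class table with a two-sided Fisher's exact test.
#'
#' @param group_a_sequences,group_b_sequences Character vectors of in-frame
#'   nucleotide sequences (length a multiple of 3).
#' @param usage Codon usage fractions from [read_codon_usage()].
#' @return A [contingency_result()] augmented with per-group counts (group A
#'   is the first table row).
#' @export
rare_codon_enrichment <- function(group_a_sequences, group_b_sequences, usage) {
  cls <- classify_codons(usage)
  count_group <- function(seqs) {
    bad <- nchar(seqs) %% 3L != 0L
    if (any(bad)) stop("sequence length not a multiple of 3 (", sum(bad), " sequence(s))")
    codons <- unlist(lapply(seqs, function(s) {
      starts <- seq.int(1L, nchar(s), by = 3L)
      substring(s, starts, starts + 2L)
    }))
    c(rare = sum(codons %in% cls$rare), common = sum(codons %in% cls$common))
  }
  a <- count_group(chartr("Uu", "Tt", toupper(group_a_sequences)))
  b <- count_group(chartr("Uu", "Tt", toupper(group_b_sequences)))
  res <- contingency_result(rbind(a, b), "two.sided")
  res$counts <- rbind(group_a = a, group_b = b)
  res
}

#' Classify a SNP overlapping a PCR by mutate-and-translate
#'
#' Substitutes the alternate allele into the PCR nucleotide sequence
#' (complemented for minus-strand loci), translates it in the PCR's frame
#' and compares the result with the originally identified MAP: identical
#' means synonymous, otherwise non-synonymous.
#'
#' @param locus A `PcrLocus`.
#' @param variant One-row data.frame (contig, pos 1-based, ref, alt, id).
#' @param genome Genome used to cross-check the reference allele.
#' @return List with id, call ("synonymous"/"non_synonymous") and the mutated
#'   peptide.
#' @export
classify_snp <- function(locus, variant, genome = NULL) {
  g0 <- variant$pos - 1L
  bases <- locus_bases(locus)
  idx <- match(g0, bases)
  if (variant$contig != locus$contig || is.na(idx))
    stop("variant ", variant$contig, ":", variant$pos, " outside the PCR")
  if (!is.null(genome)) {
    have <- substr(genome[[variant$contig]], variant$pos, variant$pos)
    if (have != variant$ref)
      stop("reference mismatch at ", variant$contig, ":", variant$pos)
  }
  # offset of the base within the 5'->3' coding sequence
  off <- if (locus$strand == "+") idx else length(bases) - idx + 1L
  alt <- if (locus$strand == "+") variant$alt else revcomp(variant$alt)
  nt <- locus$nt_sequence
  substr(nt, off, off) <- alt
  mutated <- translate_nt(nt)
  call <- if (mutated == locus$peptide) "synonymous" else "non_synonymous"
  list(id = variant$id %||% NA_character_, call = call, mutated_peptide = mutated)
}

#' ns-SNP frequency per bp in cryptic versus conventional PCRs
#'
#' Intersects a population variant set with each group's PCRs, classifies
#' every overlapping SNP by mutate-and-translate, and reports the
#' non-synonymous SNP frequency per (deduplicated) PCR base pair per group,
#' with a two-sided Fisher's exact test on the 2x2 of
#' (ns-SNP count, remaining bp) by group.
#'
#' @param cryptic_loci,conventional_loci Lists of `PcrLocus` objects.
#' @param variants Data.frame of SNVs (contig, pos, ref, alt, id).
#' @param genome Genome for reference-allele checks.
#' @return List with per-group frequencies, counts, bp totals and a
#'   [contingency_result()].
#' @export
nssnp_frequency <- function(cryptic_loci, conventional_loci, variants, genome) {
  group_stats <- function(loci) {
    keys <- character(0); ns <- 0L
    for (locus in loci) {
      keys <- c(keys, paste(locus$contig, locus_bases(locus)))
      if (nrow(variants) == 0L) next
      for (i in seq_len(nrow(variants))) {
        v <- variants[i, ]
        if (v$contig != locus$contig) next
        if (!((v$pos - 1L) %in% locus_bases(locus))) next
        if (classify_snp(locus, v, genome)$call == "non_synonymous") ns <- ns + 1L
      }
    }
    list(bp = length(unique(keys)), ns = ns)
  }
  a <- group_stats(cryptic_loci)
  b <- group_stats(conventional_loci)
  if (a$bp == 0L || b$bp == 0L) stop("zero total PCR bp in a group")
  tab <- rbind(cryptic = c(a$ns, a$bp - a$ns),
               conventional = c(b$ns, b$bp - b$ns))
  list(freq_cryptic = a$ns / a$bp, freq_conventional = b$ns / b$bp,
       ns_cryptic = a$ns, ns_conventional = b$ns,
       bp_cryptic = a$bp, bp_conventional = b$bp,
       test = contingency_result(tab, "two.sided"))
}
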