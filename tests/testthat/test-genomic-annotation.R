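# All-positions oracle: check every genomic start on both strands.
oracle_locate <- function(peptide, genome) {
  L3 <- 3 * nchar(peptide)
  hits <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    for (start in 0:(nchar(s) - L3)) {
      seg <- substr(s, start + 1, start + L3)
      if (oracle_translate(seg) == peptide)
        hits[[length(hits) + 1]] <- c(ctg, start, "+")
      if (oracle_translate(oracle_revcomp(seg)) == peptide)
        hits[[length(hits) + 1]] <- c(ctg, start, "-")
    }
  }
  hits
}

.plant_genome <- function(pep, n_copies = 1, len = 3000, seed = 61) {
  set.seed(seed)
  g <- c(chrA = random_nt(len), chrB = random_nt(len))
  enc <- vapply(strsplit(pep, "")[[1]], function(a) {
    opts <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    opts[1]
  }, character(1))
  enc <- paste0(enc, collapse = "")
  at <- c(500, 1500)
  ctg <- c("chrA", "chrB")
  for (i in seq_len(n_copies)) {
    substr(g[[ctg[i]]], at[i] + 1, at[i] + nchar(enc)) <- enc
  }
  list(genome = g, enc = enc, at = at[seq_len(n_copies)])
}

test_that("planted peptides are located with a translation-checked locus", {
  pg <- .plant_genome("MAWKGLEDQKV", 1)
  loci <- locate_pcr("MAWKGLEDQKV", pg$genome)
  expect_length(loci, 1L)
  expect_equal(unname(loci[[1]]$blocks[1, ]), c(500L, 533L))
  expect_equal(translate_nt(loci[[1]]$nt_sequence), "MAWKGLEDQKV")
  pg2 <- .plant_genome("MAWKGLEDQKV", 2)
  expect_length(locate_pcr("MAWKGLEDQKV", pg2$genome), 2L)
})

test_that("locate_pcr equals the all-positions oracle on random peptides", {
  set.seed(62)
  g <- c(chrA = random_nt(900))
  for (i in 1:8) {
    pep <- random_peptide(sample(8:9, 1))
    got <- locate_pcr(pep, g)
    want <- oracle_locate(pep, g)
    expect_equal(length(got), length(want))
    if (length(got)) {
      got_keys <- sort(vapply(got, function(l)
        paste(l$contig, l$blocks[1, 1], l$strand), character(1)))
      want_keys <- sort(vapply(want, function(h)
        paste(h[1], h[2], h[3]), character(1)))
      expect_identical(got_keys, want_keys)
    }
  }
  # a peptide whose encoding is planted also appears via the oracle
  pg <- .plant_genome("MAWKGLEDQKV", 1)
  expect_equal(length(oracle_locate("MAWKGLEDQKV", pg$genome)),
               length(locate_pcr("MAWKGLEDQKV", pg$genome)))
})

test_that("unique-locus filtering discards multi-locus peptides", {
  pg <- .plant_genome("MAWKGLEDQKV", 2)
  loci <- locate_pcr("MAWKGLEDQKV", pg$genome)
  r <- filter_unique_locus("MAWKGLEDQKV", loci)
  expect_equal(r$reason, "multi_locus")
  expect_s3_class(filter_unique_locus("MAWKGLEDQKV", loci[1]), "PcrLocus")
  expect_error(filter_unique_locus("X", list()), "unlocatable")
})

.toy_models <- function() {
  list(
    T1 = transcript_model("T1", "G1", "chr1", "+",
                          rbind(c(100, 250), c(350, 500)), cds_span = c(150, 451),
                          biotype = "protein_coding", fpkm = 5),
    T2 = transcript_model("T2", "G1", "chr1", "+",
                          rbind(c(100, 500)), biotype = "retained_intron",
                          fpkm = 1),
    T3 = transcript_model("T3", "G2", "chr1", "-",
                          rbind(c(700, 900)), cds_span = c(750, 870),
                          biotype = "protein_coding", fpkm = 2))
}

.locus_at <- function(genome, contig, start, len, strand) {
  nt <- substr(genome[[contig]], start + 1, start + len)
  if (strand == "-") nt <- revcomp(nt)
  pcr_locus(contig, rbind(c(start, start + len)), strand, nt, translate_nt(nt))
}

test_that("source-gene assignment follows strand-aware overlap precedence", {
  set.seed(63)
  g <- c(chr1 = random_nt(1200))
  ms <- .toy_models()
  plus_locus <- .locus_at(g, "chr1", 180, 33, "+")
  expect_equal(assign_source_gene(plus_locus, ms),
               list(type = "gene", gene_id = "G1", reason = NA_character_))
  anti <- .locus_at(g, "chr1", 180, 33, "-")
  r <- assign_source_gene(anti, ms)
  expect_equal(r$type, "antisense")
  expect_equal(r$gene_id, "G1")
  inter <- .locus_at(g, "chr1", 1000, 33, "+")
  expect_equal(assign_source_gene(inter, ms)$type, "intergenic")
  # nested same-strand genes -> ambiguous discard
  ms2 <- c(ms, list(T4 = transcript_model("T4", "G3", "chr1", "+",
                                          rbind(c(150, 300)))))
  r2 <- assign_source_gene(plus_locus, ms2)
  expect_equal(r2$type, "discard")
  expect_equal(r2$reason, "multi_gene")
})

test_that("assignment agrees with a naive interval-overlap oracle", {
  set.seed(64)
  g <- c(chr1 = random_nt(1200))
  ms <- .toy_models()
  spans <- list(G1 = c(100, 500, "+"), G2 = c(700, 900, "-"))
  for (i in 1:25) {
    start <- sample(0:1150, 1)
    strand <- sample(c("+", "-"), 1)
    locus <- .locus_at(g, "chr1", start, 33, strand)
    same <- opp <- character(0)
    for (gid in names(spans)) {
      sp <- spans[[gid]]
      if (start < as.numeric(sp[2]) && start + 33 > as.numeric(sp[1])) {
        if (sp[3] == strand) same <- c(same, gid) else opp <- c(opp, gid)
      }
    }
    got <- assign_source_gene(locus, ms)
    if (length(same) == 1) expect_equal(got, list(type = "gene", gene_id = same,
                                                  reason = NA_character_))
    else if (length(same) > 1) expect_equal(got$reason, "multi_gene")
    else if (length(opp) >= 1) expect_equal(got$type, "antisense")
    else expect_equal(got$type, "intergenic")
  }
})

test_that("isoform selection maximizes FPKM with deterministic ties", {
  ms <- .toy_models()
  expect_equal(select_source_isoform("G1", ms)$transcript_id, "T1")
  ms$T2$fpkm <- 5
  expect_equal(select_source_isoform("G1", ms)$transcript_id, "T1")  # tie -> min id
  ms$T1$fpkm <- 0; ms$T2$fpkm <- 0
  expect_warning(iso <- select_source_isoform("G1", ms), "no expressed isoform")
  expect_equal(iso$transcript_id, "T2")          # longest transcript fallback
  expr <- data.frame(transcript_id = c("T1", "T2"), fpkm = c(1, 9))
  expect_equal(select_source_isoform("G1", .toy_models(), expr)$transcript_id, "T2")
})

test_that("region classification follows the boundary rules", {
  set.seed(65)
  g <- c(chr1 = random_nt(1200))
  m <- .toy_models()$T1                      # 5'UTR [100,150), CDS, introns
  expect_equal(classify_region(.locus_at(g, "chr1", 110, 33, "+"), m), "5UTR")
  expect_equal(classify_region(.locus_at(g, "chr1", 140, 33, "+"), m), "5UTR/EXON")
  expect_equal(classify_region(.locus_at(g, "chr1", 160, 33, "+"), m), "EXON")
  expect_equal(classify_region(.locus_at(g, "chr1", 260, 33, "+"), m), "INTRON")
  expect_equal(classify_region(.locus_at(g, "chr1", 240, 33, "+"), m), "INTRON/EXON")
  expect_equal(classify_region(.locus_at(g, "chr1", 460, 33, "+"), m), "3UTR")
  expect_error(classify_region(.locus_at(g, "chr1", 600, 33, "+"), m),
               "does not lie within")
})

test_that("classification agrees with the per-base labelling oracle", {
  set.seed(66)
  g <- c(chr1 = random_nt(1200))
  m <- .toy_models()$T1
  for (i in 1:40) {
    start <- sample(90:460, 1)
    locus <- .locus_at(g, "chr1", start, 33, "+")
    labels <- vapply(start:(start + 32), function(p) oracle_base_label(m, p),
                     character(1))
    if (any(labels == "outside")) {
      expect_error(classify_region(locus, m))
      next
    }
    want <- if (any(labels == "intron") && !all(labels == "intron")) "INTRON/EXON"
      else if (all(labels == "intron")) "INTRON"
      else if (all(labels == "utr5")) "5UTR"
      else if (all(labels == "cds")) "EXON"
      else if (all(labels == "utr3")) "3UTR"
      else if (all(labels %in% c("utr5", "cds"))) "5UTR/EXON"
      else NA_character_
    if (is.na(want)) next                    # cds/utr3 mixes not classified
    expect_equal(classify_region(locus, m), want, label = paste("start", start))
  }
})

test_that("retained-intron isoforms reclassify intron-retaining hits", {
  set.seed(67)
  g <- c(chr1 = random_nt(1200))
  ms <- .toy_models()
  locus <- .locus_at(g, "chr1", 270, 33, "+")   # inside T1's intron
  expect_equal(classify_region(locus, ms$T1, ms), "INTRON")
  expect_equal(classify_region(locus, ms$T2, ms), "RETAINED_INTRON")
})

test_that("reading-frame validation uses CDS offset mod 3 plus translation", {
  set.seed(68)
  g <- c(chr1 = random_nt(1200))
  m <- .toy_models()$T1                      # CDS tx offset 50, + strand
  # PCR at CDS start + 12 nt (tx 62): in frame iff translation matches
  in_locus <- .locus_at(g, "chr1", 162, 33, "+")
  expect_equal(validate_reading_frame(in_locus, m, g), "in")
  out_locus <- .locus_at(g, "chr1", 163, 33, "+")
  expect_equal(validate_reading_frame(out_locus, m, g), "out")
  utr_locus <- .locus_at(g, "chr1", 110, 33, "+")
  expect_equal(validate_reading_frame(utr_locus, m, g,
                                      status = classify_region(utr_locus, m)),
               "none")
})

test_that("PCR coverage counts reads overlapping by at least 1 bp", {
  set.seed(69)
  g <- c(chr1 = random_nt(1200))
  locus <- .locus_at(g, "chr1", 200, 33, "+")
  aln <- data.frame(contig = "chr1",
                    start = c(150, 210, 232, 233, 100),
                    end = c(201, 260, 300, 300, 140),
                    name = paste0("r", 1:5), strand = "+", block = 1L)
  # r1 overlaps base 200; r4 starts exactly at the half-open end -> no overlap
  expect_equal(pcr_coverage(locus, aln), 3L)
  naive <- sum(vapply(seq_len(nrow(aln)), function(i)
    aln$start[i] < 233 && aln$end[i] > 200, logical(1)))
  expect_equal(pcr_coverage(locus, aln), naive)
})

test_that("positional bias is the normalized transcript start", {
  set.seed(70)
  g <- c(chr1 = random_nt(1200))
  m <- transcript_model("T", "G", "chr1", "+", rbind(c(0, 1000)),
                        cds_span = c(300, 900))
  expect_equal(positional_bias(.locus_at(g, "chr1", 100, 33, "+"), m, "5UTR"), 0.1)
  expect_equal(positional_bias(.locus_at(g, "chr1", 0, 33, "+"), m, "5UTR"), 0)
  expect_true(is.na(positional_bias(.locus_at(g, "chr1", 100, 33, "+"), m,
                                    "INTERGENIC")))
  expect_true(is.na(positional_bias(.locus_at(g, "chr1", 100, 33, "+"), m,
                                    "ANTISENSE")))
})

test_that("5'UTR-planted starts sit left of CDS-planted starts", {
  set.seed(71)
  g <- c(chr1 = random_nt(3000))
  m <- transcript_model("T", "G", "chr1", "+", rbind(c(0, 2800)),
                        cds_span = c(600, 2400))
  pos_utr <- replicate(50, positional_bias(
    .locus_at(g, "chr1", sample(0:560, 1), 33, "+"), m, "5UTR"))
  pos_cds <- replicate(50, positional_bias(
    .locus_at(g, "chr1", sample(620:2300, 1), 33, "+"), m, "EXON"))
  p <- stats::wilcox.test(pos_utr, pos_cds, alternative = "less")$p.value
  expect_lt(p, 0.05)
})
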