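test_that("Kozak contexts follow the optimal/strong/weak patterns", {
  # GCCACC ATG G -> optimal
  expect_equal(as.character(kozak_context("TTGCCACCATGGTT", 8)), "optimal")
  # AAAACC ATG G: -3 = A, +4 = G but prefix not GCC(R)CC -> strong
  expect_equal(as.character(kozak_context("TTAAAACCATGGTT", 8)), "strong")
  # CCCCCC ATG C: -3 = C -> weak
  expect_equal(as.character(kozak_context("TTCCCCCCATGCTT", 8)), "weak")
  # GCCGCC ATG G -> optimal with R = G
  expect_equal(as.character(kozak_context("TTGCCGCCATGGTT", 8)), "optimal")
  # +4 not G -> never optimal/strong
  expect_equal(as.character(kozak_context("TTGCCACCATGCTT", 8)), "weak")
  short <- kozak_context("ATGG", 0)
  expect_equal(as.character(short), "weak")
  expect_true(attr(short, "insufficient_context"))
})

test_that("start prediction applies the three rules in order", {
  pcr <- "GCTGCTAAAGGTCTGGAAGATCTGAAAGTTGCT"    # stop-free 33-mer
  # rule i: upstream in-frame ATG after a stop
  s1 <- paste0("TAAGGGATGGCA", pcr)
  r1 <- predict_start(s1, 12)
  expect_equal(r1$rule_applied, "i")
  expect_equal(r1$codon, "ATG")
  expect_equal(r1$position, 6)
  # rule ii: CUG in an optimal context when no ATG exists
  s2 <- paste0("TAAGCCACCCTGGCCCCC", pcr)
  r2 <- predict_start(s2, 18)
  expect_equal(r2$rule_applied, "ii")
  expect_equal(r2$codon, "CTG")
  expect_equal(r2$codon_class, "near_cognate")
  expect_equal(r2$kozak, "optimal")
  # rule iii: first codon after the upstream stop
  s3 <- paste0("TGAAAACCC", pcr)
  r3 <- predict_start(s3, 9)
  expect_equal(r3$rule_applied, "iii")
  expect_equal(r3$codon, "AAA")
  expect_equal(r3$position, 3)
})

test_that("start prediction matches the brute-force codon scan", {
  set.seed(81)
  pcr <- "GCTGCTAAAGGTCTGGAAGATCTGAAAGTTGCT"
  for (i in 1:100) {
    up <- random_nt(3 * sample(5:40, 1) + sample(0:2, 1))
    seqn <- paste0(up, pcr)
    off <- nchar(up)
    got <- predict_start(seqn, off)
    want <- oracle_predict_start(seqn, off)
    expect_equal(got$position, want$position, label = paste("case", i))
    expect_equal(got$rule_applied, want$rule, label = paste("case", i))
  }
})

test_that("the minimal source protein is 10 aa for a 9-mer MAP", {
  # ATG + 9 codons + stop: N-terminal Met trimming yields the MAP
  map9 <- "ALDKWQSVR"
  enc <- vapply(strsplit(map9, "")[[1]], function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, character(1))
  seqn <- paste0("TAATTT", "ATG", paste0(enc, collapse = ""), "TGA", "CCC")
  orf <- predict_orf(seqn, 9, map9)
  expect_equal(orf$length_aa, 10L)
  expect_equal(orf$protein, paste0("M", map9))
  expect_equal(orf$start$rule_applied, "i")
  expect_false(orf$truncated_at_end)
  expect_equal(orf$stop_position, 9 + 27)
})

test_that("near-cognate initiators are decoded as methionine", {
  map9 <- "ALDKWQSVR"
  enc <- vapply(strsplit(map9, "")[[1]], function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, character(1))
  # CUG in optimal context, then an in-frame PCR and stop
  seqn <- paste0("TAAGCCACCCTGG", "CC", paste0(enc[-1], collapse = ""), "TAG")
  off <- 15                                   # PCR starts at codon 2
  orf <- predict_orf(seqn, off, substr(map9, 2, 9))
  expect_equal(substr(orf$protein, 1, 1), "M")
  expect_equal(orf$start$codon, "CTG")
  expect_equal(orf$start$codon_class, "near_cognate")
})

test_that("predicted proteins contain the MAP and handle missing stops", {
  set.seed(82)
  for (i in 1:25) {
    map <- random_peptide(sample(8:11, 1))
    enc <- vapply(strsplit(map, "")[[1]], function(a) {
      opts <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
      opts[sample.int(length(opts), 1)]
    }, character(1))
    up <- random_nt(3 * sample(4:20, 1))
    down <- random_nt(3 * sample(0:10, 1))
    seqn <- paste0(up, paste0(enc, collapse = ""), down)
    orf <- predict_orf(seqn, nchar(up), map)
    expect_true(grepl(substr(map, 2, nchar(map)), orf$protein, fixed = TRUE))
    expect_lte(orf$start$position, nchar(up))
    if (!orf$truncated_at_end)
      expect_gte(orf$stop_position, nchar(up) + 3 * nchar(map))
  }
})

test_that("uORF detection requires optimal/strong AUG in the 5'UTR", {
  regions <- data.frame(region = c("utr5", "cds", "utr3"),
                        tx_start = c(0L, 50L, 110L), tx_end = c(50L, 110L, 160L))
  base <- strrep("C", 160)
  # strong-context ATG (0-based 6) with in-frame stop at 30 -> contained uORF
  s <- base
  substr(s, 4, 4) <- "A"                          # -3 = A
  substr(s, 7, 9) <- "ATG"
  substr(s, 10, 10) <- "G"                        # +4 = G
  substr(s, 31, 33) <- "TAA"
  u <- find_uorfs(s, regions)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start_position, 6L)
  expect_equal(u$stop_position, 30L)
  expect_equal(u$location, "contained_5UTR")
  # weak context only -> nothing
  s2 <- base
  substr(s2, 7, 9) <- "ATG"
  expect_equal(nrow(find_uorfs(s2, regions)), 0L)
  # no in-frame stop before the CDS -> junction uORF
  s3 <- base
  substr(s3, 4, 4) <- "G"
  substr(s3, 7, 9) <- "ATG"
  substr(s3, 10, 10) <- "G"
  substr(s3, 91, 93) <- "TGA"                     # stop beyond CDS start (50)
  u3 <- find_uorfs(s3, regions)
  expect_equal(u3$location, "junction_5UTR_exon")
})

test_that("uORF sets match a naive scan on random transcripts", {
  set.seed(83)
  regions <- data.frame(region = c("utr5", "cds", "utr3"),
                        tx_start = c(0L, 60L, 120L), tx_end = c(60L, 120L, 150L))
  for (i in 1:20) {
    s <- random_nt(150)
    got <- find_uorfs(s, regions)
    naive <- list()
    for (p in 0:59) {
      if (substr(s, p + 1, p + 3) != "ATG") next
      ctx <- as.character(kozak_context(s, p))
      if (!ctx %in% c("optimal", "strong")) next
      stop_pos <- NA
      q <- p
      while (q + 3 <= 150) {
        if (substr(s, q + 1, q + 3) %in% c("TAA", "TAG", "TGA") && q > p) {
          stop_pos <- q; break
        }
        q <- q + 3
      }
      naive[[length(naive) + 1]] <- c(p, stop_pos)
    }
    expect_equal(nrow(got), length(naive))
    if (length(naive)) {
      expect_equal(got$start_position, vapply(naive, `[`, numeric(1), 1))
      expect_equal(got$stop_position, vapply(naive, `[`, numeric(1), 2))
    }
  }
})

test_that("ORF context uses transcripts for sense and flanks otherwise", {
  set.seed(84)
  g <- c(chr1 = random_nt(2500))
  m <- list(T1 = transcript_model("T1", "G1", "chr1", "+",
                                  rbind(c(300, 900)), cds_span = c(450, 750)))
  nt <- substr(g[["chr1"]], 501, 533)
  locus <- pcr_locus("chr1", rbind(c(500, 533)), "+", nt, translate_nt(nt))
  row_sense <- data.frame(cryptic_status = "EXON", source_transcript_id = "T1",
                          stringsAsFactors = FALSE)
  ctx <- orf_context(row_sense, locus, g, m)
  expect_equal(ctx$pcr_offset, 200L)
  expect_equal(nchar(ctx$sequence), 600L)
  row_inter <- data.frame(cryptic_status = "INTERGENIC",
                          source_transcript_id = NA_character_,
                          stringsAsFactors = FALSE)
  ctx2 <- orf_context(row_inter, locus, g, m, flank_bp = 100)
  expect_equal(ctx2$pcr_offset, 100L)
  expect_equal(nchar(ctx2$sequence), 233L)
  # minus-strand flank is reverse-complemented with the mirrored offset
  locus_m <- pcr_locus("chr1", rbind(c(500, 533)), "-", revcomp(nt),
                       translate_nt(revcomp(nt)))
  ctx3 <- orf_context(row_inter, locus_m, g, m, flank_bp = 100)
  expect_equal(ctx3$pcr_offset, 100L)
  expect_equal(substr(ctx3$sequence, 101, 133), revcomp(nt))
})
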