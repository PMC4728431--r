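test_that("3'UTR metrics count exonic length and internal introns", {
  # 3'UTR split 150 + 50 nt over two exons with one intervening intron
  m <- transcript_model("t", "g", "chr1", "+",
                        rbind(c(0, 300), c(400, 550), c(700, 750)),
                        cds_span = c(30, 150))
  r <- utr3_metrics(m)
  expect_equal(r$length_nt, 350L)               # 150 (exon1 tail) + 150 + 50
  expect_equal(r$intron_count, 2L)
  m2 <- transcript_model("t2", "g", "chr1", "+", rbind(c(0, 120)),
                         cds_span = c(0, 120))
  r2 <- utr3_metrics(m2)
  expect_equal(r2$length_nt, 0L)
  expect_false(r2$has_utr3)
})

test_that("element scanning counts overlapping exact matches", {
  lists <- list(destabilizing = "ATTTA", stabilizing = "AGGGA")
  r <- scan_elements("ATTTATTTA", lists)
  expect_equal(r$destabilizing_count, 2L)       # offsets 0 and 4 overlap
  expect_equal(r$stabilizing_count, 0L)
  expect_equal(scan_elements("AUUUAUUUA", lists)$destabilizing_count, 2L)
  expect_warning(r0 <- scan_elements("ACGT", list(destabilizing = character(0),
                                                  stabilizing = "AG")),
                 "empty motif list")
  expect_equal(r0$destabilizing_count, 0L)
})

test_that("element counts match a naive all-offsets scan and are additive", {
  set.seed(91)
  for (i in 1:15) {
    s <- random_nt(200)
    motifs <- vapply(1:3, function(j) random_nt(sample(3:6, 1)), character(1))
    got <- suppressWarnings(scan_elements(s, list(destabilizing = motifs,
                                                  stabilizing = character(0))))
    naive <- 0L
    for (m in motifs) {
      for (o in 0:(nchar(s) - nchar(m))) {
        if (substr(s, o + 1, o + nchar(m)) == m) naive <- naive + 1L
      }
    }
    expect_equal(got$destabilizing_count, naive)
    per_motif <- vapply(motifs, function(m) suppressWarnings(
      scan_elements(s, list(destabilizing = m,
                            stabilizing = character(0)))$destabilizing_count),
      integer(1))
    expect_equal(sum(per_motif), naive)
  }
})

test_that("stability comparison runs the prescribed tests per feature", {
  mk <- function(len, destab, stab, introns) {
    data.frame(length_nt = len, destabilizing_count = destab,
               stabilizing_count = stab, intron_count = introns)
  }
  same <- mk(c(100, 200, 300), c(1, 2, 3), c(0, 1, 2), c(0, 1, 0))
  r <- compare_stability(same, same)
  expect_equal(r$utr3_length$p_value, 1, tolerance = 1e-6)
  expect_equal(r$utr3_length$median_cryptic, r$utr3_length$median_conventional)
  expect_equal(r$introns$p_value, 1)
  expect_true(compare_stability(same[1, ], same)$insufficient_data)
  # planted median shift is detected across seeds
  set.seed(92)
  hits <- 0L
  for (s in 1:20) {
    cry <- mk(rnorm(60, 1100, 150), rpois(60, 6), rpois(60, 2), rbinom(60, 1, .3))
    conv <- mk(rnorm(60, 700, 150), rpois(60, 2), rpois(60, 2), rbinom(60, 1, .3))
    rr <- compare_stability(cry, conv)
    if (rr$utr3_length$p_value < 0.01 && rr$destabilizing$p_value < 0.01)
      hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("tiny rank-sum case agrees with exhaustive permutation enumeration", {
  x <- c(5, 9, 12); y <- c(1, 2, 3)
  p_pkg <- stats::wilcox.test(x, y, alternative = "greater")$p.value
  pool <- c(x, y)
  combs <- utils::combn(6, 3)
  stat_obs <- sum(rank(pool)[1:3])
  stats_all <- apply(combs, 2, function(idx) sum(rank(pool)[idx]))
  p_perm <- mean(stats_all >= stat_obs)
  expect_equal(p_pkg, p_perm, tolerance = 1e-10)
})

test_that("expression comparison reports log10 medians and rank-sum p", {
  set.seed(93)
  a <- exp(rnorm(100, 2, 1))
  r_same <- expression_compare(a, a)
  expect_equal(r_same$p_value, 1, tolerance = 1e-6)
  b <- a * 2
  r_shift <- expression_compare(b, a)
  expect_lt(r_shift$p_value, 0.05)
  expect_equal(r_shift$median_log10_cryptic, stats::median(log10(b)))
})

test_that("the bundled human usage table yields 30 rare and 34 common codons", {
  u <- read_codon_usage()
  cls <- classify_codons(u)
  expect_length(cls$rare, 30L)
  expect_length(cls$common, 34L)
  expect_length(intersect(cls$rare, cls$common), 0L)
  expect_setequal(c(cls$rare, cls$common), names(Biostrings::GENETIC_CODE))
  # leucine CTG is heavily used -> common; single-codon ATG ties -> common
  expect_true("CTG" %in% cls$common)
  expect_true("ATG" %in% cls$common)
  expect_true("TGG" %in% cls$common)
  # within-family fractions sum to 1
  fam <- Biostrings::GENETIC_CODE[names(u)]
  sums <- tapply(as.numeric(u), fam, sum)
  expect_true(all(abs(sums - 1) < 0.01))
})

test_that("rare-codon enrichment behaves on constructed groups", {
  u <- read_codon_usage()
  cls <- classify_codons(u)
  seq_common <- strrep(cls$common[1], 40)
  seq_rare <- paste0(strrep(cls$rare[1], 20), strrep(cls$common[1], 20))
  same <- rare_codon_enrichment(seq_common, seq_common, u)
  expect_equal(same$odds_ratio, 1)
  enr <- rare_codon_enrichment(seq_rare, seq_common, u)
  expect_gt(enr$odds_ratio, 1)
  expect_lt(enr$p_value, 0.01)
  expect_true(is.finite(same$odds_ratio))       # zero cells Haldane-corrected
  expect_error(rare_codon_enrichment("ACGTA", seq_common, u), "multiple of 3")
})

test_that("SNP classification is strand-aware mutate-and-translate", {
  g <- c(chr1 = "TTTAAAGGGCCCTTTAAAGGGCCCATCGGG")
  nt <- substr(g[["chr1"]], 4, 27)                  # AAAGGGCCCTTTAAAGGGCCCATC
  locus <- pcr_locus("chr1", rbind(c(3, 27)), "+", nt, translate_nt(nt))
  # third position of the first codon (AAA): A->G keeps lysine
  syn <- classify_snp(locus, data.frame(contig = "chr1", pos = 6, ref = "A",
                                        alt = "G", id = "v1"), g)
  expect_equal(syn$call, "synonymous")
  nsyn <- classify_snp(locus, data.frame(contig = "chr1", pos = 4, ref = "A",
                                         alt = "G", id = "v2"), g)
  expect_equal(nsyn$call, "non_synonymous")
  expect_error(classify_snp(locus, data.frame(contig = "chr1", pos = 1,
                                              ref = "T", alt = "A", id = "v3"), g),
               "outside the PCR")
  # substituting the reference allele is always synonymous
  ident <- classify_snp(locus, data.frame(contig = "chr1", pos = 6, ref = "A",
                                          alt = "A", id = "v4"))
  expect_equal(ident$call, "synonymous")
  # minus-strand locus: the alt allele is complemented before insertion
  ntm <- revcomp(nt)
  locus_m <- pcr_locus("chr1", rbind(c(3, 27)), "-", ntm, translate_nt(ntm))
  r <- classify_snp(locus_m, data.frame(contig = "chr1", pos = 4, ref = "A",
                                        alt = "G", id = "v5"), g)
  mut <- g
  substr(mut[["chr1"]], 4, 4) <- "G"
  want <- translate_nt(revcomp(substr(mut[["chr1"]], 4, 27)))
  expect_equal(r$mutated_peptide, want)
})

test_that("ns-SNP frequencies and the exact test respond to planted density", {
  set.seed(94)
  mk_locus <- function(contig, start, g) {
    nt <- substr(g[[contig]], start + 1, start + 33)
    pcr_locus(contig, rbind(c(start, start + 33)), "+", nt, translate_nt(nt))
  }
  g <- c(chr1 = random_nt(4000), chr2 = random_nt(4000))
  cry <- lapply(seq(0, 900, by = 100), function(s) mk_locus("chr1", s, g))
  conv <- lapply(seq(0, 900, by = 100), function(s) mk_locus("chr2", s, g))
  mk_var <- function(contig, pos0, g) {
    ref <- substr(g[[contig]], pos0 + 1, pos0 + 1)
    data.frame(contig = contig, pos = pos0 + 1,
               ref = ref, alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               id = paste0(contig, pos0), stringsAsFactors = FALSE)
  }
  # plant first-codon-position variants: 6 in cryptic PCRs, 2 in conventional
  vars <- rbind(
    do.call(rbind, lapply(seq(0, 500, by = 100), function(s) mk_var("chr1", s, g))),
    do.call(rbind, lapply(c(0, 100), function(s) mk_var("chr2", s, g))))
  r <- nssnp_frequency(cry, conv, vars, g)
  expect_equal(r$bp_cryptic, 330L)
  expect_equal(r$bp_conventional, 330L)
  expect_lte(r$ns_cryptic, 6L)
  expect_gte(r$freq_cryptic, r$freq_conventional)
  expect_true(r$test$p_value >= 0 && r$test$p_value <= 1)
  expect_equal(unname(r$test$table[1, ]), c(r$ns_cryptic, 330L - r$ns_cryptic))
  # 2 ns-SNPs over 100 bp -> 0.02 per bp
  single <- list(mk_locus("chr1", 2000, g))
  v2 <- rbind(mk_var("chr1", 2000, g), mk_var("chr1", 2003, g))
  r2 <- nssnp_frequency(single, single, v2, g)
  if (r2$ns_cryptic == 2L) expect_equal(r2$freq_cryptic, 2 / 33)
})
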