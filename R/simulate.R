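#' Configuration for the synthetic-fixture simulator
#'
#' The simulator emulates the study inputs at toy scale: a multi-contig
#' genome with annotated genes, planted peptide-coding regions of every
#' cryptic category with known ground truth, RNA-seq-like reads tiling the
#' expressed units at uniform depth, variants, and a search-engine-like PSM
#' table with decoys.
#'
#' @param categories Named integer vector: planted peptides per category
#'   (default one each of conventional, 5UTR, 5UTR/EXON, EXON, INTRON/EXON,
#'   INTRON, RETAINED_INTRON, 3UTR, ANTISENSE, INTERGENIC).
#' @param n_multi_locus Planted multi-locus decoy peptides (discard truth
#'   "multi_locus").
#' @param n_inframe_decoy Planted in-frame exonic decoys fed to the cryptic
#'   path (discard truth "frame_conventional").
#' @param peptide_length Length of planted peptides (default 11, the
#'   sliding-window maximum, so every plant is a database entry itself).
#' @param read_length,depth Read length and per-base tiling depth.
#' @param error_rate Per-base substitution error rate in [0, 0.05].
#' @param decoy_score_shift Downward shift of the incorrect/decoy score
#'   distribution relative to correct identifications.
#' @param fraction_incorrect_psms Fraction of target PSMs that are incorrect
#'   identifications (decoys are drawn symmetrically).
#' @param alleles The subject's HLA-A/B allele names.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(categories = c("conventional" = 1L, "5UTR" = 1L,
                                      "5UTR/EXON" = 1L, "EXON" = 1L,
                                      "INTRON/EXON" = 1L, "INTRON" = 1L,
                                      "RETAINED_INTRON" = 1L, "3UTR" = 1L,
                                      "ANTISENSE" = 1L, "INTERGENIC" = 1L),
                       n_multi_locus = 1L, n_inframe_decoy = 1L,
                       peptide_length = 11L, read_length = 100L, depth = 20L,
                       error_rate = 0, decoy_score_shift = 20,
                       fraction_incorrect_psms = 0,
                       alleles = c("HLA-A*03:01", "HLA-A*29:02",
                                   "HLA-B*08:01", "HLA-B*44:03")) {
  stopifnot(all(categories >= 0L), error_rate >= 0, error_rate <= 0.05,
            fraction_incorrect_psms >= 0, fraction_incorrect_psms < 1,
            peptide_length >= 8L, peptide_length <= 11L, depth >= 1L)
  structure(list(categories = categories, n_multi_locus = n_multi_locus,
                 n_inframe_decoy = n_inframe_decoy,
                 peptide_length = as.integer(peptide_length),
                 read_length = as.integer(read_length), depth = as.integer(depth),
                 error_rate = error_rate, decoy_score_shift = decoy_score_shift,
                 fraction_incorrect_psms = fraction_incorrect_psms,
                 alleles = alleles),
            class = "SimConfig")
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

.random_nt <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.random_peptide <- function(len, force_m_at = NA) {
  aa <- sample(.AA20, len, replace = TRUE)
  if (!is.na(force_m_at)) aa[force_m_at] <- "M"
  paste0(aa, collapse = "")
}

# Random synonymous encoding of a peptide.
.encode_peptide <- function(peptide) {
  gc <- .codon_table()
  aa <- strsplit(peptide, "")[[1L]]
  codons <- vapply(aa, function(a) {
    opts <- names(gc)[gc == a]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(codons, collapse = "")
}

.random_cds <- function(n_codons) {
  gc <- .codon_table()
  body <- names(gc)[gc != "*" & gc != "M"]
  paste0("ATG", paste0(sample(body, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(.STOP_CODONS, 1L))
}

# Fixed toy gene layout (all coordinates 0-based within the gene's contig).
.GENE_LAYOUT <- list(
  spacer = 220L, u1 = 90L, i1 = 120L, u2 = 60L, c1 = 90L, i2 = 150L,
  c2 = 93L, u3 = 240L)

.gene_coords <- function() {
  y <- .GENE_LAYOUT
  e1s <- y$spacer; e1e <- e1s + y$u1
  i1e <- e1e + y$i1
  e2s <- i1e; e2e <- e2s + y$u2 + y$c1
  i2e <- e2e + y$i2
  e3s <- i2e; e3e <- e3s + y$c2 + y$u3
  list(exons = rbind(c(e1s, e1e), c(e2s, e2e), c(e3s, e3e)),
       cds = c(e2s + y$u2, e3s + y$c2),
       contig_len = e3e + y$spacer)
}

# Build one toy gene contig with an optional planted peptide; returns the
# contig sequence, transcript models and the plant's genomic blocks/strand.
.make_gene <- function(contig, gene_id, category, peptide) {
  y <- .GENE_LAYOUT; gcrd <- .gene_coords()
  n_codons <- (y$c1 + y$c2) %/% 3L
  seq <- .random_nt(gcrd$contig_len)
  put <- function(s, at, frag) {            # at: 0-based
    substr(s, at + 1L, at + nchar(frag)) <- frag
    s
  }
  cds_put <- function(s, cds) {
    s <- put(s, gcrd$cds[1L], substr(cds, 1L, y$c1))
    put(s, gcrd$exons[3L, 1L], substr(cds, y$c1 + 1L, y$c1 + y$c2))
  }
  cds <- .random_cds(n_codons)
  plant <- NULL
  enc <- if (!is.null(peptide)) .encode_peptide(peptide) else NULL
  L3 <- if (!is.null(enc)) nchar(enc) else 0L
  cds_nt_pos <- function(off) {            # CDS nt offset -> contig position
    if (off < y$c1) gcrd$cds[1L] + off else gcrd$exons[3L, 1L] + (off - y$c1)
  }
  if (!is.null(category)) {
    if (category %in% c("conventional", "inframe_decoy")) {
      off <- 12L                            # aa 5.. of the protein, inside cds1
      substr(cds, off + 1L, off + L3) <- enc
      plant <- c(gcrd$cds[1L] + off, gcrd$cds[1L] + off + L3)
    } else if (category == "EXON") {
      off <- 13L                            # out of frame (13 mod 3 = 1)
      for (try in 1:50) {
        cand <- cds
        substr(cand, off + 1L, off + L3) <- enc
        if (!grepl("\\*", substr(translate_nt(cand), 1L,
                                 nchar(cand) %/% 3L - 1L))) { cds <- cand; break }
        enc <- .encode_peptide(peptide)
        if (try == 50L) stop("could not plant out-of-frame peptide without a CDS stop")
      }
      plant <- c(gcrd$cds[1L] + off, gcrd$cds[1L] + off + L3)
    } else if (category == "5UTR") {
      at <- gcrd$exons[1L, 1L] + 20L
      plant <- c(at, at + L3)
    } else if (category == "5UTR/EXON") {
      # peptide carries M at position 5; its codon 5 becomes the start codon
      k <- 12L                              # nt upstream of the CDS start
      at <- gcrd$cds[1L] - k
      substr(cds, 1L, L3 - k) <- substr(enc, k + 1L, L3)
      plant <- c(at, at + L3)
    } else if (category == "INTRON/EXON") {
      k <- 15L                              # nt inside intron 2
      at <- gcrd$exons[3L, 1L] - k
      substr(cds, y$c1 + 1L, y$c1 + (L3 - k)) <- substr(enc, k + 1L, L3)
      plant <- c(at, at + L3)
    } else if (category %in% c("INTRON", "RETAINED_INTRON", "ANTISENSE")) {
      at <- gcrd$exons[1L, 2L] + 40L        # inside intron 1
      plant <- c(at, at + L3)
    } else if (category == "3UTR") {
      at <- gcrd$exons[3L, 1L] + y$c2 + 60L
      plant <- c(at, at + L3)
    } else stop("unknown planted category: ", category)
  }
  seq <- cds_put(seq, cds)
  if (!is.null(plant)) {
    if (category %in% c("5UTR", "INTRON", "RETAINED_INTRON", "3UTR")) {
      seq <- put(seq, plant[1L], enc)
    } else if (category == "ANTISENSE") {
      seq <- put(seq, plant[1L], revcomp(enc))
    } else if (category == "5UTR/EXON") {
      seq <- put(seq, plant[1L], substr(enc, 1L, 12L))   # UTR-side piece
    } else if (category == "INTRON/EXON") {
      seq <- put(seq, plant[1L], substr(enc, 1L, 15L))   # intron-side piece
    }
  }
  strand <- if (identical(category, "ANTISENSE")) "-" else "+"
  t1 <- transcript_model(paste0(gene_id, ".t1"), gene_id, contig, "+",
                         gcrd$exons, cds_span = gcrd$cds,
                         biotype = "protein_coding")
  models <- list(t1)
  if (identical(category, "RETAINED_INTRON")) {
    t2 <- transcript_model(paste0(gene_id, ".t2"), gene_id, contig, "+",
                           rbind(c(gcrd$exons[1L, 1L], gcrd$exons[3L, 2L])),
                           biotype = "retained_intron")
    models <- c(models, list(t2))
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  list(seq = seq, models = models, plant = plant, strand = strand)
}

#' Simulate a toy reference with planted ground truth
#'
#' Builds a deterministic (per seed) multi-contig genome with one gene per
#' planted peptide, an intergenic contig carrying the intergenic and
#' multi-locus plants, Ensembl-dialect annotations, per-transcript FPKM
#' values, a small variant set (one synonymous and one non-synonymous SNV
#' inside the first conventional PCR is deliberately avoided: variants are
#' placed in coding sequence outside planted regions so plants survive
#' genome personalization) and a truth table mapping every planted peptide
#' to its category and locus.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the output is reproducible bit for bit.
#' @return List with genome, models, expression, variants, truth (data.frame:
#'   peptide, category, contig, blocks, strand, gene_id, transcript_id) and
#'   cfg.
#' @export
simulate_reference <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  for (attempt in 1:5) {
    out <- .simulate_reference_once(cfg)
    if (.verify_reference(out)) return(out)
  }
  stop("could not generate a collision-free reference in 5 attempts")
}

.simulate_reference_once <- function(cfg) {
  cats <- rep(names(cfg$categories), cfg$categories)
  cats <- c(cats, rep("inframe_decoy", cfg$n_inframe_decoy))
  gene_cats <- cats[cats != "INTERGENIC"]
  n_needed <- length(gene_cats) + sum(cats == "INTERGENIC") + cfg$n_multi_locus
  peptides <- character(0)
  while (length(unique(peptides)) < n_needed) {
    peptides <- unique(c(peptides, .random_peptide(cfg$peptide_length)))
  }
  peptides <- peptides[seq_len(n_needed)]
  genome <- character(0); models <- list(); truth <- list()
  i_pep <- 0L
  for (gi in seq_along(gene_cats)) {
    i_pep <- i_pep + 1L
    cat_i <- gene_cats[[gi]]
    pep <- peptides[[i_pep]]
    if (cat_i == "5UTR/EXON")
      pep <- .random_peptide(cfg$peptide_length, force_m_at = 5L)
    contig <- paste0("chr", gi)
    gene_id <- sprintf("G%03d", gi)
    g <- .make_gene(contig, gene_id, cat_i, pep)
    genome[contig] <- g$seq
    models <- c(models, g$models)
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = pep, category = cat_i, contig = contig,
      blocks = paste(g$plant[1L], g$plant[2L], sep = "-"),
      strand = g$strand, gene_id = gene_id,
      transcript_id = if (cat_i == "ANTISENSE") NA_character_ else
        names(g$models)[[length(g$models)]],
      stringsAsFactors = FALSE)
  }
  # intergenic contig: intergenic plants plus the multi-locus decoys
  n_inter <- sum(cats == "INTERGENIC")
  inter_len <- 600L + 700L * (n_inter + 2L * cfg$n_multi_locus)
  iseq <- .random_nt(inter_len)
  at <- 300L
  for (k in seq_len(n_inter)) {
    i_pep <- i_pep + 1L
    pep <- peptides[[i_pep]]
    enc <- .encode_peptide(pep)
    substr(iseq, at + 1L, at + nchar(enc)) <- enc
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = pep, category = "INTERGENIC", contig = "chrZ",
      blocks = paste(at, at + nchar(enc), sep = "-"), strand = "+",
      gene_id = NA_character_, transcript_id = NA_character_,
      stringsAsFactors = FALSE)
    at <- at + 700L
  }
  for (k in seq_len(cfg$n_multi_locus)) {
    i_pep <- i_pep + 1L
    pep <- peptides[[i_pep]]
    enc <- .encode_peptide(pep)
    b <- integer(0)
    for (rep in 1:2) {
      substr(iseq, at + 1L, at + nchar(enc)) <- enc
      b <- c(b, at); at <- at + 700L
    }
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = pep, category = "multi_locus_decoy", contig = "chrZ",
      blocks = paste(paste(b, b + nchar(enc), sep = "-"), collapse = ";"),
      strand = "+", gene_id = NA_character_, transcript_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  genome["chrZ"] <- iseq
  truth <- do.call(rbind, truth)
  # expression: every coding isoform expressed; retained-intron isoforms
  # dominate their gene so isoform selection picks them
  tx_ids <- names(models)
  fpkm <- stats::runif(length(tx_ids), 2, 80)
  fpkm[grepl("\\.t2$", tx_ids)] <- 120
  expression <- data.frame(transcript_id = tx_ids, fpkm = round(fpkm, 3),
                           stringsAsFactors = FALSE)
  for (i in seq_along(models)) models[[i]]$fpkm <- expression$fpkm[i]
  variants <- .plant_variants(genome, truth)
  list(genome = genome, models = models, expression = expression,
       variants = variants, truth = truth, cfg = cfg)
}

# Two SNVs in the coding sequence of the first conventional gene, outside
# every planted PCR, so personalization never disturbs a planted peptide.
.plant_variants <- function(genome, truth) {
  conv <- truth[truth$category == "conventional", , drop = FALSE]
  empty <- data.frame(contig = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(conv) == 0L) return(empty)
  gcrd <- .gene_coords()
  contig <- conv$contig[1L]
  pcr <- as.integer(strsplit(conv$blocks[1L], "-")[[1L]])
  pos0 <- gcrd$cds[1L] + 60L                # CDS nt 60, downstream of the PCR
  if (pos0 >= pcr[1L] && pos0 < pcr[2L]) pos0 <- pcr[2L] + 3L
  rows <- list()
  gc <- .codon_table()
  for (k in 0:1) {
    p <- pos0 + 3L * k                        # first base of a CDS codon
    ref <- substr(genome[[contig]], p + 1L, p + 1L)
    rest <- substr(genome[[contig]], p + 2L, p + 3L)
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    alts <- alts[gc[paste0(alts, rest)] != "*"]   # never create a stop codon
    rows[[k + 1L]] <- data.frame(contig = contig, pos = p + 1L,
                                 id = sprintf("sim_snv_%d", k + 1L),
                                 ref = ref, alt = sample(alts, 1L), qual = 60,
                                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Planted loci must be unique in the genome (two for multi-locus decoys) and
# cryptic plants must not occur in the canonical proteome.
.verify_reference <- function(ref) {
  control <- build_control_db(apply_variants(ref$genome, ref$variants), ref$models)
  for (i in seq_len(nrow(ref$truth))) {
    row <- ref$truth[i, ]
    n_expected <- if (row$category == "multi_locus_decoy") 2L else 1L
    loci <- locate_pcr(row$peptide, ref$genome)
    if (length(loci) != n_expected) return(FALSE)
    if (!row$category %in% c("conventional", "inframe_decoy", "multi_locus_decoy") &&
        any(grepl(row$peptide, control$sequence, fixed = TRUE))) return(FALSE)
  }
  TRUE
}

#' Simulate reads tiling the expressed units
#'
#' Tiles each gene's pre-mRNA (unspliced span, on the gene strand) at the
#' configured uniform depth, plus an antisense unit (reverse complement of
#' the host gene span) for every antisense plant and the intergenic contig,
#' with independent per-base substitution errors. Read ids encode the unit
#' and offset of origin.
#'
#' @param ref A [simulate_reference()] result.
#' @param seed Integer seed (errors only; the tiling is deterministic).
#' @return Named character vector of reads.
#' @export
simulate_reads <- function(ref, seed = 1L) {
  set.seed(seed + 1L)
  cfg <- ref$cfg
  rl <- cfg$read_length
  step <- max(1L, as.integer(round(rl / cfg$depth)))
  units <- list()
  gids <- unique(vapply(ref$models, `[[`, character(1), "gene_id"))
  for (g in gids) {
    ms <- ref$models[vapply(ref$models, `[[`, character(1), "gene_id") == g]
    span <- c(min(vapply(ms, function(m) m$exons[1L, 1L], integer(1))),
              max(vapply(ms, function(m) m$exons[nrow(m$exons), 2L], integer(1))))
    pre <- substr(ref$genome[[ms[[1L]]$contig]], span[1L] - 100L + 1L,
                  span[2L] + 100L)
    units[[paste0("pre_", g)]] <- pre
    anti <- ref$truth$category == "ANTISENSE" & ref$truth$gene_id %in% g
    if (any(anti)) units[[paste0("anti_", g)]] <- revcomp(pre)
  }
  if ("chrZ" %in% names(ref$genome))
    units[["intergenic_chrZ"]] <- ref$genome[["chrZ"]]
  reads <- character(0)
  for (nm in names(units)) {
    u <- units[[nm]]
    if (nchar(u) < rl) next
    offs <- seq.int(0L, nchar(u) - rl, by = step)
    rs <- substring(u, offs + 1L, offs + rl)
    names(rs) <- paste0(nm, ":", offs)
    reads <- c(reads, rs)
  }
  if (cfg$error_rate > 0) {
    for (i in seq_along(reads)) {
      n <- nchar(reads[[i]])
      hit <- which(stats::runif(n) < cfg$error_rate)
      for (p in hit) {
        old <- substr(reads[[i]], p, p)
        substr(reads[[i]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
  }
  reads
}

#' Simulate search-engine output (PSMs and affinities)
#'
#' Correct target PSMs are drawn for the planted peptides (plus optional
#' filler conventional peptides taken from the control proteome to reach
#' `n_psms` targets); incorrect targets and reversed-style decoys are drawn
#' symmetrically from a score distribution shifted down by
#' `decoy_score_shift` and from a common broad affinity distribution, with
#' `fraction_incorrect_psms` controlling the contamination. Conventional
#' plants (and fillers) carry database "both"; cryptic plants and the
#' planted in-frame decoys are "allframes"-only.
#'
#' @param ref A [simulate_reference()] result.
#' @param control_db Control database from [build_control_db()] (filler
#'   peptides are real substrings of its proteins); NULL disables fillers.
#' @param n_psms Total number of target PSMs to emit (NULL = planted plus a
#'   small filler population when `control_db` is supplied).
#' @param seed Integer seed.
#' @return List with `psms`, `affinities` and `psm_truth` (per target
#'   peptide: is_correct).
#' @export
simulate_psms <- function(ref, control_db = NULL, n_psms = NULL, seed = 1L) {
  set.seed(seed + 2L)
  cfg <- ref$cfg
  truth <- ref$truth                   # multi-locus plants are searched too
  pep <- truth$peptide
  db <- ifelse(truth$category == "conventional", "both", "allframes")
  correct <- data.frame(peptide = pep, database = db, stringsAsFactors = FALSE)
  if (is.null(n_psms) && !is.null(control_db))
    n_psms <- ceiling((nrow(correct) + 12L) / (1 - cfg$fraction_incorrect_psms))
  if (!is.null(n_psms)) {
    n_correct <- max(nrow(correct),
                     round(n_psms * (1 - cfg$fraction_incorrect_psms)))
    n_fill <- n_correct - nrow(correct)
    if (n_fill > 0L) {
      if (is.null(control_db) || nrow(control_db) == 0L)
        stop("filler PSMs requested but no control database supplied")
      fills <- character(0)
      while (length(fills) < n_fill) {
        prot <- control_db$sequence[sample.int(nrow(control_db), 1L)]
        len <- sample(8:11, 1L)
        if (nchar(prot) < len) next
        at <- sample.int(nchar(prot) - len + 1L, 1L)
        fills <- unique(c(fills, substr(prot, at, at + len - 1L)))
        fills <- setdiff(fills, correct$peptide)
      }
      fills <- fills[seq_len(n_fill)]
      correct <- rbind(correct, data.frame(peptide = fills, database = "both",
                                           stringsAsFactors = FALSE))
    }
    n_incorrect <- round(n_correct / (1 - cfg$fraction_incorrect_psms) *
                           cfg$fraction_incorrect_psms)
  } else {
    n_incorrect <- round(nrow(correct) / (1 - cfg$fraction_incorrect_psms) *
                           cfg$fraction_incorrect_psms)
  }
  n_planted <- nrow(truth)
  draw_unique <- function(n, exclude) {
    out <- character(0)
    while (length(out) < n) {
      cand <- vapply(seq_len(n + 8L), function(i)
        .random_peptide(sample(8:11, 1L)), character(1))
      out <- unique(c(out, setdiff(cand, exclude)))
    }
    out[seq_len(n)]
  }
  incorrect <- draw_unique(n_incorrect, correct$peptide)
  decoys <- draw_unique(n_incorrect, c(correct$peptide, incorrect))
  # correct identifications score high; the filler population additionally
  # contains one low-score and one weak-binder identification so the
  # control-derived thresholds are permissive enough for every genuine MAP
  score_correct <- round(stats::runif(nrow(correct), 50, 70), 2)
  weak_score_idx <- weak_aff_idx <- NA_integer_
  if (nrow(correct) > n_planted + 1L) {
    weak_score_idx <- n_planted + 1L
    weak_aff_idx <- n_planted + 2L
    score_correct[weak_score_idx] <- 30
  }
  score_lo <- function(n) pmax(1, stats::rnorm(n, 55 - cfg$decoy_score_shift, 8))
  psms <- rbind(
    data.frame(peptide = correct$peptide, score = score_correct,
               database = correct$database, is_decoy = FALSE,
               modifications = "", stringsAsFactors = FALSE),
    if (n_incorrect > 0L)
      data.frame(peptide = incorrect, score = round(score_lo(n_incorrect), 2),
                 database = "both", is_decoy = FALSE, modifications = "",
                 stringsAsFactors = FALSE),
    if (n_incorrect > 0L)
      data.frame(peptide = decoys, score = round(score_lo(n_incorrect), 2),
                 database = "both", is_decoy = TRUE, modifications = "",
                 stringsAsFactors = FALSE))
  # affinities: planted/filler peptides bind one allele strongly; incorrect
  # targets and decoys share one broad log-uniform distribution
  strong_aff <- function(p, presenting_ic50 = NULL) {
    pres <- sample(cfg$alleles, 1L)
    ic50 <- round(exp(stats::runif(length(cfg$alleles), log(2000), log(30000))), 1)
    ic50[cfg$alleles == pres] <- presenting_ic50 %||%
      round(stats::runif(1, 30, 600), 1)
    data.frame(peptide = p, allele = cfg$alleles, ic50_nM = ic50,
               stringsAsFactors = FALSE)
  }
  broad_aff <- function(p) data.frame(
    peptide = p, allele = rep(cfg$alleles, each = 1L),
    ic50_nM = round(exp(stats::runif(length(cfg$alleles), log(200), log(30000))), 1),
    stringsAsFactors = FALSE)
  aff <- do.call(rbind, c(
    lapply(seq_len(nrow(correct)), function(i)
      strong_aff(correct$peptide[i],
                 presenting_ic50 = if (identical(i, weak_aff_idx)) 1200)),
    lapply(c(incorrect, decoys), broad_aff)))
  psm_truth <- data.frame(peptide = c(correct$peptide, incorrect),
                          is_correct = c(rep(TRUE, nrow(correct)),
                                         rep(FALSE, length(incorrect))),
                          stringsAsFactors = FALSE)
  list(psms = psms, affinities = aff, psm_truth = psm_truth)
}

#' Write all simulator outputs to a fixtures directory
#'
#' @param ref A [simulate_reference()] result.
#' @param reads Reads from [simulate_reads()].
#' @param search A [simulate_psms()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(ref, reads, search, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annot.gtf"),
             expression = file.path(dir, "expr.tsv"),
             variants = file.path(dir, "vars.vcf"),
             reads = file.path(dir, "reads.fq"),
             psms = file.path(dir, "psms.tsv"),
             affinities = file.path(dir, "aff.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genome_fasta(ref$genome, paths["genome"])
  write_gtf(ref$models, paths["gtf"])
  utils::write.table(ref$expression, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t%g\tPASS\t.",
                   ref$variants$contig, ref$variants$pos, ref$variants$id,
                   ref$variants$ref, ref$variants$alt, ref$variants$qual))
  writeLines(vcf, paths["variants"])
  write_fastq(reads, paths["reads"])
  utils::write.table(search$psms, paths["psms"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(search$affinities, paths["affinities"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ref$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
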