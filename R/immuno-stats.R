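#' Default amino-acid class table
#'
#' Groups the 20 standard residues into four bulkiness/hydrophobicity
#' classes: Hydrophobic/Large (HL), Hydrophobic/Small-Medium (HS),
#' Polar/Large (PL) and Polar/Small-Medium (PS). The membership is
#' configuration: pass your own named vector to override.
#'
#' @return Named character vector mapping residue to class.
#' @export
aa_class_table <- function() {
  c(F = "HL", I = "HL", L = "HL", M = "HL", V = "HL", W = "HL", Y = "HL",
    A = "HS", C = "HS", G = "HS", P = "HS",
    E = "PL", H = "PL", K = "PL", Q = "PL", R = "PL",
    D = "PS", N = "PS", S = "PS", T = "PS")
}

# Residues at positions P4..P1 (MAP C terminus) and P1'..P4' (flanking region
# of the source protein). Positions beyond the protein end are NA.
.signature_residues <- function(peptide, protein) {
  p1 <- rev(strsplit(substr(peptide, nchar(peptide) - 3L, nchar(peptide)), "")[[1L]])
  names(p1) <- c("P1", "P2", "P3", "P4")
  hit <- regexpr(peptide, protein, fixed = TRUE)
  flank <- rep(NA_character_, 4L)
  names(flank) <- c("P1'", "P2'", "P3'", "P4'")
  if (hit > 0L) {
    after <- substr(protein, hit + nchar(peptide), hit + nchar(peptide) + 3L)
    res <- strsplit(after, "")[[1L]]
    flank[seq_along(res)] <- res
  }
  c(p1[c("P4", "P3", "P2", "P1")], flank)
}

#' C-terminal amino-acid class signature of cryptic versus conventional MAPs
#'
#' For each of the eight positions (P4..P1 of the MAP C terminus and
#' P1'..P4' of the source-protein flanking region) and each amino-acid
#' class, tests the 2x2 of (class versus other classes) by (cryptic versus
#' conventional) with a two-sided Fisher's exact test and reports the log2
#' odds ratio. MAPs whose source protein ends before a flanking position do
#' not contribute to that position.
#'
#' @param cryptic,conventional Data.frames with columns peptide and protein
#'   (the predicted/annotated source protein containing the MAP).
#' @param classes Residue-to-class map (default [aa_class_table()]).
#' @return Data.frame with position, class, counts, log2_odds_ratio and
#'   p_value.
#' @export
cterm_signature <- function(cryptic, conventional, classes = aa_class_table()) {
  if (nrow(cryptic) == 0L || nrow(conventional) == 0L)
    stop("both MAP groups must be non-empty")
  residues <- function(d) t(mapply(.signature_residues, d$peptide, d$protein))
  rc <- residues(cryptic); rv <- residues(conventional)
  positions <- colnames(rc)
  rows <- list()
  for (pos in positions) {
    cc <- classes[rc[, pos]]; cv <- classes[rv[, pos]]
    cc <- cc[!is.na(cc)]; cv <- cv[!is.na(cv)]
    for (cl in sort(unique(classes))) {
      tab <- rbind(cryptic = c(sum(cc == cl), sum(cc != cl)),
                   conventional = c(sum(cv == cl), sum(cv != cl)))
      res <- contingency_result(tab, "two.sided")
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, class = cl,
        n_cryptic = tab[1L, 1L], n_conventional = tab[2L, 1L],
        log2_odds_ratio = log2(res$odds_ratio), p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-length enrichment between cryptic and conventional MAPs
#'
#' For each length L in 8..11, tests the 2x2 (length = L versus other
#' lengths) by group with a two-sided Fisher's exact test.
#'
#' @param cryptic,conventional Character vectors of MAP sequences.
#' @return Data.frame with length, per-group counts, odds_ratio and p_value.
#' @export
length_distribution_compare <- function(cryptic, conventional) {
  lc <- nchar(cryptic); lv <- nchar(conventional)
  rows <- lapply(8:11, function(L) {
    tab <- rbind(cryptic = c(sum(lc == L), sum(lc != L)),
                 conventional = c(sum(lv == L), sum(lv != L)))
    res <- contingency_result(tab, "two.sided")
    data.frame(length = L, n_cryptic = tab[1L, 1L], n_conventional = tab[2L, 1L],
               odds_ratio = res$odds_ratio, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign the presenting HLA allotype of a peptide
#'
#' The presenting allotype is the subject allele with the lowest predicted
#' IC50 (strongest binding); ties go to the lexicographically smallest
#' allele name.
#'
#' @param peptide The MAP.
#' @param affinities Affinity data.frame (peptide, allele, ic50_nM).
#' @param subject_alleles The subject's allele names.
#' @return The presenting allele name.
#' @export
assign_allotype <- function(peptide, affinities, subject_alleles) {
  a <- affinities[affinities$peptide == peptide &
                    affinities$allele %in% subject_alleles, , drop = FALSE]
  missing <- setdiff(subject_alleles, a$allele)
  if (length(missing))
    stop("missing affinity for ", peptide, " on allele(s): ",
         paste(missing, collapse = ", "))
  best <- a$allele[a$ic50_nM == min(a$ic50_nM)]
  sort(best)[1L]
}

#' Test HLA restriction of MAP detection across subjects
#'
#' Over all (peptide, subject) pairs for the non-index subjects, tests
#' whether detection of the peptide depends on the subject carrying the
#' allotype that presents it in the index subject (2x2, two-sided Fisher's
#' exact test).
#'
#' @param detected Named list: subject -> character vector of detected
#'   peptides.
#' @param alleles Named list: subject -> character vector of HLA alleles.
#' @param presenting Named character vector: peptide -> presenting allele in
#'   the index subject.
#' @param index_subject Name of the index subject (excluded from the pairs).
#' @return A [contingency_result()] with the detection-by-allotype table
#'   (rows: allele present/absent; columns: detected/not).
#' @export
hla_restriction_test <- function(detected, alleles, presenting, index_subject) {
  subjects <- setdiff(names(detected), index_subject)
  if (length(subjects) < 1L) stop("need at least one non-index subject")
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("allele_present", "allele_absent"),
                                c("detected", "not_detected")))
  for (s in subjects) {
    for (p in names(presenting)) {
      has <- presenting[[p]] %in% alleles[[s]]
      det <- p %in% detected[[s]]
      tab[ifelse(has, 1L, 2L), ifelse(det, 1L, 2L)] <-
        tab[ifelse(has, 1L, 2L), ifelse(det, 1L, 2L)] + 1L
    }
  }
  contingency_result(tab, "two.sided")
}

#' Call promiscuous binders among shared peptides
#'
#' A peptide detected in a subject lacking the presenting allotype is a
#' promiscuous binder when its minimum predicted IC50 over that subject's
#' alleles is at most `threshold_nM` (inclusive).
#'
#' @param peptides Peptides detected in the other subject.
#' @param affinities Affinity data.frame.
#' @param other_subject_alleles The other subject's allele names.
#' @param threshold_nM IC50 cut-off in nM (default 5000).
#' @return Data.frame with peptide, min_ic50 and promiscuous; attribute
#'   "percent_promiscuous".
#' @export
promiscuous_binders <- function(peptides, affinities, other_subject_alleles,
                                threshold_nM = 5000) {
  rows <- lapply(peptides, function(p) {
    a <- affinities[affinities$peptide == p &
                      affinities$allele %in% other_subject_alleles, , drop = FALSE]
    if (nrow(a) == 0L) stop("no affinity for ", p, " on the other subject's alleles")
    data.frame(peptide = p, min_ic50 = min(a$ic50_nM),
               promiscuous = min(a$ic50_nM) <= threshold_nM,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "percent_promiscuous") <- 100 * mean(out$promiscuous)
  out
}
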