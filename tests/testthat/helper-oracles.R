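# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with naive per-base / per-codon logic so they stay
# structurally independent of the implementation paths they check.

.ORACLE_GC <- Biostrings::GENETIC_CODE

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s)
    paste0(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3 * i - 2, 3 * i)
    out[i] <- if (codon %in% names(.ORACLE_GC)) .ORACLE_GC[[codon]] else "X"
  }
  paste0(out, collapse = "")
}

# Explicit six-frame enumeration: for each strand and frame, walk the
# 11-codon windows of that frame, chop at the first stop, drop short
# products and N-containing windows. Returns the sorted peptide multiset.
oracle_sixframe_peptides <- function(read, min_len = 8, w = 33) {
  out <- character(0)
  for (s in c(read, oracle_revcomp(read))) {
    len <- nchar(s)
    for (f in 0:2) {
      n_cod <- (len - f) %/% 3
      if (n_cod < w / 3) next
      for (wi in 0:(n_cod - w / 3)) {
        o <- f + 3 * wi
        if (o + w > len) next
        nt <- substr(s, o + 1, o + w)
        if (grepl("N", nt, fixed = TRUE)) next
        aa <- oracle_translate(nt)
        stop_at <- regexpr("*", aa, fixed = TRUE)
        pep <- if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
        if (nchar(pep) >= min_len) out <- c(out, pep)
      }
    }
  }
  sort(out)
}

# Naive per-base genomic label of position g (0-based) relative to a model:
# walks the exons base by base.
oracle_base_label <- function(model, g) {
  ex <- model$exons
  span <- c(ex[1, 1], ex[nrow(ex), 2])
  exonic <- FALSE
  for (i in seq_len(nrow(ex))) if (g >= ex[i, 1] && g < ex[i, 2]) exonic <- TRUE
  if (!exonic) {
    if (g >= span[1] && g < span[2]) return("intron")
    return("outside")
  }
  if (is.null(model$cds_span)) return("exon")
  cs <- model$cds_span
  if (g >= cs[1] && g < cs[2]) return("cds")
  before_cds <- g < cs[1]
  if (model$strand == "+") {
    if (before_cds) "utr5" else "utr3"
  } else {
    if (before_cds) "utr3" else "utr5"
  }
}

# Naive transcript coordinate of genomic base g: walk every exonic base.
oracle_tx_coord <- function(model, g) {
  ex <- model$exons
  tx <- 0L
  hit <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    for (p in seq.int(ex[i, 1], ex[i, 2] - 1L)) {
      if (p == g) hit <- tx
      tx <- tx + 1L
    }
  }
  if (is.na(hit)) return(NA_integer_)
  if (model$strand == "+") hit else tx - 1L - hit
}

# Full hypergeometric enumeration of the two-sided exact test p-value.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force start-codon scan: walks the in-frame codons from the 5' end,
# tracking the last stop, then applies the three rules directly.
oracle_predict_start <- function(sequence, pcr_offset) {
  near <- c("CTG", "GTG", "TTG", "ATA", "ATT", "ATC", "ACG", "AAG", "AGG")
  stops <- c("TAA", "TAG", "TGA")
  frame <- pcr_offset %% 3
  positions <- seq(frame, pcr_offset, by = 3)
  codon_at <- function(p) substr(sequence, p + 1, p + 3)
  last_stop <- -Inf
  for (p in positions) if (codon_at(p) %in% stops && p < pcr_offset) last_stop <- p
  region <- positions[positions > last_stop]
  kz <- function(p) as.character(kozak_context(sequence, p))
  for (p in region) if (codon_at(p) == "ATG")
    return(list(position = p, rule = "i"))
  for (p in region) if (codon_at(p) %in% near && kz(p) %in% c("optimal", "strong"))
    return(list(position = p, rule = "ii"))
  list(position = region[1], rule = "iii")
}

random_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_peptide <- function(n) {
  paste0(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL),
                n, replace = TRUE), collapse = "")
}

# Random toy transcript model on a fresh random contig; returns both.
random_toy_model <- function(id = "T1", coding = TRUE) {
  n_ex <- sample(1:3, 1)
  pos <- 10L
  exons <- matrix(0L, n_ex, 2)
  for (i in seq_len(n_ex)) {
    pos <- pos + sample(5:30, 1)            # gap / leading spacer
    len <- sample(30:90, 1)
    exons[i, ] <- c(pos, pos + len)
    pos <- pos + len
  }
  contig <- random_nt(pos + 50L)
  m <- transcript_model(id, paste0(id, "_gene"), "chrT",
                        sample(c("+", "-"), 1), exons)
  if (coding) {
    L <- tx_length(m)
    cds_len <- 3L * sample(5:((L - 6) %/% 3), 1)
    a <- sample.int(L - cds_len, 1) - 1L
    gpos <- sort(tx_to_genomic(m, c(a, a + cds_len - 1L)))
    m <- transcript_model(id, paste0(id, "_gene"), "chrT", m$strand, exons,
                          cds_span = c(gpos[1], gpos[2] + 1L))
  }
  list(model = m, contig = contig)
}
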