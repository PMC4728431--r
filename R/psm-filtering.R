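# Collapse PSMs to the best-scoring record per (peptide, database, is_decoy)
# and attach the per-peptide minimum IC50 across the subject's alleles.
collapse_psms <- function(psms, affinities, alleles) {
  o <- order(psms$peptide, psms$database, psms$is_decoy, -psms$score)
  psms <- psms[o, , drop = FALSE]
  key <- paste(psms$peptide, psms$database, psms$is_decoy)
  psms <- psms[!duplicated(key), , drop = FALSE]
  aff <- affinities[affinities$allele %in% alleles, , drop = FALSE]
  min_ic50 <- tapply(aff$ic50_nM, aff$peptide, min)
  missing <- setdiff(unique(psms$peptide), names(min_ic50))
  if (length(missing))
    stop("no affinity record for the subject's alleles for peptide(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  psms$min_ic50 <- as.numeric(min_ic50[psms$peptide])
  rownames(psms) <- NULL
  psms
}

#' Compute the target-decoy FDR at a threshold pair
#'
#' A (collapsed, peptide-level) record passes when its score is at least
#' `score_min` and its minimum IC50 across the subject's alleles is at most
#' `ic50_max_nM`. The FDR is 100 x (passing decoys) / (passing targets);
#' with zero passing targets the FDR is undefined and reported as `Inf` so it
#' fails any `<=` comparison.
#'
#' @param psms PSM data.frame (peptide, score, database, is_decoy).
#' @param affinities Affinity data.frame (peptide, allele, ic50_nM).
#' @param score_min,ic50_max_nM Threshold pair.
#' @param alleles The subject's HLA allele names.
#' @return List with n_targets, n_decoys and fdr_percent.
#' @export
compute_fdr <- function(psms, affinities, score_min, ic50_max_nM, alleles) {
  cp <- collapse_psms(psms, affinities, alleles)
  .fdr_at(cp, score_min, ic50_max_nM)
}

.fdr_at <- function(collapsed, score_min, ic50_max_nM) {
  pass <- collapsed$score >= score_min & collapsed$min_ic50 <= ic50_max_nM
  n_targets <- sum(pass & !collapsed$is_decoy)
  n_decoys <- sum(pass & collapsed$is_decoy)
  fdr <- if (n_targets > 0L) 100 * n_decoys / n_targets else Inf
  list(n_targets = n_targets, n_decoys = n_decoys, fdr_percent = fdr)
}

#' Optimize joint score/affinity thresholds at a target FDR
#'
#' Searches the grid of observed scores x observed per-peptide minimum
#' affinities and returns the pair admitting the largest number of target
#' peptides subject to the decoy FDR bound. Ties are broken toward lower
#' FDR, then lower score threshold, then higher (more permissive) affinity
#' threshold.
#'
#' @inheritParams compute_fdr
#' @param fdr_target_percent Target FDR in percent (default 5).
#' @return List with score_min, ic50_max_nM and the [compute_fdr()] result at
#'   the chosen pair.
#' @export
optimize_thresholds <- function(psms, affinities, alleles, fdr_target_percent = 5) {
  cp <- collapse_psms(psms, affinities, alleles)
  if (!any(!cp$is_decoy)) stop("no target PSMs")
  scores <- sort(unique(cp$score))
  ic50s <- sort(unique(cp$min_ic50))
  # counts with score >= s_i and min_ic50 <= a_j, by 2-D cumulative sums
  counts_at <- function(records) {
    m <- matrix(0L, length(scores), length(ic50s))
    if (nrow(records) > 0L) {
      i <- match(records$score, scores)
      j <- match(records$min_ic50, ic50s)
      for (r in seq_along(i)) m[i[r], j[r]] <- m[i[r], j[r]] + 1L
    }
    m <- apply(m, 2L, function(col) rev(cumsum(rev(col))))
    m <- matrix(m, length(scores), length(ic50s))
    t(apply(m, 1L, cumsum))
  }
  n_t <- counts_at(cp[!cp$is_decoy, , drop = FALSE])
  n_t <- matrix(n_t, length(scores), length(ic50s))
  n_d <- matrix(counts_at(cp[cp$is_decoy, , drop = FALSE]),
                length(scores), length(ic50s))
  fdr <- ifelse(n_t > 0L, 100 * n_d / n_t, Inf)
  admissible <- fdr <= fdr_target_percent
  if (!any(admissible))
    stop("no admissible threshold pair at ", fdr_target_percent, "% FDR")
  max_t <- max(n_t[admissible])
  idx <- which(admissible & n_t == max_t, arr.ind = TRUE)
  o <- order(fdr[idx], scores[idx[, 1L]], -ic50s[idx[, 2L]])
  pick <- idx[o[1L], ]
  list(score_min = scores[pick[1L]], ic50_max_nM = ic50s[pick[2L]],
       fdr = list(n_targets = n_t[pick[1L], pick[2L]],
                  n_decoys = n_d[pick[1L], pick[2L]],
                  fdr_percent = fdr[pick[1L], pick[2L]]))
}

#' Accepted target peptides at a threshold pair
#'
#' @inheritParams compute_fdr
#' @param database Restrict to records from this database label (NULL = all).
#' @return Character vector of accepted (non-decoy) peptides.
#' @export
accepted_peptides <- function(psms, affinities, score_min, ic50_max_nM, alleles,
                              database = NULL) {
  cp <- collapse_psms(psms, affinities, alleles)
  if (!is.null(database)) cp <- cp[cp$database %in% database, , drop = FALSE]
  pass <- cp$score >= score_min & cp$min_ic50 <= ic50_max_nM & !cp$is_decoy
  sort(unique(cp$peptide[pass]))
}

#' Split accepted identifications into conventional and putative cryptic MAPs
#'
#' Peptides identified by both databases are conventional; peptides
#' identified only by the all-frames database are putative cryptic.
#' Control-only peptides (unexpected, since the all-frames database derives
#' from the same reads) are reported with a warning.
#'
#' @param accepted_allframes,accepted_control Character vectors of accepted
#'   peptides per database.
#' @return List with `conventional`, `putative_cryptic` and `control_only`.
#' @export
split_conventional_cryptic <- function(accepted_allframes, accepted_control) {
  conventional <- sort(intersect(accepted_allframes, accepted_control))
  cryptic <- sort(setdiff(accepted_allframes, accepted_control))
  control_only <- sort(setdiff(accepted_control, accepted_allframes))
  if (length(control_only))
    warning(length(control_only), " peptide(s) accepted from the control ",
            "database only")
  list(conventional = conventional, putative_cryptic = cryptic,
       control_only = control_only)
}
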